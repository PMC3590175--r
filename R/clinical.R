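#' Partial correlation controlling for covariates
#'
#' Residualises `x` and `y` on an intercept plus the covariate columns and
#' takes the Pearson correlation of the residuals; with no covariates this
#' reduces to the plain Pearson correlation. The two-tailed p-value comes
#' from t = r sqrt((n - 2 - k) / (1 - r^2)) on n - 2 - k degrees of
#' freedom, where k is the number of (independent) covariates. Collinear
#' covariate columns are dropped with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix / data.frame (n rows) of
#'   control variables.
#' @return list with `r` (partial correlation), `p` (two-tailed), `df`,
#'   `n`, `k`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    z <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    z <- as.matrix(covariates)
    stopifnot(nrow(z) == n)
  }
  design <- cbind(intercept = 1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("collinear covariates; dropping ",
            ncol(design) - qrd$rank, " column(s)")
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  k <- ncol(design) - 1L
  if (n <= k + 2L)
    stop("need n > k + 2 observations (n = ", n, ", k = ", k, ")")
  rx <- x - design %*% qr.coef(qrd, x)
  ry <- y - design %*% qr.coef(qrd, y)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n, k = k)
}

#' Regional ALFF versus drug-use history
#'
#' For each dependent-group (group B) subject, the mean standardized ALFF
#' over the region of interest is correlated with drug-use duration
#' (months) and daily dose (g/day), partialling out age, education and
#' nicotine use. Subjects with missing covariates or drug-use values are
#' dropped with a warning. P-values are reported per variable without
#' multiplicity correction by default; `bonferroni = TRUE` multiplies them
#' by the number of variables tested.
#'
#' @param maps named list of standardized `alff_map`s (or 3D arrays),
#'   names matching `manifest$subject`.
#' @param roi region of interest (linear indices, index matrix, or
#'   logical array).
#' @param manifest cohort manifest data.frame (see [read_manifest()]).
#' @param use_vars drug-use variable columns to test.
#' @param control_vars covariate columns to partial out.
#' @param alpha significance level for the `significant` flag.
#' @param bonferroni apply Bonferroni correction across `use_vars`.
#' @return data.frame with one row per variable: `variable`, `r_partial`,
#'   `p`, `df`, `n`, `significant`.
#' @export
alff_use_association <- function(maps, roi, manifest,
                                 use_vars = c("duration", "dose"),
                                 control_vars = c("age", "education",
                                                  "nicotine"),
                                 alpha = 0.05, bonferroni = FALSE) {
  b <- manifest[manifest$group == "B", , drop = FALSE]
  stopifnot(nrow(b) >= 1L, all(use_vars %in% names(b)),
            all(control_vars %in% names(b)))
  missing_maps <- setdiff(b$subject, names(maps))
  if (length(missing_maps) > 0L)
    stop("no ALFF map for subject(s): ",
         paste(missing_maps, collapse = ", "))
  alff <- vapply(b$subject, function(id)
    regional_mean_alff(maps[[id]], roi), numeric(1L))
  rows <- lapply(use_vars, function(v) {
    ok <- stats::complete.cases(b[, c(v, control_vars)])
    if (any(!ok))
      warning(sum(!ok), " subject(s) dropped for missing ", v,
              " or covariates")
    pc <- partial_correlation(alff[ok], b[[v]][ok],
                              b[ok, control_vars, drop = FALSE])
    data.frame(variable = v, r_partial = pc$r, p = pc$p, df = pc$df,
               n = pc$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * length(use_vars))
  out$significant <- out$p < alpha
  out
}

#' Two-sample demographic tests from summary statistics or raw values
#'
#' Pooled-variance (Student) two-sample t tests for each demographic
#' variable, either from per-group mean / SD / n summaries (as printed in
#' a demographics table) or from raw per-subject values. With summaries
#' computed from the raw data the two modes agree exactly. A Welch option
#' is available for raw data.
#'
#' @param summaries data.frame with columns `variable`, `mean_A`, `sd_A`,
#'   `n_A`, `mean_B`, `sd_B`, `n_B` (summary mode), or `NULL`.
#' @param manifest cohort manifest (raw mode) with a `group` column.
#' @param variables columns of `manifest` to test (raw mode).
#' @param welch use Welch's unequal-variance t (raw mode only).
#' @return data.frame with `variable`, `t`, `df`, `p`. The sign convention
#'   is group B minus group A.
#' @export
demographic_tests <- function(summaries = NULL, manifest = NULL,
                              variables = c("age", "education", "nicotine"),
                              welch = FALSE) {
  if (!is.null(summaries)) {
    req <- c("variable", "mean_A", "sd_A", "n_A", "mean_B", "sd_B", "n_B")
    stopifnot(all(req %in% names(summaries)))
    rows <- lapply(seq_len(nrow(summaries)), function(i) {
      s <- summaries[i, ]
      if (s$n_A < 2L || s$n_B < 2L) stop("need n >= 2 in each group")
      df <- s$n_A + s$n_B - 2
      sp2 <- ((s$n_A - 1) * s$sd_A^2 + (s$n_B - 1) * s$sd_B^2) / df
      tval <- (s$mean_B - s$mean_A) / sqrt(sp2 * (1 / s$n_A + 1 / s$n_B))
      data.frame(variable = s$variable, t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  stopifnot(!is.null(manifest), "group" %in% names(manifest))
  rows <- lapply(variables, function(v) {
    a <- manifest[[v]][manifest$group == "A"]
    b <- manifest[[v]][manifest$group == "B"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in each group")
    tt <- stats::t.test(b, a, var.equal = !welch)
    data.frame(variable = v, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
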