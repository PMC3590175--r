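#' Construct a BOLD series object
#'
#' Lightweight container for one subject's 4D BOLD acquisition: the data
#' array (X x Y x Z x T), the repetition time, and the voxel-to-world
#' affine (NIfTI convention, 0-based indices).
#'
#' @param data 4D numeric array.
#' @param tr_s repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix.
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, tr_s, affine) {
  stopifnot(length(dim(data)) == 4L, tr_s > 0,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, tr_s = tr_s, affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d frames, TR = %g s\n",
              d[1L], d[2L], d[3L], d[4L], x$tr_s))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

#' Read / write a 4D BOLD volume in NIfTI-1 format
#'
#' `read_bold()` loads a 4D NIfTI-1 file (plain or gzipped) into a
#' [bold_series()]; the TR is taken from the header's fourth pixdim unless
#' `tr_s` overrides it (a mismatch is reported with a warning).
#' `write_bold()` writes one, storing the TR in the header.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tr_s optional TR override in seconds; `NULL` trusts the header.
#' @param x a `bold_series`.
#' @return `read_bold()` a `bold_series`; `write_bold()` `path`, invisibly.
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D NIfTI volume, got ", length(d), "D: ", path)
  hdr_tr <- RNifti::pixdim(img)[4L]
  if (is.null(tr_s)) {
    if (!is.finite(hdr_tr) || hdr_tr <= 0)
      stop("no usable TR in header of ", path, "; pass tr_s explicitly")
    tr_s <- hdr_tr
  } else if (is.finite(hdr_tr) && hdr_tr > 0 &&
             abs(hdr_tr - tr_s) > 1e-6) {
    warning(sprintf("TR mismatch for %s: header %g s, config %g s; using config",
                    path, hdr_tr, tr_s))
  }
  aff <- unclass(RNifti::xform(img))
  bold_series(array(as.numeric(img), dim = d), tr_s = tr_s,
              affine = matrix(as.numeric(aff), 4L, 4L))
}

#' @rdname read_bold
#' @export
write_bold <- function(x, path) {
  stopifnot(inherits(x, "bold_series"))
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(x$data, reference = NULL)
  img <- RNifti::`pixdim<-`(img, c(vs, x$tr_s))
  img <- RNifti::`qform<-`(img, structure(x$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a 3D map as NIfTI-1
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path file path.
#' @return `read_map()` a list with `values` and `affine`;
#'   `write_map()` `path`, invisibly.
#' @export
write_map <- function(values, affine, path) {
  stopifnot(length(dim(values)) == 3L)
  img <- RNifti::asNifti(values, reference = NULL)
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(affine[1:3, 1:3]^2)))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  aff <- unclass(RNifti::xform(img))
  list(values = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(aff), 4L, 4L))
}

#' Read / write rigid-body motion traces
#'
#' Motion traces follow the SPM `rp_*.txt` dialect: whitespace-delimited
#' text, one row per frame, six columns — three translations in mm followed
#' by three rotations in degrees.
#'
#' @param path file path.
#' @param trace numeric matrix with 6 columns.
#' @return `read_motion()` a T x 6 numeric matrix; `write_motion()` `path`.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion trace must have 6 columns, got ", ncol(m), ": ", path)
  dimnames(m) <- list(NULL,
    c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg"))
  m
}

#' @rdname read_motion
#' @export
write_motion <- function(trace, path) {
  stopifnot(is.matrix(trace), ncol(trace) == 6L)
  utils::write.table(format(trace, scientific = FALSE, digits = 8),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write the cohort subject manifest
#'
#' The manifest is a TSV with one row per subject: subject id, group label
#' (`A` = control, `B` = dependent), demographic covariates (age years,
#' education years, nicotine cigarettes/day), drug-use variables for group B
#' (duration months, dose g/day; `NA` for group A), and the paths of the
#' subject's BOLD and motion files.
#'
#' @param manifest a data.frame as produced by [generate_cohort()].
#' @param path TSV path.
#' @return `read_manifest()` a data.frame; `write_manifest()` `path`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
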