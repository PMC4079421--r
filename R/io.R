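# File formats: tensor volumes as 4D NIfTI with 6 lower-triangular
# components per voxel, FSL-style bval/bvec text files, and delimited
# evaluation reports. NIfTI handling is delegated to RNifti; every volume
# written here gets a small JSON sidecar recording provenance (component
# order, unit, config, seed) since the NIfTI header cannot carry it.

write_sidecar <- function(path, extra = list()) {
  meta <- c(list(package = "dtnlm",
                 version = as.character(utils::packageVersion("dtnlm")),
                 component_order = c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz",
                                     "Dzz")),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

#' Read a tensor field from NIfTI
#'
#' Expects a 4D volume with exactly 6 components per voxel in the
#' lower-triangular order `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Optional logical array; default marks voxels with any
#'   nonzero component as foreground.
#' @param unit Diffusivity unit of the stored components.
#' @return A [tensor_field()].
#' @export
read_tensor_nifti <- function(path, mask = NULL,
                              unit = c("cm^2/s", "mm^2/s")) {
  unit <- match.arg(unit)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4L] != 6L)
    stop(sprintf(
      "expected a 4D NIfTI with 6 tensor components, got dimensions [%s]",
      paste(d, collapse = ", ")))
  voxdim <- RNifti::pixdim(img)[1:3]
  D <- array(as.numeric(img), d)
  if (is.null(mask)) mask <- array(rowSums(abs(matrix(D, prod(d[1:3]),
                                                      6L))) > 0, d[1:3])
  tensor_field(D, mask = mask, voxdim = voxdim, unit = unit)
}

#' Write a tensor field to NIfTI
#'
#' @param field A [tensor_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param sidecar Also write `<path>.json` with provenance metadata.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_tensor_nifti <- function(field, path, sidecar = TRUE, meta = list()) {
  img <- RNifti::asNifti(field$D, pixdim = c(field$voxdim, 1))
  RNifti::writeNifti(img, path)
  if (sidecar)
    write_sidecar(path, c(list(unit = field$unit,
                               voxdim = field$voxdim), meta))
  invisible(path)
}

#' Read FSL-style bval/bvec files
#'
#' `bval` is a single whitespace-separated row of b-values; `bvec` holds
#' three rows (x, y, z components), one column per volume.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [gradient_table()]. Directions off unit norm by more than 1e-3
#'   are renormalized with a warning.
#' @export
read_gradients <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- utils::read.table(bvec_path)
  if (nrow(rows) != 3L)
    stop(sprintf(
      "bvec file must have 3 rows (x, y, z), found %d; is it transposed?",
      nrow(rows)))
  bvecs <- t(as.matrix(rows))
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("bval lists %d volumes but bvec lists %d",
                 length(bvals), nrow(bvecs)))
  gradient_table(bvals, bvecs)
}

#' Write FSL-style bval/bvec files
#'
#' @param gtab A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @return `bval_path`, invisibly.
#' @export
write_gradients <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(gtab$bvecs), 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), bvec_path)
  invisible(bval_path)
}

#' Read a DWI set from NIfTI plus bval/bvec
#'
#' @param path 4D NIfTI of all volumes in gradient-table order (baselines
#'   first or interleaved; matched by the b-values).
#' @param bval_path,bvec_path FSL-style gradient files.
#' @param sigma Known noise standard deviation, if any.
#' @return A `dwi_set`. Multiple b0 volumes are averaged into the baseline.
#' @export
read_dwi_nifti <- function(path, bval_path, bvec_path, sigma = NA_real_) {
  gtab <- read_gradients(bval_path, bvec_path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4L] != length(gtab$bvals))
    stop("DWI volume count does not match the gradient table")
  vols <- array(as.numeric(img), d)
  dw <- gtab$bvals > 0
  s0 <- if (any(!dw)) {
    apply(vols[, , , !dw, drop = FALSE], 1:3, mean)
  } else stop("gradient table has no b = 0 baseline volume")
  structure(list(s0 = array(s0, d[1:3]),
                 signals = vols[, , , dw, drop = FALSE],
                 gtab = gtab, mask = array(TRUE, d[1:3]),
                 voxdim = RNifti::pixdim(img)[1:3], sigma = sigma),
            class = "dwi_set")
}

#' Write a DWI set to NIfTI plus bval/bvec
#'
#' @param dwi A `dwi_set`.
#' @param path Output NIfTI path; gradient files are written alongside with
#'   `.bval`/`.bvec` extensions unless given explicitly.
#' @param bval_path,bvec_path Optional explicit gradient-file paths.
#' @param meta Named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_dwi_nifti <- function(dwi, path, bval_path = NULL, bvec_path = NULL,
                            meta = list()) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  if (is.null(bval_path)) bval_path <- paste0(stem, ".bval")
  if (is.null(bvec_path)) bvec_path <- paste0(stem, ".bvec")
  dw <- dwi$gtab$bvals > 0
  sp <- dim(dwi$s0)
  vols <- array(NA_real_, c(sp, length(dwi$gtab$bvals)))
  vols[, , , !dw] <- dwi$s0
  vols[, , , dw] <- dwi$signals
  img <- RNifti::asNifti(vols, pixdim = c(dwi$voxdim, 1))
  RNifti::writeNifti(img, path)
  write_gradients(dwi$gtab, bval_path, bvec_path)
  write_sidecar(path, c(list(sigma = dwi$sigma), meta))
  invisible(path)
}

#' Write an evaluation report table
#'
#' Tab-delimited table with one row per method and columns
#' `method`, `mean_pd_deviation`, `mean_fa_deviation`.
#'
#' @param report Data frame as returned by [run_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
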