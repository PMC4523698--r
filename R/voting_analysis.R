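#' Decompose an accumulated tensor field into saliency maps
#'
#' Per-voxel eigendecomposition of the accumulated field with
#' `lambda1 >= lambda2 >= lambda3 >= 0` yields three feature maps, each a
#' 2-tuple (saliency `s`, unit direction `w`):
#'
#' * **S-map** (surfaceness): `s = lambda1 - lambda2`, `w = e1`. In the
#'   vessel pipeline this is the consensus vesselness and the direction along
#'   the vessel.
#' * **C-map** (curveness): `s = lambda2 - lambda3`, `w = e3`.
#' * **J-map** (junctionness): `s = lambda3`, direction arbitrary (zero).
#'
#' Voxels holding the zero tensor get `s = 0` and the sentinel direction
#' `w = (0,0,0)`; fusion treats sentinel directions as zero alignment.
#' Eigenvalues more negative than `-psd_tol * trace` raise an error naming
#' the offending voxel; tiny negatives are clamped to zero.
#'
#' @param tf a `tensor_field` from [cast_all_votes()].
#' @param psd_tol relative PSD tolerance (default `1e-8`).
#' @return List with elements `S`, `C`, `J` (each a `saliency_map`: list with
#'   `s` array, `w` array of dim `c(dim, 3)`, `kind`, `spacing`) and
#'   `lambdas` (nvox x 3).
#' @export
extract_maps <- function(tf, psd_tol = 1e-8) {
  stopifnot(inherits(tf, "tensor_field"))
  d <- tf$dim
  nvox <- prod(d)
  nz <- which(rowSums(abs(tf$field)) > 0)
  lam <- matrix(0, nvox, 3)
  e1 <- matrix(0, nvox, 3)
  e3 <- matrix(0, nvox, 3)
  if (length(nz)) {
    dec <- eig_sym_field_cpp(tf$field[nz, , drop = FALSE], FALSE)
    tr <- rowSums(dec$values)
    bad <- dec$values[, 3] < -psd_tol * pmax(tr, 0)
    if (any(bad)) {
      vox <- arrayInd(nz[which(bad)[1]], d)
      stop(sprintf(paste0("accumulated tensor is not PSD at voxel ",
                          "(%d, %d, %d): min eigenvalue %.3e"),
                   vox[1], vox[2], vox[3],
                   dec$values[which(bad)[1], 3]), call. = FALSE)
    }
    dec$values[dec$values < 0] <- 0
    lam[nz, ] <- dec$values
    e1[nz, ] <- dec$vec1
    e3[nz, ] <- dec$vec3
  }
  mk <- function(s, w, kind) {
    s <- pmax(s, 0)
    dim(s) <- d
    dim(w) <- c(d, 3L)
    structure(list(s = s, w = w, kind = kind, spacing = tf$spacing),
              class = "saliency_map")
  }
  list(S = mk(lam[, 1] - lam[, 2], e1, "S"),
       C = mk(lam[, 2] - lam[, 3], e3, "C"),
       J = mk(lam[, 3], matrix(0, nvox, 3), "J"),
       lambdas = lam)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %s-map, %s voxels, max saliency %.4g\n",
              x$kind, paste(dim(x$s), collapse = "x"), max(x$s)))
  invisible(x)
}

#' Construct a saliency map from raw arrays
#'
#' Mostly useful for tests and for re-importing maps written to NIfTI.
#'
#' @param s non-negative saliency array.
#' @param w direction array of dim `c(dim(s), 3)`; rows are renormalised to
#'   unit length where nonzero.
#' @param kind map kind label.
#' @param spacing voxel spacing in mm.
#' @return A `saliency_map`.
#' @export
saliency_map <- function(s, w, kind = "S", spacing = c(1, 1, 1)) {
  d <- dim(s)
  stopifnot(length(d) == 3L, all(dim(w) == c(d, 3L)), all(s >= 0))
  wm <- matrix(w, ncol = 3)
  nrm <- sqrt(rowSums(wm^2))
  pos <- nrm > 0
  wm[pos, ] <- wm[pos, , drop = FALSE] / nrm[pos]
  dim(wm) <- c(d, 3L)
  structure(list(s = s, w = wm, kind = kind, spacing = spacing),
            class = "saliency_map")
}

#' Write a saliency map's components as NIfTI volumes
#'
#' Writes `<prefix>_s.nii.gz` (scalar saliency) and `<prefix>_w.nii.gz`
#' (3-component direction field).
#'
#' @param map a `saliency_map`.
#' @param prefix output path prefix.
#' @param reference optional `niftiImage` header template.
#' @return Character vector of the two paths, invisibly.
#' @export
write_saliency_map <- function(map, prefix, reference = NULL) {
  stopifnot(inherits(map, "saliency_map"))
  ps <- paste0(prefix, "_s.nii.gz")
  pw <- paste0(prefix, "_w.nii.gz")
  write_volume(scalar_volume(map$s, spacing = map$spacing,
                             reference = reference), ps)
  img <- if (is.null(reference)) RNifti::asNifti(map$w, datatype = "float")
         else RNifti::asNifti(map$w, reference = reference, datatype = "float")
  RNifti::writeNifti(img, pw)
  invisible(c(ps, pw))
}
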