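#' 3-D scalar volume with physical voxel spacing
#'
#' Lightweight container for a 3-D intensity grid together with its voxel
#' spacing in millimetres and (optionally) the NIfTI image it was read from,
#' whose affine/orientation metadata is passed through unchanged on write.
#'
#' @param data 3-D numeric array, all values finite, each dimension >= 8.
#' @param spacing numeric length-3, strictly positive per-axis voxel size (mm).
#' @param reference optional `niftiImage` used as a header template on write.
#' @return An object of class `scalar_volume`: a list with elements `data`,
#'   `spacing` and `reference`.
#' @examples
#' vol <- scalar_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
#' dim(vol$data)
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), reference = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 8L))
    stop("all three volume dimensions must be >= 8", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel sizes in mm",
         call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume data must be finite everywhere", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, reference = reference),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

as_scalar_volume <- function(x, spacing = NULL) {
  if (inherits(x, "scalar_volume")) return(x)
  if (inherits(x, "niftiImage")) {
    sp <- RNifti::pixdim(x)[seq_len(3)]
    arr <- as.array(x)
    arr <- array(as.numeric(arr), dim = dim(arr))
    return(scalar_volume(arr, spacing = sp, reference = x))
  }
  scalar_volume(x, spacing = if (is.null(spacing)) c(1, 1, 1) else spacing)
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file and wraps it as a [scalar_volume()], keeping the
#' original image as header template for later writes. 4-D images with a
#' trailing singleton dimension are accepted and dropped to 3-D.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) d <- d[seq_len(3)]
  if (length(d) != 3L)
    stop("'", path, "' is not a 3-D volume (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  arr <- array(as.numeric(arr), dim = d)   # strip image attributes
  scalar_volume(arr, spacing = RNifti::pixdim(img)[seq_len(3)],
                reference = img)
}

#' Write a volume or array as 32-bit float NIfTI
#'
#' @param x `scalar_volume` or 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param reference optional `niftiImage` header template; defaults to the
#'   template stored in `x`, else a minimal header with the volume's spacing.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, reference = NULL) {
  if (inherits(x, "scalar_volume")) {
    if (is.null(reference)) reference <- x$reference
    spacing <- x$spacing
    arr <- x$data
  } else {
    arr <- x
    spacing <- c(1, 1, 1)
  }
  storage.mode(arr) <- "double"
  img <- if (is.null(reference)) {
    attr(arr, "pixdim") <- spacing
    RNifti::asNifti(arr, datatype = "float")
  } else {
    RNifti::asNifti(arr, reference = reference, datatype = "float")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
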