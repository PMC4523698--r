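#' Log-spaced scale ladder
#'
#' Scales (standard deviations of the Gaussian derivative kernels, in mm) are
#' distributed equally in log-space between `sigma_min` and `sigma_max`, the
#' standard choice for multi-scale tubular filters. The defaults elsewhere in
#' the package use 10 scales between 1.0 and 4.5 mm.
#'
#' @param sigma_min,sigma_max smallest and largest scale in mm,
#'   `0 < sigma_min < sigma_max` (or equal only if `n == 1`).
#' @param n number of scales, >= 2.
#' @return Numeric vector of `n` strictly increasing scales; endpoints exact.
#' @examples
#' make_scale_ladder(1, 4, 3) # 1, 2, 4 (geometric midpoint)
#' @export
make_scale_ladder <- function(sigma_min, sigma_max, n) {
  if (!is.numeric(sigma_min) || !is.numeric(sigma_max) ||
      sigma_min <= 0 || sigma_max <= sigma_min)
    stop("need 0 < sigma_min < sigma_max", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need n >= 2 scales", call. = FALSE)
  s <- exp(seq(log(sigma_min), log(sigma_max), length.out = n))
  s[1] <- sigma_min
  s[n] <- sigma_max
  s
}

# Reflect out-of-range 1-based indices back into [1, n] (whole-sample
# symmetric boundary, repeated reflection for kernels wider than the axis).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

# Sampled Gaussian (derivative) kernel at scale `sigma` voxels, with discrete
# moment correction so that order-1 responds to a unit ramp with exactly 1 and
# order-2 to x^2 with exactly 2 (interior voxels).
gaussian_kernel1d <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- switch(as.character(order),
              "0" = g,
              "1" = -x / sigma^2 * g,
              "2" = (x^2 - sigma^2) / sigma^4 * g)
  if (order == 0L) {
    k <- k / sum(k)
  } else if (order == 1L) {
    # out(x) = sum_o k_o f(x - o); for f = x this gives -sum(k_o * o)
    k <- k / (-sum(k * x))
  } else {
    k <- k - mean(k)               # zero response to constants
    k <- k * (2 / sum(k * x^2))    # exact response 2 to f = x^2
  }
  k
}

# Separable convolution of a 3-D array along one axis with reflect padding,
# implemented as a dense band-matrix multiply (axis lengths are modest).
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  j <- seq_len(n)
  for (t in seq_along(kernel)) {
    o <- t - r - 1L                     # offset in [-r, r]
    src <- reflect_index(j - o, n)
    K[cbind(j, src)] <- K[cbind(j, src)] + kernel[t]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  out <- K %*% matrix(ap, nrow = n)
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussian_derivative <- function(volume, sigma, orders) {
  v <- as_scalar_volume(volume)
  out <- v$data
  for (axis in 1:3) {
    sig_vox <- sigma / v$spacing[axis]
    k <- gaussian_kernel1d(sig_vox, orders[axis])
    out <- convolve_axis(out, k, axis)
    if (orders[axis] > 0L)
      out <- out / v$spacing[axis]^orders[axis]  # derivative w.r.t. mm
  }
  out
}

#' Gamma-normalised Hessian of a volume at one scale
#'
#' Second Gaussian derivatives at physical scale `sigma` (mm), computed
#' separably with per-axis kernels in voxel units (spacing-aware, no
#' resampling) and reflect boundary handling. The six independent components
#' are multiplied by `sigma^2` (gamma = 1 normalisation) so that responses are
#' comparable across scales and the per-voxel argmax over a scale ladder is
#' well posed.
#'
#' @param volume a [scalar_volume()] (or 3-D array, unit spacing assumed).
#' @param sigma scale in mm, > 0. A warning is issued when `sigma` is smaller
#'   than half the largest voxel spacing (under-resolved kernel).
#' @param gamma_normalize multiply by `sigma^2`? Default `TRUE`.
#' @return List of six arrays `h11, h12, h13, h22, h23, h33` plus `sigma`.
#' @export
hessian_at_scale <- function(volume, sigma, gamma_normalize = TRUE) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be a positive scale in mm", call. = FALSE)
  v <- as_scalar_volume(volume)
  if (sigma < max(v$spacing) / 2)
    warning("sigma = ", sigma, " mm is below half the largest voxel spacing (",
            max(v$spacing), " mm); Hessian is under-resolved", call. = FALSE)
  ords <- list(h11 = c(2, 0, 0), h12 = c(1, 1, 0), h13 = c(1, 0, 1),
               h22 = c(0, 2, 0), h23 = c(0, 1, 1), h33 = c(0, 0, 2))
  g <- if (gamma_normalize) sigma^2 else 1
  out <- lapply(ords, function(o) g * gaussian_derivative(v, sigma, o))
  out$sigma <- sigma
  out
}

# Vectorised analytic eigenvalues of symmetric 3x3 matrices given as six
# component vectors; returns algebraically sorted l1 >= l2 >= l3.
eig3_vals_desc <- function(h11, h12, h13, h22, h23, h33) {
  p1 <- h12^2 + h13^2 + h23^2
  q <- (h11 + h22 + h33) / 3
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  scale_ref <- pmax(abs(h11), abs(h22), abs(h33), sqrt(p1))
  iso <- p <= 1e-14 * pmax(scale_ref, 1e-300)
  ps <- ifelse(iso, 1, p)
  b11 <- (h11 - q) / ps; b22 <- (h22 - q) / ps; b33 <- (h33 - q) / ps
  b12 <- h12 / ps; b13 <- h13 / ps; b23 <- h23 / ps
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  list(l1 = l1, l2 = l2, l3 = l3)
}

# Reorder algebraically sorted eigenvalues by absolute value:
# |k3| >= |k2| >= |k1|. l2 can never have the largest magnitude.
kappas_by_abs <- function(l1, l2, l3) {
  first_big <- abs(l1) >= abs(l3)
  k3 <- ifelse(first_big, l1, l3)
  rest_a <- ifelse(first_big, l2, l1)
  rest_b <- ifelse(first_big, l3, l2)
  a_big <- abs(rest_a) >= abs(rest_b)
  k2 <- ifelse(a_big, rest_a, rest_b)
  k1 <- ifelse(a_big, rest_b, rest_a)
  list(k1 = k1, k2 = k2, k3 = k3)
}

# Deterministic eigenvector sign: largest-magnitude component positive
# (ties resolved to the first such component by which.max).
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Eigendecomposition of a symmetric 3x3 matrix, ordered by magnitude
#'
#' Eigenvalues are returned as `(kappa1, kappa2, kappa3)` with
#' `|kappa3| >= |kappa2| >= |kappa1|` (the ordering used throughout the
#' tubular-structure analysis), with matched orthonormal eigenvectors. Each
#' eigenvector's sign is fixed so that its largest-magnitude component is
#' positive, for determinism.
#'
#' @param H symmetric 3x3 numeric matrix.
#' @param tol relative symmetry tolerance; asymmetry beyond it is an error.
#' @return List with `kappas` (length 3, `|.|`-ascending) and `vectors`
#'   (3x3 matrix whose columns `v1, v2, v3` match `kappas`).
#' @export
eigendecompose <- function(H, tol = 1e-8) {
  if (!is.matrix(H) || !all(dim(H) == c(3L, 3L)) || !is.numeric(H))
    stop("`H` must be a numeric 3x3 matrix", call. = FALSE)
  asym <- max(abs(H - t(H)))
  if (asym > tol * max(1, max(abs(H))))
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  Hs <- (H + t(H)) / 2
  e <- eigen(Hs, symmetric = TRUE)         # values decreasing
  ord <- order(abs(e$values))              # |k1| <= |k2| <= |k3|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (max(abs(Hs)) == 0) {
    vals <- c(0, 0, 0)
    vecs <- diag(3)
  }
  for (j in 1:3) vecs[, j] <- fix_sign(vecs[, j])
  list(kappas = vals, vectors = vecs)
}

#' Vesselness filter parameters
#'
#' Parameters of the tube-likeness functions built from the magnitude-ordered
#' Hessian eigenvalues. Two variants share the interface:
#' `"manniesing"` (default), the smooth vesselness used for vessel-enhancing
#' diffusion — the three classic factors times a smoothing term
#' `exp(-2C^2 / (|kappa2| kappa3^2))` that removes the hard cutoff at
#' `kappa2 = 0`; and `"frangi"`, the classic alpha/beta/c form.
#'
#' @param variant `"manniesing"` or `"frangi"`.
#' @param alpha sensitivity of the plate-vs-line ratio `|k2|/|k3|`
#'   (default 0.5, the published guideline).
#' @param beta sensitivity of the blob ratio `|k1|/sqrt(|k2 k3|)`
#'   (default 0.5).
#' @param c structureness (Frobenius norm) sensitivity; `NULL` (default)
#'   resolves adaptively to half the maximum Frobenius norm of the
#'   gamma-normalised Hessian over the whole scale ladder.
#' @param C smoothness constant of the `"manniesing"` variant; only active
#'   near the `kappa2 = 0` boundary. Default `1e-6`.
#' @return A list of class `vesselness_params`.
#' @export
vesselness_params <- function(variant = c("manniesing", "frangi"),
                              alpha = 0.5, beta = 0.5, c = NULL, C = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, beta > 0, is.null(c) || c > 0, C >= 0)
  structure(list(variant = variant, alpha = alpha, beta = beta, c = c, C = C),
            class = "vesselness_params")
}

#' Vesselness response from magnitude-ordered Hessian eigenvalues
#'
#' Bright-vessel convention: the response is 0 wherever `kappa2 >= 0` or
#' `kappa3 >= 0`, in (0, 1] for ideal bright tubes, and smooth in the
#' eigenvalues. Inputs may be vectors/arrays (evaluated voxel-wise) or the
#' list returned by [eigendecompose()].
#'
#' @param k1,k2,k3 eigenvalues with `|k3| >= |k2| >= |k1|`; alternatively
#'   `k1` may be an [eigendecompose()] result or a length-3 vector.
#' @param params a [vesselness_params()]; its `c` must be resolved
#'   (non-`NULL`) unless all eigenvalues are zero.
#' @return Vesselness values in `[0, 1]`, same shape as the input.
#' @export
vesselness <- function(k1, k2 = NULL, k3 = NULL, params = vesselness_params()) {
  if (is.list(k1) && !is.null(k1$kappas)) {
    k <- k1$kappas; k1 <- k[1]; k2 <- k[2]; k3 <- k[3]
  } else if (is.null(k2) && length(k1) == 3L) {
    k <- k1; k1 <- k[1]; k2 <- k[2]; k3 <- k[3]
  }
  cpar <- params$c
  if (is.null(cpar)) {
    smax <- sqrt(max(k1^2 + k2^2 + k3^2))
    cpar <- if (smax > 0) smax / 2 else 1
  }
  ra2 <- k2^2 / pmax(k3^2, 1e-300)
  rb2 <- k1^2 / pmax(abs(k2 * k3), 1e-300)
  s2 <- k1^2 + k2^2 + k3^2
  v <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
    exp(-rb2 / (2 * params$beta^2)) *
    (1 - exp(-s2 / (2 * cpar^2)))
  if (params$variant == "manniesing" && params$C > 0) {
    denom <- pmax(abs(k2) * k3^2, 1e-300)
    v <- v * exp(-2 * params$C^2 / denom)
  }
  v[k2 >= 0 | k3 >= 0] <- 0
  v
}

#' Multi-scale vesselness analysis of a volume
#'
#' Computes gamma-normalised Hessians and their magnitude-ordered eigenvalues
#' over a log-spaced scale ladder, the vesselness response at every scale, the
#' optimal-scale image `M(x) = argmax_sigma nu(x, sigma)` (ties broken toward
#' the smallest scale), the per-voxel maximum response `nu_max`, and the
#' bright-tube sign condition `kappa2 < 0 & kappa3 < 0` tracked across scales
#' for token selection. When the vesselness `c` parameter is `NULL` it is
#' resolved to half the maximum Hessian Frobenius norm over all scales, so
#' that responses at different scales are compared on a common footing.
#'
#' @param volume a [scalar_volume()] (or 3-D array).
#' @param ladder scale ladder from [make_scale_ladder()]; default 10 scales,
#'   1.0--4.5 mm.
#' @param params [vesselness_params()].
#' @param invert set `TRUE` for dark-vessel inputs; intensities are negated
#'   so the bright-vessel sign condition applies unchanged.
#' @return An object of class `scale_space`: list with `nu` (per-scale
#'   response arrays), `M` (optimal scale, mm), `M_idx` (ladder index),
#'   `nu_max`, `cond` (token sign condition satisfied at >= 1 scale),
#'   `hessians` and `kappas` per scale, `ladder`, resolved `params`,
#'   `spacing`, and the (possibly inverted) input `volume`.
#' @export
build_scale_space <- function(volume, ladder = make_scale_ladder(1.0, 4.5, 10),
                              params = vesselness_params(), invert = FALSE) {
  v <- as_scalar_volume(volume)
  if (isTRUE(invert)) v$data <- -v$data
  if (!is.numeric(ladder) || length(ladder) < 2L || any(diff(ladder) <= 0))
    stop("`ladder` must be >= 2 strictly increasing scales", call. = FALSE)
  nsc <- length(ladder)
  hessians <- vector("list", nsc)
  kappas <- vector("list", nsc)
  smax <- 0
  for (i in seq_len(nsc)) {
    H <- hessian_at_scale(v, ladder[i])
    ev <- eig3_vals_desc(H$h11, H$h12, H$h13, H$h22, H$h23, H$h33)
    kp <- kappas_by_abs(ev$l1, ev$l2, ev$l3)
    smax <- max(smax, sqrt(max(kp$k1^2 + kp$k2^2 + kp$k3^2)))
    hessians[[i]] <- H
    kappas[[i]] <- kp
  }
  params_res <- params
  if (is.null(params_res$c)) params_res$c <- if (smax > 0) smax / 2 else 1
  nu <- vector("list", nsc)
  d <- dim(v$data)
  best_nu <- array(-Inf, d)
  best_idx <- array(1L, d)
  cond <- array(FALSE, d)
  # curvature significance floor: well below any real structure, well above
  # the convolution roundoff of a flat region (which would otherwise pass
  # the strict sign test with noise-level |kappa|)
  tau <- 1e-12 * max(abs(v$data))
  for (i in seq_len(nsc)) {
    kp <- kappas[[i]]
    dark <- kp$k2 >= -tau | kp$k3 >= -tau
    nui <- vesselness(kp$k1, kp$k2, kp$k3, params_res)
    nui[dark] <- 0
    dim(nui) <- d
    nu[[i]] <- nui
    upd <- nui > best_nu            # strict: ties keep the smaller scale
    best_idx[upd] <- i
    best_nu[upd] <- nui[upd]
    cond <- cond | !dark
  }
  M <- array(ladder[best_idx], d)
  structure(list(nu = nu, M = M, M_idx = best_idx, nu_max = best_nu,
                 cond = cond, hessians = hessians, kappas = kappas,
                 ladder = ladder, params = params_res, spacing = v$spacing,
                 volume = v),
            class = "scale_space")
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf(paste0("<scale_space> %s voxels, %d scales [%.3g, %.3g] mm, ",
                     "%d candidate tokens\n"),
              paste(dim(x$M), collapse = "x"), length(x$ladder),
              min(x$ladder), max(x$ladder), sum(x$cond)))
  invisible(x)
}

#' Select voting tokens from a scale space
#'
#' A voxel is admitted as a token iff the bright-tube sign condition
#' `kappa2 < 0 & kappa3 < 0` holds at at least one scale (intersected with an
#' optional region mask). Each admitted token carries the Hessian eigensystem
#' at its locally optimal scale `M(x)`, magnitude-ordered with the
#' deterministic sign convention, along with its optimal scale, vesselness
#' and image intensity — everything the tensor initialisation strategies need.
#'
#' @param ss a `scale_space` from [build_scale_space()].
#' @param mask optional logical/0-1 array on the same grid (e.g. an
#'   intracranial mask), applied before token selection.
#' @return Object of class `token_set`: list with `index` (linear voxel
#'   indices), `ijk` (n x 3 voxel coordinates), `scale_idx`, `M` (mm), `nu`,
#'   `intensity`, `kappas` (n x 3: kappa1..3), `v1`, `v2`, `v3` (n x 3
#'   eigenvectors), plus grid metadata (`dim`, `spacing`, `ladder`).
#' @export
select_tokens <- function(ss, mask = NULL) {
  stopifnot(inherits(ss, "scale_space"))
  keep <- ss$cond
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(keep)))
      stop("mask grid does not match the volume grid", call. = FALSE)
    keep <- keep & (mask > 0)
  }
  idx <- which(keep)
  n <- length(idx)
  ijk <- arrayInd(idx, dim(keep))
  scale_idx <- ss$M_idx[idx]
  kap <- matrix(0, n, 3)
  v1 <- matrix(0, n, 3); v2 <- matrix(0, n, 3); v3 <- matrix(0, n, 3)
  if (n > 0) {
    Hmat <- matrix(0, n, 6)
    for (s in unique(scale_idx)) {
      rows <- which(scale_idx == s)
      H <- ss$hessians[[s]]
      ii <- idx[rows]
      Hmat[rows, ] <- cbind(H$h11[ii], H$h12[ii], H$h13[ii],
                            H$h22[ii], H$h23[ii], H$h33[ii])
    }
    dec <- eig3_abs_field(Hmat)
    kap <- dec$kappas
    v1 <- dec$v1; v2 <- dec$v2; v3 <- dec$v3
  }
  structure(list(index = idx, ijk = ijk, scale_idx = scale_idx,
                 M = ss$ladder[scale_idx], nu = ss$nu_max[idx],
                 intensity = ss$volume$data[idx], kappas = kap,
                 v1 = v1, v2 = v2, v3 = v3,
                 dim = dim(keep), spacing = ss$spacing, ladder = ss$ladder),
            class = "token_set")
}

#' @export
print.token_set <- function(x, ...) {
  cat(sprintf("<token_set> %d tokens on a %s grid\n", length(x$index),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# Magnitude-ordered eigendecomposition of many symmetric 3x3 matrices
# (n x 6 matrix of h11,h12,h13,h22,h23,h33), C++-backed.
eig3_abs_field <- function(Hmat) {
  res <- eig_sym_field_cpp(Hmat, TRUE)
  list(kappas = res$values, v1 = res$vec1, v2 = res$vec2, v3 = res$vec3)
}
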