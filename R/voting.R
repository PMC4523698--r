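#' Tensor voting parameters
#'
#' Controls the vote kernels. The decay width is tied to the voter's window:
#' `sigma_d = decay_fraction * N_q` with `N_q = 2 M(q)` mm, so votes are
#' negligible at the window edge. The curvature penalty is
#' `c = curvature_weight * sigma_d^4`, i.e. an arc whose curvature radius
#' equals `sigma_d` is penalised by `exp(-curvature_weight)` (dimensionally
#' consistent: arc curvature enters as `c * kappa_arc^2 / sigma_d^2`).
#'
#' @param angular_cutoff_deg angular cutoff of the stick kernel in degrees,
#'   in (0, 90]; votes are zero when the receiver lies further than this from
#'   the voter's tangent line. Default 45.
#' @param curvature_weight dimensionless curvature penalty (default 1).
#' @param decay_fraction `sigma_d / N_q` (default 1/3; the vote decays to
#'   `exp(-9)` at the window edge).
#' @param n_phi nodes of the (exact, trigonometric) circle rule for plate
#'   votes over orientation period `[0, pi)`; default 16.
#' @param n_theta Gauss-Legendre nodes of the ball vote's polar integral over
#'   `[0, cutoff]`; default 48.
#' @return List of class `vote_params`.
#' @export
vote_params <- function(angular_cutoff_deg = 45, curvature_weight = 1,
                        decay_fraction = 1 / 3, n_phi = 16L, n_theta = 48L) {
  stopifnot(angular_cutoff_deg > 0, angular_cutoff_deg <= 90,
            curvature_weight >= 0, decay_fraction > 0,
            n_phi >= 4L, n_theta >= 8L)
  structure(list(cutoff = angular_cutoff_deg * pi / 180,
                 curvature_weight = curvature_weight,
                 decay_fraction = decay_fraction,
                 n_phi = as.integer(n_phi), n_theta = as.integer(n_theta)),
            class = "vote_params")
}

phi_nodes <- function(params) {
  pi * (seq_len(params$n_phi) - 1) / params$n_phi
}

theta_quadrature <- function(params) {
  pracma::gaussLegendre(params$n_theta, 0, params$cutoff)
}

#' Scale-adaptive voting window half-width
#'
#' The physical window half-width is `N_p = 2 M(p)` mm, converted per axis to
#' voxels with a ceiling rule and a floor of 1 voxel.
#'
#' @param M_p optimal scale(s) in mm.
#' @param spacing per-axis voxel size in mm.
#' @return Integer half-widths; a vector (per axis) for scalar `M_p`, or an
#'   `length(M_p) x 3` matrix otherwise.
#' @export
voting_window <- function(M_p, spacing) {
  hw <- ceiling(outer(2 * M_p, spacing, "/"))
  hw[hw < 1] <- 1
  storage.mode(hw) <- "integer"
  if (length(M_p) == 1L) hw[1, ] else hw
}

# Shared arc-kernel geometry: theta in [0, pi/2] from the tangent line,
# arc length l*theta/sin(theta), curvature 2*sin(theta)/l.
arc_decay <- function(l, theta, sigma_d, curv_c) {
  st <- sin(theta)
  if (st < 1e-12) {
    s_arc <- l
    kap <- 0
  } else {
    s_arc <- l * theta / st
    kap <- 2 * st / l
  }
  exp(-(s_arc^2 + curv_c * kap^2) / sigma_d^2)
}

#' Single stick/plate/ball votes (reference implementations)
#'
#' Plain-R vote kernels used as the unit of specification: the compiled
#' accumulator in [cast_all_votes()] reproduces these to near machine
#' precision. A stick vote from a voter with unit tangent `e1` at displacement
#' `v` (receiver minus voter, mm) is the arc-rotated rank-1 tensor scaled by
#' the arc decay; it is zero beyond the angular cutoff and returns the stick
#' component itself at `v = 0`. Plate votes average unit stick votes over the
#' plate plane's orientation circle (factor 2, period pi); ball votes reduce
#' the orientation-sphere integral to a 1-D polar quadrature by azimuthal
#' symmetry, scaled so the self-vote returns the ball component.
#'
#' @param v displacement receiver - voter, length-3, mm.
#' @param e1,e2 unit orientation vectors (stick tangent; plate plane basis).
#' @param saliency component saliency (stick `lambda1-lambda2`, plate
#'   `lambda2-lambda3`, ball `lambda3`).
#' @param sigma_d decay width in mm.
#' @param params [vote_params()].
#' @return A 3x3 symmetric PSD matrix.
#' @export
stick_vote <- function(v, e1, saliency = 1, sigma_d,
                       params = vote_params()) {
  l <- sqrt(sum(v^2))
  if (l == 0) return(saliency * tcrossprod(e1))
  curv_c <- params$curvature_weight * sigma_d^4
  ct <- sum(v * e1) / l
  es <- if (ct < 0) -e1 else e1
  ct <- min(abs(ct), 1)
  theta <- acos(ct)
  if (theta > params$cutoff + 1e-12) return(matrix(0, 3, 3))
  st <- sin(theta)
  if (st < 1e-12) {
    tp <- es
  } else {
    b <- v / l - ct * es
    b <- b / sqrt(sum(b^2))
    tp <- cos(2 * theta) * es + sin(2 * theta) * b
  }
  saliency * arc_decay(l, theta, sigma_d, curv_c) * tcrossprod(tp)
}

#' @rdname stick_vote
#' @export
plate_vote <- function(v, e1, e2, saliency = 1, sigma_d,
                       params = vote_params()) {
  if (sum(v^2) == 0) return(saliency * (tcrossprod(e1) + tcrossprod(e2)))
  phis <- phi_nodes(params)
  acc <- matrix(0, 3, 3)
  for (p in phis) {
    eq <- cos(p) * e1 + sin(p) * e2
    acc <- acc + stick_vote(v, eq, 1, sigma_d, params)
  }
  saliency * 2 / params$n_phi * acc
}

#' @rdname stick_vote
#' @export
ball_vote <- function(v, saliency = 1, sigma_d, params = vote_params()) {
  l <- sqrt(sum(v^2))
  if (l == 0) return(saliency * diag(3))
  curv_c <- params$curvature_weight * sigma_d^4
  gq <- theta_quadrature(params)
  alpha <- 0
  beta <- 0
  for (i in seq_along(gq$x)) {
    th <- gq$x[i]
    df <- arc_decay(l, th, sigma_d, curv_c)
    alpha <- alpha + gq$w[i] * df * cos(th)^2 * sin(th)
    beta <- beta + gq$w[i] * df * sin(th)^3 / 2
  }
  vh <- v / l
  3 * saliency * (beta * diag(3) + (alpha - beta) * tcrossprod(vh))
}

#' Cast all token votes and accumulate the tensor field
#'
#' Every token casts stick, plate and ball votes (whichever components are
#' nonzero) to all voxels of its scale-adaptive window (`N_q = 2 M(q)` mm,
#' voter-centric), and votes are summed voxel-wise into a symmetric PSD
#' tensor field. The accumulation runs in compiled code with per-scale cached
#' ball stencils; it is linear in the token set and order-independent.
#'
#' @param tt a `token_tensors` object from [init_tokens()].
#' @param params [vote_params()].
#' @return Object of class `tensor_field`: list with `field` (nvox x 6 matrix
#'   of components `xx, xy, xz, yy, yz, zz` in column-major voxel order),
#'   `dim` and `spacing`.
#' @export
cast_all_votes <- function(tt, params = vote_params()) {
  stopifnot(inherits(tt, "token_tensors"))
  tok <- tt$tokens
  d <- tok$dim
  nvox <- prod(d)
  if (length(tok$index) == 0L) {
    warning("empty token set: accumulated field is zero", call. = FALSE)
    return(new_tensor_field(matrix(0, nvox, 6), d, tok$spacing))
  }
  comp <- tensor_components(tt)
  ladder <- tok$ladder
  hw <- voting_window(ladder, tok$spacing)
  if (is.null(dim(hw))) hw <- matrix(hw, 1)
  sigma_d <- params$decay_fraction * 2 * ladder
  curv_c <- params$curvature_weight * sigma_d^4
  gq <- theta_quadrature(params)
  field <- cast_votes_cpp(as.integer(d), tok$spacing,
                          tok$ijk, as.integer(tok$scale_idx),
                          hw, sigma_d, curv_c, params$cutoff,
                          comp$s_stick, comp$e1,
                          comp$s_plate, comp$e2,
                          comp$s_ball, phi_nodes(params),
                          gq$x, gq$w)
  new_tensor_field(field, d, tok$spacing)
}

new_tensor_field <- function(field, dim, spacing) {
  structure(list(field = field, dim = dim, spacing = spacing),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  nz <- sum(rowSums(abs(x$field)) > 0)
  cat(sprintf("<tensor_field> %s voxels, %d non-zero\n",
              paste(x$dim, collapse = "x"), nz))
  invisible(x)
}

# 3x3 tensor at voxel (i, j, k), for tests and diagnostics.
tensor_field_at <- function(tf, i, j, k) {
  r <- tf$field[i + tf$dim[1] * (j - 1) + tf$dim[1] * tf$dim[2] * (k - 1), ]
  matrix(r[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
}
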