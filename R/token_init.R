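#' @name token_init
#' @title Token tensor initialisation strategies
#'
#' @description Each admitted token is encoded as a 3x3 symmetric
#' positive-semidefinite tensor `T = sum_i lambda_i e_i e_i^T`, equivalently
#' decomposed into a stick (`lambda1 - lambda2`, orientation `e1`), a plate
#' (`lambda2 - lambda3`, plane `e1, e2`) and a ball (`lambda3`) component.
#' Six configurations are supported, combining three families with their
#' saliency sources:
#'
#' * **ball** (no preferred orientation): `lambda1 = lambda2 = lambda3` equal
#'   to a constant `K`, the image intensity `I(p)`, or the vesselness
#'   `nu(p)`; eigenvectors are the canonical basis.
#' * **Hessian stick**: orientation from the Hessian eigensystem at the
#'   locally optimal scale, `e1 = v1` along the vessel; eigenvalues either
#'   `|kappa_i|^-1` (paired with `v_i`) or `(nu(p), 0, 0)`.
#' * **structure tensor**: pure stick `grad(I) grad(I)^T` with saliency
#'   `||grad(I)||^2`, the gradient taken at the Gaussian scale `M(p)`.
#'
#' Intensity-derived saliencies (intensity ball, structure tensor) are
#' rescaled to `[0, 1]` by their 99.9th percentile over the volume's tokens so
#' that fusion across modalities with different intensity units remains
#' comparable; vesselness saliencies are already in `[0, 1]`.
#'
#' @param tokens a `token_set` from [select_tokens()].
#' @param ss the `scale_space` the tokens came from (needed for the
#'   structure-tensor gradient scales).
#' @param mode saliency mode within the family (see above).
#' @param K constant saliency for the constant ball mode (default 1).
#' @param kappa_cap_factor inverse-kappa eigenvalues are capped at
#'   `kappa_cap_factor` times the median nonzero `|kappa|^-1` over the
#'   token set, guarding the singularity at `kappa = 0` (default `1e3`).
#' @return An object of class `token_tensors`: list with the originating
#'   `tokens`, `lambdas` (n x 3, non-increasing, non-negative), `e1`, `e2`,
#'   `e3` (n x 3 orthonormal rows; zero rows where a component is absent),
#'   and the `strategy` label.
NULL

new_token_tensors <- function(tokens, lambdas, e1, e2, e3, strategy) {
  structure(list(tokens = tokens, lambdas = lambdas,
                 e1 = e1, e2 = e2, e3 = e3, strategy = strategy),
            class = "token_tensors")
}

#' @export
print.token_tensors <- function(x, ...) {
  cat(sprintf("<token_tensors> %d tokens, strategy '%s'\n",
              nrow(x$lambdas), x$strategy))
  invisible(x)
}

normalize_saliency <- function(s, pct = 99.9) {
  pos <- s[s > 0]
  if (!length(pos)) return(s)
  q <- quantile(pos, pct / 100, names = FALSE)
  if (q <= 0) return(s)
  pmin(s / q, 1)
}

#' @rdname token_init
#' @export
init_ball <- function(tokens, mode = c("vesselness", "intensity", "constant"),
                      K = 1) {
  stopifnot(inherits(tokens, "token_set"))
  mode <- match.arg(mode)
  n <- length(tokens$index)
  s <- switch(mode,
              constant = rep(K, n),
              intensity = {
                si <- tokens$intensity
                if (any(si < 0)) {
                  warning("negative intensity saliencies clamped to 0 ",
                          "(tensors must stay PSD)", call. = FALSE)
                  si <- pmax(si, 0)
                }
                normalize_saliency(si)
              },
              vesselness = tokens$nu)
  lam <- unname(cbind(s, s, s))
  e1 <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  e2 <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  e3 <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  new_token_tensors(tokens, lam, e1, e2, e3, paste0("ball_", mode))
}

#' @rdname token_init
#' @export
init_stick_hessian <- function(tokens,
                               mode = c("vesselness", "inverse_kappa"),
                               kappa_cap_factor = 1e3) {
  stopifnot(inherits(tokens, "token_set"))
  mode <- match.arg(mode)
  n <- length(tokens$index)
  if (mode == "vesselness") {
    lam <- cbind(tokens$nu, 0, 0)
  } else {
    inv <- 1 / abs(tokens$kappas)        # |kappa_i|^-1, paired with v_i
    fin <- inv[is.finite(inv) & inv > 0]
    cap <- if (length(fin)) kappa_cap_factor * median(fin) else 1
    inv[!is.finite(inv)] <- cap
    lam <- pmin(inv, cap)
    dim(lam) <- c(n, 3L)
    # |k3| >= |k2| >= |k1|  =>  lambda1 >= lambda2 >= lambda3 automatically
    if (n > 0 && (any(lam[, 1] < lam[, 2]) || any(lam[, 2] < lam[, 3])))
      stop("inverse-kappa eigenvalues lost their ordering; ",
           "Hessian eigensystem is inconsistent", call. = FALSE)
  }
  new_token_tensors(tokens, lam, tokens$v1, tokens$v2, tokens$v3,
                    paste0("hessian_",
                           if (mode == "vesselness") "vesselness" else "kappa"))
}

#' @rdname token_init
#' @export
init_structure_tensor <- function(tokens, ss) {
  stopifnot(inherits(tokens, "token_set"), inherits(ss, "scale_space"))
  n <- length(tokens$index)
  g <- matrix(0, n, 3)
  for (s in unique(tokens$scale_idx)) {
    rows <- which(tokens$scale_idx == s)
    ii <- tokens$index[rows]
    sig <- ss$ladder[s]
    # sigma-normalised first derivatives at the token's optimal scale
    g[rows, 1] <- sig * gaussian_derivative(ss$volume, sig, c(1, 0, 0))[ii]
    g[rows, 2] <- sig * gaussian_derivative(ss$volume, sig, c(0, 1, 0))[ii]
    g[rows, 3] <- sig * gaussian_derivative(ss$volume, sig, c(0, 0, 1))[ii]
  }
  gn2 <- rowSums(g^2)
  # significance floor: flat regions produce convolution-roundoff gradients
  # that must not be rescaled into spurious sticks
  gn2[gn2 <= (1e-10 * max(abs(ss$volume$data)))^2] <- 0
  s_tok <- normalize_saliency(gn2)
  e1 <- matrix(0, n, 3)
  nz <- gn2 > 0
  e1[nz, ] <- g[nz, , drop = FALSE] / sqrt(gn2[nz])
  lam <- cbind(s_tok, 0, 0)
  zeros <- matrix(0, n, 3)
  new_token_tensors(tokens, lam, e1, zeros, zeros, "structure_tensor")
}

#' Initialise token tensors by strategy name
#'
#' Dispatcher over the six supported configurations:
#' `"ball_k"`, `"ball_intensity"`, `"ball_vesselness"`, `"hessian_kappa"`,
#' `"hessian_vesselness"` (default elsewhere in the package) and
#' `"structure_tensor"`.
#'
#' @inheritParams token_init
#' @param strategy one of the six strategy names above.
#' @return A `token_tensors` object.
#' @export
init_tokens <- function(tokens, strategy = c("hessian_vesselness",
                                             "ball_vesselness", "ball_k",
                                             "ball_intensity", "hessian_kappa",
                                             "structure_tensor"),
                        ss = NULL, K = 1) {
  strategy <- match.arg(strategy)
  switch(strategy,
         ball_k = init_ball(tokens, "constant", K = K),
         ball_intensity = init_ball(tokens, "intensity"),
         ball_vesselness = init_ball(tokens, "vesselness"),
         hessian_kappa = init_stick_hessian(tokens, "inverse_kappa"),
         hessian_vesselness = init_stick_hessian(tokens, "vesselness"),
         structure_tensor = {
           if (is.null(ss))
             stop("structure_tensor initialisation needs the scale space",
                  call. = FALSE)
           init_structure_tensor(tokens, ss)
         })
}

#' Stick/plate/ball decomposition of token tensors
#'
#' Returns the per-token component saliencies `s_stick = lambda1 - lambda2`,
#' `s_plate = lambda2 - lambda3`, `s_ball = lambda3` and the orientation
#' basis, i.e. the terms of the spectral split of `T`.
#'
#' @param tt a `token_tensors` object.
#' @return List with `s_stick`, `s_plate`, `s_ball` (length n) and `e1`,
#'   `e2`, `e3` (n x 3).
#' @export
tensor_components <- function(tt) {
  stopifnot(inherits(tt, "token_tensors"))
  list(s_stick = tt$lambdas[, 1] - tt$lambdas[, 2],
       s_plate = tt$lambdas[, 2] - tt$lambdas[, 3],
       s_ball = tt$lambdas[, 3],
       e1 = tt$e1, e2 = tt$e2, e3 = tt$e3)
}

# Reconstruct the i-th token's full 3x3 tensor (for tests and diagnostics).
token_tensor_matrix <- function(tt, i) {
  l <- tt$lambdas[i, ]
  e1 <- tt$e1[i, ]; e2 <- tt$e2[i, ]; e3 <- tt$e3[i, ]
  (l[1] - l[2]) * tcrossprod(e1) +
    (l[2] - l[3]) * (tcrossprod(e1) + tcrossprod(e2)) +
    l[3] * (tcrossprod(e1) + tcrossprod(e2) + tcrossprod(e3))
}
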