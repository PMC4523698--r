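# Independent oracles used across the suite.

# Brute-force eigensolver for symmetric 3x3 matrices via the characteristic
# polynomial (polyroot) and null-space eigenvectors; independent of both
# base eigen() and the package's solvers.
poly_eig_oracle <- function(H) {
  # det(H - x I) = -x^3 + c2 x^2 + c1 x + c0
  c2 <- sum(diag(H))
  c1 <- -(H[1, 1] * H[2, 2] + H[1, 1] * H[3, 3] + H[2, 2] * H[3, 3] -
            H[1, 2]^2 - H[1, 3]^2 - H[2, 3]^2)
  c0 <- det(H)
  r <- polyroot(c(c0, c1, c2, -1))
  vals <- sort(Re(r))                 # symmetric => real roots
  vecs <- sapply(vals, function(l) {
    A <- H - l * diag(3)
    # eigenvector = cross product of the two most independent rows
    cr <- list(pracma::cross(A[1, ], A[2, ]),
               pracma::cross(A[1, ], A[3, ]),
               pracma::cross(A[2, ], A[3, ]))
    n <- vapply(cr, function(v) sqrt(sum(v^2)), 0)
    if (max(n) < 1e-12) {
      # (near) repeated eigenvalue: orthonormalise against the rows
      i <- which.max(rowSums(A^2))
      v <- A[i, ]
      if (sqrt(sum(v^2)) < 1e-12) return(c(1, 0, 0))
      basis <- diag(3)
      cand <- basis[, which.max(abs(crossprod(basis, v)) < 0.9)[1]]
      v2 <- cand - sum(cand * v) / sum(v * v) * v
      return(v2 / sqrt(sum(v2^2)))
    }
    v <- cr[[which.max(n)]]
    v / sqrt(sum(v^2))
  })
  list(values = vals, vectors = vecs)  # ascending algebraic order
}

# Naive double-loop accumulation of all votes, using only the exported
# single-vote functions; the reference for the compiled accumulator.
naive_cast_votes <- function(tt, params = vote_params()) {
  tok <- tt$tokens
  d <- tok$dim
  comp <- tensor_components(tt)
  field <- array(0, c(d, 3, 3))
  for (t in seq_along(tok$index)) {
    M <- tok$M[t]
    hw <- voting_window(M, tok$spacing)
    sigd <- params$decay_fraction * 2 * M
    site <- tok$ijk[t, ]
    for (dk in -hw[3]:hw[3]) for (dj in -hw[2]:hw[2]) for (di in -hw[1]:hw[1]) {
      i <- site[1] + di; j <- site[2] + dj; k <- site[3] + dk
      if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) next
      v <- c(di, dj, dk) * tok$spacing
      vote <- matrix(0, 3, 3)
      if (comp$s_stick[t] != 0)
        vote <- vote + stick_vote(v, comp$e1[t, ], comp$s_stick[t], sigd,
                                  params)
      if (comp$s_plate[t] != 0)
        vote <- vote + plate_vote(v, comp$e1[t, ], comp$e2[t, ],
                                  comp$s_plate[t], sigd, params)
      if (comp$s_ball[t] != 0)
        vote <- vote + ball_vote(v, comp$s_ball[t], sigd, params)
      field[i, j, k, , ] <- field[i, j, k, , ] + vote
    }
  }
  field
}

# Build a token_set by hand (token sites with given orientations/scales) so
# voting can be tested without running the scale-space machinery.
manual_token_set <- function(ijk, dim, spacing = c(1, 1, 1),
                             ladder = c(1.0, 2.0), scale_idx = NULL,
                             v1 = NULL, nu = NULL, kappas = NULL) {
  n <- nrow(ijk)
  if (is.null(scale_idx)) scale_idx <- rep(1L, n)
  if (is.null(nu)) nu <- rep(0.8, n)
  if (is.null(v1)) v1 <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  # complete v1 to an orthonormal frame
  v2 <- t(apply(v1, 1, function(e) {
    ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b <- pracma::cross(e, ref)
    b / sqrt(sum(b^2))
  }))
  v3 <- t(sapply(seq_len(n), function(r) pracma::cross(v1[r, ], v2[r, ])))
  if (is.null(kappas))
    kappas <- matrix(rep(c(0.05, -1, -1.2), each = n), n, 3)
  idx <- ijk[, 1] + dim[1] * (ijk[, 2] - 1) + dim[1] * dim[2] * (ijk[, 3] - 1)
  structure(list(index = idx, ijk = ijk, scale_idx = as.integer(scale_idx),
                 M = ladder[scale_idx], nu = nu,
                 intensity = rep(1, n), kappas = kappas,
                 v1 = v1, v2 = v2, v3 = v3,
                 dim = dim, spacing = spacing, ladder = ladder),
            class = "token_set")
}

# Arbitrary token tensors (generic lambdas/orientations) for oracle tests.
manual_token_tensors <- function(tok, lambdas, e1 = NULL) {
  if (is.null(e1)) e1 <- tok$v1
  e2 <- t(apply(e1, 1, function(e) {
    ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b <- pracma::cross(e, ref)
    b / sqrt(sum(b^2))
  }))
  e3 <- t(sapply(seq_len(nrow(e1)),
                 function(r) pracma::cross(e1[r, ], e2[r, ])))
  structure(list(tokens = tok, lambdas = lambdas, e1 = e1, e2 = e2, e3 = e3,
                 strategy = "manual"), class = "token_tensors")
}

field_as_matrix <- function(arr_field, d) {
  # array(dim, 3, 3) -> nvox x 6 in the package's component order
  m <- matrix(0, prod(d), 6)
  comp <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  for (cidx in seq_along(comp)) {
    a <- comp[[cidx]]
    m[, cidx] <- as.vector(arr_field[, , , a[1], a[2]])
  }
  m
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Analytic Gaussian tube along the z axis (no phantom module involved).
gauss_tube_volume <- function(dim, spacing = c(1, 1, 1), sd = 1,
                              center = NULL, peak = 1) {
  if (is.null(center)) center <- (dim[1:2] - 1) / 2 * spacing[1:2]
  x <- (seq_len(dim[1]) - 1) * spacing[1]
  y <- (seq_len(dim[2]) - 1) * spacing[2]
  r2 <- outer((x - center[1])^2, (y - center[2])^2, "+")
  slice <- peak * exp(-r2 / (2 * sd^2))
  array(rep(slice, dim[3]), dim)
}
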