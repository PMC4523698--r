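test_that("voting windows follow the 2M(p) rule with ceiling and floor", {
  expect_equal(voting_window(2.0, c(1, 1, 1)), c(4L, 4L, 4L))
  expect_equal(voting_window(1.0, c(0.43, 0.43, 1))[1:2], c(5L, 5L))
  expect_equal(voting_window(0.1, c(1, 1, 1)), c(1L, 1L, 1L))
  hw <- voting_window(c(1, 2), c(1, 1, 0.5))
  expect_equal(dim(hw), c(2L, 3L))
  expect_equal(hw[2, ], c(4L, 4L, 8L))
})

test_that("stick votes follow the arc kernel contract", {
  vp <- vote_params()
  e1 <- c(0, 0, 1)
  sigd <- 1.5

  # self-vote identity
  expect_equal(stick_vote(c(0, 0, 0), e1, 0.7, sigd, vp),
               0.7 * tcrossprod(e1))

  # along the orientation: zero-curvature arc, pure distance decay
  for (l in c(0.5, 1, 2)) {
    v <- c(0, 0, l)
    expect_equal(stick_vote(v, e1, 1, sigd, vp),
                 exp(-l^2 / sigd^2) * tcrossprod(e1), tolerance = 1e-12)
  }
  # unsigned: votes behind equal votes ahead
  expect_equal(stick_vote(c(0, 0, -1), e1, 1, sigd, vp),
               stick_vote(c(0, 0, 1), e1, 1, sigd, vp))

  # beyond the angular cutoff: zero
  expect_equal(stick_vote(c(1, 0, 0), e1, 1, sigd, vp), matrix(0, 3, 3))
  expect_equal(stick_vote(c(1, 0, 0.5), e1, 1, sigd, vp), matrix(0, 3, 3))

  # at 30 degrees: positive, principal direction rotated by 2*theta
  v <- c(sin(pi / 6), 0, cos(pi / 6))
  vote <- stick_vote(v, e1, 1, sigd, vp)
  dec <- eigen(vote, symmetric = TRUE)
  expect_gt(dec$values[1], 0)
  expect_equal(dec$values[2:3], c(0, 0), tolerance = 1e-12)
  tpred <- c(sin(pi / 3), 0, cos(pi / 3))   # e1 rotated by 2*30 deg
  expect_equal(abs(sum(dec$vectors[, 1] * tpred)), 1, tolerance = 1e-9)

  # decay is eventually monotone at fixed angle (near the voter the
  # curvature penalty, which relaxes with distance, can dominate)
  mags <- sapply(c(1.5, 2, 2.5, 3), function(l)
    sum(diag(stick_vote(l * v, e1, 1, sigd, vp))))
  expect_true(all(diff(mags) < 0))
})

test_that("plate and ball self-votes return the component unchanged", {
  vp <- vote_params()
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(plate_vote(c(0, 0, 0), e1, e2, 0.4, 1, vp),
               0.4 * diag(c(1, 1, 0)))
  expect_equal(ball_vote(c(0, 0, 0), 0.9, 1, vp), 0.9 * diag(3))
})

test_that("ball votes are isotropic in the displacement direction", {
  vp <- vote_params()
  set.seed(5)
  for (rep in 1:5) {
    u <- rand_unit()
    l <- runif(1, 0.3, 2)
    b1 <- ball_vote(l * u, 1, 1.2, vp)
    b2 <- ball_vote(c(0, 0, l), 1, 1.2, vp)
    expect_equal(norm(b1, "F"), norm(b2, "F"), tolerance = 1e-10)
    # principal direction along the displacement
    expect_equal(abs(sum(eigen(b1, symmetric = TRUE)$vectors[, 1] * u)), 1,
                 tolerance = 1e-8)
  }
})

test_that("compiled accumulation matches the naive double loop", {
  set.seed(21)
  d <- c(14, 14, 14)
  n <- 15
  ijk <- cbind(sample(2:13, n, TRUE), sample(2:13, n, TRUE),
               sample(2:13, n, TRUE))
  ijk <- ijk[!duplicated(ijk), , drop = FALSE]
  n <- nrow(ijk)
  tok <- manual_token_set(ijk, dim = d, spacing = c(1, 0.8, 1.1),
                          ladder = c(0.9, 1.4),
                          scale_idx = sample(1:2, n, TRUE),
                          v1 = t(replicate(n, rand_unit())))
  # generic tensors: all three components non-zero
  lam <- cbind(runif(n, 1, 2), runif(n, 0.4, 0.9), runif(n, 0, 0.3))
  tt <- manual_token_tensors(tok, lam)
  prod_field <- cast_all_votes(tt)
  ref <- field_as_matrix(naive_cast_votes(tt), d)
  expect_lt(max(abs(prod_field$field - ref)), 1e-8)
})

test_that("voting is linear in the token set and PSD", {
  set.seed(22)
  d <- c(12, 12, 12)
  ijkA <- cbind(sample(3:10, 6), sample(3:10, 6), sample(3:10, 6))
  ijkB <- cbind(sample(3:10, 5), sample(3:10, 5), sample(3:10, 5))
  keep <- !(paste(ijkB[, 1], ijkB[, 2], ijkB[, 3]) %in%
              paste(ijkA[, 1], ijkA[, 2], ijkA[, 3]))
  ijkB <- ijkB[keep, , drop = FALSE]
  mk <- function(ijk) {
    n <- nrow(ijk)
    tok <- manual_token_set(ijk, dim = d,
                            v1 = t(replicate(n, rand_unit())))
    manual_token_tensors(tok, cbind(runif(n, 1, 2), runif(n, 0.2, 0.8),
                                    runif(n, 0, 0.2)))
  }
  ttA <- mk(ijkA); ttB <- mk(ijkB)
  ttAB <- mk(rbind(ijkA, ijkB))
  ttAB$lambdas <- rbind(ttA$lambdas, ttB$lambdas)
  ttAB$e1 <- rbind(ttA$e1, ttB$e1)
  ttAB$e2 <- rbind(ttA$e2, ttB$e2)
  ttAB$e3 <- rbind(ttA$e3, ttB$e3)
  ttAB$tokens <- manual_token_set(rbind(ijkA, ijkB), dim = d,
                                  v1 = rbind(ttA$e1, ttB$e1))
  fA <- cast_all_votes(ttA)$field
  fB <- cast_all_votes(ttB)$field
  fAB <- cast_all_votes(ttAB)$field
  expect_lt(max(abs(fAB - (fA + fB))), 1e-8)

  # PSD at every voxel
  lam <- vesselvote:::eig3_abs_field(fAB)$kappas
  tr <- rowSums(abs(fAB[, c(1, 4, 6)]))
  expect_true(all(lam >= -1e-8 * pmax(tr, 1e-300)))
})

test_that("an isolated token's field is its self-vote plus decaying votes", {
  d <- c(16, 16, 16)
  tok <- manual_token_set(matrix(c(8, 8, 8), 1), dim = d,
                          v1 = matrix(c(0, 0, 1), 1), ladder = c(1.5, 2))
  tt <- manual_token_tensors(tok, matrix(c(1, 0, 0), 1))
  tf <- cast_all_votes(tt)
  expect_equal(vesselvote:::tensor_field_at(tf, 8, 8, 8),
               tcrossprod(c(0, 0, 1)), tolerance = 1e-12)
  sigd <- 2 * 1.5 / 3
  expect_equal(vesselvote:::tensor_field_at(tf, 8, 8, 10),
               exp(-4 / sigd^2) * tcrossprod(c(0, 0, 1)), tolerance = 1e-12)
  # outside the window: zero
  expect_equal(vesselvote:::tensor_field_at(tf, 8, 8, 16), matrix(0, 3, 3))
  hw <- voting_window(1.5, c(1, 1, 1))
  ii <- arrayInd(seq_len(prod(d)), d)
  out <- which(abs(ii[, 1] - 8) > hw[1] | abs(ii[, 2] - 8) > hw[2] |
                 abs(ii[, 3] - 8) > hw[3])
  expect_true(all(tf$field[out, ] == 0))
})

test_that("aligned collinear sticks reinforce at the midpoint", {
  d <- c(16, 16, 16)
  mk1 <- function(k) {
    tok <- manual_token_set(matrix(c(8, 8, k), 1), dim = d,
                            v1 = matrix(c(0, 0, 1), 1))
    manual_token_tensors(tok, matrix(c(1, 0, 0), 1))
  }
  both <- manual_token_set(rbind(c(8, 8, 7), c(8, 8, 9)), dim = d,
                           v1 = matrix(rep(c(0, 0, 1), each = 2), 2, 3))
  s_mid <- function(tf) {
    lam <- eigen(vesselvote:::tensor_field_at(tf, 8, 8, 8),
                 symmetric = TRUE, only.values = TRUE)$values
    lam[1] - lam[2]
  }
  s_both <- s_mid(cast_all_votes(manual_token_tensors(
    both, matrix(rep(c(1, 0, 0), each = 2), 2, 3))))
  s_one <- s_mid(cast_all_votes(mk1(7)))
  expect_gt(s_both, s_one)
  expect_equal(s_both, 2 * s_one, tolerance = 1e-10)  # symmetric pair
})

test_that("the accumulated field is equivariant under 90-degree rotation", {
  set.seed(33)
  d <- c(14, 14, 12)
  n <- 8
  ijk <- cbind(sample(3:12, n, TRUE), sample(3:12, n, TRUE),
               sample(3:10, n, TRUE))
  ijk <- ijk[!duplicated(ijk), , drop = FALSE]
  n <- nrow(ijk)
  v1 <- t(replicate(n, rand_unit()))
  lam <- cbind(runif(n, 1, 2), runif(n, 0.2, 0.8), runif(n, 0, 0.3))
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # (x,y,z)->(-y,x,z)
  ijk_r <- cbind(d[1] + 1 - ijk[, 2], ijk[, 1], ijk[, 3])
  v1_r <- t(R %*% t(v1))
  tt <- manual_token_tensors(manual_token_set(ijk, dim = d, v1 = v1), lam)
  # rotate the full orientation frame, not just v1, so tensors correspond
  tt_r <- manual_token_tensors(manual_token_set(ijk_r, dim = d, v1 = v1_r),
                               lam, e1 = v1_r)
  tt_r$e2 <- t(R %*% t(tt$e2))
  tt_r$e3 <- t(R %*% t(tt$e3))
  f1 <- cast_all_votes(tt)
  f2 <- cast_all_votes(tt_r)
  for (q in seq_len(n)) {
    T1 <- vesselvote:::tensor_field_at(f1, ijk[q, 1], ijk[q, 2], ijk[q, 3])
    T2 <- vesselvote:::tensor_field_at(f2, ijk_r[q, 1], ijk_r[q, 2],
                                       ijk_r[q, 3])
    expect_equal(T2, R %*% T1 %*% t(R), tolerance = 1e-8)
  }
})

test_that("an empty token set warns and returns a zero field", {
  tok <- manual_token_set(matrix(numeric(0), 0, 3), dim = c(10, 10, 10))
  tok$index <- integer(0)
  tt <- manual_token_tensors(tok, matrix(numeric(0), 0, 3),
                             e1 = matrix(numeric(0), 0, 3))
  expect_warning(tf <- cast_all_votes(tt), "empty token set")
  expect_true(all(tf$field == 0))
})
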