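test_that("scale ladders are log-uniform with exact endpoints", {
  s <- make_scale_ladder(1.0, 4.5, 10)
  expect_length(s, 10)
  expect_identical(s[1], 1.0)
  expect_identical(s[10], 4.5)
  expect_equal(diff(log(s)), rep(log(4.5) / 9, 9), tolerance = 1e-12)

  expect_equal(make_scale_ladder(2.0, 2.0 * exp(1), 2), c(2.0, 2.0 * exp(1)))
  expect_equal(make_scale_ladder(1.0, 4.0, 3), c(1.0, 2.0, 4.0))

  expect_error(make_scale_ladder(-1, 2, 3), "sigma_min")
  expect_error(make_scale_ladder(3, 2, 3), "sigma_min")
  expect_error(make_scale_ladder(1, 2, 1), "n >= 2")
})

test_that("Hessian components reproduce analytic second derivatives", {
  d <- c(16, 16, 16)
  vol_const <- scalar_volume(array(7, d))
  H <- hessian_at_scale(vol_const, 1.5)
  for (comp in c("h11", "h12", "h13", "h22", "h23", "h33"))
    expect_lt(max(abs(H[[comp]])), 1e-10)

  # separable quadratic along axis 1: d2/dx2 = 2 exactly (interior), before
  # gamma-normalisation; off-diagonal zero
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  vol <- scalar_volume(array(g$x^2, d))
  H <- hessian_at_scale(vol, 1.5, gamma_normalize = FALSE)
  expect_equal(H$h11[8, 8, 8], 2, tolerance = 1e-10)
  expect_lt(abs(H$h12[8, 8, 8]), 1e-10)
  expect_lt(abs(H$h22[8, 8, 8]), 1e-10)

  expect_error(hessian_at_scale(vol, -1), "positive")
  expect_warning(hessian_at_scale(scalar_volume(array(0, d),
                                                spacing = c(4, 4, 4)), 1),
                 "under-resolved")
})

test_that("a bright Gaussian tube has two negative cross-tube curvatures", {
  d <- c(20, 20, 16)
  vol <- scalar_volume(gauss_tube_volume(d, sd = 1.5))
  H <- hessian_at_scale(vol, 1.5)
  c0 <- (d[1:2] - 1) / 2 + 1  # on-axis voxel (odd center: 10.5 -> use 10)
  i <- floor(c0[1]); j <- floor(c0[2])
  Hm <- matrix(c(H$h11[i, j, 8], H$h12[i, j, 8], H$h13[i, j, 8],
                 H$h12[i, j, 8], H$h22[i, j, 8], H$h23[i, j, 8],
                 H$h13[i, j, 8], H$h23[i, j, 8], H$h33[i, j, 8]), 3, 3)
  dec <- eigendecompose(Hm)
  expect_lt(dec$kappas[2], 0)          # cross-tube
  expect_lt(dec$kappas[3], 0)          # cross-tube
  expect_lt(abs(dec$kappas[1]), 0.05 * abs(dec$kappas[3]))  # along axis
})

test_that("eigendecompose orders by magnitude and matches the polynomial oracle", {
  dec <- eigendecompose(diag(c(-5, -4, 0.1)))
  expect_equal(dec$kappas, c(0.1, -4, -5))

  z <- eigendecompose(matrix(0, 3, 3))
  expect_equal(z$kappas, c(0, 0, 0))
  expect_equal(z$vectors, diag(3))

  expect_error(eigendecompose(matrix(c(1, 2, 3, 0, 1, 2, 0, 0, 1), 3, 3)),
               "symmetric")

  set.seed(11)
  for (rep in 1:60) {
    A <- matrix(rnorm(9), 3, 3)
    H <- (A + t(A)) / 2
    dec <- eigendecompose(H)
    orc <- poly_eig_oracle(H)
    expect_equal(sort(dec$kappas), orc$values, tolerance = 1e-8)
    for (c in 1:3) {
      v <- dec$vectors[, c]
      expect_equal(as.vector(H %*% v), dec$kappas[c] * v, tolerance = 1e-7)
      expect_equal(sum(v^2), 1, tolerance = 1e-10)
    }
  }
})

test_that("vectorised eigenvalues agree with eigen() and sort by magnitude", {
  set.seed(12)
  n <- 300
  Hm <- matrix(rnorm(n * 6), n, 6)
  ev <- vesselvote:::eig3_vals_desc(Hm[, 1], Hm[, 2], Hm[, 3],
                                    Hm[, 4], Hm[, 5], Hm[, 6])
  kp <- vesselvote:::kappas_by_abs(ev$l1, ev$l2, ev$l3)
  for (r in seq_len(n)) {
    H <- matrix(Hm[r, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
    ref <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(sort(c(kp$k1[r], kp$k2[r], kp$k3[r])), ref,
                 tolerance = 1e-8)
    expect_true(abs(kp$k3[r]) >= abs(kp$k2[r]) - 1e-12)
    expect_true(abs(kp$k2[r]) >= abs(kp$k1[r]) - 1e-12)
  }
})

test_that("vesselness obeys the bright-tube sign convention and shape ordering", {
  p <- vesselness_params(c = 1)
  expect_identical(vesselness(0, 3, 5, p), 0)
  expect_identical(vesselness(0, -3, 5, p), 0)
  # ideal tube outscores blob at equal magnitude
  cc <- 0.8
  tube <- vesselness(0, -cc, -cc, p)
  blob <- vesselness(-cc, -cc, -cc, p)
  expect_gt(tube, blob)
  expect_gt(tube, 0)
  expect_lte(tube, 1)
  # smoothness factor vanishes as kappa2 -> 0-
  pm <- vesselness_params(c = 1, C = 1e-2)
  expect_lt(vesselness(0, -1e-9, -1, pm), 1e-6)
})

test_that("tube centerline vesselness dominates background by >= 10x", {
  d <- c(24, 24, 16)
  vol <- scalar_volume(gauss_tube_volume(d, sd = 1.5) +
                         0.001 * array(sin(seq_len(prod(d))), d))
  ss <- build_scale_space(vol, make_scale_ladder(1, 3, 5))
  center <- ss$nu_max[12, 12, 8]
  bg <- ss$nu_max[3, 3, 8]
  expect_gt(center, 10 * max(bg, 1e-12))
})

test_that("optimal-scale image selects the tube scale and breaks ties small", {
  # constant volume: nu == 0 everywhere, M == sigma_min by tie-break
  ss0 <- build_scale_space(scalar_volume(array(3, c(12, 12, 12))),
                           make_scale_ladder(1, 2, 3))
  expect_true(all(ss0$nu_max == 0))
  expect_true(all(ss0$M == 1))
  expect_equal(sum(ss0$cond), 0)

  # Gaussian tube of profile sd r: centerline M within one ladder step of r
  r <- 1.6
  ladder <- make_scale_ladder(0.8, 3.2, 7)
  step <- exp(diff(log(ladder))[1])
  vol <- scalar_volume(gauss_tube_volume(c(24, 24, 16), sd = r))
  ss <- build_scale_space(vol, ladder)
  Mc <- ss$M[12, 12, 4:13]
  expect_true(all(Mc >= r / step - 1e-9 & Mc <= r * step + 1e-9))

  # thicker tube selects a larger centerline scale than a thinner one
  vol2 <- gauss_tube_volume(c(40, 20, 16), sd = 1.0, center = c(9, 9.5)) +
    gauss_tube_volume(c(40, 20, 16), sd = 2.0, center = c(29, 9.5))
  ss2 <- build_scale_space(scalar_volume(vol2), make_scale_ladder(0.8, 3.2, 7))
  expect_gt(ss2$M[30, 10, 8], ss2$M[10, 10, 8])
})

test_that("vesselness is invariant to adding an intensity offset", {
  vol <- gauss_tube_volume(c(16, 16, 12), sd = 1.2)
  ss1 <- build_scale_space(scalar_volume(vol), make_scale_ladder(1, 2, 3),
                           vesselness_params(c = 0.5))
  ss2 <- build_scale_space(scalar_volume(vol + 11.3),
                           make_scale_ladder(1, 2, 3),
                           vesselness_params(c = 0.5))
  expect_equal(ss1$nu_max, ss2$nu_max, tolerance = 1e-10)
})

test_that("scale selection is covariant with joint radius/ladder scaling", {
  f <- 2
  lad1 <- make_scale_ladder(0.7, 2.8, 6)
  step <- exp(diff(log(lad1))[1])
  ss1 <- build_scale_space(scalar_volume(gauss_tube_volume(c(24, 24, 12),
                                                           sd = 1.2)), lad1)
  ss2 <- build_scale_space(scalar_volume(
    gauss_tube_volume(c(48, 48, 12), spacing = c(1, 1, 1), sd = 1.2 * f,
                      center = c(23, 23))), lad1 * f)
  M1 <- ss1$M[12, 12, 6]
  M2 <- ss2$M[24, 24, 6]
  expect_lt(abs(log(M2 / (f * M1))), log(step) + 1e-9)
})

test_that("token selection follows the two-negative-curvature condition", {
  expect_length(select_tokens(build_scale_space(
    scalar_volume(array(1, c(12, 12, 12))),
    make_scale_ladder(1, 2, 2)))$index, 0)

  # bright tube admits >= 95% of centerline; inverted tube excludes it
  vol <- gauss_tube_volume(c(20, 20, 16), sd = 1.5)
  ss <- build_scale_space(scalar_volume(vol), make_scale_ladder(1, 3, 5))
  tok <- select_tokens(ss)
  cl <- cbind(10, 10, 1:16)
  lin <- cl[, 1] + 20 * (cl[, 2] - 1) + 400 * (cl[, 3] - 1)
  expect_gte(mean(lin %in% tok$index), 0.95)

  ssi <- build_scale_space(scalar_volume(-vol), make_scale_ladder(1, 3, 5))
  toki <- select_tokens(ssi)
  expect_true(all(!(lin %in% toki$index)))
  # but the invert flag recovers them
  ssinv <- build_scale_space(scalar_volume(-vol), make_scale_ladder(1, 3, 5),
                             invert = TRUE)
  expect_gte(mean(lin %in% select_tokens(ssinv)$index), 0.95)

  # tokens are a superset of nu_max > 0
  expect_true(all(ss$cond[ss$nu_max > 0]))

  # mask restricts tokens
  mask <- array(FALSE, c(20, 20, 16)); mask[, , 1:8] <- TRUE
  tm <- select_tokens(ss, mask)
  expect_true(all(tm$ijk[, 3] <= 8))
  expect_error(select_tokens(ss, array(TRUE, c(4, 4, 4))), "mask grid")
})

test_that("token eigensystems satisfy the eigenpair and orthonormality contracts", {
  vol <- gauss_tube_volume(c(16, 16, 12), sd = 1.3) +
    array(0.01 * sin(1:(16 * 16 * 12)), c(16, 16, 12))
  ss <- build_scale_space(scalar_volume(vol), make_scale_ladder(1, 2.5, 4))
  tok <- select_tokens(ss)
  expect_gt(length(tok$index), 0)
  pick <- seq(1, length(tok$index), length.out = min(25, length(tok$index)))
  for (t in round(pick)) {
    s <- tok$scale_idx[t]
    H <- ss$hessians[[s]]
    ii <- tok$index[t]
    Hm <- matrix(c(H$h11[ii], H$h12[ii], H$h13[ii],
                   H$h12[ii], H$h22[ii], H$h23[ii],
                   H$h13[ii], H$h23[ii], H$h33[ii]), 3, 3)
    V <- rbind(tok$v1[t, ], tok$v2[t, ], tok$v3[t, ])
    expect_equal(V %*% t(V), diag(3), tolerance = 1e-6)
    for (c in 1:3)
      expect_lt(sqrt(sum((Hm %*% V[c, ] - tok$kappas[t, c] * V[c, ])^2)),
                1e-5 * max(1, norm(Hm, "F")))
    expect_true(abs(tok$kappas[t, 3]) >= abs(tok$kappas[t, 2]) - 1e-12)
    expect_true(abs(tok$kappas[t, 2]) >= abs(tok$kappas[t, 1]) - 1e-12)
  }
})
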