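test_that("double-well factor dp matches both branches and their limits", {
  # independent branch-wise evaluation
  expect_identical(drlse_dp(1), 0)
  expect_equal(drlse_dp(2), 0.5, tolerance = 1e-15)
  expect_equal(drlse_dp(0.5), sin(pi) / pi, tolerance = 1e-15)
  expect_identical(drlse_dp(0), 1)
  ss <- seq(0.01, 0.99, by = 0.01)
  expect_equal(drlse_dp(ss), sin(2 * pi * ss) / (2 * pi * ss), tolerance = 1e-14)
  sh <- seq(1.01, 4, by = 0.01)
  expect_equal(drlse_dp(sh), (sh - 1) / sh, tolerance = 1e-14)
  # continuity at s = 1 and s -> 0
  expect_lt(abs(drlse_dp(1 - 1e-8) - drlse_dp(1 + 1e-8)), 1e-6)
  expect_lt(abs(drlse_dp(1e-9) - 1), 1e-6)
  expect_error(drlse_dp(-0.1), class = "osg_contract_error")
})

test_that("CFL time step obeys the advective and parabolic bounds", {
  expect_equal(suggest_time_step(1, 5), 0.1)
  expect_equal(suggest_time_step(1, 0.1), 0.25)
  expect_equal(suggest_time_step(evolution_params(alpha = 1), 5), 0.1)
  # zero/absent speed -> parabolic bound alone
  expect_equal(suggest_time_step(2, 0), 0.125)
  # doubling alpha never increases dt
  for (ms in c(0.01, 1, 10))
    expect_lte(suggest_time_step(2, ms), suggest_time_step(1, ms))
})

test_that("proposed rhs vanishes off the band and composes its terms", {
  n <- 32
  img <- image_grid(det_matrix(n))
  phi <- disk_sdf(n, 15, 15, 9)
  p <- evolution_params(lambda1 = 2, lambda2 = 1)
  st <- compute_region_means(img, phi, p$eps)
  g <- edge_indicator(img, p$sigma, p$edge_scale)
  cv <- compute_curvature(phi, csi_sigma = p$csi_sigma)
  r <- proposed_rhs(phi, img, st, g, cv, p)
  expect_true(all(r[abs(phi) > p$eps] == 0))

  # equal weights and I = (c1+c2)/2 kill the data term
  mid <- image_grid(matrix((st$c1 + st$c2) / 2, n, n))
  stm <- list(c1 = st$c1, c2 = st$c2)
  p11 <- evolution_params(lambda1 = 1, lambda2 = 1)
  r_mid <- proposed_rhs(phi, mid, stm, g, cv, p11)
  r_geo <- smoothed_dirac(phi, p11$eps) *
    (p11$alpha * cv$kappa + p11$mu * g + p11$beta * (1 - cv$s) * cv$kappa)
  expect_equal(r_mid, r_geo, tolerance = 1e-12)

  # s = 0 everywhere removes the data contribution entirely
  cv0 <- cv; cv0$s <- matrix(0, n, n)
  r0 <- proposed_rhs(phi, img, st, g, cv0, p)
  term <- smoothed_dirac(phi, p$eps) *
    (p$alpha * cv$kappa + p$mu * g + p$beta * cv$kappa)
  expect_equal(r0, term, tolerance = 1e-12)

  expect_error(proposed_rhs(phi[1:16, 1:16], img, st, g, cv, p),
               class = "osg_contract_error")
})

test_that("with the CSI pinned to 1 the proposed update reduces to Chan-Vese plus a weighted area force", {
  # field-wise equality at 1e-10 on 20 deterministic 32x32 instances
  for (k in 1:20) {
    n <- 32
    img <- image_grid(det_matrix(n, k = k))
    phi <- det_levelset(n, k)
    p <- evolution_params(lambda1 = 1 + k / 10, lambda2 = 1, alpha = 1.3,
                          mu = 4)
    st <- compute_region_means(img, phi, p$eps)
    g <- edge_indicator(img, p$sigma, p$edge_scale)
    cv <- compute_curvature(phi)
    cv$s <- matrix(1, n, n)
    r_prop <- proposed_rhs(phi, img, st, g, cv, p)
    cvp <- cv_params(mu_cv = p$alpha, v = p$mu * g, lambda1 = p$lambda1,
                     lambda2 = p$lambda2, eps = p$eps)
    r_cv <- cv_rhs(phi, img, st, cvp)
    expect_equal(r_prop, r_cv, tolerance = 1e-10)
  }
})

test_that("compiled step kernels equal the R reference composition", {
  n <- 40
  img <- image_grid(det_matrix(n, k = 3))
  phi <- det_levelset(n, 2)
  p <- evolution_params(lambda1 = 2.5)
  st <- compute_region_means(img, phi, p$eps)
  g <- edge_indicator(img, p$sigma, p$edge_scale)
  cv <- compute_curvature(phi, csi_sigma = p$csi_sigma)

  fast <- organoidseg:::cpp_proposed_step(phi, img$intensities, g, st$c1,
                                          st$c2, p$lambda1, p$lambda2,
                                          p$alpha, p$mu, p$beta, p$eps,
                                          p$csi_sigma)
  expect_equal(fast, proposed_rhs(phi, img, st, g, cv, p), tolerance = 1e-12)

  cvp <- cv_params(mu_cv = 0.1, v = 0.5)
  fast_cv <- organoidseg:::cpp_cv_step(phi, img$intensities,
                                       matrix(0.5, n, n), st$c1, st$c2,
                                       cvp$lambda1, cvp$lambda2, cvp$mu_cv,
                                       cvp$eps)
  expect_equal(fast_cv, cv_rhs(phi, img, st, cvp), tolerance = 1e-12)

  clp <- cplse_params()
  fast_cp <- organoidseg:::cpp_cplse_step(phi, g, clp$mu_reg, clp$lambda_len,
                                          clp$alpha_area, clp$eps,
                                          clp$csi_sigma)
  expect_equal(fast_cp, cplse_rhs(phi, img, g, cv, clp), tolerance = 1e-12)
})

test_that("CPLSE with the CSI pinned to 1 is exactly the three-term DRLSE update", {
  n <- 32
  img <- image_grid(det_matrix(n, k = 5))
  phi <- det_levelset(n, 4)
  p <- cplse_params()
  g <- edge_indicator(img, p$sigma, p$edge_scale)
  cv <- compute_curvature(phi, csi_sigma = p$csi_sigma)
  cv$s <- matrix(1, n, n)
  got <- cplse_rhs(phi, img, g, cv, p)
  # independent DRLSE composition
  gr <- organoidseg:::cpp_grad(phi)
  nrm <- sqrt(gr$gx^2 + gr$gy^2)
  dp <- drlse_dp(nrm)
  reg <- organoidseg:::cpp_divergence(dp * gr$gx, dp * gr$gy)
  nf <- pmax(nrm, 1e-8)
  len <- organoidseg:::cpp_divergence(g * gr$gx / nf, g * gr$gy / nf)
  dd <- smoothed_dirac(phi, p$eps)
  want <- p$mu_reg * reg + p$lambda_len * dd * len + p$alpha_area * g * dd
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the CPLSE regularizer maintains the signed-distance property", {
  n <- 96
  phi <- disk_sdf(n, 47.5, 47.5, 25)
  img <- image_grid(matrix(0.5, n, n))
  p <- cplse_params(lambda_len = 0, alpha_area = 0, max_iterations = 500L,
                    tolerance = 0, snapshot_stride = 0L)
  res <- cplse_evolve(phi, img, p)
  gr <- organoidseg:::cpp_grad(res$phi)
  nrm <- sqrt(gr$gx^2 + gr$gy^2)
  band <- abs(res$phi) < 10 & abs(res$phi) > 2  # away from kink and front
  expect_true(all(nrm[band] > 0.9 & nrm[band] < 1.1))
})

test_that("Chan-Vese is exact on a noiseless two-phase image", {
  tp <- two_phase_disk(96, r = 28)
  phi0 <- rectangle_to_levelset(make_rect(47.5, 47.5, 40, 40), tp$grid)
  res <- cv_evolve(phi0, tp$grid, cv_params())
  expect_gte(dice(res$mask, tp$truth)$value, 0.99)
})

test_that("on a constant image the Chan-Vese data force vanishes", {
  n <- 32
  flat <- image_grid(matrix(0.5, n, n))
  phi <- disk_sdf(n, 15, 15, 9)
  p <- cv_params(mu_cv = 0.05)
  st <- compute_region_means(flat, phi, p$eps)
  r <- cv_rhs(phi, flat, st, p)
  # only the length term remains: bounded by mu_cv * |kappa| * delta
  kap <- compute_curvature(phi)$kappa
  bound <- p$mu_cv * abs(kap) * smoothed_dirac(phi, p$eps) + 1e-10
  expect_true(all(abs(r) <= bound))
})

test_that("length+area-only evolution shrinks the contour monotonically until it vanishes", {
  n <- 64
  blank <- image_grid(matrix(0.5, n, n))
  phi0 <- rectangle_to_levelset(make_rect(31.5, 31.5, 22, 22), blank)
  p <- evolution_params(lambda1 = 0, lambda2 = 0, mu = 10,
                        max_iterations = 3000L, tolerance = 0,
                        snapshot_stride = 25L)
  res <- evolve_proposed(phi0, blank, p)
  expect_identical(res$reason, "contour_vanished")
  areas <- vapply(res$snapshots, sum, 0L)
  expect_true(all(diff(areas) <= 0))
})

test_that("evolutions are deterministic and report contract errors", {
  tp <- two_phase_disk(64, r = 18)
  phi0 <- rectangle_to_levelset(make_rect(31.5, 31.5, 26, 26), tp$grid)
  p <- evolution_params(max_iterations = 120L)
  r1 <- evolve_proposed(phi0, tp$grid, p)
  r2 <- evolve_proposed(phi0, tp$grid, p)
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$iterations, r2$iterations)

  # phi0 of one sign is rejected
  expect_error(evolve_proposed(matrix(1, 64, 64), tp$grid, p),
               class = "osg_param_error")
  # non-finite phi0 rejected
  bad <- phi0; bad[5, 5] <- NaN
  expect_error(evolve_proposed(bad, tp$grid, p), class = "osg_numeric_error")
  expect_error(evolution_params(alpha = 0), class = "osg_param_error")
  expect_error(cplse_params(dt = 10, mu_reg = 0.2), class = "osg_param_error")
})

test_that("a contour with no support vanishes with the documented reason", {
  n <- 48
  blank <- image_grid(matrix(0.5, n, n))
  phi0 <- disk_sdf(n, 23.5, 23.5, 6)
  p <- evolution_params(lambda1 = 0, lambda2 = 0, mu = 10,
                        max_iterations = 3000L, tolerance = 0)
  res <- evolve_proposed(phi0, blank, p)
  expect_identical(res$reason, "contour_vanished")
  expect_false(any(res$mask))
})

test_that("redistancing restores the unit-gradient property", {
  n <- 64
  phi <- 3 * disk_sdf(n, 31.5, 31.5, 15)   # slope 3 everywhere
  out <- redistance(phi, sweeps = 60L)
  gr <- organoidseg:::cpp_grad(out)
  nrm <- sqrt(gr$gx^2 + gr$gy^2)
  band <- abs(out) < 8 & abs(out) > 2
  expect_true(mean(abs(nrm[band] - 1)) < 0.1)
  # the zero level set does not move appreciably
  expect_lt(mean(xor(out < 0, phi < 0)), 0.01)
})
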