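RTLN10 <- R_GAS * 298.15 * log(10)

test_that("decoupled dyad reproduces one-site Henderson-Hasselbalch pointwise", {
  ph <- seq(0, 14, 0.05)
  crv <- dyad_titration(coupled_dyad(4.2, 6.8, w = 0), ph)
  expect_equal(crv$frac_a, hh_curve(ph, 4.2), tolerance = 1e-12)
  expect_equal(crv$frac_b, hh_curve(ph, 6.8), tolerance = 1e-12)
})

test_that("dyad marginals match brute-force 4-state enumeration", {
  ph <- seq(-2, 16, 0.25)
  cases <- list(c(4, 4, 8), c(3.5, 5.2, -4), c(10, 4, 2.5), c(7, 7, 0))
  for (cs in cases) {
    d <- coupled_dyad(cs[1], cs[2], w = cs[3])
    crv <- dyad_titration(d, ph)
    oracle <- brute_dyad_marginals(cs[1], cs[2], cs[3], 298.15, ph)
    expect_equal(crv$frac_a, unname(oracle[, 1]), tolerance = 1e-10)
    expect_equal(crv$frac_b, unname(oracle[, 2]), tolerance = 1e-10)
  }
})

test_that("microstate populations normalize exactly and saturate at the pH extremes", {
  d <- coupled_dyad(4, 5, w = 6)
  ms <- dyad_microstates(d, seq(-5, 20, 0.5))
  expect_equal(ms$HH + ms$Hm + ms$mH + ms$mm, rep(1, nrow(ms)),
               tolerance = 1e-12)
  crv <- dyad_titration(d, c(-30, 40))
  expect_equal(crv$frac_a[1], 1, tolerance = 1e-9)
  expect_equal(crv$frac_b[1], 1, tolerance = 1e-9)
  expect_equal(crv$frac_a[2], 0, tolerance = 1e-9)
  expect_equal(crv$frac_b[2], 0, tolerance = 1e-9)
})

test_that("total protons bound decreases monotonically with pH", {
  for (w in c(-6, 0, 4, 12)) {
    crv <- dyad_titration(coupled_dyad(3.8, 4.4, w = w), seq(0, 14, 0.1))
    expect_true(all(diff(crv$frac_a + crv$frac_b) < 1e-12))
  }
})

test_that("apparent pKa reads half-protonation to high precision", {
  ph <- seq(0, 14, 0.1)
  crv <- dyad_titration(coupled_dyad(4, 9, w = 0), ph)
  expect_equal(apparent_pka(crv, "a"), 4, tolerance = 1e-6)
  expect_equal(apparent_pka(crv, "b"), 9, tolerance = 1e-6)

  # repulsive symmetric dyad: both apparent values shift outward from 4
  crv2 <- dyad_titration(coupled_dyad(4, 4, w = 3 * RTLN10), ph)
  # dense-grid scan as independent locator (coarse pass, then 1e-5 steps)
  coarse <- seq(0, 14, 0.01)
  oc <- brute_dyad_marginals(4, 4, 3 * RTLN10, 298.15, coarse)
  near <- coarse[which.min(abs(oc[, 1] - 0.5))]
  dense <- seq(near - 0.02, near + 0.02, 1e-5)
  oracle <- brute_dyad_marginals(4, 4, 3 * RTLN10, 298.15, dense)
  half_a <- dense[which.min(abs(oracle[, 1] - 0.5))]
  expect_lt(abs(apparent_pka(crv2, "a") - half_a), 1e-5)

  narrow <- dyad_titration(coupled_dyad(4, 9, w = 0), seq(6, 7, 0.1))
  expect_error(apparent_pka(narrow, "a"), "widen")
})

test_that("repulsive coupling splits a symmetric dyad's titration into two waves", {
  w <- 4 * RTLN10
  crv <- dyad_titration(coupled_dyad(4, 4, w = w), seq(-2, 14, 0.001))
  protons <- crv$frac_a + crv$frac_b
  ph <- crv$ph
  first <- ph[which.min(abs(protons - 1.5))]   # first deprotonation midpoint
  second <- ph[which.min(abs(protons - 0.5))]  # second deprotonation midpoint
  expect_lt(first, 4)
  expect_gt(second, 4)
  expect_gt(second - first, 2)  # separation grows with w; > 2 pK at w = 4 RTln10
})

test_that("triad reduction fixes the most acidic site and shifts the rest", {
  sites <- tibble::tibble(id = c("D10", "E45", "K12"),
                          pka = c(3.0, 4.0, 5.0))
  coup0 <- tibble::tibble(id1 = c("D10", "D10", "E45"),
                          id2 = c("E45", "K12", "K12"),
                          w = c(0, 0, 0))
  red <- reduce_triad(sites, coup0)
  expect_equal(red$fixed, "D10")
  expect_equal(red$dyad$pk_a, 4.0)
  expect_equal(red$dyad$pk_b, 5.0)
  expect_equal(red$dyad$w, 0)

  coup1 <- coup0
  coup1$w <- c(RTLN10, RTLN10, 2.5)
  red1 <- reduce_triad(sites, coup1)
  expect_equal(red1$dyad$pk_a, 5.0, tolerance = 1e-12)
  expect_equal(red1$dyad$pk_b, 6.0, tolerance = 1e-12)
  expect_equal(red1$dyad$w, 2.5)

  # permutation invariance
  perm <- reduce_triad(sites[c(3, 1, 2), ], coup1[c(2, 3, 1), ])
  expect_equal(perm$fixed, red1$fixed)
  expect_equal(perm$dyad$pk_a, red1$dyad$pk_a)
  expect_equal(perm$dyad$pk_b, red1$dyad$pk_b)

  tied <- sites
  tied$pka <- c(4, 4, 5)
  expect_error(reduce_triad(tied, coup0), "Tie")
})

test_that("Henderson-Hasselbalch fit recovers the generating pKa", {
  ph <- seq(1, 8, length.out = 50)
  fit <- hh_fit(ph, hh_curve(ph, 4.0))
  expect_equal(fit$pka, 4.0, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(hh_curve(fit$pka, fit$pka), 0.5)

  withr::with_seed(31, {
    noisy <- hh_curve(ph, 4.0) + rnorm(50, 0, 0.02)
    expect_lt(abs(hh_fit(ph, noisy)$pka - 4.0), 0.05)
  })
  expect_error(hh_fit(ph, rep(0.5, 50)), "no pKa information")
  expect_error(hh_fit(c(1, 2), c(1, 0)), ">= 3")
})

test_that("conditional predictions carry their condition and refuse empty ones", {
  cy <- ddg_from_legs(fe_estimate(3, 0.2), fe_estimate(1, 0.1))
  cond <- conditional_pka(cy, "ASP", condition = "HIS72 doubly protonated")
  std <- pka_from_ddg(cy, "ASP")
  expect_equal(cond$pka, std$pka)
  expect_equal(cond$kind, "conditional")
  expect_equal(cond$condition, "HIS72 doubly protonated")
  expect_error(conditional_pka(cy, "ASP", condition = "  "), "non-empty")
})

test_that("benchmark layer refuses to pool standard and conditional estimates", {
  rec <- tibble::tibble(class = rep("ASP", 4), expt_pka = c(4, 5, 3, 4.5),
                        pred = c(4.1, 4.9, 3.2, 4.4),
                        kind = c("standard", "standard", "conditional",
                                 "standard"))
  expect_error(metric_bootstrap(rec, n_boot = 20), "mixed")
  expect_silent(metric_bootstrap(rec, n_boot = 20, allow_mixed_kinds = TRUE))
})

test_that("dyad interaction energy recovers from conditional ddG quadruples", {
  expect_equal(dyad_w_from_ddg(2, 7, 10, 15), 5)
  expect_warning(dyad_w_from_ddg(2, 7, 10, 14), "closure")
})
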