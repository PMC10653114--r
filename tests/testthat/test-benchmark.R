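make_records <- function(n, seed = 1, classes = c("ASP", "GLU", "LYS"),
                         err_sd = 0.5) {
  withr::with_seed(seed, {
    cl <- sample(classes, n, replace = TRUE)
    refs <- residue_class_refs()
    expt <- refs$ref_pka[match(cl, refs$class)] + rnorm(n, 0, 1.5)
    tibble::tibble(protein = "P", residue = sprintf("R%d", seq_len(n)),
                   class = cl, expt_pka = expt,
                   pred = expt + rnorm(n, 0, err_sd))
  })
}

test_that("AUE matches hand arithmetic and its invariances", {
  expect_equal(aue(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(aue(c(2, 3, 4), c(1, 2, 3)), 1)
  expect_equal(aue(c(3, 5), c(4, 4)), 1.0)
  expect_error(aue(1:3, 1:2), "equal")
  # permutation invariance and shift equivariance
  p <- c(3.2, 4.7, 9.9)
  e <- c(4, 4.5, 10.4)
  expect_equal(aue(p, e), aue(rev(p), rev(e)))
  expect_equal(aue(p + 2, e + 2), aue(p, e))
})

test_that("Pearson matches closed forms and guards degenerate input", {
  e <- c(2, 4.5, 7, 9)
  expect_equal(pearson_r(2 * e + 3, e), 1.0)
  expect_equal(pearson_r(-e, e), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(rep(4, 3), e[1:3]), "zero variance")
  expect_error(pearson_r(1, 1), ">= 2")
})

test_that("metric bootstrap is seed-deterministic with sane degenerate limits", {
  rec <- make_records(40, seed = 2)
  r1 <- metric_bootstrap(rec, n_boot = 300, seed = 5)
  r2 <- metric_bootstrap(rec, n_boot = 300, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$n, 40L)
  expect_true(r1$pearson > 0.8)

  # identical unsigned error everywhere: aue = e, aue_se = 0
  const <- tibble::tibble(class = "ASP", expt_pka = c(3, 4, 5, 6),
                          pred = c(3, 4, 5, 6) + 0.7)
  rep_c <- metric_bootstrap(const, n_boot = 100, seed = 1)
  expect_equal(rep_c$aue, 0.7)
  expect_equal(rep_c$aue_se, 0)
})

test_that("bootstrap AUE SE matches the half-normal closed form", {
  # i.i.d. Gaussian errors: SD of mean |error| = sigma*sqrt(1 - 2/pi)/sqrt(n)
  sigma <- 0.8
  n <- 100
  rec <- withr::with_seed(7, {
    expt <- runif(n, 2, 12)
    tibble::tibble(class = "ASP", expt_pka = expt,
                   pred = expt + rnorm(n, 0, sigma))
  })
  est <- metric_bootstrap(rec, n_boot = 2000, seed = 3)$aue_se
  theory <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(est / theory, 1.3)
  expect_gt(est / theory, 1 / 1.3)
})

test_that("the null model predicts the class reference everywhere", {
  rec <- tibble::tibble(class = c("ASP", "GLU", "LYS"),
                        expt_pka = c(3.94, 5.0, 10.4))
  nm <- null_model(rec)
  expect_equal(nm$pred_null, c(3.94, 4.25, 10.4))
  # residues at their reference have zero null error
  expect_equal(abs(nm$pred_null - nm$expt_pka)[c(1, 3)], c(0, 0))
  expect_error(null_model(tibble::tibble(class = "HIS", expt_pka = 6)),
               "Unknown residue class")
})

test_that("null AUE grows linearly with the injected shift magnitude", {
  for (d in c(0.5, 1, 2)) {
    rec <- tibble::tibble(class = rep("GLU", 10),
                          expt_pka = 4.25 + d * rep(c(-1, 1), 5))
    nm <- null_model(rec)
    expect_equal(aue(nm$pred_null, nm$expt_pka), d)
  }
})

test_that("within-class null Pearson is undefined but cross-class is computable", {
  rec <- make_records(30, seed = 9)
  nm <- null_model(rec)
  one_class <- nm[nm$class == nm$class[1], ]
  expect_error(pearson_r(one_class$pred_null, one_class$expt_pka),
               "zero variance")
  expect_true(is.finite(pearson_r(nm$pred_null, nm$expt_pka)))
})

test_that("class breakdown averages per-class AUEs into the overall row", {
  # two classes with per-class AUE 1.0 and 0.0 -> overall 0.5
  rec <- tibble::tibble(
    class = rep(c("ASP", "GLU"), each = 4),
    expt_pka = c(3, 4, 5, 6, 3, 4, 5, 6),
    pred = c(4, 5, 6, 7, 3, 4, 5, 6))
  bd <- class_breakdown(rec, n_boot = 100, seed = 1)
  expect_equal(bd$aue[bd$class == "ASP"], 1.0)
  expect_equal(bd$aue[bd$class == "GLU"], 0.0)
  expect_equal(bd$aue[bd$class == "overall"], 0.5)

  # single-class input: breakdown equals the full-set report
  rec1 <- make_records(20, seed = 4, classes = "LYS")
  bd1 <- class_breakdown(rec1, n_boot = 200, seed = 2)
  full <- metric_bootstrap(rec1, n_boot = 200, seed = 2)
  expect_equal(bd1$aue[bd1$class == "LYS"], full$aue)
  expect_equal(bd1$aue[bd1$class == "overall"], full$aue)

  # permutation of records changes nothing
  rec_p <- rec[sample(nrow(rec)), ]
  bd_p <- class_breakdown(rec_p, n_boot = 100, seed = 1)
  expect_equal(bd_p$aue, bd$aue)

  # residue-weighted alternative
  bdw <- class_breakdown(rec, n_boot = 100, seed = 1, residue_weighted = TRUE)
  expect_equal(bdw$aue[bdw$class == "overall"], aue(rec$pred, rec$expt_pka))

  # an underpopulated class is skipped with a warning
  rec_small <- rbind(rec, tibble::tibble(class = "LYS", expt_pka = 10.4,
                                         pred = 10.5))
  expect_warning(class_breakdown(rec_small, n_boot = 50, seed = 1),
                 "skipped")
})

test_that("adjusted predictions replace flagged residues only", {
  rec <- make_records(10, seed = 3)
  adj <- tibble::tibble(protein = "P", residue = c("R2", "R7"),
                        pred = c(99, 98))
  out <- apply_adjustments(rec, adj)
  expect_equal(out$pred[out$residue == "R2"], 99)
  expect_equal(out$pred[out$residue == "R7"], 98)
  expect_equal(out$pred[!out$residue %in% c("R2", "R7")],
               rec$pred[!rec$residue %in% c("R2", "R7")])
  expect_equal(sum(out$adjusted), 2L)
  expect_error(
    apply_adjustments(rec, tibble::tibble(protein = "P", residue = "R99",
                                          pred = 1)),
    "absent")
})

test_that("convergence curve is deterministic with zero SD at full size", {
  ws <- gaussian_cft_pair(8, 4, 60, 60, seed = 12)
  cc <- convergence_curve(ws, n_grid = c(10, 30, 60), reps = 10, seed = 4)
  expect_identical(cc, convergence_curve(ws, c(10, 30, 60), reps = 10,
                                         seed = 4))
  expect_equal(cc$sd_dg[cc$n == 60], 0, tolerance = 1e-9)
  expect_true(all(cc$sd_dg[cc$n < 60] > 0))
  expect_error(convergence_curve(ws, c(1, 10)), ">= 2")
  expect_error(convergence_curve(ws, c(10, 100)), "exceeds")
})

test_that("subsample scatter shrinks with n and stays near the truth", {
  sds <- matrix(NA_real_, nrow = 12, ncol = 3)
  for (s in 1:12) {
    ws <- gaussian_cft_pair(5, 5, 120, 120, seed = 300 + s)
    cc <- convergence_curve(ws, n_grid = c(10, 40, 120), reps = 12,
                            seed = s)
    sds[s, ] <- cc$sd_dg
    expect_true(all(abs(cc$mean_dg - 5) < 4))  # within dissipation scale
  }
  avg <- colMeans(sds)
  expect_true(all(diff(avg) < 0))
})
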