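RTLN10 <- R_GAS * 298.15 * log(10)

test_that("cycle ddG is the leg difference with quadrature-propagated SE", {
  cy <- ddg_from_legs(fe_estimate(10, 0.3), fe_estimate(10, 0.4))
  expect_equal(cy$ddg, 0)
  expect_equal(cy$se, 0.5)

  exact <- ddg_from_legs(fe_estimate(7, 0), fe_estimate(2, 0))
  expect_equal(exact$ddg, 5)
  expect_equal(exact$se, 0)

  swapped <- ddg_from_legs(fe_estimate(2, 0.4), fe_estimate(7, 0.3))
  expect_equal(swapped$ddg, -5)
  expect_equal(swapped$se, 0.5)

  expect_error(
    ddg_from_legs(fe_estimate(1, temperature = 298.15),
                  fe_estimate(1, temperature = 310)),
    "temperatures differ")
})

test_that("zero ddG returns each class reference pKa", {
  cy <- ddg_from_legs(fe_estimate(10, 0), fe_estimate(10, 0))
  expect_equal(pka_from_ddg(cy, "ASP")$pka, 3.94)
  expect_equal(pka_from_ddg(cy, "GLU")$pka, 4.25)
  expect_equal(pka_from_ddg(cy, "LYS")$pka, 10.4)
  expect_error(pka_from_ddg(cy, "HIS"), "Unknown residue class")
})

test_that("one RT ln10 of ddG shifts the pKa by one unit with the class sign", {
  cy <- ddg_from_legs(fe_estimate(RTLN10, 0), fe_estimate(0, 0))
  expect_equal(pka_from_ddg(cy, "GLU")$pka, 5.25, tolerance = 1e-12)
  # base class: a deprotonation penalty lowers the pKa
  expect_equal(pka_from_ddg(cy, "LYS")$pka, 9.4, tolerance = 1e-12)
  cy2 <- ddg_from_legs(fe_estimate(-2 * RTLN10, 0), fe_estimate(0, 0))
  expect_equal(pk_int_from_ddg(cy2, "ASP")$pka, 3.94 - 2, tolerance = 1e-12)
})

test_that("SE propagation combines cycle and reference uncertainty in quadrature", {
  cy <- ddg_from_legs(fe_estimate(0, 0), fe_estimate(0, 0))
  expect_equal(pka_from_ddg(cy, "ASP")$se, 0.03)
  cy2 <- ddg_from_legs(fe_estimate(0, 3), fe_estimate(0, 4))
  p <- pka_from_ddg(cy2, "GLU")
  expect_equal(p$se, sqrt(0.05^2 + (5 / RTLN10)^2), tolerance = 1e-12)
  expect_equal(pka_from_ddg(cy2, "GLU", include_ref_error = FALSE)$se,
               5 / RTLN10, tolerance = 1e-12)
})

test_that("pKa conversion round-trips back to ddG", {
  for (cl in c("ASP", "GLU", "LYS")) {
    for (ddg in c(-12.3, 0, 4.56, 20)) {
      cy <- ddg_from_legs(fe_estimate(ddg, 0), fe_estimate(0, 0))
      p <- pka_from_ddg(cy, cl)
      expect_equal(ddg_from_pka(p$pka, cl), ddg, tolerance = 1e-10)
    }
  }
})

test_that("acid pKa rises and base pKa falls monotonically with ddG", {
  grid <- seq(-20, 20, 4)
  acid <- vapply(grid, function(d) {
    pka_from_ddg(ddg_from_legs(fe_estimate(d, 0), fe_estimate(0, 0)),
                 "ASP")$pka
  }, numeric(1))
  base <- vapply(grid, function(d) {
    pka_from_ddg(ddg_from_legs(fe_estimate(d, 0), fe_estimate(0, 0)),
                 "LYS")$pka
  }, numeric(1))
  expect_true(all(diff(acid) > 0))
  expect_true(all(diff(base) < 0))
})

test_that("intrinsic predictions share arithmetic with standard ones, differing in kind", {
  cy <- ddg_from_legs(fe_estimate(3, 0.2), fe_estimate(1, 0.1))
  std <- pka_from_ddg(cy, "GLU")
  int <- pk_int_from_ddg(cy, "GLU")
  expect_equal(int$pka, std$pka)
  expect_equal(int$se, std$se)
  expect_equal(std$kind, "standard")
  expect_equal(int$kind, "intrinsic")
})

test_that("consensus is the unweighted mean with quadrature-mean SE", {
  preds <- rbind(
    pka_from_ddg(ddg_from_legs(fe_estimate(ddg_from_pka(4.0, "ASP"), 0),
                               fe_estimate(0, 0)), "ASP",
                 include_ref_error = FALSE),
    pka_from_ddg(ddg_from_legs(fe_estimate(ddg_from_pka(5.0, "ASP"), 0),
                               fe_estimate(0, 0)), "ASP",
                 include_ref_error = FALSE))
  preds$se <- c(0.2, 0.2)
  cons <- consensus_pka(preds)
  expect_equal(cons$pka, 4.5)
  expect_equal(cons$se, sqrt(0.08) / 2)
  expect_equal(cons$source, "consensus")

  # permutation invariance and single-input identity
  expect_equal(consensus_pka(preds[2:1, ])$pka, cons$pka)
  single <- consensus_pka(preds[1, ])
  expect_equal(single$pka, preds$pka[1])
  expect_equal(single$source, "consensus")

  mixed <- preds
  mixed$class <- c("ASP", "GLU")
  expect_error(consensus_pka(mixed), "mixed")
})

test_that("inverse-variance weighting and ddG-level consensus are available", {
  preds <- rbind(
    pka_from_ddg(ddg_from_legs(fe_estimate(0, 0), fe_estimate(0, 0)), "ASP"),
    pka_from_ddg(ddg_from_legs(fe_estimate(0, 0), fe_estimate(0, 0)), "ASP"))
  preds$pka <- c(4, 5)
  preds$se <- c(0.1, 0.3)
  wtd <- consensus_pka(preds, weighted = TRUE)
  w <- 1 / preds$se^2
  expect_equal(wtd$pka, sum(w * preds$pka) / sum(w))
  expect_equal(wtd$se, sqrt(1 / sum(w)))

  cys <- list(ddg_from_legs(fe_estimate(2, 0.1), fe_estimate(0, 0)),
              ddg_from_legs(fe_estimate(4, 0.2), fe_estimate(0, 0)))
  cd <- consensus_ddg(cys)
  expect_equal(cd$ddg, 3)
  expect_equal(cd$se, sqrt(0.1^2 + 0.2^2) / 2)
})

test_that("reference table overrides replace matching classes only", {
  refs <- residue_class_refs(tibble::tibble(class = "ASP", ref_pka = 4.0,
                                            ref_pka_se = 0.1))
  expect_equal(refs$ref_pka[refs$class == "ASP"], 4.0)
  expect_equal(refs$ref_pka[refs$class == "LYS"], 10.4)
})

test_that("a noiseless synthetic shift survives the whole cycle exactly", {
  for (cl in c("GLU", "LYS")) {
    shift <- 1.75
    ddg <- ddg_from_pka(3.0 + shift, cl) - ddg_from_pka(3.0, cl)  # sign via class
    ws_p <- workset(30 + ddg, -(30 + ddg))
    ws_s <- workset(30, -30)
    cy <- ddg_from_legs(bar_estimate(ws_p), bar_estimate(ws_s))
    ref <- residue_class_refs()
    expect_equal(pka_from_ddg(cy, cl)$pka,
                 ref$ref_pka[ref$class == cl] + shift, tolerance = 1e-7)
  }
})
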