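#' Crooks-consistent Gaussian work distributions
#'
#' Draws forward and reverse work samples from the Gaussian pair that
#' satisfies the Crooks fluctuation theorem exactly at the density level for
#' a specified true \eqn{\Delta G} and dissipation: forward works
#' \eqn{\sim N(\Delta G + \beta\sigma^2/2,\ \sigma^2)} and reverse works
#' (in their own direction) \eqn{\sim N(-\Delta G + \beta\sigma^2/2,\
#' \sigma^2)}, so that \eqn{P_F(W)/P_R(-W) = e^{\beta(W - \Delta G)}}. The
#' mean dissipated work per direction is \eqn{\beta\sigma^2/2}.
#'
#' This stands in for molecular dynamics output: the generator emulates the
#' work *statistics* of fast-switching alchemical transitions, nothing about
#' conformational sampling.
#'
#' @param dg_true True free energy difference, kJ/mol.
#' @param sigma Work distribution standard deviation, kJ/mol (> 0).
#' @param n_forward,n_reverse Transitions per direction (default 200 each,
#'   the protocol scale emulated throughout).
#' @param temperature Temperature in Kelvin.
#' @param seed RNG seed; output is fully deterministic given it.
#' @param label Label passed to the workset.
#' @return A [workset()].
#' @examples
#' ws <- gaussian_cft_pair(dg_true = 10, sigma = 5, seed = 7)
#' bar_estimate(ws)$value
#' @export
gaussian_cft_pair <- function(dg_true, sigma, n_forward = 200L,
                              n_reverse = 200L, temperature = 298.15,
                              seed = 1L, label = "") {
  mixture_cft_pair(dg_true, components = tibble(weight = 1, sigma = sigma),
                   n_forward = n_forward, n_reverse = n_reverse,
                   temperature = temperature, seed = seed, label = label)
}

#' Crooks-consistent Gaussian-mixture work distributions
#'
#' Non-Gaussian stress-test generator: each mixture component is a
#' Crooks-consistent Gaussian pair at the *common* `dg_true`, and because
#' the same exponential factor \eqn{e^{\beta(W - \Delta G)}} relates every
#' component's forward and reverse densities, the mixture as a whole
#' satisfies the Crooks relation too. Sampling draws a component per
#' transition (by weight) and then the Gaussian work.
#'
#' @inheritParams gaussian_cft_pair
#' @param components Data frame with columns `weight` and `sigma`; weights
#'   must sum to 1 (tolerance 1e-9) and all sigmas be > 0.
#' @return A [workset()].
#' @export
mixture_cft_pair <- function(dg_true, components, n_forward = 200L,
                             n_reverse = 200L, temperature = 298.15,
                             seed = 1L, label = "") {
  check_scalar_number(dg_true, "dg_true")
  components <- as_tibble(components)
  if (!all(c("weight", "sigma") %in% names(components))) {
    abort("`components` needs columns `weight` and `sigma`.")
  }
  if (any(components$sigma <= 0)) abort("All component sigmas must be > 0.")
  if (abs(sum(components$weight) - 1) > 1e-9) {
    abort("Component weights must sum to 1.")
  }
  if (n_forward < 1L || n_reverse < 1L) {
    abort("Need at least one transition per direction.")
  }
  beta <- beta_factor(temperature)
  k <- nrow(components)
  draw <- function(n, sign_dg) {
    comp <- if (k == 1L) rep(1L, n) else {
      sample.int(k, n, replace = TRUE, prob = components$weight)
    }
    sig <- components$sigma[comp]
    rnorm(n, mean = sign_dg * dg_true + beta * sig^2 / 2, sd = sig)
  }
  withr::with_seed(seed, {
    wf <- draw(n_forward, +1)
    wr <- draw(n_reverse, -1)
    workset(forward = wf, reverse = wr, temperature = temperature,
            label = label)
  })
}

#' Empirical Crooks density-ratio check
#'
#' Regression test of generated (or measured) work data against the Crooks
#' fluctuation theorem: on shared histogram bins, the log ratio
#' \eqn{\ln[\hat P_F(W)/\hat P_R(-W)]} is regressed on \eqn{W}. For
#' Crooks-consistent data the slope estimates \eqn{\beta} and the intercept
#' \eqn{-\beta\,\Delta G}, so `dg_implied = -intercept/slope` recovers the
#' free energy difference without any estimator.
#'
#' The fit is weighted by the delta-method variance of each bin's log count
#' ratio (\eqn{1/n_F^{bin} + 1/n_R^{bin}}), which keeps sparsely populated
#' tail bins from biasing the slope.
#'
#' @param ws A [workset()].
#' @param bins Number of shared histogram bins.
#' @param min_count Minimum per-direction count for a bin to enter the fit.
#' @return A one-row tibble: `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `beta`, `dg_implied`, `n_bins`.
#' @export
cft_ratio_check <- function(ws, bins = 60L, min_count = 5L) {
  check_workset(ws)
  f <- ws$forward
  r <- -ws$reverse
  rng <- range(c(f, r))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  cf <- tabulate(findInterval(f, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  cr <- tabulate(findInterval(r, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  ok <- cf >= min_count & cr >= min_count
  if (sum(ok) < 3L) {
    abort("Too few overlapping histogram bins for the density-ratio fit.")
  }
  log_ratio <- log(cf[ok] / length(f)) - log(cr[ok] / length(r))
  x <- mids[ok]
  wts <- 1 / (1 / cf[ok] + 1 / cr[ok])
  fit <- stats::lm(log_ratio ~ x, weights = wts)
  cf_mat <- summary(fit)$coefficients
  tibble(
    slope = cf_mat[2, 1], slope_se = cf_mat[2, 2],
    intercept = cf_mat[1, 1], intercept_se = cf_mat[1, 2],
    beta = beta_factor(ws$temperature),
    dg_implied = -cf_mat[1, 1] / cf_mat[2, 1],
    n_bins = sum(ok)
  )
}

#' Synthetic residue benchmark dataset with known ground truth
#'
#' Emulates the design of a pKa benchmark — residue classes at configurable
#' proportions (default mirroring a 57 ASP / 48 GLU / 39 LYS composition),
#' true pKa shifts drawn from a truncated normal, and per-residue
#' protein/peptide leg worksets generated by [gaussian_cft_pair()] at the
#' free energies those shifts imply. The "experimental" pKa of each residue
#' is `reference + true shift` (plus optional measurement noise), so
#' pipeline errors against `expt_pka` measure recovery of the injected
#' truth.
#'
#' A stated fraction of residues is marked as coupled dyad partners with an
#' interaction free energy recorded in the truth table; the work
#' distributions themselves always reflect the intrinsic (uncoupled) shift,
#' leaving the pH-dependent correction to the coupling module.
#'
#' @param n_res Number of residues (>= 1).
#' @param class_probs Named class proportions (renormalized).
#' @param shift_sd SD of the true-shift distribution, pK units.
#' @param shift_max Truncation bound: shifts lie in `[-shift_max,
#'   shift_max]`.
#' @param sigma Work distribution SD per leg, kJ/mol.
#' @param n_transitions Transitions per direction per leg.
#' @param coupling_fraction Fraction of residues assigned a coupled partner
#'   (paired within the set; rounded down to whole pairs).
#' @param coupling_w_range Range from which dyad interaction energies are
#'   drawn uniformly, kJ/mol.
#' @param expt_noise_sd SD of measurement noise added to `expt_pka`.
#' @param temperature Temperature in Kelvin.
#' @param seed Master RNG seed; all per-residue seeds derive from it.
#' @param refs Reference table from [residue_class_refs()].
#' @return A list with
#'   * `records`: benchmark-ready tibble (`protein`, `residue`, `class`,
#'     `expt_pka`);
#'   * `worksets`: per-residue list of `list(protein = , peptide = )`
#'     [workset()]s, named by residue id;
#'   * `truth`: tibble of every latent value (true shift and ΔΔG, leg free
#'     energies, generator settings, coupling assignments).
#' @export
synthetic_residue_dataset <- function(n_res,
                                      class_probs = c(ASP = 57, GLU = 48,
                                                      LYS = 39),
                                      shift_sd = 1.5, shift_max = 5,
                                      sigma = 5, n_transitions = 200L,
                                      coupling_fraction = 0,
                                      coupling_w_range = c(2, 8),
                                      expt_noise_sd = 0,
                                      temperature = 298.15, seed = 1L,
                                      refs = residue_class_refs()) {
  if (n_res < 1L) abort("`n_res` must be >= 1.")
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (coupling_fraction < 0 || coupling_fraction > 1) {
    abort("`coupling_fraction` must be in [0, 1].")
  }
  class_probs <- class_probs / sum(class_probs)
  scale <- rt_ln10(temperature)
  truth <- withr::with_seed(seed, {
    classes <- sample(names(class_probs), n_res, replace = TRUE,
                      prob = class_probs)
    ## truncated-normal shifts: redraw outside the bound
    shifts <- rnorm(n_res, 0, shift_sd)
    while (any(bad <- abs(shifts) > shift_max)) {
      shifts[bad] <- rnorm(sum(bad), 0, shift_sd)
    }
    dg_peptide <- runif(n_res, 20, 60)
    leg_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_res),
                        ncol = 2)
    noise <- if (expt_noise_sd > 0) rnorm(n_res, 0, expt_noise_sd) else 0
    n_pairs <- floor(coupling_fraction * n_res / 2)
    partner <- rep(NA_character_, n_res)
    w_pair <- rep(NA_real_, n_res)
    if (n_pairs > 0) {
      picked <- sample.int(n_res, 2L * n_pairs)
      ws <- runif(n_pairs, coupling_w_range[1], coupling_w_range[2])
      for (p in seq_len(n_pairs)) {
        i <- picked[2L * p - 1L]
        j <- picked[2L * p]
        partner[i] <- sprintf("R%03d", j)
        partner[j] <- sprintf("R%03d", i)
        w_pair[c(i, j)] <- ws[p]
      }
    }
    sgn <- unname(vapply(classes, class_sign, numeric(1)))
    ref_idx <- match(classes, refs$class)
    tibble(
      protein = "SYNTH",
      residue = sprintf("R%03d", seq_len(n_res)),
      class = classes,
      true_shift = shifts,
      true_ddg = sgn * shifts * scale,
      ref_pka = refs$ref_pka[ref_idx],
      expt_pka = refs$ref_pka[ref_idx] + shifts + noise,
      dg_peptide = dg_peptide,
      dg_protein = dg_peptide + sgn * shifts * scale,
      sigma = sigma,
      n_transitions = as.integer(n_transitions),
      temperature = temperature,
      seed_protein = leg_seeds[, 1],
      seed_peptide = leg_seeds[, 2],
      partner = partner,
      coupling_w = w_pair
    )
  })
  worksets <- lapply(seq_len(n_res), function(i) {
    list(
      protein = gaussian_cft_pair(truth$dg_protein[i], sigma,
                                  n_forward = n_transitions,
                                  n_reverse = n_transitions,
                                  temperature = temperature,
                                  seed = truth$seed_protein[i],
                                  label = paste(truth$residue[i], "protein")),
      peptide = gaussian_cft_pair(truth$dg_peptide[i], sigma,
                                  n_forward = n_transitions,
                                  n_reverse = n_transitions,
                                  temperature = temperature,
                                  seed = truth$seed_peptide[i],
                                  label = paste(truth$residue[i], "peptide"))
    )
  })
  names(worksets) <- truth$residue
  list(
    records = truth[, c("protein", "residue", "class", "expt_pka")],
    worksets = worksets,
    truth = truth
  )
}

#' Run the full prediction pipeline on a synthetic dataset
#'
#' For every residue: BAR on the protein and peptide leg worksets (with
#' bootstrap SEs), thermodynamic-cycle ΔΔG, and conversion to a pKa
#' prediction against the class reference. Returns the benchmark records
#' with `pred`/`pred_se` columns, ready for [metric_bootstrap()] or
#' [class_breakdown()].
#'
#' @param dataset Output of [synthetic_residue_dataset()].
#' @param n_boot Bootstrap replicates per leg (0 skips SEs).
#' @param seed RNG seed for the bootstraps.
#' @param source Provenance tag recorded on the predictions.
#' @param refs Reference table.
#' @param include_ref_error Include reference pKa° SE in prediction SEs.
#' @return A tibble: `protein`, `residue`, `class`, `expt_pka`, `pred`,
#'   `pred_se`, `ddg`, `ddg_se`, `kind`, `source`.
#' @export
predict_dataset <- function(dataset, n_boot = 100L, seed = 1L,
                            source = "synthetic",
                            refs = residue_class_refs(),
                            include_ref_error = FALSE) {
  records <- as_tibble(dataset$records)
  worksets <- dataset$worksets
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    rid <- records$residue[i]
    legs <- worksets[[rid]]
    prot <- bar_estimate(legs$protein, n_boot = n_boot, seed = seed + 2L * i)
    pept <- bar_estimate(legs$peptide, n_boot = n_boot,
                         seed = seed + 2L * i + 1L)
    cyc <- ddg_from_legs(prot, pept)
    pk <- pka_from_ddg(cyc, records$class[i], refs = refs,
                       protein = records$protein[i], residue = rid,
                       source = source,
                       include_ref_error = include_ref_error)
    tibble(protein = records$protein[i], residue = rid,
           class = records$class[i], expt_pka = records$expt_pka[i],
           pred = pk$pka, pred_se = pk$se, ddg = cyc$ddg, ddg_se = cyc$se,
           kind = pk$kind, source = pk$source)
  })
  bind_rows(rows)
}
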