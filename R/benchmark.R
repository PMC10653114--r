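#' Average unsigned error
#'
#' Mean absolute deviation between predicted and experimental pKa values,
#' the headline accuracy statistic for pKa benchmarks.
#'
#' @param pred,expt Numeric vectors of equal, non-zero length.
#' @return Mean of `|pred - expt|`.
#' @export
aue <- function(pred, expt) {
  if (length(pred) == 0L || length(pred) != length(expt)) {
    abort("`pred` and `expt` must have equal non-zero length.")
  }
  mean(abs(pred - expt))
}

#' Pearson correlation with a zero-variance guard
#'
#' Sample Pearson correlation between predictions and experiment. A
#' degenerate input (fewer than two points, or zero variance on either side)
#' is an error, never a silent 0 or NaN — notably the within-class null
#' model, whose predictions are constant, has no defined correlation.
#'
#' @param pred,expt Numeric vectors of equal length >= 2.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
pearson_r <- function(pred, expt) {
  if (length(pred) < 2L || length(pred) != length(expt)) {
    abort("`pred` and `expt` must have equal length >= 2.")
  }
  if (sd(pred) == 0 || sd(expt) == 0) {
    abort("Pearson correlation undefined: zero variance in pred or expt.")
  }
  cor(pred, expt)
}

check_records <- function(records, pred_col) {
  records <- as_tibble(records)
  need <- c("class", "expt_pka", pred_col)
  if (!all(need %in% names(records))) {
    abort(sprintf("Records need columns: %s.", paste(need, collapse = ", ")))
  }
  if (!all(is.finite(records$expt_pka))) {
    abort("Experimental pKa values must be finite.")
  }
  bad <- setdiff(unique(records$class), c("ASP", "GLU", "LYS"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown residue class(es): %s.", paste(bad, collapse = ", ")))
  }
  records
}

#' Benchmark metrics with residue-resampling bootstrap errors
#'
#' Computes AUE and Pearson r of a prediction column against experiment,
#' with standard errors from resampling residues with replacement `n_boot`
#' times. Resamples on which the correlation is degenerate (zero variance)
#' are skipped and counted; it is an error if every resample is degenerate.
#' Deterministic for a given seed.
#'
#' Records carrying mixed estimate kinds (e.g. `standard` alongside
#' `conditional`) are refused unless `allow_mixed_kinds = TRUE`, so
#' conditioned estimates are never silently pooled with standard ones.
#'
#' @param records Tibble with columns `class`, `expt_pka` and the prediction
#'   column, optionally `kind`.
#' @param pred_col Name of the prediction column.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @param allow_mixed_kinds Permit pooling records of different `kind`.
#' @return A one-row tibble: `aue`, `aue_se`, `pearson`, `pearson_se`, `n`.
#' @export
metric_bootstrap <- function(records, pred_col = "pred", n_boot = 1000L,
                             seed = 1L, allow_mixed_kinds = FALSE) {
  records <- check_records(records, pred_col)
  if ("kind" %in% names(records) && !allow_mixed_kinds &&
      length(unique(records$kind)) > 1L) {
    abort(paste("Records mix estimate kinds",
                sprintf("(%s);", paste(unique(records$kind), collapse = ", ")),
                "pass allow_mixed_kinds = TRUE to pool them."))
  }
  pred <- records[[pred_col]]
  expt <- records$expt_pka
  n <- length(pred)
  if (n < 2L) abort("Need at least 2 records.")
  point_aue <- aue(pred, expt)
  point_r <- tryCatch(pearson_r(pred, expt), error = function(e) NA_real_)
  boot <- withr::with_seed(seed, {
    aues <- numeric(n_boot)
    rs <- rep(NA_real_, n_boot)
    degenerate <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      aues[b] <- mean(abs(pred[idx] - expt[idx]))
      if (sd(pred[idx]) > 0 && sd(expt[idx]) > 0) {
        rs[b] <- cor(pred[idx], expt[idx])
      } else {
        degenerate <- degenerate + 1L
      }
    }
    list(aues = aues, rs = rs, degenerate = degenerate)
  })
  if (boot$degenerate == n_boot && !is.na(point_r)) {
    abort("All bootstrap resamples were degenerate for the correlation.")
  }
  tibble(
    aue = point_aue,
    aue_se = sd(boot$aues),
    pearson = point_r,
    pearson_se = if (all(is.na(boot$rs))) NA_real_ else sd(boot$rs, na.rm = TRUE),
    n = n
  )
}

#' Null-model predictions
#'
#' The baseline every predictor must beat: predict the class reference pKa°
#' for every residue, i.e. a zero-shift prediction. Its unsigned error on a
#' residue equals that residue's |ΔpKa|, so its AUE grows linearly with the
#' typical shift magnitude.
#'
#' @param records Tibble with columns `class` and `expt_pka`.
#' @param refs Reference table from [residue_class_refs()].
#' @return The records with a `pred_null` column (and `pred_null_se` from
#'   the reference uncertainties).
#' @export
null_model <- function(records, refs = residue_class_refs()) {
  records <- check_records(records, "expt_pka")
  idx <- match(records$class, refs$class)
  mutate(records,
         pred_null = refs$ref_pka[idx],
         pred_null_se = refs$ref_pka_se[idx])
}

#' Per-class benchmark breakdown
#'
#' Partitions records by residue class, applies [metric_bootstrap()] to each
#' partition, and appends an `overall` row whose AUE is the unweighted mean
#' of the per-class AUEs (SE combined in quadrature over classes). The
#' overall Pearson r is computed across all residues, where the spread of
#' class reference values contributes to the correlation.
#' `residue_weighted = TRUE` reports the plain full-set AUE instead of the
#' class mean.
#'
#' A class with fewer than two records is skipped with a warning.
#'
#' @inheritParams metric_bootstrap
#' @param residue_weighted Overall AUE over residues instead of class means.
#' @return A tibble with a `class` column (`ASP`/`GLU`/`LYS`/`overall`) and
#'   the [metric_bootstrap()] columns.
#' @export
class_breakdown <- function(records, pred_col = "pred", n_boot = 1000L,
                            seed = 1L, allow_mixed_kinds = FALSE,
                            residue_weighted = FALSE) {
  records <- check_records(records, pred_col)
  classes <- intersect(c("ASP", "GLU", "LYS"), unique(records$class))
  per_class <- list()
  for (cl in classes) {
    sub <- records[records$class == cl, ]
    if (nrow(sub) < 2L) {
      warn(sprintf("Class %s has %d record(s); skipped.", cl, nrow(sub)))
      next
    }
    rep_cl <- metric_bootstrap(sub, pred_col = pred_col, n_boot = n_boot,
                               seed = seed,
                               allow_mixed_kinds = allow_mixed_kinds)
    per_class[[cl]] <- mutate(rep_cl, class = cl, .before = 1)
  }
  if (length(per_class) == 0L) abort("No class with >= 2 records.")
  out <- bind_rows(per_class)
  full <- metric_bootstrap(records, pred_col = pred_col, n_boot = n_boot,
                           seed = seed,
                           allow_mixed_kinds = allow_mixed_kinds)
  overall <- tibble(
    class = "overall",
    aue = if (residue_weighted) full$aue else mean(out$aue),
    aue_se = if (residue_weighted) full$aue_se
             else sqrt(sum(out$aue_se^2)) / nrow(out),
    pearson = full$pearson,
    pearson_se = full$pearson_se,
    n = full$n
  )
  bind_rows(out, overall)
}

#' Substitute adjusted predictions for flagged residues
#'
#' Replaces the standard prediction with a coupling- or condition-adjusted
#' one for a user-selected subset of residues, marking them `adjusted`.
#' Which residues to adjust is an analysis decision (e.g. sites with known
#' coupled neighbors), recorded explicitly rather than inferred.
#'
#' @param records Benchmark records with `protein`, `residue` and the
#'   prediction column.
#' @param adjustments Tibble with `protein`, `residue`, `pred` (and
#'   optionally `pred_se`) holding the replacement predictions.
#' @param pred_col Prediction column to overwrite.
#' @return Records with substituted predictions and a logical `adjusted`
#'   column.
#' @export
apply_adjustments <- function(records, adjustments, pred_col = "pred") {
  records <- as_tibble(records)
  adjustments <- as_tibble(adjustments)
  need <- c("protein", "residue", "pred")
  if (!all(need %in% names(adjustments))) {
    abort("`adjustments` needs columns protein, residue, pred.")
  }
  key <- function(df) paste(df$protein, df$residue, sep = "\r")
  idx <- match(key(records), key(adjustments))
  if (anyNA(match(key(adjustments), key(records)))) {
    abort("Some adjustments refer to residues absent from `records`.")
  }
  hit <- !is.na(idx)
  records$adjusted <- hit
  records[[pred_col]][hit] <- adjustments$pred[idx[hit]]
  se_col <- paste0(pred_col, "_se")
  if ("pred_se" %in% names(adjustments) && se_col %in% names(records)) {
    records[[se_col]][hit] <- adjustments$pred_se[idx[hit]]
  }
  records
}

#' Free energy convergence with the number of transitions
#'
#' Subsamples `n` forward and `n` reverse works without replacement `reps`
#' times for each `n`, re-estimates \eqn{\Delta G} with BAR, and reports the
#' mean and SD across subsamples — the standard check that the transition
#' count has converged the estimate. At the full sample size every
#' subsample is a permutation of the data, so the SD is exactly 0.
#'
#' @param ws A [workset()].
#' @param n_grid Integer vector of subsample sizes (each >= 2, at most the
#'   available transitions in each direction).
#' @param reps Subsamples per grid point.
#' @param seed RNG seed; results are deterministic given it.
#' @return A tibble of class `convergence_curve`: `n`, `mean_dg`, `sd_dg`,
#'   `reps`.
#' @export
convergence_curve <- function(ws, n_grid, reps = 20L, seed = 1L) {
  check_workset(ws)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 2L)) abort("All subsample sizes must be >= 2.")
  if (max(n_grid) > min(length(ws$forward), length(ws$reverse))) {
    abort("Subsample size exceeds available transitions.")
  }
  rows <- withr::with_seed(seed, {
    lapply(n_grid, function(n) {
      dgs <- vapply(seq_len(reps), function(r) {
        wf <- ws$forward[sample.int(length(ws$forward), n)]
        wr <- ws$reverse[sample.int(length(ws$reverse), n)]
        bar_root(wf, wr, ws$temperature)
      }, numeric(1))
      tibble(n = n, mean_dg = mean(dgs), sd_dg = sd(dgs), reps = reps)
    })
  })
  out <- bind_rows(rows)
  class(out) <- c("convergence_curve", class(out))
  out
}

#' @rdname convergence_curve
#' @param object A `convergence_curve`.
#' @param ... Unused.
#' @export
autoplot.convergence_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$n, y = .data$mean_dg)) +
    geom_ribbon(aes(ymin = .data$mean_dg - .data$sd_dg,
                    ymax = .data$mean_dg + .data$sd_dg), alpha = 0.25) +
    geom_line() + geom_point() +
    labs(x = "transitions per direction", y = "BAR dG (kJ/mol)") +
    theme_minimal()
}

#' Predicted-versus-experimental scatter plot
#'
#' @param records Benchmark records.
#' @param pred_col Prediction column to plot.
#' @return A ggplot object with the identity line.
#' @export
plot_benchmark <- function(records, pred_col = "pred") {
  records <- check_records(records, pred_col)
  ggplot(records, aes(x = .data$expt_pka, y = .data[[pred_col]],
                      colour = .data$class)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_point() +
    labs(x = "experimental pKa", y = "predicted pKa") +
    theme_minimal()
}
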