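#' Reference pKa values of model compounds
#'
#' pKa of each titratable residue class measured in a capped reference
#' peptide in solution — the anchor of the thermodynamic cycle. Defaults:
#' aspartate 3.94 ± 0.03, glutamate 4.25 ± 0.05, lysine 10.4 ± 0.08.
#'
#' @param overrides Optional data frame with columns `class`, `ref_pka`,
#'   `ref_pka_se` replacing or extending the defaults.
#' @return A tibble with columns `class`, `ref_pka`, `ref_pka_se`.
#' @examples
#' residue_class_refs()
#' @export
residue_class_refs <- function(overrides = NULL) {
  refs <- tibble(
    class = c("ASP", "GLU", "LYS"),
    ref_pka = c(3.94, 4.25, 10.4),
    ref_pka_se = c(0.03, 0.05, 0.08)
  )
  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    need <- c("class", "ref_pka", "ref_pka_se")
    if (!all(need %in% names(overrides))) {
      abort("`overrides` needs columns class, ref_pka, ref_pka_se.")
    }
    refs <- bind_rows(overrides[need],
                      refs[!refs$class %in% overrides$class, ])
  }
  if (any(refs$ref_pka_se < 0)) abort("ref_pka_se must be >= 0.")
  arrange(refs, .data$class)
}

class_ref <- function(class, refs = residue_class_refs()) {
  row <- refs[refs$class == class, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown residue class `%s` (known: %s).",
                  class, paste(refs$class, collapse = ", ")))
  }
  row
}

## Deprotonation sign per class: +1 for acids (a deprotonation penalty in
## the protein raises the pKa), -1 for bases.
class_sign <- function(class) {
  switch(class, ASP = 1, GLU = 1, LYS = -1,
         abort(sprintf("Unknown residue class `%s`.", class)))
}

#' Double free energy difference from the two cycle legs
#'
#' Closes the thermodynamic cycle: the deprotonation free energy of the
#' residue in the protein minus that of the same residue in the reference
#' peptide, \eqn{\Delta\Delta G = \Delta G_{protein} - \Delta G_{peptide}},
#' with the leg uncertainties propagated in quadrature.
#'
#' @param protein,peptide [fe_estimate()]s for the protein and peptide legs.
#'   Leg temperatures must agree.
#' @param temperature Optional override; defaults to the legs' common
#'   temperature and must match it when given.
#' @return A `cycle_result`: list with `ddg`, `se`, `protein_leg`,
#'   `peptide_leg`, `temperature`.
#' @export
ddg_from_legs <- function(protein, peptide, temperature = NULL) {
  for (leg in list(protein, peptide)) {
    if (!inherits(leg, "fe_estimate")) abort("Legs must be `fe_estimate`s.")
  }
  if (abs(protein$temperature - peptide$temperature) > 1e-9) {
    abort(sprintf("Leg temperatures differ: %.4f vs %.4f K.",
                  protein$temperature, peptide$temperature))
  }
  if (!is.null(temperature) &&
      abs(temperature - protein$temperature) > 1e-9) {
    abort("`temperature` does not match the leg temperatures.")
  }
  se_p <- if (is.na(protein$se)) 0 else protein$se
  se_s <- if (is.na(peptide$se)) 0 else peptide$se
  structure(
    list(ddg = protein$value - peptide$value,
         se = sqrt(se_p^2 + se_s^2),
         protein_leg = protein, peptide_leg = peptide,
         temperature = protein$temperature),
    class = "cycle_result"
  )
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> ddG = %.4f ± %.4f kJ/mol at %.2f K\n",
              x$ddg, x$se, x$temperature))
  invisible(x)
}

#' @export
tidy.cycle_result <- function(x, ...) {
  tibble(ddg = x$ddg, se = x$se, temperature = x$temperature,
         protein_dg = x$protein_leg$value, peptide_dg = x$peptide_leg$value)
}

#' Convert a cycle ΔΔG into a pKa prediction
#'
#' The protein pKa follows from the double free energy difference and the
#' class reference pKa°:
#' \deqn{pK_a = pK_a^\circ + s\,\frac{\Delta\Delta G}{RT\ln 10},}
#' where \eqn{\Delta\Delta G} is the deprotonation free energy shift of the
#' protein environment relative to the peptide and \eqn{s = +1} for acids
#' (ASP, GLU), \eqn{-1} for the base class (LYS), so worksets always
#' describe the deprotonation direction regardless of class.
#'
#' Uncertainty combines the cycle SE (converted to pK units) and, by
#' default, the reference pKa° uncertainty in quadrature; set
#' `include_ref_error = FALSE` to propagate the alchemical uncertainty only.
#'
#' `pk_int_from_ddg()` is the same arithmetic tagged `kind = "intrinsic"`,
#' for cycles computed with all neighboring titratable residues fixed in a
#' chosen protonation state (a pH-independent environment term);
#' [conditional_pka()] tags an estimate conditioned on a stated neighbor
#' state. The tags exist so these are never silently averaged with standard
#' estimates.
#'
#' @param cycle A [ddg_from_legs()] result.
#' @param class Residue class: `"ASP"`, `"GLU"` or `"LYS"`.
#' @param refs Reference table from [residue_class_refs()].
#' @param protein,residue Identifiers carried into the output.
#' @param source Free-text provenance tag (e.g. a force field name).
#' @param include_ref_error Include the reference pKa° SE in the prediction
#'   SE.
#' @return A one-row tibble of class `pka_prediction` with columns
#'   `protein`, `residue`, `class`, `pka`, `se`, `kind`, `condition`,
#'   `source`.
#' @examples
#' leg_p <- fe_estimate(30, 0.3)
#' leg_s <- fe_estimate(30, 0.4)
#' pka_from_ddg(ddg_from_legs(leg_p, leg_s), "ASP") # ddG = 0 -> 3.94
#' @export
pka_from_ddg <- function(cycle, class, refs = residue_class_refs(),
                         protein = "", residue = "", source = "",
                         include_ref_error = TRUE) {
  pka_convert(cycle, class, refs, kind = "standard", condition = "",
              protein = protein, residue = residue, source = source,
              include_ref_error = include_ref_error)
}

#' @rdname pka_from_ddg
#' @export
pk_int_from_ddg <- function(cycle, class, refs = residue_class_refs(),
                            protein = "", residue = "", source = "",
                            include_ref_error = TRUE) {
  pka_convert(cycle, class, refs, kind = "intrinsic", condition = "",
              protein = protein, residue = residue, source = source,
              include_ref_error = include_ref_error)
}

pka_convert <- function(cycle, class, refs, kind, condition,
                        protein, residue, source, include_ref_error) {
  if (!inherits(cycle, "cycle_result")) abort("Expected a `cycle_result`.")
  ref <- class_ref(class, refs)
  scale <- rt_ln10(cycle$temperature)
  pka <- ref$ref_pka + class_sign(class) * cycle$ddg / scale
  se_cycle <- cycle$se / scale
  se <- if (include_ref_error) sqrt(ref$ref_pka_se^2 + se_cycle^2) else se_cycle
  new_pka_prediction(protein = protein, residue = residue, class = class,
                     pka = pka, se = se, kind = kind, condition = condition,
                     source = source)
}

new_pka_prediction <- function(protein, residue, class, pka, se, kind,
                               condition, source) {
  out <- tibble(protein = as.character(protein),
                residue = as.character(residue),
                class = class, pka = pka, se = se, kind = kind,
                condition = as.character(condition),
                source = as.character(source))
  class(out) <- c("pka_prediction", class(out))
  out
}

#' Invert a pKa prediction back to a ΔΔG
#'
#' Inverse of the conversion in [pka_from_ddg()]:
#' \eqn{\Delta\Delta G = s\,(pK_a - pK_a^\circ)\,RT\ln 10}.
#'
#' @param pka Predicted pKa value.
#' @param class Residue class.
#' @param refs Reference table.
#' @param temperature Temperature in Kelvin.
#' @return \eqn{\Delta\Delta G} in kJ/mol.
#' @export
ddg_from_pka <- function(pka, class, refs = residue_class_refs(),
                         temperature = 298.15) {
  ref <- class_ref(class, refs)
  class_sign(class) * (pka - ref$ref_pka) * rt_ln10(temperature)
}

#' Consensus pKa across force fields
#'
#' Combines several predictions for the same residue and kind (typically one
#' per force field) into a consensus estimate: the unweighted mean of the
#' pKa values with SE \eqn{\sqrt{\sum se_i^2}/k}, or the inverse-variance
#' weighted mean when `weighted = TRUE`.
#'
#' @param predictions A `pka_prediction` tibble (rows for one residue, one
#'   kind).
#' @param weighted Use inverse-variance weights instead of the plain mean
#'   (requires all SEs > 0).
#' @return A one-row `pka_prediction` with `source = "consensus"`.
#' @export
consensus_pka <- function(predictions, weighted = FALSE) {
  predictions <- as_tibble(predictions)
  k <- nrow(predictions)
  if (k < 1L) abort("Need at least one prediction.")
  for (col in c("protein", "residue", "class", "kind")) {
    if (length(unique(predictions[[col]])) != 1L) {
      abort(sprintf(
        "Consensus requires a single residue and kind; `%s` is mixed.", col))
    }
  }
  if (weighted) {
    if (any(predictions$se <= 0)) {
      abort("Inverse-variance weighting requires all SEs > 0.")
    }
    w <- 1 / predictions$se^2
    pka <- sum(w * predictions$pka) / sum(w)
    se <- sqrt(1 / sum(w))
  } else {
    pka <- mean(predictions$pka)
    se <- sqrt(sum(predictions$se^2)) / k
  }
  new_pka_prediction(protein = predictions$protein[1],
                     residue = predictions$residue[1],
                     class = predictions$class[1],
                     pka = pka, se = se, kind = predictions$kind[1],
                     condition = predictions$condition[1],
                     source = "consensus")
}

#' Consensus ΔΔG across force fields
#'
#' Alternative consensus rule operating on the free energy scale before
#' conversion: unweighted mean ΔΔG and quadrature-mean SE. For a single
#' residue class the two rules give identical pKa values.
#'
#' @param cycles List of `cycle_result`s for the same residue.
#' @return A `cycle_result` whose legs are the first input's (retained for
#'   metadata only).
#' @export
consensus_ddg <- function(cycles) {
  if (length(cycles) < 1L) abort("Need at least one cycle.")
  for (cy in cycles) {
    if (!inherits(cy, "cycle_result")) abort("Inputs must be `cycle_result`s.")
  }
  temps <- vapply(cycles, function(cy) cy$temperature, numeric(1))
  if (diff(range(temps)) > 1e-9) abort("Cycle temperatures differ.")
  ddgs <- vapply(cycles, function(cy) cy$ddg, numeric(1))
  ses <- vapply(cycles, function(cy) cy$se, numeric(1))
  out <- cycles[[1]]
  out$ddg <- mean(ddgs)
  out$se <- sqrt(sum(ses^2)) / length(cycles)
  out
}
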