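#' Two coupled titratable sites
#'
#' Microstate model of a pair of interacting titratable residues (a dyad,
#' e.g. two carboxylates within 0.5 nm). Each site has an intrinsic pKa —
#' its pKa with the partner held protonated — and the two deprotonated forms
#' interact with free energy `w`. The four microstates (HH, H-, -H, --) have
#' relative free energies
#' \deqn{G(HH) = 0,\ G(H-) = g_b,\ G(-H) = g_a,\ G(--) = g_a + g_b + w,}
#' with \eqn{g_x(pH) = RT\ln 10\,(pK_x - pH)}, so deprotonation of site x is
#' favorable exactly when pH exceeds its intrinsic pKa. Positive `w`
#' penalizes the doubly deprotonated state (mutually repulsive anions);
#' negative `w` stabilizes it.
#'
#' @param pk_a,pk_b Intrinsic pKa of sites A and B.
#' @param w Interaction free energy of the doubly deprotonated state,
#'   kJ/mol.
#' @param temperature Temperature in Kelvin.
#' @return An object of class `coupled_dyad`.
#' @examples
#' coupled_dyad(pk_a = 4, pk_b = 4, w = 5.7)
#' @export
coupled_dyad <- function(pk_a, pk_b, w = 0, temperature = 298.15) {
  check_scalar_number(pk_a, "pk_a")
  check_scalar_number(pk_b, "pk_b")
  check_scalar_number(w, "w")
  check_temperature(temperature)
  structure(list(pk_a = pk_a, pk_b = pk_b, w = w, temperature = temperature),
            class = "coupled_dyad")
}

#' @export
print.coupled_dyad <- function(x, ...) {
  cat(sprintf("<coupled_dyad> pK_a = %.3f, pK_b = %.3f, w = %.3f kJ/mol, %.2f K\n",
              x$pk_a, x$pk_b, x$w, x$temperature))
  invisible(x)
}

## Microstate log-Boltzmann weights at one pH, order HH, H-, -H, --.
dyad_log_weights <- function(d, ph) {
  beta <- beta_factor(d$temperature)
  scale <- rt_ln10(d$temperature)
  g_a <- scale * (d$pk_a - ph)
  g_b <- scale * (d$pk_b - ph)
  -beta * c(0, g_b, g_a, g_a + g_b + d$w)
}

#' Microstate populations of a dyad at given pH values
#'
#' Boltzmann populations of the four protonation microstates, normalized
#' exactly at each pH.
#'
#' @param d A [coupled_dyad()].
#' @param ph Numeric vector of pH values.
#' @return A tibble with columns `ph`, `HH`, `Hm`, `mH`, `mm` (`m` marks a
#'   deprotonated site), each row summing to 1.
#' @export
dyad_microstates <- function(d, ph) {
  if (!inherits(d, "coupled_dyad")) abort("Expected a `coupled_dyad`.")
  rows <- lapply(ph, function(p) {
    lw <- dyad_log_weights(d, p)
    if (!all(is.finite(lw))) abort("Non-finite microstate free energy.")
    w <- exp(lw - max(lw))
    w / sum(w)
  })
  m <- do.call(rbind, rows)
  tibble(ph = ph, HH = m[, 1], Hm = m[, 2], mH = m[, 3], mm = m[, 4])
}

#' pH-resolved titration of a coupled dyad
#'
#' Computes each site's protonated-fraction marginal over a pH grid from the
#' four-state partition function. With `w = 0` each marginal reduces
#' exactly to the one-site Henderson–Hasselbalch curve at its intrinsic pKa;
#' repulsive coupling (`w > 0`) splits the titration into two separated
#' waves.
#'
#' @param d A [coupled_dyad()].
#' @param ph_grid Ascending pH values (length >= 2).
#' @return A `titration_curve`: tibble with columns `ph`, `frac_a`,
#'   `frac_b`, carrying the dyad as an attribute.
#' @examples
#' crv <- dyad_titration(coupled_dyad(4, 5, w = 0), seq(0, 14, 0.1))
#' apparent_pka(crv, "a")
#' @export
dyad_titration <- function(d, ph_grid) {
  if (!inherits(d, "coupled_dyad")) abort("Expected a `coupled_dyad`.")
  ph_grid <- as.numeric(ph_grid)
  if (length(ph_grid) < 2L || is.unsorted(ph_grid, strictly = TRUE)) {
    abort("`ph_grid` must be ascending with length >= 2.")
  }
  ms <- dyad_microstates(d, ph_grid)
  out <- tibble(ph = ph_grid,
                frac_a = ms$HH + ms$Hm,
                frac_b = ms$HH + ms$mH)
  attr(out, "dyad") <- d
  class(out) <- c("titration_curve", class(out))
  out
}

#' One-site Henderson–Hasselbalch curve
#'
#' Protonated fraction \eqn{f(pH) = 1/(1 + 10^{pH - pK_a})}.
#'
#' @param ph pH values.
#' @param pka The site pKa.
#' @return Protonated fractions in \eqn{[0, 1]}.
#' @export
hh_curve <- function(ph, pka) 1 / (1 + 10^(ph - pka))

#' Apparent pKa of a site from its titration curve
#'
#' The pH at which the site's protonated fraction crosses 0.5, located by
#' monotone interpolation of the curve and root refinement to 1e-6 pH. For
#' a coupled site this apparent value differs from the intrinsic pKa by the
#' pH-dependent influence of the partner.
#'
#' @param curve A [dyad_titration()] result.
#' @param site `"a"` or `"b"`.
#' @return Apparent pKa (numeric scalar).
#' @export
apparent_pka <- function(curve, site = c("a", "b")) {
  site <- match.arg(site)
  if (!inherits(curve, "titration_curve")) {
    abort("Expected a `titration_curve`.")
  }
  frac <- curve[[paste0("frac_", site)]]
  ph <- curve$ph
  above <- frac >= 0.5
  if (all(above) || all(!above)) {
    abort(sprintf(
      "Site %s does not cross half-protonation within [%g, %g]; widen the pH grid.",
      site, min(ph), max(ph)))
  }
  hit <- which(abs(frac - 0.5) < 1e-14)
  if (length(hit) > 0L) return(ph[hit[1]])
  i <- max(which(above))  # fractions are non-increasing in pH
  d <- attr(curve, "dyad")
  f <- if (!is.null(d)) {
    ## exact marginal available: refine on it
    function(p) {
      ms <- dyad_microstates(d, p)
      (if (site == "a") ms$HH + ms$Hm else ms$HH + ms$mH) - 0.5
    }
  } else {
    sf <- stats::splinefun(ph, frac, method = "hyman")
    function(p) sf(p) - 0.5
  }
  uniroot(f, lower = ph[i], upper = ph[i + 1L], tol = 1e-8)$root
}

#' Reduce a coupled triad to a dyad
#'
#' For three mutually coupled sites, the most probable first deprotonation
#' event is assigned to the site with the lowest intrinsic pKa; that site is
#' fixed in its deprotonated state, and the remaining two sites form a dyad
#' whose intrinsic pKas are shifted by their coupling to the fixed anion:
#' \eqn{pK' = pK + w_{x,fixed}/(RT\ln 10)}.
#'
#' An exact tie for the lowest pKa is an error: the choice of first
#' deprotonation is then genuinely ambiguous and must be made explicitly by
#' dropping one site.
#'
#' @param sites Data frame with columns `id` and `pka` (three rows), or a
#'   named numeric vector of three intrinsic pKas.
#' @param couplings Data frame with columns `id1`, `id2`, `w` (kJ/mol)
#'   covering the three pairs, in any order.
#' @param temperature Temperature in Kelvin.
#' @return A list with `fixed` (the id deprotonated first), `dyad` (a
#'   [coupled_dyad()] of the remaining sites) and `dyad_ids` (ids mapped to
#'   sites A and B of the dyad, in the input's row order).
#' @export
reduce_triad <- function(sites, couplings, temperature = 298.15) {
  if (is.numeric(sites)) {
    if (is.null(names(sites))) abort("Numeric `sites` must be named.")
    sites <- tibble(id = names(sites), pka = unname(sites))
  }
  sites <- as_tibble(sites)
  if (nrow(sites) != 3L || !all(c("id", "pka") %in% names(sites))) {
    abort("`sites` must have three rows with columns `id`, `pka`.")
  }
  couplings <- as_tibble(couplings)
  if (!all(c("id1", "id2", "w") %in% names(couplings))) {
    abort("`couplings` must have columns `id1`, `id2`, `w`.")
  }
  pair_w <- function(x, y) {
    hit <- (couplings$id1 == x & couplings$id2 == y) |
      (couplings$id1 == y & couplings$id2 == x)
    if (sum(hit) != 1L) {
      abort(sprintf("Need exactly one coupling for pair (%s, %s).", x, y))
    }
    couplings$w[hit]
  }
  lowest <- which(sites$pka == min(sites$pka))
  if (length(lowest) > 1L) {
    abort(paste("Tie for the lowest intrinsic pKa; the first deprotonation",
                "event is ambiguous — resolve it explicitly."))
  }
  fixed <- sites$id[lowest]
  rest <- sites[-lowest, ]
  rest <- rest[order(rest$id), ]  # make the A/B assignment order-invariant
  scale <- rt_ln10(temperature)
  pk_shifted <- rest$pka + unname(vapply(rest$id, function(id) pair_w(id, fixed),
                                         numeric(1))) / scale
  list(
    fixed = fixed,
    dyad = coupled_dyad(pk_a = pk_shifted[1], pk_b = pk_shifted[2],
                        w = pair_w(rest$id[1], rest$id[2]),
                        temperature = temperature),
    dyad_ids = setNames(rest$id, c("a", "b"))
  )
}

#' Fit a Henderson–Hasselbalch curve to titration data
#'
#' Least-squares fit of \eqn{f(pH) = 1/(1 + 10^{pH - pK_a})} over the single
#' parameter \eqn{pK_a} — the same reading used to extract pKa values from
#' NMR chemical-shift titrations.
#'
#' @param ph pH values (>= 3 points).
#' @param fraction Protonated fractions in \eqn{[0, 1]}.
#' @return A list with `pka` (fitted value) and `rss` (residual sum of
#'   squares).
#' @examples
#' ph <- seq(2, 6, 0.25)
#' hh_fit(ph, hh_curve(ph, 4))$pka
#' @export
hh_fit <- function(ph, fraction) {
  ph <- as.numeric(ph)
  fraction <- as.numeric(fraction)
  if (length(ph) < 3L || length(ph) != length(fraction)) {
    abort("Need >= 3 (ph, fraction) pairs of equal length.")
  }
  if (any(fraction < -0.5 | fraction > 1.5)) {
    abort("Fractions far outside [0, 1]; check the input scale.")
  }
  if (diff(range(fraction)) == 0) {
    abort("All fractions are equal; the curve carries no pKa information.")
  }
  rss <- function(pka) sum((fraction - hh_curve(ph, pka))^2)
  opt <- optimize(rss, lower = min(ph) - 10, upper = max(ph) + 10,
                  tol = .Machine$double.eps^0.5)
  list(pka = opt$minimum, rss = opt$objective)
}

#' @describeIn pka_from_ddg Conditional pKa: identical arithmetic, tagged
#'   `kind = "conditional"` with the conditioning environment (e.g.
#'   `"HIS31 doubly protonated"`) recorded verbatim. `condition` must be
#'   non-empty.
#' @param condition Description of the clamped neighbor state.
#' @export
conditional_pka <- function(cycle, class, condition,
                            refs = residue_class_refs(),
                            protein = "", residue = "", source = "",
                            include_ref_error = TRUE) {
  if (!is.character(condition) || length(condition) != 1L ||
      !nzchar(trimws(condition))) {
    abort("`condition` must be a non-empty description of the neighbor state.")
  }
  pka_convert(cycle, class, refs, kind = "conditional",
              condition = condition, protein = protein, residue = residue,
              source = source, include_ref_error = include_ref_error)
}

#' Dyad interaction free energy from conditional ΔΔG values
#'
#' When the deprotonation ΔΔG of each site has been computed alchemically
#' with the partner clamped in each of its two states, the interaction free
#' energy follows as the double difference
#' \eqn{w = \Delta\Delta G(A | B^-) - \Delta\Delta G(A | B^H)}, and
#' symmetrically from the B-side pair. The two routes are thermodynamically
#' identical; the helper averages them and warns if they disagree by more
#' than `tol`.
#'
#' @param ddg_a_bprot,ddg_a_bdeprot Deprotonation ΔΔG of site A with B
#'   protonated / deprotonated (kJ/mol).
#' @param ddg_b_aprot,ddg_b_adeprot Likewise for site B.
#' @param tol Consistency warning threshold, kJ/mol.
#' @return `w` in kJ/mol.
#' @export
dyad_w_from_ddg <- function(ddg_a_bprot, ddg_a_bdeprot,
                            ddg_b_aprot, ddg_b_adeprot, tol = 1e-6) {
  w_a <- ddg_a_bdeprot - ddg_a_bprot
  w_b <- ddg_b_adeprot - ddg_b_aprot
  if (abs(w_a - w_b) > tol) {
    warn(sprintf(
      "Cycle closure violated: w from site A (%.4f) and site B (%.4f) differ.",
      w_a, w_b))
  }
  (w_a + w_b) / 2
}

#' Titration curve plot
#'
#' @param object A [dyad_titration()] result.
#' @param ... Unused.
#' @return A ggplot object showing each site's protonated fraction and the
#'   total protons bound.
#' @export
autoplot.titration_curve <- function(object, ...) {
  df <- tibble(
    ph = rep(object$ph, 3L),
    value = c(object$frac_a, object$frac_b, object$frac_a + object$frac_b),
    series = rep(c("site A", "site B", "total protons"),
                 each = nrow(object))
  )
  ggplot(df, aes(x = .data$ph, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(x = "pH", y = "protonated fraction / protons bound") +
    theme_minimal()
}
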