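#' Forward/reverse nonequilibrium work samples for one alchemical leg
#'
#' A `workset` bundles the work values collected from repeated fast
#' switching transitions in both directions of one alchemical transformation
#' (e.g. deprotonating a residue in the protein, or in the reference
#' peptide), together with the temperature at which they were generated.
#'
#' Sign convention: each reverse work is recorded as the work done along the
#' reverse transition *in its own direction*, so that the Crooks fluctuation
#' theorem reads \eqn{P_F(W)/P_R(-W) = \exp[\beta(W - \Delta G)]}. In the
#' dissipationless limit the forward works collapse to \eqn{\Delta G} and the
#' reverse works to \eqn{-\Delta G}.
#'
#' @param forward,reverse Numeric vectors of work values in kJ/mol. Both must
#'   be non-empty and finite (two-sided estimators need both directions).
#' @param temperature Temperature in Kelvin.
#' @param label Optional character tag (e.g. `"1EY0 D19 protein"`).
#' @return An object of class `workset` with elements `forward`, `reverse`,
#'   `temperature`, `label`.
#' @seealso [bar_estimate()], [gaussian_cft_pair()], [load_workset()]
#' @examples
#' ws <- workset(forward = c(10.2, 9.8), reverse = c(-9.9, -10.1),
#'               temperature = 298.15)
#' ws
#' @export
workset <- function(forward, reverse, temperature = 298.15, label = "") {
  if (length(forward) == 0L || length(reverse) == 0L) {
    abort("`forward` and `reverse` must both be non-empty.")
  }
  forward <- as.numeric(forward)
  reverse <- as.numeric(reverse)
  if (!all(is.finite(forward)) || !all(is.finite(reverse))) {
    abort("All work values must be finite.")
  }
  check_temperature(temperature)
  structure(
    list(forward = forward, reverse = reverse,
         temperature = temperature, label = as.character(label)[1]),
    class = "workset"
  )
}

#' @export
print.workset <- function(x, ...) {
  cat(sprintf("<workset%s>  %d forward / %d reverse works at %.2f K\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$forward), length(x$reverse), x$temperature))
  cat(sprintf("  mean W_F = %+.3f  mean W_R = %+.3f kJ/mol\n",
              mean(x$forward), mean(x$reverse)))
  invisible(x)
}

#' @export
tidy.workset <- function(x, ...) {
  tibble(
    direction = rep(c("forward", "reverse"),
                    c(length(x$forward), length(x$reverse))),
    work_kjmol = c(x$forward, x$reverse),
    temperature = x$temperature,
    label = x$label
  )
}

is_workset <- function(x) inherits(x, "workset")

check_workset <- function(ws) {
  if (!is_workset(ws)) abort("Expected a `workset` object.")
  invisible(ws)
}

#' Work histogram plot for a workset
#'
#' Overlays the forward work distribution with the *negated* reverse work
#' distribution, the two densities whose crossing point marks the free energy
#' difference under the Crooks fluctuation theorem.
#'
#' @param object A [workset()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.workset <- function(object, bins = 40, ...) {
  check_workset(object)
  df <- tibble(
    work = c(object$forward, -object$reverse),
    distribution = rep(c("P_F(W)", "P_R(-W)"),
                       c(length(object$forward), length(object$reverse)))
  )
  ggplot(df, aes(x = .data$work, fill = .data$distribution)) +
    geom_histogram(aes(y = after_stat(.data$density)),
                   bins = bins, alpha = 0.55, position = "identity") +
    labs(x = "work (kJ/mol, forward frame)", y = "density",
         title = object$label) +
    theme_minimal()
}

#' Read and write pre-integrated work tables
#'
#' CSV work tables have a header `transition,work_kjmol`, one row per
#' nonequilibrium transition. `write_workset()` writes one file per
#' direction; `read_work_csv()` reads a single direction.
#'
#' @param path Path to a work CSV.
#' @param kcal If `TRUE`, values in the file are kcal/mol and are converted
#'   to kJ/mol (multiplied by 4.184) on read. Units are never guessed.
#' @return `read_work_csv()` returns a numeric vector of works in kJ/mol.
#' @export
read_work_csv <- function(path, kcal = FALSE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("transition", "work_kjmol") %in% names(df))) {
    abort(sprintf(
      "Work CSV %s must have columns `transition,work_kjmol` (found: %s).",
      path, paste(names(df), collapse = ",")))
  }
  w <- as.numeric(df$work_kjmol)
  if (length(w) == 0L) abort(sprintf("Empty work table: %s", path))
  if (anyNA(w)) abort(sprintf("Non-numeric work values in %s", path))
  if (kcal) w <- w * 4.184
  w
}

#' @rdname read_work_csv
#' @param ws A [workset()].
#' @param forward_path,reverse_path Output CSV paths.
#' @return `write_workset()` invisibly returns the two paths written.
#' @export
write_workset <- function(ws, forward_path, reverse_path) {
  check_workset(ws)
  write_one <- function(w, path) {
    df <- data.frame(transition = seq_along(w),
                     work_kjmol = format(w, digits = 17, trim = TRUE,
                                         scientific = FALSE))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_one(ws$forward, forward_path)
  write_one(ws$reverse, reverse_path)
  invisible(c(forward_path, reverse_path))
}
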