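#' Read a GROMACS dH/dlambda XVG curve
#'
#' Parses the two-column text format GROMACS writes for per-transition
#' dH/d\eqn{\lambda} output. Lines beginning with `#` or `@` are comments or
#' plotting directives and are ignored wherever they occur; data lines are
#' whitespace-separated pairs, either `lambda dhdl` or `time dhdl`.
#'
#' When the first column is simulation time rather than \eqn{\lambda}
#' (`time_as_lambda = TRUE`), it is mapped linearly onto \eqn{[0, 1]} —
#' ascending for forward transitions and descending (1 to 0) for reverse
#' transitions, matching the direction the switch was driven.
#'
#' @param path Path to an XVG file.
#' @param direction `"forward"` or `"reverse"`.
#' @param time_as_lambda Treat the first column as time and rescale to
#'   \eqn{\lambda}.
#' @return A `dhdl_curve`: list with `lambdas`, `dhdl` (kJ/mol), `direction`.
#' @examples
#' f <- tempfile(fileext = ".xvg")
#' writeLines(c("@ title \"dhdl\"", "0.0 2.0", "0.5 2.0", "1.0 2.0"), f)
#' read_xvg(f)
#' @export
read_xvg <- function(path, direction = c("forward", "reverse"),
                     time_as_lambda = FALSE) {
  direction <- match.arg(direction)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 2L) {
    abort(sprintf("%s: fewer than 2 data rows.", path))
  }
  xs <- numeric(length(idx))
  ys <- numeric(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "\\s+")[[1]]
    if (length(fields) < 2L) {
      abort(sprintf("%s line %d: expected two columns.", path, idx[k]))
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      abort(sprintf("%s line %d: non-numeric data (`%s`).",
                    path, idx[k], trimws(lines[idx[k]])))
    }
    xs[k] <- vals[1]
    ys[k] <- vals[2]
  }
  if (time_as_lambda) {
    rng <- range(xs)
    if (diff(rng) <= 0) abort(sprintf("%s: time column is constant.", path))
    lam <- (xs - rng[1]) / diff(rng)
    if (direction == "reverse") lam <- 1 - lam
    xs <- lam
  }
  dhdl_curve(lambdas = xs, dhdl = ys, direction = direction)
}

#' Construct a dH/dlambda curve
#'
#' @param lambdas Strictly monotone \eqn{\lambda} values in \eqn{[0, 1]}:
#'   ascending 0 to 1 for forward curves, descending 1 to 0 for reverse ones
#'   (the traversal order of the switch).
#' @param dhdl dH/d\eqn{\lambda} values in kJ/mol, same length.
#' @param direction `"forward"` or `"reverse"`.
#' @return A `dhdl_curve` object.
#' @export
dhdl_curve <- function(lambdas, dhdl, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  lambdas <- as.numeric(lambdas)
  dhdl <- as.numeric(dhdl)
  if (length(lambdas) < 2L || length(lambdas) != length(dhdl)) {
    abort("`lambdas` and `dhdl` must have equal length >= 2.")
  }
  if (!all(is.finite(lambdas)) || !all(is.finite(dhdl))) {
    abort("All curve values must be finite.")
  }
  d <- diff(lambdas)
  if (direction == "forward") {
    ok <- all(d > 0) && abs(lambdas[1]) < 1e-9 &&
      abs(lambdas[length(lambdas)] - 1) < 1e-9
  } else {
    ok <- all(d < 0) && abs(lambdas[1] - 1) < 1e-9 &&
      abs(lambdas[length(lambdas)]) < 1e-9
  }
  if (!ok) {
    abort(sprintf(
      "lambda grid must run %s for a %s curve.",
      if (direction == "forward") "strictly from 0 to 1" else "strictly from 1 to 0",
      direction))
  }
  structure(list(lambdas = lambdas, dhdl = dhdl, direction = direction),
            class = "dhdl_curve")
}

#' @export
print.dhdl_curve <- function(x, ...) {
  cat(sprintf("<dhdl_curve> %s, %d lambda points, W = %.4f kJ/mol\n",
              x$direction, length(x$lambdas), integrate_dhdl(x)))
  invisible(x)
}

#' Thermodynamic-integration work of one transition
#'
#' Integrates dH/d\eqn{\lambda} along the traversal order of the curve by the
#' trapezoidal rule, giving the work of that transition in its own direction:
#' forward curves integrate from 0 to 1, reverse curves from 1 to 0 (so the
#' same integrand yields works of opposite sign, as the Crooks bookkeeping
#' requires). The \eqn{\lambda} grid need not be uniform.
#'
#' @param curve A [dhdl_curve()].
#' @return Work in kJ/mol.
#' @examples
#' integrate_dhdl(dhdl_curve(c(0, 0.5, 1), c(0, 1, 2))) # int 2*lambda = 1
#' @export
integrate_dhdl <- function(curve) {
  if (!inherits(curve, "dhdl_curve")) abort("Expected a `dhdl_curve`.")
  x <- curve$lambdas
  y <- curve$dhdl
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Assemble a workset from XVG directories or work CSVs
#'
#' Each source is either a directory containing one XVG file per transition
#' or a single CSV with header `transition,work_kjmol` (see
#' [read_work_csv()]). XVG curves are integrated with [integrate_dhdl()].
#'
#' @param forward_source,reverse_source Directory of `.xvg` files or path to
#'   a work CSV.
#' @param temperature Temperature in Kelvin.
#' @param label Optional label for the resulting workset.
#' @param time_as_lambda Passed to [read_xvg()] for XVG sources.
#' @param kcal Input works are kcal/mol; convert to kJ/mol. Applies to both
#'   sources (mixed units across directions are not supported).
#' @return A [workset()].
#' @export
load_workset <- function(forward_source, reverse_source,
                         temperature = 298.15, label = "",
                         time_as_lambda = FALSE, kcal = FALSE) {
  load_one <- function(source, direction) {
    if (dir.exists(source)) {
      files <- sort(list.files(source, pattern = "\\.xvg$", full.names = TRUE))
      if (length(files) == 0L) {
        abort(sprintf("No .xvg files in directory %s", source))
      }
      w <- vapply(files, function(f) {
        integrate_dhdl(read_xvg(f, direction = direction,
                                time_as_lambda = time_as_lambda))
      }, numeric(1))
      if (kcal) w <- w * 4.184
      unname(w)
    } else if (file.exists(source)) {
      read_work_csv(source, kcal = kcal)
    } else {
      abort(sprintf("Source %s is neither a directory nor a file.", source))
    }
  }
  workset(forward = load_one(forward_source, "forward"),
          reverse = load_one(reverse_source, "reverse"),
          temperature = temperature, label = label)
}
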