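# Shared fixtures and independent oracles used across test files.

R_GAS <- 0.0083144621

# Write a temporary XVG file and return its path.
write_xvg <- function(lines, ext = ".xvg") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Independent oracle for the BAR estimate: dense grid maximization of the
# label log-likelihood, written from the definition (no calls into the
# estimator under test). A pooled sample at forward-frame work W is a
# forward draw with probability q(W) = 1/(1 + (nR/nF) exp(-beta (W - dG))).
grid_bar_oracle <- function(ws, lo, hi, step = 1e-4) {
  beta <- 1 / (R_GAS * ws$temperature)
  nf <- length(ws$forward)
  nr <- length(ws$reverse)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(g) {
    sum(-log1p((nr / nf) * exp(-beta * (ws$forward - g)))) +
      sum(-log1p((nf / nr) * exp(beta * (-ws$reverse - g))))
  }, numeric(1))
  grid[which.max(ll)]
}

# Brute-force 4-state dyad marginals by direct enumeration of the partition
# function (independent of dyad_titration internals).
brute_dyad_marginals <- function(pk_a, pk_b, w, temperature, ph) {
  beta <- 1 / (R_GAS * temperature)
  s <- R_GAS * temperature * log(10)
  t(vapply(ph, function(p) {
    g_a <- s * (pk_a - p)
    g_b <- s * (pk_b - p)
    g <- c(HH = 0, Hm = g_b, mH = g_a, mm = g_a + g_b + w)
    z <- exp(-beta * g)
    z <- z / sum(z)
    c(frac_a = z[["HH"]] + z[["Hm"]], frac_b = z[["HH"]] + z[["mH"]])
  }, numeric(2)))
}
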