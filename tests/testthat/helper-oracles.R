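# Independent oracle implementations used to cross-check the package's
# estimators.  These deliberately use naive double loops and direct formulas,
# not the code paths they validate.

# Benjamini-Hochberg step-up, computed literally: for each p(i) (sorted),
# adjusted = min over j >= i of p(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Plug-in mutual information from a 2-D histogram, via explicit loops over
# the occupied bins of (log2 x, log2 y) with fixed bin width.
mi_oracle <- function(x, y, bin_width = 0.05) {
  ix <- floor(log2(x) / bin_width)
  iy <- floor(log2(y) / bin_width)
  n <- length(x)
  ux <- unique(ix)
  uy <- unique(iy)
  mi <- 0
  for (a in ux) {
    px <- sum(ix == a) / n
    for (b in uy) {
      pxy <- sum(ix == a & iy == b) / n
      if (pxy > 0) {
        py <- sum(iy == b) / n
        mi <- mi + pxy * log2(pxy / (px * py))
      }
    }
  }
  mi
}

# Exact Hill curve as a dose_response-shaped data.frame
hill_curve <- function(h, k, r_grid) {
  data.frame(R = r_grid, fraction = r_grid^h / (k^h + r_grid^h))
}
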