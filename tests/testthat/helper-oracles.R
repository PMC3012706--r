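# Independent oracles used across the suite. Each is a deliberately
# naive implementation kept separate from the package's code paths.

# union-find connected components over an edge list
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edges) > 0)
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  vapply(nodes, find, character(1))
}

# term-by-term summation of the Audic-Claverie conditional tails
# (integer y; log-space accumulation until relative convergence)
audic_tail_sum <- function(x, y, r, lower = TRUE, tol = 1e-16) {
  lpmf <- function(k) k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) -
    lgamma(k + 1) - (x + k + 1) * log1p(r)
  if (lower) {
    sum(exp(lpmf(0:y)))
  } else {
    total <- 0
    k <- y
    repeat {
      term <- exp(lpmf(k))
      total <- total + term
      if (term < tol * max(total, .Machine$double.xmin) && k > y + 10) break
      k <- k + 1
      if (k > y + 1e6) break
    }
    total
  }
}

# two-sided Fisher p by full enumeration of tables with fixed margins
# (point-mass rule: sum of probabilities <= observed probability)
fisher_enum <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  lp <- stats::dhyper(support, m, n, k, log = TRUE)
  p_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  sum(exp(lp[lp <= p_obs + 1e-7]))
}

# sort-and-scan N50 plus the four assembly length bins
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  s[min(which(cumsum(s) >= sum(s) / 2))]
}
bins_oracle <- function(lengths) {
  c(sum(lengths < 500),
    sum(lengths >= 500 & lengths < 1000),
    sum(lengths >= 1000 & lengths < 2000),
    sum(lengths >= 2000))
}

# per-base depth by explicit counting
depth_oracle <- function(starts, ends, width) {
  depth <- integer(width)
  for (i in seq_along(starts))
    depth[starts[i]:ends[i]] <- depth[starts[i]:ends[i]] + 1L
  depth
}

# small two-library designs used by the DE simulations
pair_design <- function(deep = FALSE) {
  data.frame(library = c("G-x", "S-x"), phase = c("G", "S"), stage = "x",
             size_factor = if (deep) c(20, 20) else c(1, 1),
             lanes = 1, stringsAsFactors = FALSE)
}

# singleton catalog of n units with fixed-length transcripts
flat_catalog <- function(n, len = 1000) {
  data.frame(transcript = sprintf("T%05d", seq_len(n)),
             length = rep(len, n), stringsAsFactors = FALSE)
}
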