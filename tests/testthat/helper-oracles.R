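# Independent oracles used to cross-check the analytical implementations.

# Natural-abundance MID by exhaustive multinomial enumeration over isotope
# count vectors, independent of the package's convolution code.
oracle_natural_mid <- function(counts, abundances) {
  if (is.character(counts)) counts <- parse_formula(counts)
  agg <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    probs <- abundances[[el]]
    k <- length(probs)
    if (k == 1) next
    combos <- expand.grid(rep(list(0:n), k))
    combos <- combos[rowSums(combos) == n, , drop = FALSE]
    d <- numeric(n * (k - 1) + 1)
    for (i in seq_len(nrow(combos))) {
      kv <- as.numeric(combos[i, ])
      shift <- sum(kv * (seq_len(k) - 1))
      d[shift + 1] <- d[shift + 1] + dmultinom(kv, prob = probs)
    }
    new <- numeric(length(agg) + length(d) - 1)
    for (a in seq_along(agg)) {
      for (b in seq_along(d)) new[a + b - 1] <- new[a + b - 1] + agg[a] * d[b]
    }
    agg <- new
  }
  agg
}

# Forward simulation of a measured MID at enrichment E: binomial labelling of
# the tracer carbons, each species' natural pattern from the enumeration
# oracle, truncated to the measured window.
oracle_forward_mid <- function(formula, n_tracer, enrichment, abundances) {
  counts <- parse_formula(formula)
  out <- numeric(n_tracer + 1)
  for (j in 0:n_tracer) {
    resid <- counts
    resid[["C"]] <- counts[["C"]] - j
    nm <- oracle_natural_mid(resid, abundances)
    col <- c(rep(0, j), nm)[seq_len(n_tracer + 1)]
    col[is.na(col)] <- 0
    out <- out + dbinom(j, n_tracer, enrichment) * col
  }
  out
}

# Exact permutation p-value for a Pearson correlation on a small sample:
# enumerates every permutation of y.
oracle_permutation_p <- function(x, y) {
  r_obs <- abs(cor(x, y))
  perms <- all_permutations(seq_along(y))
  r_null <- apply(perms, 1, function(idx) abs(cor(x, y[idx])))
  mean(r_null >= r_obs - 1e-12)
}

all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_permutations(v[-i]))
  }))
}
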