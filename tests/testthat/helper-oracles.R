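# independent reference implementations used as oracles across test files

# brute-force per-cell activity rules, written directly from the four-case
# truth table (DNA 0/+, cDNA 0/+) x phantom prevalence above/below the cut
oracle_classify <- function(dna, cdna, threshold, phantom_prev) {
  state <- matrix(NA_character_, nrow(dna), ncol(dna), dimnames = dimnames(dna))
  prev <- sapply(seq_len(ncol(dna)), function(j)
    mean(dna[, j] == 0 & cdna[, j] > 0))
  for (i in seq_len(nrow(dna))) for (j in seq_len(ncol(dna))) {
    d <- dna[i, j]; r <- cdna[i, j]
    state[i, j] <-
      if (d == 0 && r == 0) "undetected"
      else if (d > 0 && r == 0) "inactive"
      else if (d > 0 && r > 0) {
        if (r / d >= threshold) "active" else "inactive"
      } else {                       # phantom detection
        if (prev[j] > phantom_prev) "phantom_rescued" else "phantom_dropped"
      }
  }
  active <- dna
  active[dna == 0] <- 1L             # the DNA := 1 substitution
  active[!(state %in% c("active", "phantom_rescued"))] <- 0L
  list(state = state, active = active)
}

# weighted correlation as explicit sums (group-equalized weights)
weighted_cor_oracle <- function(x, y, groups) {
  groups <- factor(groups)
  n_g <- table(groups)
  w <- as.numeric(length(x) / (nlevels(groups) * n_g[groups]))
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  num <- sum(w * (x - mx) * (y - my))
  num / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# module-level indicator recovery fixture: 2x2 factorial, 5 replicates per
# cell, 10 of 100 log-normal taxa enriched 2-fold in the planted-drought
# cell, multiplicative replicate noise sdlog 0.2
sim_indicator_case <- function(seed, sdlog = 0.2, fold = 2) {
  set.seed(seed)
  g <- factor(rep(c("planted.drought", "planted.watered",
                    "unplanted.drought", "unplanted.watered"), each = 5))
  base <- rlnorm(100, 0, 1.5)
  resp <- sample(100, 10)
  x <- t(sapply(seq_along(g), function(i) {
    comp <- base * rlnorm(100, 0, sdlog)
    if (g[i] == "planted.drought") comp[resp] <- comp[resp] * fold
    comp / sum(comp)
  }))
  colnames(x) <- sprintf("t%03d", 1:100)
  list(x = x, g = g, resp = colnames(x)[resp])
}
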