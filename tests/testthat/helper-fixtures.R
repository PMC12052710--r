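# Shared fixtures and independent oracles, built in code at test time.

# Small cohort for fast end-to-end checks.
small_cohort <- function(seed = 1L, n = 60L, G = 30L, causal = TRUE) {
  generate_cohort(sim_config(
    n_samples = n, n_genera = G,
    n_causal_quant = if (causal) 2L else 0L,
    n_causal_binary = if (causal) 1L else 0L,
    depth_range = c(5000L, 10000L), seed = seed))
}

# Consensus genus lists for the two fiber fractions with their phylum
# memberships, as a fixture taxonomy for the tally worked examples.
consensus_fixture <- function() {
  firmicutes_ndfd <- c("Anaerotruncus", "Family_XIII_UCG-002",
                       "Lachnoclostridium_1", "Moryella",
                       "Ruminococcaceae_NK4A214_group",
                       "Veillonellaceae_UCG-001")
  firmicutes_adfd <- c("Lachnospiraceae_ND3007_group", "Family_XIII_UCG-002",
                       "Lachnoclostridium_1", "Lachnospiraceae_UCG-002",
                       "Moryella", "Ruminococcaceae_NK4A214_group")
  ndfd <- c(firmicutes_ndfd, "Prevotellaceae_UCG-003")
  adfd <- c(firmicutes_adfd, "Prevotellaceae_UCG-003", "Olsenella")
  taxonomy <- c(
    stats::setNames(rep("Firmicutes", 6), firmicutes_ndfd),
    stats::setNames(rep("Firmicutes", 6), firmicutes_adfd),
    `Prevotellaceae_UCG-003` = "Bacteroidetes",
    Olsenella = "Actinobacteria")
  taxonomy <- taxonomy[!duplicated(names(taxonomy))]
  list(ndfd = ndfd, adfd = adfd, taxonomy = taxonomy)
}

# Independent Spearman oracle: mid-ranks computed from scratch by sorting,
# then the explicit Pearson sum formula (no calls into the package).
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Independent partial-t oracle via lm(), for cross-checking the fast path.
oracle_partial_t <- function(y, g, pcs = NULL) {
  df <- if (is.null(pcs)) data.frame(y = y, g = g)
        else data.frame(y = y, g = g, pcs)
  fit <- stats::lm(y ~ ., data = df)
  unname(abs(summary(fit)$coefficients["g", "t value"]))
}
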