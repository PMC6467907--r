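# Independent oracles, kept deliberately naive so they cannot share a bug
# with the implementation they check.

# Gini by explicit double loop over all ordered pairs:
# sum_{i,j} |m_i - m_j| / (2 N (N-1) mu)
gini_pairwise_oracle <- function(masses) {
  n <- length(masses)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + abs(masses[i] - masses[j])
    }
  }
  total / (2 * n * (n - 1) * mean(masses))
}

# Exact replacement probability for a FIXED brood: enumerate all 2^n
# predation-survival outcomes; a survivor also needs mass >= threshold.
replacement_prob_oracle <- function(masses, p, threshold, w = 2) {
  n <- length(masses)
  fed <- masses >= threshold
  prob <- 0
  for (code in 0:(2^n - 1)) {
    surv <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    pr <- prod(ifelse(surv, 1 - p, p))
    if (sum(surv & fed) >= w) prob <- prob + pr
  }
  prob
}

# A small valid species table as a tibble, for classify/io tests.
make_species_tbl <- function() {
  tibble::tibble(
    species = c("many-cheap", "few-costly", "apex", "social"),
    taxon_group = c("fish", "mammal", "shark", "social insect"),
    n_offspring = c(5000, 2, 4, 800),
    offspring_mass = c(0.01, 30, 5, 6),
    breeder_mass = c(1000, 100, 400, 10),
    brood_masses = list(NULL, c(32, 28), NULL, NULL)
  )
}

write_species_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
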