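# Small in-code fixtures shared across test files.

# Minimal valid long-format mutation table.
make_table <- function(individual = "m1", cell = "c1", position = 100L,
                       ref = "A", alt = "G", abundance = 10, coverage = 1000,
                       region = NA_character_) {
  tibble::tibble(individual_id = individual, cell_id = cell,
                 position = as.integer(position), ref = ref, alt = alt,
                 abundance_pct = abundance, coverage = coverage,
                 region = region)
}

# A cohort table built from per-individual lists of (cell, abundance) pairs
# for a single allele, padded with a low-abundance decoy allele so every
# individual appears in the table.
allele_cohort_table <- function(abundances_by_individual, position = 16100L,
                                ref = "A", alt = "G") {
  rows <- list()
  for (ind in names(abundances_by_individual)) {
    ab <- abundances_by_individual[[ind]]
    if (length(ab))
      rows[[length(rows) + 1L]] <- make_table(
        individual = ind, cell = sprintf("%s_c%03d", ind, seq_along(ab)),
        position = position, ref = ref, alt = alt, abundance = ab)
    rows[[length(rows) + 1L]] <- make_table(
      individual = ind, cell = paste0(ind, "_decoy"), position = 200L,
      ref = "C", alt = "T", abundance = 0.5)
  }
  dplyr::bind_rows(rows)
}

# Exact neutral Wright-Fisher fixation probability by power iteration of the
# (N+1)-state binomial transition matrix; independent of the simulator.
wf_fixation_prob_exact <- function(N, init, n_iter = 5000) {
  P <- outer(0:N, 0:N, function(i, j) dbinom(j, N, i / N))
  v <- numeric(N + 1)
  v[init + 1] <- 1
  for (i in seq_len(n_iter)) v <- as.vector(v %*% P)
  v[N + 1]
}

# Wide per-cell abundance matrix (0 = undetected) for selected positions.
tidyr_lite <- function(tab, positions) {
  cells <- unique(tab$cell_id)
  out <- data.frame(cell_id = cells)
  for (p in positions) {
    v <- stats::setNames(rep(0, length(cells)), cells)
    sub <- tab[tab$position == p, ]
    v[sub$cell_id] <- sub$abundance_pct
    out[[paste0("p", p)]] <- unname(v[cells])
  }
  out
}

# Brute-force two-sample permutation p-value by bitmask enumeration of all
# subsets (independent of the combn-based implementation path).
perm_p_bruteforce <- function(obs, sim) {
  pooled <- c(obs, sim)
  n <- length(pooled)
  n1 <- length(obs)
  stat <- function(idx) abs(mean(pooled[idx]) - mean(pooled[setdiff(seq_len(n), idx)]))
  s0 <- stat(seq_len(n1))
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) != n1) next
    total <- total + 1L
    if (stat(idx) >= s0) hits <- hits + 1L
  }
  hits / total
}
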