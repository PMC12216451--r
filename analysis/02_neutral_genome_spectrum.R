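#!/usr/bin/env Rscript
# Whole-genome neutral mutation spectrum of an aged mouse liver.
#
# Simulates 3,195 hepatocytes (the size of the aged wild-type mouse
# dataset) under pure drift: L = 16,299 bp, N = 10,000 genomes/cell,
# mu = 2e-8 per bp per replication, 40 generations. The across-cell total of
# segregating mutations should sit near 65,772 and essentially all of them
# below 2% cellular abundance - drift alone cannot populate the
# high-abundance tail seen in real aged tissue.

suppressPackageStartupMessages(library(mtdrive))
dir.create("results", showWarnings = FALSE)

n_cells <- 3195L
params <- sim_params(n_genomes = 10000, mu = 2e-8, genome_length = 16299,
                     generations = 40)

rows <- withr::with_seed(20260924, {
  lapply(seq_len(n_cells), function(i) {
    m <- simulate_genome(params)$mutations
    if (!nrow(m)) return(NULL)
    tibble::tibble(individual_id = "sim", cell_id = sprintf("c%04d", i),
                   position = m$site, ref = "N", alt = "M",
                   abundance_pct = m$abundance_pct, coverage = 1e6,
                   region = NA_character_)
  })
})
tab <- dplyr::bind_rows(rows)

cat(sprintf("segregating mutations across %d cells: %d (printed value 65,772)\n",
            n_cells, nrow(tab)))
cat(sprintf("above 2%% abundance: %d records (%.3f%% of all)\n",
            sum(tab$abundance_pct > 2), 100 * mean(tab$abundance_pct > 2)))

hist <- abundance_histogram(tab, bin_width = 2)
readr::write_tsv(hist, "results/02_neutral_abundance_histogram.tsv")

# fine bins below 2% where virtually everything lives
fine <- abundance_histogram(tab, bin_width = 0.1)
readr::write_tsv(fine[fine$bin_start < 2, ],
                 "results/02_neutral_abundance_below2pct.tsv")
cat("wrote results/02_neutral_abundance_histogram.tsv (+ sub-2% detail)\n")
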