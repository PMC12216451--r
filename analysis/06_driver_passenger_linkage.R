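#!/usr/bin/env Rscript
# Driver-passenger linkage: per-cell maxima and the 50% "red square".
#
# Reads the synthetic cohort and driver calls written by
# 03_synthetic_cohort_drivers.R, computes for every cell the maximum
# abundance of a driver allele and of a non-driver coding allele, and counts
# cells in the red square (both > 50%), where co-residence of the two
# alleles on the same genomes is forced by the pigeonhole bound.
# Run analysis/03 first.

suppressPackageStartupMessages(library(mtdrive))
dir.create("results", showWarnings = FALSE)

tab <- read_mutation_table("results/03_cohort_mutations.tsv", species = "mouse")
calls <- readr::read_tsv("results/03_driver_calls.tsv",
                         show_col_types = FALSE)
truth <- readr::read_tsv("results/03_cohort_truth.tsv",
                         show_col_types = FALSE)
# driver axis: rule-passing alleles in the NCR (replicative-drive alleles
# live in the replication-control region; a hitchhiking coding passenger can
# also pass the recurrence rule but belongs on the coding axis)
drivers <- calls$allele_id[calls$pass & calls$position > 15288]
cat(sprintf("driver set (NCR): %s\n", paste(drivers, collapse = ", ")))

# mouse mtDNA protein-coding span (ND1 start through CYTB end); the abundant
# clonal mutation is excluded so it cannot masquerade as a passenger
coding <- data.frame(start = 2751, end = 15288)
clonal_ids <- truth$allele_id[truth$role == "clonal"]

pts <- per_cell_max_table(tab, drivers, coding,
                          exclude_alleles = clonal_ids)
readr::write_tsv(pts, "results/06_per_cell_maxima.tsv")

red <- pts[pts$in_red_square, ]
cat(sprintf("cells with any detection: %d; in the red square: %d\n",
            nrow(pts), nrow(red)))
if (nrow(red)) {
  red$min_coresidence_pct <- min_coresidence(red$max_driver_pct,
                                             red$max_coding_pct)
  cat("red-square cells (driver %, coding %, forced co-residence %):\n")
  print(as.data.frame(red[, c("individual_id", "cell_id", "max_driver_pct",
                              "max_coding_pct", "min_coresidence_pct")]),
        digits = 3)
  readr::write_tsv(red, "results/06_red_square_cells.tsv")
}
cat("wrote results/06_per_cell_maxima.tsv\n")
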