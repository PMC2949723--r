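#!/usr/bin/env Rscript
# Stage 2: normalize all arrays against the computational naive control pool.
#
# Each control is normalized against the median control array through a
# monotone piecewise-linear curve trained on rank-stable probes (< 10% rank
# drift); the pool is the mean of the normalized controls, and every sample
# is then normalized against the pool.

suppressPackageStartupMessages(library(connmap))

out <- "results/analysis"
m <- read_signal_matrix(file.path(out, "expression.tsv"),
                        file.path(out, "groups.tsv"))

norm <- normalize_matrix(m, rank_tol = 0.10, n_knots = 20)
write_signal_matrix(norm$matrix, file.path(out, "normalized.tsv"),
                    file.path(out, "groups.tsv"))

message(sprintf("Median control array: %s.", norm$median_array))
message(sprintf("Rank-stable probes per sample: %d-%d of %d.",
                min(norm$n_stable), max(norm$n_stable), nrow(m$signals)))
message("Wrote normalized.tsv under ", out)
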