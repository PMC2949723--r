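#!/usr/bin/env Rscript
# Stage 1: simulate the two-group array study.
#
# Emulates the design the pipeline targets: 5 control and 6 treated arrays
# over 1000 probes, 20 probes planted up- and 20 down-regulated at 2-fold in
# the treated group, 10% multiplicative noise, 75% of probes annotated, and
# a 5% weak-signal fraction below the fold floor of 10.

suppressPackageStartupMessages(library(connmap))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- synthetic_design(n_probes = 1000, n_control = 5, n_treated = 6,
                           n_up = 20, n_down = 20, fold_planted = 2,
                           noise_cv = 0.1, frac_annotated = 0.75,
                           seed = 4001)
gen <- generate_expression(design)

write_signal_matrix(gen$matrix, file.path(out, "expression.tsv"),
                    file.path(out, "groups.tsv"))
write_annotation(gen$annotation, file.path(out, "annotation.tsv"))
write.table(gen$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("Simulated %d probes x %d arrays (%d control, %d treated).",
                nrow(gen$matrix$signals), ncol(gen$matrix$signals),
                sum(gen$matrix$groups == "control"),
                sum(gen$matrix$groups == "treated")))
message(sprintf("Planted %d up and %d down probes at %.1f-fold; %d of %d planted probes carry a gene symbol.",
                sum(gen$truth$direction == "up"),
                sum(gen$truth$direction == "down"), design$fold_planted,
                sum(gen$truth$symbol != ""), nrow(gen$truth)))
message("Wrote expression.tsv, groups.tsv, annotation.tsv, truth.tsv under ", out)
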