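#!/usr/bin/env Rscript
# Stage 4: screen the signature against a synthetic compound reference
# database and select negatively connected (signature-reversing) instances.
#
# The database plants 5 reversers and 5 mimics at maximal strength among 90
# nulls over the annotated-gene universe. Scoring is the rank-based KS
# connectivity score scaled to [-1, 1], with tag-permutation p-values
# (n_perm = 1999); selection uses the strict thresholds scaled score < -0.5
# and p < 0.005.

suppressPackageStartupMessages(library(connmap))

out <- "results/analysis"
sig <- read_gmt(file.path(out, "signature.gmt"))
ann <- read_annotation(file.path(out, "annotation.tsv"))
universe <- ann$symbol[ann$symbol != ""]

db <- generate_reference_db(
  reference_db_design(n_instances = 100, n_reversers = 5, n_mimics = 5,
                      effect_strength = 1, seed = 4002),
  sig, universe)
write_reference_db(db, file.path(out, "refdb.tsv"),
                   file.path(out, "refdb_labels.tsv"))

res <- score_reference_db(sig, db$profiles, n_perm = 1999, seed = 4003,
                          score_cut = -0.5, p_cut = 0.005)
write_connectivity_results(res, file.path(out, "connectivity.tsv"))
sel <- rank_and_select(res, score_cut = -0.5, p_cut = 0.005)
write.table(sel, file.path(out, "selected.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

types <- db$labels$type[match(sel$instance_id, db$labels$instance_id)]
message(sprintf("%d of %d instances selected at scaled score < -0.5 and p < 0.005.",
                nrow(sel), nrow(res)))
message(sprintf("Selected types: %s.", paste(sort(types), collapse = ", ")))
message(sprintf("Scaled scores of selected instances: %s; max p-value %.4f.",
                paste(sprintf("%.3f", sel$scaled_score), collapse = ", "),
                max(sel$p_value)))
message("Wrote refdb.tsv, connectivity.tsv, selected.tsv under ", out)
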