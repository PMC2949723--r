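#!/usr/bin/env Rscript
# Stage 3: differential expression, the up/down query signature, and the
# clustering check that the signature separates the groups.
#
# Probes pass at >= 1.5-fold (means floored at 10) and p <= 0.05 from an
# equal-variance t-test on log signals; passing probes with gene symbols
# define the up/down tag lists.

suppressPackageStartupMessages(library(connmap))

out <- "results/analysis"
m <- read_signal_matrix(file.path(out, "normalized.tsv"),
                        file.path(out, "groups.tsv"))
ann <- read_annotation(file.path(out, "annotation.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"), stringsAsFactors = FALSE)

de <- compute_de(m, ann, floor = 10, fold_cut = 1.5, p_cut = 0.05)
write.table(de, file.path(out, "de_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- extract_signature(de, fold_cut = 1.5, p_cut = 0.05)
write_gmt(sig$signature, file.path(out, "signature.gmt"), name = "PLANTED")

message(sprintf("%d of %d probes pass the 1.5-fold / p<=0.05 filter; %d carry gene symbols.",
                sig$report$n_pass, sig$report$n_probes,
                sig$report$n_pass_annotated))
message(sprintf("Signature: %d up tags, %d down tags.",
                sig$report$n_up_tags, sig$report$n_down_tags))

truth_sym <- truth$symbol[truth$symbol != ""]
found <- c(sig$signature$up, sig$signature$down)
message(sprintf("Against the planted truth: recall %.2f, precision %.2f.",
                length(intersect(found, truth_sym)) / length(truth_sym),
                length(intersect(found, truth_sym)) / length(found)))

cl <- cluster_samples(m, de$probe_id[de$passes_filter])
jsonlite::write_json(list(leaf_order = cl$leaf_order,
                          root_split = cl$root_split,
                          merge_heights = cl$hclust$height),
                     file.path(out, "clustering.json"), digits = NA)
groups <- split(names(m$groups), m$groups)
s <- lapply(cl$root_split, sort)
sep <- (setequal(s[[1]], groups$control) && setequal(s[[2]], groups$treated)) ||
  (setequal(s[[1]], groups$treated) && setequal(s[[2]], groups$control))
message("Root split separates control from treated: ", sep)
message("Wrote de_report.tsv, signature.gmt, clustering.json under ", out)
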