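test_that("noiseless planting yields exact fold ratios and a null design yields none", {
  d <- synthetic_design(n_probes = 50, n_control = 3, n_treated = 3,
                        n_up = 1, n_down = 1, fold_planted = 2,
                        noise_cv = 0, frac_weak = 0, seed = 3)
  g <- generate_expression(d)
  ctrl <- group_columns(g$matrix, "control")
  trt <- group_columns(g$matrix, "treated")
  up <- g$truth$probe_id[g$truth$direction == "up"]
  down <- g$truth$probe_id[g$truth$direction == "down"]
  for (i in seq_len(ncol(trt))) {
    expect_equal(unname(trt[up, i] / ctrl[up, 1]), 2)
    expect_equal(unname(trt[down, i] / ctrl[down, 1]), 0.5)
  }
  others <- setdiff(probe_ids(g$matrix), g$truth$probe_id)
  expect_equal(unname(trt[others, 1] / ctrl[others, 1]),
               rep(1, length(others)))

  null_d <- synthetic_design(n_probes = 50, n_up = 0, n_down = 0,
                             noise_cv = 0, frac_weak = 0, seed = 3)
  gn <- generate_expression(null_d)
  expect_equal(nrow(gn$truth), 0)
  expect_equal(unname(group_columns(gn$matrix, "treated")[, 1]),
               unname(group_columns(gn$matrix, "control")[, 1]))
})

test_that("generated signals are strictly positive, weak probes and empty symbols appear", {
  d <- synthetic_design(n_probes = 500, noise_cv = 0.2, frac_weak = 0.1,
                        frac_annotated = 0.6, seed = 9)
  g <- generate_expression(d)
  expect_true(all(g$matrix$signals > 0))
  ctrl_means <- rowMeans(group_columns(g$matrix, "control"))
  expect_gt(sum(ctrl_means < 10), 0)            # flooring rule exercised
  expect_equal(sum(g$annotation$symbol == ""), 500 - round(0.6 * 500))
  expect_equal(anyDuplicated(g$annotation$symbol[g$annotation$symbol != ""]), 0L)
})

test_that("identical design and seed reproduce bit-identical output", {
  d <- synthetic_design(n_probes = 1000, n_up = 20, n_down = 20,
                        fold_planted = 2, noise_cv = 0.1, seed = 7)
  g1 <- generate_expression(d)
  g2 <- generate_expression(d)
  expect_identical(g1$matrix$signals, g2$matrix$signals)
  expect_identical(g1$truth, g2$truth)

  sig <- deg_signature(c("A", "B"), c("C", "D"))
  db_d <- reference_db_design(n_instances = 20, n_reversers = 3, seed = 5)
  uni <- c(LETTERS, letters)
  db1 <- generate_reference_db(db_d, sig, uni)
  db2 <- generate_reference_db(db_d, sig, uni)
  expect_identical(lapply(db1$profiles, `[[`, "ranking"),
                   lapply(db2$profiles, `[[`, "ranking"))
})

test_that("invalid designs are rejected", {
  expect_error(synthetic_design(n_probes = 10, n_up = 6, n_down = 6),
               "invalid design")
  expect_error(synthetic_design(fold_planted = 0.5), "invalid design")
  expect_error(reference_db_design(n_instances = 3, n_mimics = 2,
                                   n_reversers = 2), "invalid design")
  sig <- deg_signature("A", "B")
  db_d <- reference_db_design(n_instances = 2, seed = 1)
  expect_error(generate_reference_db(db_d, sig, character(0)),
               "empty probe universe")
  expect_error(generate_reference_db(db_d, sig, c("A", "X")),
               "outside the universe")
})

test_that("maximal-strength reverser places up-tags last and down-tags first", {
  uni <- sprintf("g%d", 1:10)
  sig <- deg_signature("g1", "g2")
  db <- generate_reference_db(
    reference_db_design(n_instances = 1, n_reversers = 1,
                        effect_strength = 1, seed = 2),
    sig, uni)
  r <- db$profiles[[1]]$ranking
  expect_setequal(r, uni)
  expect_equal(match("g1", r), 10)
  expect_equal(match("g2", r), 1)

  # and a maximal mimic does the opposite
  dbm <- generate_reference_db(
    reference_db_design(n_instances = 1, n_mimics = 1,
                        effect_strength = 1, seed = 2),
    sig, uni)
  rm_ <- dbm$profiles[[1]]$ranking
  expect_equal(match("g1", rm_), 1)
  expect_equal(match("g2", rm_), 10)
})

test_that("every instance is a complete permutation of the universe", {
  uni <- sprintf("g%d", 1:40)
  sig <- deg_signature(sprintf("g%d", 1:3), sprintf("g%d", 4:6))
  db <- generate_reference_db(
    reference_db_design(n_instances = 30, n_mimics = 5, n_reversers = 5,
                        effect_strength = 0.5, seed = 8),
    sig, uni)
  for (p in db$profiles) expect_setequal(p$ranking, uni)
})

test_that("at zero effect strength and in nulls, tag positions are uniform", {
  uni <- sprintf("g%d", 1:50)
  sig <- deg_signature("g1", "g2")
  db <- generate_reference_db(
    reference_db_design(n_instances = 1200, n_reversers = 1200,
                        effect_strength = 0, seed = 13),
    sig, uni)
  pos <- vapply(db$profiles, function(p) match("g1", p$ranking), 0L)
  counts <- tabulate(pos, nbins = 50)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  dbn <- generate_reference_db(
    reference_db_design(n_instances = 1200, seed = 14), sig, uni)
  posn <- vapply(dbn$profiles, function(p) match("g2", p$ranking), 0L)
  expect_gt(stats::chisq.test(tabulate(posn, nbins = 50))$p.value, 0.01)
})

test_that("expression and reference-db TSV round-trips preserve content", {
  d <- synthetic_design(n_probes = 30, n_control = 2, n_treated = 2,
                        n_up = 3, n_down = 3, seed = 4)
  g <- generate_expression(d)
  td <- withr::local_tempdir()
  write_signal_matrix(g$matrix, file.path(td, "m.tsv"), file.path(td, "g.tsv"))
  m2 <- read_signal_matrix(file.path(td, "m.tsv"), file.path(td, "g.tsv"))
  expect_equal(m2$signals, g$matrix$signals, tolerance = 1e-12)
  expect_identical(m2$groups, g$matrix$groups)
  write_annotation(g$annotation, file.path(td, "a.tsv"))
  expect_identical(read_annotation(file.path(td, "a.tsv")), g$annotation)

  sig <- deg_signature("GENE1", "GENE2")
  db <- generate_reference_db(
    reference_db_design(n_instances = 4, n_reversers = 1, seed = 6),
    sig, c("GENE1", "GENE2", sprintf("X%d", 1:10)))
  write_reference_db(db, file.path(td, "db.tsv"), file.path(td, "lab.tsv"))
  db2 <- read_reference_db(file.path(td, "db.tsv"), file.path(td, "lab.tsv"))
  expect_identical(lapply(db2$profiles, `[[`, "ranking"),
                   lapply(db$profiles, `[[`, "ranking"))
  expect_identical(db2$labels$type, db$labels$type)
})
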