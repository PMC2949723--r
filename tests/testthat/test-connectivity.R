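test_that("KS enrichment reproduces the worked extremes and rejects bad input", {
  expect_equal(ks_enrichment(c(1, 2), 10), 0.8)
  expect_equal(ks_enrichment(c(9, 10), 10), -0.9)
  expect_error(ks_enrichment(integer(0), 10), "empty tag set")
  expect_error(ks_enrichment(c(1, 1), 10), "distinct")
  expect_error(ks_enrichment(c(0, 5), 10), "distinct integers")
})

test_that("KS enrichment equals the brute-force CDF-scan oracle exhaustively", {
  for (n in 2:8) {
    for (t in 1:min(3, n)) {
      sets <- utils::combn(n, t)
      for (k in seq_len(ncol(sets))) {
        V <- sets[, k]
        expect_equal(ks_enrichment(V, n), ks_oracle(V, n),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment stays within [-1, 1] for random tag placements", {
  set.seed(3)
  for (i in 1:500) {
    n <- sample(5:200, 1)
    t <- sample.int(min(20, n), 1)
    es <- ks_enrichment(sample.int(n, t), n)
    expect_true(es >= -1 && es <= 1)
  }
})

test_that("connectivity score composes the two enrichments with the same-sign zero rule", {
  uni <- sprintf("g%d", 1:10)
  sig <- deg_signature(c("g1", "g2"), c("g9", "g10"))
  prof <- structure(list(instance_id = "I1", compound_name = "x",
                         ranking = uni), class = "reference_profile")
  cs <- connectivity_score(sig, prof)
  expect_equal(cs$ks_up, 0.8)
  expect_equal(cs$ks_down, -0.9)
  expect_equal(cs$raw_score, 1.7)

  # both directions enriched at the top -> same sign -> raw score 0
  sig_same <- deg_signature(c("g1", "g2"), c("g3", "g4"))
  expect_equal(connectivity_score(sig_same, prof)$raw_score, 0)

  # inverse connectivity: up-tags at the bottom, down-tags at the top
  sig_inv <- deg_signature(c("g9", "g10"), c("g1", "g2"))
  expect_lt(connectivity_score(sig_inv, prof)$raw_score, 0)
})

test_that("unresolvable tags are dropped and flagged; fully unresolvable errors", {
  uni <- sprintf("g%d", 1:20)
  prof <- structure(list(instance_id = "I1", compound_name = "x",
                         ranking = uni), class = "reference_profile")
  sig <- deg_signature(c("g1", "nope1", "nope2"), c("g20", "nope3"))
  cs <- connectivity_score(sig, prof)
  expect_equal(cs$n_resolved_up, 1)
  expect_equal(cs$n_resolved_down, 1)
  expect_true(cs$flagged)

  sig_bad <- deg_signature(c("zz1", "zz2"), "g5")
  expect_error(connectivity_score(sig_bad, prof), "no resolvable tags")
})

test_that("score scaling divides each sign by its extreme and keeps zeros", {
  expect_equal(scale_scores(c(1.7, -1.7, 0)), c(1, -1, 0))
  expect_equal(scale_scores(c(0.5, 1.0, -0.2)), c(0.5, 1.0, -1.0))
  expect_equal(scale_scores(c(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  s <- scale_scores(rnorm(100))
  expect_true(all(s >= -1 & s <= 1))
  expect_true(any(s == 1) && any(s == -1))
})

test_that("permutation p-values hit the add-one extremes and are seed-deterministic", {
  uni <- sprintf("g%d", 1:300)
  prof <- structure(list(instance_id = "I1", compound_name = "x",
                         ranking = uni), class = "reference_profile")
  # maximal inverse planting: no random tag set can beat |raw| ~ 2
  sig <- deg_signature(rev(uni)[1:5], uni[1:5])
  cs <- connectivity_score(sig, prof)
  p <- permutation_pvalue(5, 5, prof, cs$raw_score, n_perm = 999, seed = 10)
  expect_equal(p, 1 / 1000)

  expect_equal(permutation_pvalue(5, 5, prof, 0, n_perm = 99, seed = 10), 1)

  p1 <- permutation_pvalue(5, 5, prof, 1.0, n_perm = 199, seed = 10)
  p2 <- permutation_pvalue(5, 5, prof, 1.0, n_perm = 199, seed = 10)
  expect_identical(p1, p2)
  expect_error(ks_null_scores(200, 200, 300, 10), "larger than the universe")
})

test_that("reversing a ranking negates the enrichments within the step asymmetry", {
  set.seed(9)
  uni <- sprintf("g%d", 1:100)
  tags <- sample(uni, 16)
  sig <- deg_signature(tags[1:8], tags[9:16])
  prof <- structure(list(instance_id = "I1", compound_name = "x",
                         ranking = sample(uni)), class = "reference_profile")
  prof_rev <- prof
  prof_rev$ranking <- rev(prof$ranking)
  a <- connectivity_score(sig, prof)
  b <- connectivity_score(sig, prof_rev)
  expect_lt(abs(a$ks_up + b$ks_up), 1 / 100 + 1e-12)
  expect_lt(abs(a$ks_down + b$ks_down), 1 / 100 + 1e-12)
})

test_that("selection applies strict thresholds and orders most-negative first", {
  res <- data.frame(
    instance_id = c("I3", "I1", "I2", "I4", "I5"),
    compound_name = letters[1:5],
    scaled_score = c(-0.6, -0.6, -0.5, -0.9, -0.7),
    p_value = c(0.001, 0.001, 0.001, 0.005, 0.004),
    stringsAsFactors = FALSE)
  sel <- rank_and_select(res, score_cut = -0.5, p_cut = 0.005)
  # I2 fails the strict score bound, I4 the strict p bound
  expect_equal(sel$instance_id, c("I5", "I1", "I3"))
  expect_error(rank_and_select(res[0, ]), "empty")
})

test_that("mean scaled score of reversers decreases with effect strength", {
  uni <- sprintf("g%d", 1:200)
  sig <- deg_signature(uni[1:10], uni[11:20])
  means <- sapply(c(0, 0.5, 1), function(e) {
    db <- generate_reference_db(
      reference_db_design(n_instances = 40, n_reversers = 10,
                          effect_strength = e, seed = 17),
      sig, uni)
    res <- score_reference_db(sig, db$profiles, n_perm = 99, seed = 18)
    mean(res$scaled_score[db$labels$type == "reverser"])
  })
  expect_true(all(diff(means) < 0))
  expect_lt(means[3], -0.9)
})

test_that("null p-values are calibrated below the zero-score atom", {
  # the same-sign rule places an atom of raw scores at exactly 0, which the
  # add-one estimator maps to p = 1; below that atom p is uniform
  uni <- sprintf("g%d", 1:300)
  prof <- structure(list(instance_id = "I1", compound_name = "x",
                         ranking = uni), class = "reference_profile")
  set.seed(44)
  nulls <- ks_null_scores(10, 10, 300, 999)
  pvals <- replicate(600, {
    tags <- sample(uni, 20)
    sig <- deg_signature(tags[1:10], tags[11:20])
    cs <- connectivity_score(sig, prof)
    permutation_pvalue(10, 10, prof, cs$raw_score, null_scores = nulls)
  })
  expect_gte(mean(pvals <= 0.05), 0.03)
  expect_lte(mean(pvals <= 0.05), 0.07)
  for (q in c(0.1, 0.2, 0.3))
    expect_lt(abs(mean(pvals <= q) - q), 0.05)
  expect_gt(mean(pvals == 1), 0.3)  # the atom is real and sizable
})

test_that("database scoring is reproducible and its results survive a TSV round-trip", {
  uni <- sprintf("g%d", 1:100)
  sig <- deg_signature(uni[1:6], uni[7:12])
  db <- generate_reference_db(
    reference_db_design(n_instances = 20, n_reversers = 2, seed = 3),
    sig, uni)
  r1 <- score_reference_db(sig, db$profiles, n_perm = 199, seed = 7)
  r2 <- score_reference_db(sig, db$profiles, n_perm = 199, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$scaled_score >= -1 & r1$scaled_score <= 1))
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))

  td <- withr::local_tempdir()
  write_connectivity_results(r1, file.path(td, "res.tsv"))
  back <- utils::read.delim(file.path(td, "res.tsv"), stringsAsFactors = FALSE)
  expect_equal(back$scaled_score, r1$scaled_score, tolerance = 1e-12)
})
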