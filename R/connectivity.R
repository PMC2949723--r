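#' Kolmogorov-Smirnov enrichment score of a tag set in a ranking
#'
#' For tag positions V(1) < ... < V(t) in a ranked universe of size n
#' (position 1 = most up-regulated), the statistic compares the tags'
#' empirical distribution to uniform:
#' a = max_j \[ j/t - V(j)/n \], b = max_j \[ V(j)/n - (j-1)/t \],
#' and the score is `a` if a > b, else `-b`. It is positive when tags
#' concentrate at the top of the ranking, negative at the bottom, and is
#' always in \[-1, 1\].
#'
#' @param positions Integer positions of the tags in the ranking (any
#'   order; must be distinct and within 1..n).
#' @param n Size of the ranked universe.
#' @return The enrichment score.
#' @examples
#' ks_enrichment(c(1, 2), 10)   #  0.8: tags at the very top
#' ks_enrichment(c(9, 10), 10)  # -0.9: tags at the very bottom
#' @export
ks_enrichment <- function(positions, n) {
  t <- length(positions)
  if (t == 0) stop("empty tag set", call. = FALSE)
  if (t > n || any(positions < 1) || any(positions > n) ||
      anyDuplicated(positions))
    stop("positions must be distinct integers in 1..n", call. = FALSE)
  V <- sort.int(positions)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a > b) a else -b
}

# Unchecked kernel used in permutation loops.
ks_es_fast <- function(V_sorted, t, n) {
  j <- seq_len(t)
  a <- max(j / t - V_sorted / n)
  b <- max(V_sorted / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity score of a signature against one reference profile
#'
#' Resolves the signature's up- and down-tags to positions in the profile's
#' ranking (unresolvable tags are dropped and counted), computes the KS
#' enrichment score of each direction, and combines them: the raw score is
#' 0 when the two enrichments share a sign (the profile does not separate
#' the directions), otherwise `ks_up - ks_down`. A negative raw score is
#' the "inverse connectivity" configuration: the compound's profile opposes
#' the query signature.
#'
#' @param sig A [deg_signature()].
#' @param prof A `reference_profile` (fields `instance_id`,
#'   `compound_name`, `ranking`).
#' @return A list: `ks_up`, `ks_down`, `raw_score`, `n_resolved_up`,
#'   `n_resolved_down`, and `flagged` (TRUE when < 50% of tags resolved).
#' @export
connectivity_score <- function(sig, prof) {
  n <- length(prof$ranking)
  pos_up <- match(sig$up, prof$ranking)
  pos_down <- match(sig$down, prof$ranking)
  n_res_up <- sum(!is.na(pos_up))
  n_res_down <- sum(!is.na(pos_down))
  if (n_res_up == 0 || n_res_down == 0)
    stop("no resolvable tags in one direction for instance ",
         prof$instance_id, call. = FALSE)
  ks_up <- ks_enrichment(pos_up[!is.na(pos_up)], n)
  ks_down <- ks_enrichment(pos_down[!is.na(pos_down)], n)
  raw <- if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
  n_tags <- length(sig$up) + length(sig$down)
  list(ks_up = ks_up, ks_down = ks_down, raw_score = raw,
       n_resolved_up = n_res_up, n_resolved_down = n_res_down,
       flagged = (n_res_up + n_res_down) < 0.5 * n_tags)
}

#' Scale raw connectivity scores to \[-1, 1\]
#'
#' Positive raw scores are divided by the maximum positive raw score,
#' negative ones by the magnitude of the most negative; zeros stay zero.
#' Whenever any raw score is nonzero, at least one instance attains +1 or
#' -1.
#'
#' @param raw Numeric vector of raw scores.
#' @return Scaled scores in \[-1, 1\].
#' @export
scale_scores <- function(raw) {
  if (length(raw) == 0) stop("need at least one instance", call. = FALSE)
  out <- numeric(length(raw))
  p <- raw > 0; q <- raw < 0
  if (any(p)) out[p] <- raw[p] / max(raw[p])
  if (any(q)) out[q] <- raw[q] / abs(min(raw[q]))
  out
}

#' Null distribution of raw connectivity scores
#'
#' Draws `n_perm` random disjoint tag sets of sizes `t_up` and `t_down`
#' over a universe of size `n` and returns their raw scores. The null
#' depends only on the tag-set sizes and universe size, not on any
#' particular profile permutation.
#'
#' @param t_up,t_down Tag-set sizes.
#' @param n Universe size.
#' @param n_perm Number of permutations.
#' @return Numeric vector of `n_perm` raw scores.
#' @export
ks_null_scores <- function(t_up, t_down, n, n_perm) {
  if (t_up + t_down > n)
    stop("tag sets larger than the universe", call. = FALSE)
  tt <- t_up + t_down
  vapply(seq_len(n_perm), function(i) {
    s <- sample.int(n, tt)
    ku <- ks_es_fast(sort.int(s[seq_len(t_up)]), t_up, n)
    kd <- ks_es_fast(sort.int(s[(t_up + 1):tt]), t_down, n)
    if (sign(ku) == sign(kd)) 0 else ku - kd
  }, numeric(1))
}

#' Permutation p-value of an observed connectivity score
#'
#' Two-sided add-one permutation test: random disjoint tag sets of the
#' query's sizes are drawn over the profile's universe and
#' p = (1 + #\{|raw_perm| >= |raw_obs|\}) / (n_perm + 1), so p is never 0.
#'
#' @param t_up,t_down Query tag-set sizes.
#' @param prof A `reference_profile` (only its universe size is used), or a
#'   single integer universe size.
#' @param observed_raw Observed raw score.
#' @param n_perm Number of permutations (default 1999).
#' @param seed Optional seed for the permutation draws.
#' @param null_scores Optional precomputed vector from [ks_null_scores()]
#'   (then no draws are made and `n_perm` is taken from its length).
#' @return p-value in (0, 1\].
#' @export
permutation_pvalue <- function(t_up, t_down, prof, observed_raw,
                               n_perm = 1999, seed = NULL,
                               null_scores = NULL) {
  n <- if (is.numeric(prof) && length(prof) == 1) prof
       else length(prof$ranking)
  if (is.null(null_scores)) {
    stopifnot(n_perm >= 1)
    null_scores <- if (is.null(seed)) ks_null_scores(t_up, t_down, n, n_perm)
                   else with_seed(seed, ks_null_scores(t_up, t_down, n, n_perm))
  }
  (1 + sum(abs(null_scores) >= abs(observed_raw))) /
    (length(null_scores) + 1)
}

#' Score a signature against every instance of a reference database
#'
#' Computes per-instance KS connectivity scores, scales them to \[-1, 1\]
#' across the database, and attaches a permutation p-value per instance.
#' The permutation null is drawn once per distinct (t_up, t_down, n)
#' combination and shared across the instances it applies to, which is
#' exact because the null depends only on those sizes.
#'
#' @param sig A [deg_signature()].
#' @param profiles List of `reference_profile`s.
#' @param n_perm Permutations per null (default 1999).
#' @param seed Seed for the permutation draws (mandatory for
#'   reproducibility).
#' @param score_cut,p_cut Strict selection thresholds (defaults -0.5 and
#'   0.005): an instance is selected iff scaled_score < score_cut and
#'   p_value < p_cut.
#' @return Data frame with one row per instance: `instance_id`,
#'   `compound_name`, `ks_up`, `ks_down`, `raw_score`, `scaled_score`,
#'   `p_value`, `selected`, `flagged`.
#' @export
score_reference_db <- function(sig, profiles, n_perm = 1999, seed,
                               score_cut = -0.5, p_cut = 0.005) {
  stopifnot(length(profiles) >= 1)
  scores <- lapply(profiles, function(p) connectivity_score(sig, p))
  raw <- vapply(scores, `[[`, 0, "raw_score")
  scaled <- scale_scores(raw)
  res <- data.frame(
    instance_id = vapply(profiles, `[[`, "", "instance_id"),
    compound_name = vapply(profiles, `[[`, "", "compound_name"),
    ks_up = vapply(scores, `[[`, 0, "ks_up"),
    ks_down = vapply(scores, `[[`, 0, "ks_down"),
    raw_score = raw, scaled_score = scaled,
    p_value = NA_real_,
    selected = FALSE,
    flagged = vapply(scores, `[[`, TRUE, "flagged"),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    null_cache <- new.env(parent = emptyenv())
    for (i in seq_along(profiles)) {
      key <- sprintf("%d_%d_%d", scores[[i]]$n_resolved_up,
                     scores[[i]]$n_resolved_down,
                     length(profiles[[i]]$ranking))
      if (!exists(key, envir = null_cache, inherits = FALSE))
        null_cache[[key]] <- ks_null_scores(
          scores[[i]]$n_resolved_up, scores[[i]]$n_resolved_down,
          length(profiles[[i]]$ranking), n_perm)
      res$p_value[i] <- permutation_pvalue(
        scores[[i]]$n_resolved_up, scores[[i]]$n_resolved_down,
        length(profiles[[i]]$ranking), raw[i],
        null_scores = null_cache[[key]])
    }
  })
  res$selected <- res$scaled_score < score_cut & res$p_value < p_cut
  res
}

#' Select and rank negatively connected instances
#'
#' Applies the strict selection rule (scaled score below `score_cut` AND
#' p-value below `p_cut`) and orders the selected instances most-negative
#' first, ties broken by instance id.
#'
#' @param results Data frame from [score_reference_db()].
#' @param score_cut Strict scaled-score threshold (default -0.5).
#' @param p_cut Strict p-value threshold (default 0.005).
#' @return The selected rows, ordered by `scaled_score` ascending.
#' @export
rank_and_select <- function(results, score_cut = -0.5, p_cut = 0.005) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  sel <- results[results$scaled_score < score_cut &
                   results$p_value < p_cut, , drop = FALSE]
  sel[order(sel$scaled_score, sel$instance_id), , drop = FALSE]
}

#' Write a connectivity results table as TSV
#'
#' @param results Data frame from [score_reference_db()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_connectivity_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
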