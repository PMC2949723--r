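#' Floored signed fold change
#'
#' Both group means are first raised to a minimum floor (default 10) so weak
#' signals cannot produce extreme ratios; the ratio of floored means is then
#' reported on a signed scale: +r for up-regulation (r >= 1), -1/r for
#' down-regulation, so |fold| >= 1 always and down-regulation is negative.
#'
#' @param mean_treated,mean_control Positive group means (vectorized).
#' @param floor Positive signal floor (default 10).
#' @return Signed fold change(s).
#' @examples
#' floored_fold(200, 100)  # +2
#' floored_fold(2, 40)     # 2 floored to 10 -> -4
#' @export
floored_fold <- function(mean_treated, mean_control, floor = 10) {
  if (any(mean_treated <= 0) || any(mean_control <= 0))
    stop("group means must be positive", call. = FALSE)
  stopifnot(floor > 0)
  t_ <- pmax(mean_treated, floor)
  c_ <- pmax(mean_control, floor)
  r <- t_ / c_
  ifelse(r >= 1, r, -1 / r)
}

#' Per-probe two-sample Student t-test
#'
#' Classical equal-variance two-sided t-test between the treated and control
#' groups for every probe, computed on log intensities by default (matching
#' the log-space normalization; set `log_scale = FALSE` for raw scale).
#' Degenerate probes with zero pooled variance get p = 1 when the group
#' means are equal and p = 0 otherwise.
#'
#' @param m A [signal_matrix()] with >= 2 samples per group.
#' @param log_scale Test on log signals (default `TRUE`).
#' @return Named numeric vector of p-values in \[0, 1\], one per probe.
#' @export
per_probe_ttest <- function(m, log_scale = TRUE) {
  stopifnot(inherits(m, "signal_matrix"))
  xc <- group_columns(m, "control")
  xt <- group_columns(m, "treated")
  n1 <- ncol(xc); n2 <- ncol(xt)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples for a t-test", call. = FALSE)
  if (log_scale) {
    if (any(xc <= 0) || any(xt <= 0))
      stop("log-scale t-test requires strictly positive signals", call. = FALSE)
    xc <- log(xc); xt <- log(xt)
  }
  m1 <- rowMeans(xc); m2 <- rowMeans(xt)
  v1 <- apply(xc, 1, stats::var); v2 <- apply(xt, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- ifelse(se > 0,
              2 * stats::pt(abs(m2 - m1) / ifelse(se > 0, se, 1),
                            df, lower.tail = FALSE),
              ifelse(m1 == m2, 1, 0))
  stats::setNames(pmin(pmax(p, 0), 1), probe_ids(m))
}

#' Per-probe differential-expression table
#'
#' Computes group means of the (normalized) signals, the floored signed fold
#' change, the Student t-test p-value, and the pass/fail flag at the fold
#' and p cutoffs (both inclusive).
#'
#' @param m A normalized [signal_matrix()].
#' @param annotation Optional data frame (`probe_id`, `symbol`); unannotated
#'   probes get an empty symbol.
#' @param floor Signal floor for [floored_fold()] (default 10).
#' @param fold_cut Fold cutoff, inclusive (default 1.5).
#' @param p_cut p-value cutoff, inclusive (default 0.05).
#' @param log_scale Scale of the t-test (default log).
#' @return Data frame with columns `probe_id`, `symbol`, `mean_control`,
#'   `mean_treated`, `signed_fold`, `p_value`, `passes_filter`.
#' @export
compute_de <- function(m, annotation = NULL, floor = 10,
                       fold_cut = 1.5, p_cut = 0.05, log_scale = TRUE) {
  stopifnot(inherits(m, "signal_matrix"), fold_cut >= 1)
  mc <- rowMeans(group_columns(m, "control"))
  mt <- rowMeans(group_columns(m, "treated"))
  fold <- floored_fold(mt, mc, floor)
  p <- per_probe_ttest(m, log_scale = log_scale)
  symbol <- rep("", nrow(m$signals))
  if (!is.null(annotation)) {
    idx <- match(probe_ids(m), annotation$probe_id)
    symbol <- ifelse(is.na(idx), "", annotation$symbol[idx])
    symbol[is.na(symbol)] <- ""
  }
  data.frame(probe_id = probe_ids(m), symbol = symbol,
             mean_control = unname(mc), mean_treated = unname(mt),
             signed_fold = unname(fold), p_value = unname(p),
             passes_filter = abs(unname(fold)) >= fold_cut & unname(p) <= p_cut,
             stringsAsFactors = FALSE)
}

#' Construct an up/down gene signature
#'
#' @param up,down Character vectors of unique, non-empty gene symbols; the
#'   two directions must be disjoint.
#' @param provenance Optional list of filter parameters / source metadata.
#' @return A `deg_signature` with fields `up`, `down`, `provenance` and an
#'   attribute `usable` (FALSE when a direction is empty).
#' @export
deg_signature <- function(up, down, provenance = list()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (any(up == "") || any(down == ""))
    stop("signature tags must be non-empty symbols", call. = FALSE)
  if (length(intersect(up, down)) > 0)
    stop("up and down tags must be disjoint", call. = FALSE)
  sig <- structure(list(up = up, down = down, provenance = provenance),
                   class = "deg_signature")
  attr(sig, "usable") <- length(up) > 0 && length(down) > 0
  sig
}

#' @export
print.deg_signature <- function(x, ...) {
  cat(sprintf("<deg_signature> %d up tags, %d down tags%s\n",
              length(x$up), length(x$down),
              if (isTRUE(attr(x, "usable"))) "" else " (unusable)"))
  invisible(x)
}

#' Extract the differential-expression signature from a DE table
#'
#' Probes pass the filter iff |signed_fold| >= `fold_cut` and
#' p <= `p_cut` (both inclusive). Passing probes without a symbol are
#' counted but excluded from the signature; duplicate symbols collapse to
#' one tag (a gene enters a direction if any passing probe supports it);
#' a symbol supported in both directions is dropped from both with a
#' warning. An empty direction yields a warning and an unusable signature.
#'
#' @param de DE table from [compute_de()]; must contain `symbol`,
#'   `signed_fold`, `p_value`.
#' @param annotation Optional (`probe_id`, `symbol`) table overriding the
#'   `symbol` column of `de`.
#' @param fold_cut,p_cut Inclusive filter cutoffs (defaults 1.5 and 0.05).
#' @return A list: `signature` ([deg_signature()]) and `report` (list of
#'   counts: probes passing, passing with symbols, tags per direction,
#'   conflicted symbols dropped).
#' @export
extract_signature <- function(de, annotation = NULL,
                              fold_cut = 1.5, p_cut = 0.05) {
  if (nrow(de) == 0) stop("empty DE table", call. = FALSE)
  stopifnot(fold_cut >= 1)
  symbol <- de$symbol
  if (!is.null(annotation)) {
    idx <- match(de$probe_id, annotation$probe_id)
    symbol <- ifelse(is.na(idx), "", annotation$symbol[idx])
    symbol[is.na(symbol)] <- ""
  }
  pass <- abs(de$signed_fold) >= fold_cut & de$p_value <= p_cut
  up_sym <- unique(symbol[pass & de$signed_fold > 0 & symbol != ""])
  down_sym <- unique(symbol[pass & de$signed_fold < 0 & symbol != ""])
  conflicted <- intersect(up_sym, down_sym)
  if (length(conflicted) > 0) {
    warning("symbols supported in both directions dropped: ",
            paste(conflicted, collapse = ", "), call. = FALSE)
    up_sym <- setdiff(up_sym, conflicted)
    down_sym <- setdiff(down_sym, conflicted)
  }
  sig <- deg_signature(up_sym, down_sym,
                       provenance = list(fold_cut = fold_cut, p_cut = p_cut,
                                         n_probes = nrow(de)))
  if (!isTRUE(attr(sig, "usable")))
    warning("signature has an empty direction and is unusable as a query",
            call. = FALSE)
  list(signature = sig,
       report = list(n_probes = nrow(de),
                     n_pass = sum(pass),
                     n_pass_annotated = sum(pass & symbol != ""),
                     n_up_tags = length(sig$up),
                     n_down_tags = length(sig$down),
                     n_conflicted = length(conflicted)))
}

#' Read / write a signature as a two-set GMT file
#'
#' Written as two GMT lines, `<name>_UP` and `<name>_DN`.
#'
#' @param sig A [deg_signature()].
#' @param path GMT path.
#' @param name Set-name stem (default "SIG").
#' @return The path (write) or a [deg_signature()] (read).
#' @export
write_gmt <- function(sig, path, name = "SIG") {
  lines <- c(paste(c(paste0(name, "_UP"), "up-regulated tags", sig$up),
                   collapse = "\t"),
             paste(c(paste0(name, "_DN"), "down-regulated tags", sig$down),
                   collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                          vapply(fields, `[[`, "", 1))
  up_i <- grep("_UP$", names(sets)); dn_i <- grep("_DN$", names(sets))
  if (length(up_i) != 1 || length(dn_i) != 1)
    stop("GMT must contain exactly one _UP and one _DN set", call. = FALSE)
  deg_signature(sets[[up_i]], sets[[dn_i]],
                provenance = list(source = path))
}

#' Hierarchically cluster samples on the signature probes
#'
#' Each probe row is mean-centered and scaled to unit norm across samples;
#' samples are then clustered by complete linkage on the correlation
#' distance 1 - Pearson(sample, sample). Rows that are constant after
#' centering carry no information and are dropped with a warning.
#'
#' @param m A [signal_matrix()] with >= 2 samples.
#' @param probes Probe ids (>= 2) to cluster on, typically the signature
#'   probes.
#' @return A list: `hclust` (the [stats::hclust] tree), `leaf_order`
#'   (sample ids left to right), and `root_split` (the two sample sets under
#'   the root).
#' @export
cluster_samples <- function(m, probes) {
  stopifnot(inherits(m, "signal_matrix"))
  if (ncol(m$signals) < 2) stop("need >= 2 samples", call. = FALSE)
  probes <- intersect(probes, probe_ids(m))
  if (length(probes) < 2) stop("need >= 2 probes", call. = FALSE)
  x <- m$signals[probes, , drop = FALSE]
  x <- x - rowMeans(x)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    warning(sum(norms == 0), " constant probe row(s) dropped", call. = FALSE)
    x <- x[norms > 0, , drop = FALSE]
    norms <- norms[norms > 0]
    if (nrow(x) < 2) stop("fewer than 2 informative probes", call. = FALSE)
  }
  x <- x / norms
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "complete")
  k2 <- stats::cutree(hc, k = 2)
  list(hclust = hc,
       leaf_order = hc$labels[hc$order],
       root_split = split(names(k2), k2))
}
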