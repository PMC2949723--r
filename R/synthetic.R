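#' Design of a synthetic two-group expression experiment
#'
#' Describes the planted structure of a simulated one-color array study:
#' a control group and a treated group, a fixed number of probes planted
#' up- or down-regulated at a known fold, multiplicative log-normal noise,
#' and a configurable annotated fraction. Defaults mirror the study design
#' the pipeline targets: 5 control and 6 treated arrays, with a small
#' weak-signal fraction so the fold floor is exercised.
#'
#' @param n_probes Number of probes on the array.
#' @param n_control,n_treated Samples per group.
#' @param n_up,n_down Number of probes planted up-/down-regulated in the
#'   treated group.
#' @param fold_planted Planted fold (>= 1); treated means are multiplied by
#'   it for up probes and divided by it for down probes.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise (0 = noiseless). The noise has expectation exactly 1, so planted
#'   expected group ratios equal `fold_planted`.
#' @param frac_annotated Fraction of probes carrying a gene symbol; the rest
#'   get an empty symbol and are excluded from signatures downstream.
#' @param frac_weak Fraction of (non-planted) probes with baselines below the
#'   fold floor of 10, exercising the weak-signal flooring rule.
#' @param baseline_range Two-element range; baselines are log-uniform over it.
#' @param seed Integer seed; identical design + seed gives identical output.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_probes = 1000, n_control = 5, n_treated = 6,
                             n_up = 20, n_down = 20, fold_planted = 2,
                             noise_cv = 0.1, frac_annotated = 0.75,
                             frac_weak = 0.05, baseline_range = c(50, 5000),
                             seed = 1) {
  stopifnot(n_probes >= 1, n_control >= 1, n_treated >= 1,
            n_up >= 0, n_down >= 0, noise_cv >= 0,
            length(baseline_range) == 2, baseline_range[1] > 0,
            baseline_range[2] >= baseline_range[1])
  if (n_up + n_down > n_probes)
    stop("invalid design: n_up + n_down exceeds n_probes", call. = FALSE)
  if (fold_planted < 1)
    stop("invalid design: fold_planted must be >= 1", call. = FALSE)
  if (frac_annotated < 0 || frac_annotated > 1)
    stop("invalid design: frac_annotated must be in [0, 1]", call. = FALSE)
  if (frac_weak < 0 || frac_weak > 1)
    stop("invalid design: frac_weak must be in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_design")
}

#' Generate a synthetic expression matrix with planted differential probes
#'
#' Baselines are drawn log-uniform over `baseline_range`; a `frac_weak`
#' subset of non-planted probes is forced below the fold floor of 10.
#' Planted up probes have expected treated/control ratio `fold_planted`,
#' planted down probes `1/fold_planted`; all other probes have expected
#' ratio 1. Noise is multiplicative log-normal with unit mean and
#' coefficient of variation `noise_cv`.
#'
#' @param design A [synthetic_design()].
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{[signal_matrix()] of strictly positive signals.}
#'     \item{annotation}{data frame `probe_id`, `symbol` ("" = unannotated).}
#'     \item{truth}{data frame of planted probes: `probe_id`, `symbol`,
#'       `direction` ("up"/"down"), `fold_planted`.}
#'   }
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    n <- design$n_probes
    pids <- sprintf("PROBE_%05d", seq_len(n))
    samples <- c(sprintf("ctrl_%02d", seq_len(design$n_control)),
                 sprintf("trt_%02d", seq_len(design$n_treated)))
    groups <- stats::setNames(
      rep(c("control", "treated"), c(design$n_control, design$n_treated)),
      samples)

    baseline <- exp(stats::runif(n, log(design$baseline_range[1]),
                                 log(design$baseline_range[2])))

    n_planted <- design$n_up + design$n_down
    planted <- if (n_planted > 0) sample.int(n, n_planted) else integer(0)
    up_idx <- utils::head(planted, design$n_up)
    down_idx <- utils::tail(planted, design$n_down)

    # weak probes sit below the fold floor; drawn outside the planted set so
    # planted effects stay measurable by construction
    n_weak <- min(round(design$frac_weak * n), n - n_planted)
    weak <- if (n_weak > 0) sample(setdiff(seq_len(n), planted), n_weak)
            else integer(0)
    if (n_weak > 0)
      baseline[weak] <- exp(stats::runif(n_weak, log(1), log(9)))

    effect <- rep(1, n)
    effect[up_idx] <- design$fold_planted
    effect[down_idx] <- 1 / design$fold_planted

    mean_mat <- outer(baseline, rep(1, length(samples)))
    treated_cols <- which(groups == "treated")
    mean_mat[, treated_cols] <- mean_mat[, treated_cols] * effect

    sigma <- sqrt(log1p(design$noise_cv^2))
    noise <- if (sigma > 0) {
      exp(matrix(stats::rnorm(n * length(samples), -sigma^2 / 2, sigma),
                 n, length(samples)))
    } else {
      matrix(1, n, length(samples))
    }
    signals <- mean_mat * noise
    dimnames(signals) <- list(pids, samples)

    n_ann <- round(design$frac_annotated * n)
    ann_idx <- if (n_ann > 0) sort(sample.int(n, n_ann)) else integer(0)
    symbol <- rep("", n)
    symbol[ann_idx] <- sprintf("GENE%05d", ann_idx)
    annotation <- data.frame(probe_id = pids, symbol = symbol,
                             stringsAsFactors = FALSE)

    truth <- data.frame(
      probe_id = pids[c(up_idx, down_idx)],
      symbol = symbol[c(up_idx, down_idx)],
      direction = rep(c("up", "down"), c(length(up_idx), length(down_idx))),
      fold_planted = rep(design$fold_planted, length(up_idx) + length(down_idx)),
      stringsAsFactors = FALSE)

    list(matrix = signal_matrix(signals, groups),
         annotation = annotation, truth = truth)
  })
}

#' Design of a synthetic compound reference database
#'
#' @param n_instances Total number of compound instances.
#' @param n_mimics Instances whose rankings agree with the target signature
#'   (up-tags toward the top, down-tags toward the bottom).
#' @param n_reversers Instances whose rankings oppose it.
#' @param effect_strength In \[0, 1\]: 1 places planted tags at the exact
#'   extremes of the ranking, 0 makes planted instances indistinguishable
#'   from nulls.
#' @param seed Integer seed.
#' @return A `reference_db_design` list.
#' @export
reference_db_design <- function(n_instances = 100, n_mimics = 0,
                                n_reversers = 0, effect_strength = 1,
                                seed = 1) {
  stopifnot(n_instances >= 1, n_mimics >= 0, n_reversers >= 0)
  if (n_mimics + n_reversers > n_instances)
    stop("invalid design: n_mimics + n_reversers exceeds n_instances",
         call. = FALSE)
  if (effect_strength < 0 || effect_strength > 1)
    stop("invalid design: effect_strength must be in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "reference_db_design")
}

#' Generate a reference database with planted mimics and reversers
#'
#' Each instance is a complete permutation of the probe/gene universe
#' (position 1 = most up-regulated by the compound). Each element gets a
#' latent uniform key and the ranking sorts keys descending; for planted
#' instances the target signature's tag keys are pulled toward the extremes
#' with weight `effect_strength` (reversers pull up-tags to the bottom and
#' down-tags to the top; mimics the opposite). Nulls are uniform random
#' permutations.
#'
#' @param db_design A [reference_db_design()].
#' @param signature A [deg_signature()] (or list with `up`/`down` character
#'   vectors); all tags must be in `universe`.
#' @param universe Character vector of the full probe/gene universe.
#' @return A list with `profiles` (list of `reference_profile`s: fields
#'   `instance_id`, `compound_name`, `ranking`) and `labels` (data frame
#'   `instance_id`, `compound_name`, `type` in mimic/reverser/null).
#' @export
generate_reference_db <- function(db_design, signature, universe) {
  stopifnot(inherits(db_design, "reference_db_design"))
  if (length(universe) == 0) stop("empty probe universe", call. = FALSE)
  if (anyDuplicated(universe)) stop("universe ids must be unique", call. = FALSE)
  up <- signature$up
  down <- signature$down
  missing <- setdiff(c(up, down), universe)
  if (length(missing) > 0)
    stop("signature tags outside the universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)

  with_seed(db_design$seed, {
    n <- length(universe)
    n_inst <- db_design$n_instances
    types <- rep("null", n_inst)
    planted_slots <- if (db_design$n_mimics + db_design$n_reversers > 0)
      sample.int(n_inst, db_design$n_mimics + db_design$n_reversers)
    else integer(0)
    types[utils::head(planted_slots, db_design$n_mimics)] <- "mimic"
    types[utils::tail(planted_slots, db_design$n_reversers)] <- "reverser"

    up_idx <- match(up, universe)
    down_idx <- match(down, universe)
    e <- db_design$effect_strength

    counters <- c(mimic = 0L, reverser = 0L, null = 0L)
    profiles <- vector("list", n_inst)
    names_out <- character(n_inst)
    for (i in seq_len(n_inst)) {
      keys <- stats::runif(n)
      if (types[i] == "reverser") {
        keys[up_idx] <- (1 - e) * keys[up_idx]          # toward bottom
        keys[down_idx] <- (1 - e) * keys[down_idx] + e  # toward top
      } else if (types[i] == "mimic") {
        keys[up_idx] <- (1 - e) * keys[up_idx] + e
        keys[down_idx] <- (1 - e) * keys[down_idx]
      }
      counters[types[i]] <- counters[types[i]] + 1L
      names_out[i] <- sprintf("%s_%02d", types[i], counters[types[i]])
      profiles[[i]] <- structure(
        list(instance_id = sprintf("INST_%03d", i),
             compound_name = names_out[i],
             ranking = universe[order(keys, decreasing = TRUE)]),
        class = "reference_profile")
    }
    labels <- data.frame(
      instance_id = vapply(profiles, `[[`, "", "instance_id"),
      compound_name = names_out, type = types, stringsAsFactors = FALSE)
    list(profiles = profiles, labels = labels)
  })
}

#' Read / write a reference database as TSV
#'
#' One row per instance: `instance_id`, `compound_name`, then the ranked
#' universe left to right (position 1 = most up-regulated). The label
#' sidecar holds the planted-type ground truth.
#'
#' @param db List as returned by [generate_reference_db()].
#' @param path Ranking TSV path.
#' @param labels_path Label sidecar TSV path.
#' @return The path (write) or a db list (read).
#' @export
write_reference_db <- function(db, path, labels_path = NULL) {
  rows <- vapply(db$profiles, function(p)
    paste(c(p$instance_id, p$compound_name, p$ranking), collapse = "\t"), "")
  n <- length(db$profiles[[1]]$ranking)
  header <- paste(c("instance_id", "compound_name",
                    sprintf("rank_%d", seq_len(n))), collapse = "\t")
  writeLines(c(header, rows), path)
  if (!is.null(labels_path))
    utils::write.table(db$labels, labels_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path, labels_path = NULL) {
  lines <- readLines(path)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  profiles <- lapply(fields, function(f) structure(
    list(instance_id = f[1], compound_name = f[2], ranking = f[-(1:2)]),
    class = "reference_profile"))
  labels <- if (!is.null(labels_path))
    utils::read.delim(labels_path, stringsAsFactors = FALSE) else NULL
  list(profiles = profiles, labels = labels)
}
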