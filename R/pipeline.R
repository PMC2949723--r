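#' Build and validate a pipeline run configuration
#'
#' One nested configuration drives the whole chain: synthetic data,
#' normalization, signature extraction, clustering, reference-database
#' generation, and connectivity scoring. Unknown keys are rejected and
#' parameter domains are checked up front.
#'
#' @param seed Global integer seed; per-stage seeds are derived from it by
#'   fixed offsets so each stage is independently reproducible.
#' @param synth Named list overriding [synthetic_design()] arguments
#'   (except `seed`).
#' @param refdb Named list overriding [reference_db_design()] arguments
#'   (except `seed`).
#' @param normalization Named list: `rank_tol`, `n_knots`, `floor_eps`.
#' @param signature Named list: `floor`, `fold_cut`, `p_cut`, `log_scale`.
#' @param connectivity Named list: `n_perm`, `score_cut`, `p_cut`.
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(seed = 1, synth = list(), refdb = list(),
                            normalization = list(), signature = list(),
                            connectivity = list()) {
  defaults <- list(
    synth = list(n_probes = 1000, n_control = 5, n_treated = 6,
                 n_up = 20, n_down = 20, fold_planted = 2, noise_cv = 0.1,
                 frac_annotated = 0.75, frac_weak = 0.05,
                 baseline_range = c(50, 5000)),
    refdb = list(n_instances = 100, n_mimics = 0, n_reversers = 5,
                 effect_strength = 1),
    normalization = list(rank_tol = 0.10, n_knots = 20, floor_eps = 1),
    signature = list(floor = 10, fold_cut = 1.5, p_cut = 0.05,
                     log_scale = TRUE),
    connectivity = list(n_perm = 1999, score_cut = -0.5, p_cut = 0.005))
  merge_section <- function(section, user) {
    unknown <- setdiff(names(user), names(defaults[[section]]))
    if (length(unknown) > 0)
      stop("unknown ", section, " config key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    utils::modifyList(defaults[[section]], user)
  }
  cfg <- list(seed = as.integer(seed),
              synth = merge_section("synth", synth),
              refdb = merge_section("refdb", refdb),
              normalization = merge_section("normalization", normalization),
              signature = merge_section("signature", signature),
              connectivity = merge_section("connectivity", connectivity))
  if (cfg$signature$fold_cut < 1)
    stop("signature fold_cut must be >= 1", call. = FALSE)
  if (cfg$signature$p_cut <= 0 || cfg$signature$p_cut > 1)
    stop("signature p_cut must be in (0, 1]", call. = FALSE)
  if (cfg$connectivity$p_cut <= 0 || cfg$connectivity$p_cut > 1)
    stop("connectivity p_cut must be in (0, 1]", call. = FALSE)
  if (cfg$connectivity$n_perm < 1)
    stop("n_perm must be >= 1", call. = FALSE)
  if (cfg$normalization$rank_tol <= 0 || cfg$normalization$rank_tol > 1)
    stop("rank_tol must be in (0, 1]", call. = FALSE)
  # constructors validate the rest
  do.call(synthetic_design, c(cfg$synth, list(seed = 0L)))
  do.call(reference_db_design, c(cfg$refdb, list(seed = 0L)))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the
#'   [pipeline_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline into an output directory
#'
#' Executes the chain synth -> normalize -> signature (+ clustering) ->
#' reference DB -> connectivity, writing every stage's output as TSV/GMT
#' plus a JSON run manifest with parameters, per-stage seeds, stage counts
#' and md5 hashes of every output file. Reruns with the same config are
#' identical.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress per-stage messages (default FALSE).
#' @return Invisibly, a list with the in-memory stage results:
#'   `expression`, `normalized`, `de`, `signature`, `clustering`, `refdb`,
#'   `connectivity`, `selected`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(out_dir, f)
  seeds <- list(expression = stage_seed(config$seed, "expression"),
                refdb = stage_seed(config$seed, "refdb"),
                permutation = stage_seed(config$seed, "permutation"))

  design <- do.call(synthetic_design,
                    c(config$synth, list(seed = seeds$expression)))
  expr <- generate_expression(design)
  write_signal_matrix(expr$matrix, path("expression.tsv"), path("manifest.tsv"))
  write_annotation(expr$annotation, path("annotation.tsv"))
  utils::write.table(expr$truth, path("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("synth: %d probes x %d samples, %d planted up + %d down",
      nrow(expr$matrix$signals), ncol(expr$matrix$signals),
      design$n_up, design$n_down)

  norm <- normalize_matrix(expr$matrix,
                           rank_tol = config$normalization$rank_tol,
                           n_knots = config$normalization$n_knots,
                           floor_eps = config$normalization$floor_eps)
  write_signal_matrix(norm$matrix, path("normalized.tsv"),
                      path("manifest.tsv"))
  say("normalize: median array %s, stable probes %d-%d per sample",
      norm$median_array, min(norm$n_stable), max(norm$n_stable))

  de <- compute_de(norm$matrix, expr$annotation,
                   floor = config$signature$floor,
                   fold_cut = config$signature$fold_cut,
                   p_cut = config$signature$p_cut,
                   log_scale = config$signature$log_scale)
  utils::write.table(de, path("de_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sig_out <- extract_signature(de, fold_cut = config$signature$fold_cut,
                               p_cut = config$signature$p_cut)
  write_gmt(sig_out$signature, path("signature.gmt"))
  say("signature: %d probes pass filter, %d annotated; %d up + %d down tags",
      sig_out$report$n_pass, sig_out$report$n_pass_annotated,
      sig_out$report$n_up_tags, sig_out$report$n_down_tags)

  clustering <- NULL
  if (sig_out$report$n_pass >= 2) {
    clustering <- cluster_samples(expr$matrix,
                                  de$probe_id[de$passes_filter])
    jsonlite::write_json(
      list(leaf_order = clustering$leaf_order,
           root_split = clustering$root_split,
           merge_heights = clustering$hclust$height),
      path("clustering.json"), auto_unbox = FALSE, digits = NA)
  }

  universe <- expr$annotation$symbol[expr$annotation$symbol != ""]
  db_design <- do.call(reference_db_design,
                       c(config$refdb, list(seed = seeds$refdb)))
  refdb <- generate_reference_db(db_design, sig_out$signature, universe)
  write_reference_db(refdb, path("refdb.tsv"), path("refdb_labels.tsv"))

  conn <- score_reference_db(sig_out$signature, refdb$profiles,
                             n_perm = config$connectivity$n_perm,
                             seed = seeds$permutation,
                             score_cut = config$connectivity$score_cut,
                             p_cut = config$connectivity$p_cut)
  write_connectivity_results(conn, path("connectivity.tsv"))
  selected <- rank_and_select(conn, config$connectivity$score_cut,
                              config$connectivity$p_cut)
  say("connectivity: %d of %d instances selected", nrow(selected), nrow(conn))

  files <- list.files(out_dir, pattern = "\\.(tsv|gmt|json)$")
  files <- setdiff(files, "run_manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("connmap")),
    config = unclass(config), seeds = seeds,
    counts = sig_out$report,
    n_selected = nrow(selected),
    file_md5 = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(expression = expr, normalized = norm, de = de,
                 signature = sig_out, clustering = clustering,
                 refdb = refdb, connectivity = conn, selected = selected,
                 manifest = manifest))
}
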