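#' Construct a signal matrix
#'
#' The basic container of the pipeline: a probe x sample table of
#' non-negative intensities together with a sample -> group assignment.
#' Probes are rows, samples are columns.
#'
#' @param signals Numeric matrix with unique rownames (probe ids) and unique
#'   colnames (sample ids). All values must be finite and non-negative.
#' @param groups Named character vector mapping every sample id to
#'   `"control"` or `"treated"`.
#' @return An object of class `signal_matrix`: a list with elements
#'   `signals` (the matrix) and `groups` (reordered to match the columns).
#' @examples
#' m <- signal_matrix(
#'   matrix(c(100, 200, 110, 190), 2, 2,
#'          dimnames = list(c("p1", "p2"), c("s1", "s2"))),
#'   groups = c(s1 = "control", s2 = "treated")
#' )
#' @export
signal_matrix <- function(signals, groups) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(signals)) || is.null(colnames(signals)))
    stop("`signals` must have probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(signals)))
    stop("probe ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(signals)))
    stop("sample ids must be unique", call. = FALSE)
  if (any(!is.finite(signals)) || any(signals < 0))
    stop("signals must be finite and non-negative", call. = FALSE)
  if (is.null(names(groups)) || !setequal(names(groups), colnames(signals)))
    stop("`groups` must be named by exactly the sample ids", call. = FALSE)
  groups <- groups[colnames(signals)]
  if (!all(groups %in% c("control", "treated")))
    stop("groups must be 'control' or 'treated'", call. = FALSE)
  structure(list(signals = signals, groups = groups), class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "<signal_matrix> %d probes x %d samples (%d control, %d treated)\n",
    nrow(x$signals), ncol(x$signals),
    sum(x$groups == "control"), sum(x$groups == "treated")
  ))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$signals)

probe_ids <- function(m) rownames(m$signals)
sample_ids <- function(m) colnames(m$signals)

#' Extract the sample columns belonging to one group
#'
#' @param m A [signal_matrix()].
#' @param group `"control"` or `"treated"`.
#' @return Numeric matrix of the group's columns.
#' @export
group_columns <- function(m, group = c("control", "treated")) {
  group <- match.arg(group)
  m$signals[, names(m$groups)[m$groups == group], drop = FALSE]
}

#' Read / write signal matrices as TSV
#'
#' The on-disk format is tab-delimited: first column `probe_id`, then one
#' column per sample, with a header row. The group manifest is a separate
#' two-column TSV (`sample_id`, `group`).
#'
#' @param m A [signal_matrix()].
#' @param path Path of the matrix TSV.
#' @param manifest_path Path of the manifest TSV.
#' @return `write_signal_matrix()` returns `path` invisibly;
#'   `read_signal_matrix()` returns a [signal_matrix()].
#' @export
write_signal_matrix <- function(m, path, manifest_path) {
  df <- data.frame(probe_id = probe_ids(m), m$signals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- data.frame(sample_id = sample_ids(m), group = unname(m$groups))
  utils::write.table(mf, manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path, manifest_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sig <- as.matrix(df[, -1, drop = FALSE])
  rownames(sig) <- df[[1]]
  mf <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(mf$group, mf$sample_id)
  signal_matrix(sig, groups)
}

#' Read / write a probe annotation table
#'
#' Two-column TSV (`probe_id`, `symbol`); an empty symbol marks an
#' unannotated probe.
#'
#' @param annotation Data frame with columns `probe_id` and `symbol`.
#' @param path Output path.
#' @return The path (write) or the annotation data frame (read).
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(all(c("probe_id", "symbol") %in% names(annotation)))
  utils::write.table(annotation[, c("probe_id", "symbol")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  df$symbol[is.na(df$symbol)] <- ""
  df
}
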