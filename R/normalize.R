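#' Local background subtraction
#'
#' Subtracts a per-cell background matrix from the signal matrix on the raw
#' intensity scale, clamping at a small positive floor so downstream logs
#' stay finite.
#'
#' @param m A [signal_matrix()] of foreground signals.
#' @param bg A [signal_matrix()] (or plain matrix) of local backgrounds over
#'   the same probe and sample universe.
#' @param floor_eps Positive floor applied after subtraction (default 1).
#' @return A [signal_matrix()] with strictly positive signals.
#' @export
subtract_background <- function(m, bg, floor_eps = 1) {
  stopifnot(inherits(m, "signal_matrix"), floor_eps > 0)
  bgs <- if (inherits(bg, "signal_matrix")) bg$signals else bg
  if (!identical(dim(bgs), dim(m$signals)) ||
      !identical(rownames(bgs), rownames(m$signals)) ||
      !identical(colnames(bgs), colnames(m$signals)))
    stop("background matrix does not match the signal matrix universe",
         call. = FALSE)
  out <- pmax(m$signals - bgs, floor_eps)
  signal_matrix(out, m$groups)
}

#' Select rank-stable probes between two sample columns
#'
#' The normalization curve is trained only on probes whose intensity rank
#' moves by less than `rank_tol` of the probe count between the two samples
#' (ranks ascending, average ranks on ties).
#'
#' @param a,b Numeric intensity vectors over the same probes (same length
#'   and, if named, the same names).
#' @param rank_tol Maximum allowed |rank difference| / n, exclusive
#'   (default 0.10).
#' @return Integer indices (named if the inputs are named) of the stable
#'   probes.
#' @export
select_stable_probes <- function(a, b, rank_tol = 0.10) {
  n <- length(a)
  if (n == 0) stop("empty sample columns", call. = FALSE)
  if (length(b) != n) stop("columns differ in length", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("columns are over different probes", call. = FALSE)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  idx <- which(abs(ra - rb) / n < rank_tol)
  if (!is.null(names(a))) names(idx) <- names(a)[idx]
  idx
}

#' Fit a monotone smoothed piecewise-linear normalization curve
#'
#' Fits, by least squares, a continuous piecewise-linear map from the log
#' intensities of sample `a` to those of reference `ref`, using only the
#' rank-stable probes. Knots are placed at quantiles of log(a) over the
#' stable probes; the fitted knot values are then isotonically adjusted so
#' the curve is monotone non-decreasing. Beyond the outer knots the curve
#' extrapolates linearly with the terminal segment slopes.
#'
#' @param a,ref Strictly positive intensity vectors over the same probes.
#' @param stable Indices (or probe names) of the training probes, as from
#'   [select_stable_probes()].
#' @param n_knots Number of knots (default 20).
#' @return A `normalization_curve`: knot positions `x`, knot values `y` in
#'   log space, and `training_probe_count`.
#' @export
fit_curve <- function(a, ref, stable, n_knots = 20) {
  if (n_knots < 2) stop("n_knots must be >= 2", call. = FALSE)
  if (length(stable) < n_knots)
    stop("too few stable probes (", length(stable), ") for ", n_knots,
         " knots; relax rank_tol", call. = FALSE)
  x <- log(a[stable])
  y <- log(ref[stable])
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("signals must be strictly positive to fit in log space",
         call. = FALSE)
  knots <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_knots),
                                  names = FALSE, type = 7))
  if (length(knots) < 2)
    stop("training intensities are degenerate (fewer than 2 distinct knots)",
         call. = FALSE)
  X <- linear_spline_basis(x, knots)
  fit <- stats::lm.fit(X, y)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  knot_y <- drop(linear_spline_basis(knots, knots) %*% beta)
  iso <- stats::isoreg(knots, knot_y)
  structure(list(x = knots, y = iso$yf,
                 training_probe_count = length(stable)),
            class = "normalization_curve")
}

# Design matrix of a continuous linear spline: intercept, slope, and a
# hinge term per interior knot.
linear_spline_basis <- function(x, knots) {
  interior <- knots[-c(1, length(knots))]
  cbind(1, x, vapply(interior, function(k) pmax(x - k, 0), numeric(length(x))))
}

#' Evaluate a normalization curve in log space
#'
#' @param object A `normalization_curve`.
#' @param newdata Numeric vector of log intensities.
#' @param ... Unused.
#' @return Mapped log intensities (linear interpolation between knots,
#'   linear extrapolation with terminal slopes outside them).
#' @export
predict.normalization_curve <- function(object, newdata, ...) {
  kx <- object$x; ky <- object$y
  out <- stats::approx(kx, ky, xout = newdata, rule = 2)$y
  nk <- length(kx)
  lo_slope <- (ky[2] - ky[1]) / (kx[2] - kx[1])
  hi_slope <- (ky[nk] - ky[nk - 1]) / (kx[nk] - kx[nk - 1])
  below <- newdata < kx[1]
  above <- newdata > kx[nk]
  out[below] <- ky[1] + lo_slope * (newdata[below] - kx[1])
  out[above] <- ky[nk] + hi_slope * (newdata[above] - kx[nk])
  out
}

#' Apply a normalization curve to a sample column
#'
#' @param a Strictly positive intensity vector.
#' @param curve A `normalization_curve` from [fit_curve()].
#' @return Normalized intensities, `exp(curve(log(a)))`; strictly positive.
#' @export
apply_curve <- function(a, curve) {
  if (any(a <= 0)) stop("signals must be strictly positive", call. = FALSE)
  out <- exp(predict(curve, log(a)))
  names(out) <- names(a)
  out
}

#' Select the median control array
#'
#' The median array is the control sample least distant from the other
#' controls, with distance d(a, b) = 1 - Spearman correlation of log
#' signals, summed over the other controls. Ties break by sample order.
#'
#' @param controls A probes x samples matrix of control columns, or a
#'   [signal_matrix()] (its control group is used).
#' @return The selected sample id (column name).
#' @export
select_median_array <- function(controls) {
  if (inherits(controls, "signal_matrix"))
    controls <- group_columns(controls, "control")
  k <- ncol(controls)
  if (is.null(k) || k == 0) stop("no control columns", call. = FALSE)
  if (k == 1) return(colnames(controls))
  rho <- stats::cor(log(controls), method = "spearman")
  dist_sum <- rowSums(1 - rho) - diag(1 - rho)
  colnames(controls)[which.min(dist_sum)]
}

#' Build the computational naive control pool
#'
#' Every control array is normalized against the median control array
#' ([select_median_array()], then [fit_curve()] on its rank-stable probes and
#' [apply_curve()]); the pool is the per-probe arithmetic mean of the
#' normalized controls.
#'
#' @param m A [signal_matrix()] with at least two control samples.
#' @param rank_tol,n_knots Passed to [select_stable_probes()] / [fit_curve()].
#' @return The pooled pseudo-sample: a named numeric vector over the probe
#'   universe, with attributes `median_array` (sample id) and `n_stable`
#'   (named vector of stable-probe counts per control).
#' @export
build_control_pool <- function(m, rank_tol = 0.10, n_knots = 20) {
  controls <- group_columns(m, "control")
  if (ncol(controls) < 2)
    stop("need at least 2 control samples to build a pool", call. = FALSE)
  med_id <- select_median_array(controls)
  med <- controls[, med_id]
  n_stable <- integer(ncol(controls))
  names(n_stable) <- colnames(controls)
  normed <- controls
  for (s in colnames(controls)) {
    stable <- select_stable_probes(controls[, s], med, rank_tol)
    n_stable[s] <- length(stable)
    curve <- fit_curve(controls[, s], med, stable, n_knots)
    normed[, s] <- apply_curve(controls[, s], curve)
  }
  pool <- rowMeans(normed)
  attr(pool, "median_array") <- med_id
  attr(pool, "n_stable") <- n_stable
  pool
}

#' Normalize every sample against the control pool
#'
#' Each sample column (control and treated alike) gets its own curve fitted
#' against the pooled pseudo-sample and is mapped through it. Group labels
#' are preserved.
#'
#' @param m A [signal_matrix()].
#' @param pool Pooled column from [build_control_pool()], over the same
#'   probe universe.
#' @param rank_tol,n_knots Passed to [select_stable_probes()] / [fit_curve()].
#' @return A normalized [signal_matrix()]; attribute `n_stable` records the
#'   stable-probe count used per sample.
#' @export
normalize_to_pool <- function(m, pool, rank_tol = 0.10, n_knots = 20) {
  stopifnot(inherits(m, "signal_matrix"))
  if (length(pool) != nrow(m$signals) ||
      (!is.null(names(pool)) && !identical(names(pool), probe_ids(m))))
    stop("pool does not match the probe universe", call. = FALSE)
  out <- m$signals
  n_stable <- integer(ncol(out))
  names(n_stable) <- colnames(out)
  for (s in colnames(out)) {
    stable <- select_stable_probes(m$signals[, s], pool, rank_tol)
    n_stable[s] <- length(stable)
    curve <- fit_curve(m$signals[, s], pool, stable, n_knots)
    out[, s] <- apply_curve(m$signals[, s], curve)
  }
  res <- signal_matrix(out, m$groups)
  attr(res, "n_stable") <- n_stable
  res
}

#' Full normalization chain
#'
#' Optional local background subtraction, then control-pool construction and
#' per-sample normalization against the pool.
#'
#' @param m A [signal_matrix()] of raw signals.
#' @param background Optional background [signal_matrix()]; when `NULL`
#'   (the default) background subtraction is skipped.
#' @param floor_eps Positive floor used by [subtract_background()].
#' @param rank_tol,n_knots Curve-training parameters.
#' @return A list: `matrix` (normalized [signal_matrix()]), `pool`,
#'   `median_array`, and `n_stable` per sample.
#' @export
normalize_matrix <- function(m, background = NULL, floor_eps = 1,
                             rank_tol = 0.10, n_knots = 20) {
  if (!is.null(background))
    m <- subtract_background(m, background, floor_eps)
  pool <- build_control_pool(m, rank_tol, n_knots)
  normed <- normalize_to_pool(m, pool, rank_tol, n_knots)
  list(matrix = normed, pool = pool,
       median_array = attr(pool, "median_array"),
       n_stable = attr(normed, "n_stable"))
}
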