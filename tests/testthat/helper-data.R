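# Small hand-buildable fixtures used across test files.

toy_matrix <- function(signals, n_control, n_treated) {
  n <- nrow(signals)
  samples <- c(sprintf("c%d", seq_len(n_control)),
               sprintf("t%d", seq_len(n_treated)))
  colnames(signals) <- samples
  if (is.null(rownames(signals)))
    rownames(signals) <- sprintf("p%d", seq_len(n))
  signal_matrix(signals, stats::setNames(
    rep(c("control", "treated"), c(n_control, n_treated)), samples))
}

# Two-group matrix with a clean separation on `n_de` probes (half planted
# up, half down so the probe patterns are not all collinear), for clustering.
separated_matrix <- function(n_probes = 50, n_de = 10, n_control = 3,
                             n_treated = 3, fold = 4, noise_sd = 0.05,
                             seed = 42) {
  set.seed(seed)
  base <- exp(runif(n_probes, log(100), log(1000)))
  sig <- matrix(base, n_probes, n_control + n_treated)
  trt <- n_control + seq_len(n_treated)
  up <- seq_len(ceiling(n_de / 2))
  down <- setdiff(seq_len(n_de), up)
  sig[up, trt] <- sig[up, trt] * fold
  sig[down, trt] <- sig[down, trt] / fold
  sig <- sig * exp(matrix(rnorm(length(sig), 0, noise_sd), nrow(sig)))
  toy_matrix(sig, n_control, n_treated)
}
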