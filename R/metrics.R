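#' Windowed mean firing rates
#'
#' Per-neuron mean firing rate (Hz) of one population over an analysis
#' window.  With `window_ms = NULL` the rates computed over the
#' simulation's own analysis window are returned; an explicit window
#' requires a recorded raster (`record_raster = TRUE`) and must be longer
#' than the refractory period.  Graded populations (OSN, PG) report their
#' mean transfer output instead of a rate.
#'
#' @param sim an [run_simulation()] result.
#' @param population one of `"mi"`, `"gr"`, `"ff"`, `"pyr"`, `"fb"`,
#'   `"osn"`, `"pg"`.
#' @param window_ms optional `c(start, end)` in ms.
#' @return Numeric vector, one value per neuron.
#' @export
mean_rates <- function(sim, population, window_ms = NULL) {
  stopifnot(inherits(sim, "obpc_sim"))
  population <- match.arg(population, names(sim$rates))
  if (is.null(window_ms)) return(sim$rates[[population]])
  if (population %in% c("osn", "pg")) {
    stop("explicit windows are only supported for spiking populations")
  }
  if (is.null(sim$raster)) {
    stop("explicit windows require a simulation run with record_raster = TRUE")
  }
  len <- diff(window_ms)
  if (length(window_ms) != 2 || len <= 0) stop("empty analysis window")
  if (len <= 2) {
    stop("window (", len, " ms) is not longer than the refractory period")
  }
  if (window_ms[2] > sim$duration_ms) {
    stop("window exceeds the simulated duration")
  }
  r <- sim$raster[[population]]
  keep <- r$time_ms >= window_ms[1] & r$time_ms < window_ms[2]
  counts <- tabulate(r$neuron[keep], nbins = length(sim$rates[[population]]))
  counts / (len / 1000)
}

#' Baseline-calibrated odor detection index
#'
#' Quantifies how far an odor-evoked population rate vector lies from
#' spontaneous activity, in units of the spontaneous variability: the
#' baseline is the set of pairwise Euclidean distances among independent
#' spontaneous runs, and the index is
#' `(evoked_distance - baseline_mean) / (2 * baseline_sd)`.
#' An index above 1 (evoked distance more than two baseline standard
#' deviations above the baseline mean) is considered detectable.
#'
#' @param spont_runs list of >= 2 spontaneous rate vectors (the baseline).
#' @param evoked the odor-evoked rate vector.
#' @param spont_ref the spontaneous reference vector that `evoked` is
#'   compared against (default: an extra run should be supplied; falls
#'   back to the first baseline run).
#' @return An object of class `detection_report`: `baseline_mean`,
#'   `baseline_sd`, `evoked_distance`, `index`, `detectable`.
#' @export
detection_index <- function(spont_runs, evoked,
                            spont_ref = spont_runs[[1]]) {
  if (!is.list(spont_runs) || length(spont_runs) < 2) {
    stop("need at least 2 spontaneous runs to form baseline pairs")
  }
  pairs <- utils::combn(length(spont_runs), 2)
  d <- apply(pairs, 2, function(ij) {
    euclidean_distance(spont_runs[[ij[1]]], spont_runs[[ij[2]]])
  })
  m <- mean(d)
  s <- stats::sd(d)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate baseline: sd of ", length(d),
         " pairwise distances is ", s)
  }
  ed <- euclidean_distance(evoked, spont_ref)
  idx <- (ed - m) / (2 * s)
  structure(list(baseline_mean = m, baseline_sd = s, evoked_distance = ed,
                 index = idx, detectable = idx > 1,
                 n_pairs = length(d)),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> index = %.3f (%s)\n  baseline %.3f +/- %.3f (%d pairs), evoked distance %.3f\n",
    x$index, if (x$detectable) "detectable" else "not detectable",
    x$baseline_mean, x$baseline_sd, x$n_pairs, x$evoked_distance))
  invisible(x)
}

#' Lifetime sparseness of a non-negative vector
#'
#' Treves-Rolls-style sparseness of a weight (or rate) distribution:
#' `S = (1 - (sum(w)/N)^2 / (sum(w^2)/N)) / (1 - 1/N)`.
#' `S = 0` for a uniform distribution and `S = 1` when a single element
#' carries all the weight; scale-invariant.
#'
#' @param w non-negative numeric vector, length >= 2, not all zero.
#' @return Sparseness in \[0, 1\].
#' @examples
#' sparseness(rep(1, 100)) # 0
#' sparseness(c(1, rep(0, 99))) # 1
#' @export
sparseness <- function(w) {
  n <- length(w)
  if (n < 2) stop("sparseness needs at least 2 values")
  if (any(w < 0)) stop("sparseness is defined for non-negative values")
  s2 <- sum(w^2)
  if (s2 == 0) stop("sparseness undefined for an all-zero vector")
  (1 - (sum(w) / n)^2 / (s2 / n)) / (1 - 1 / n)
}

#' Paired condition comparison with Bonferroni correction
#'
#' Thin wrapper over [stats::wilcox.test()] (signed-rank, paired) and
#' [stats::t.test()] that reports the raw and Bonferroni-corrected p-value
#' (`min(1, p * n_comparisons)`).
#'
#' @param samples_a,samples_b numeric sample vectors (paired unless
#'   `paired = FALSE`).
#' @param test `"wilcoxon"` or `"ttest"`.
#' @param n_comparisons number of comparisons in the family, >= 1.
#' @param paired logical.
#' @param alternative passed through to the test.
#' @return List with `statistic`, `p_value`, `p_corrected`, `test`,
#'   `n_comparisons`.
#' @export
compare_conditions <- function(samples_a, samples_b,
                               test = c("wilcoxon", "ttest"),
                               n_comparisons = 1, paired = TRUE,
                               alternative = "two.sided") {
  test <- match.arg(test)
  stopifnot(n_comparisons >= 1)
  if (paired && length(samples_a) != length(samples_b)) {
    stop("paired comparison requires equal sample sizes")
  }
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("need at least 2 observations per condition")
  }
  ht <- if (test == "wilcoxon") {
    if (paired && all(samples_a == samples_b)) {
      # all differences zero: the signed-rank statistic is degenerate and
      # cannot reject
      list(statistic = c(V = 0), p.value = 1)
    } else {
      suppressWarnings(stats::wilcox.test(samples_a, samples_b,
                                          paired = paired, exact = FALSE,
                                          alternative = alternative))
    }
  } else {
    stats::t.test(samples_a, samples_b, paired = paired,
                  alternative = alternative)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       p_corrected = min(1, ht$p.value * n_comparisons),
       test = test, n_comparisons = n_comparisons)
}
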