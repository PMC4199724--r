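#' Summarise a collection of search results
#'
#' Computes the moments of the rescaled computational cost across replicate
#' searches, the std-to-mean ratio (equal to 1 for an exponential
#' distribution), and the maximum-likelihood exponential rate (`1/mean` for
#' the exponential family).  Capped runs are excluded from the moments and
#' reported separately; at realistic parameter settings the cap is
#' effectively never reached.
#'
#' @param results list of [run_search()] results (sharing parameters).
#' @return an object of class `summary_stats`: list with `n_runs`,
#'   `n_used`, `capped_runs`, `mean_rescaled`, `std_rescaled`,
#'   `ratio_std_mean`, `exp_rate`, `sem_rescaled`.
#' @export
summarize_runs <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  capped <- vapply(results, function(r) isTRUE(r$capped), logical(1L))
  if (all(capped)) stop("all runs were capped; nothing to summarise")
  x <- vapply(results[!capped], function(r) r$rescaled_cost, numeric(1L))
  if (length(x) < 2L) stop("fewer than 2 uncapped runs")
  m <- mean(x); s <- stats::sd(x)
  structure(list(
    n_runs = length(results),
    n_used = length(x),
    capped_runs = sum(capped),
    mean_rescaled = m,
    std_rescaled = s,
    ratio_std_mean = s / m,
    exp_rate = 1 / m,
    sem_rescaled = s / sqrt(length(x))
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "summary_stats over %d runs (%d capped): mean=%.4g sd=%.4g sd/mean=%.3f rate=%.3g sem=%.2g\n",
    x$n_runs, x$capped_runs, x$mean_rescaled, x$std_rescaled,
    x$ratio_std_mean, x$exp_rate, x$sem_rescaled))
  invisible(x)
}

# shared histogram builder: probability sums to 1; density = prob / width
.hist_table <- function(values, breaks, log_bins) {
  if (log_bins) {
    v <- values[values > 0]
    h <- graphics::hist(log10(v), breaks = breaks, plot = FALSE)
    left <- 10^h$breaks[-length(h$breaks)]
    right <- 10^h$breaks[-1L]
  } else {
    h <- graphics::hist(values, breaks = breaks, plot = FALSE)
    left <- h$breaks[-length(h$breaks)]
    right <- h$breaks[-1L]
  }
  prob <- h$counts / sum(h$counts)
  data.frame(bin_left = left, bin_right = right, probability = prob,
             density = prob / (right - left))
}

#' Histogram of rescaled computational costs
#'
#' @inheritParams summarize_runs
#' @param breaks passed to [graphics::hist()] (count or break vector).
#' @param log_bins bin on a log10 scale (the cost distributions span
#'   decades); fits should nevertheless use raw per-run values except for
#'   the large-cost tail fit, which operates on the histogram itself.
#' @return data.frame with `bin_left`, `bin_right`, `probability` (sums to
#'   1) and `density` (probability / bin width).
#' @export
cost_histogram <- function(results, breaks = 30, log_bins = FALSE) {
  capped <- vapply(results, function(r) isTRUE(r$capped), logical(1L))
  x <- vapply(results[!capped], function(r) r$rescaled_cost, numeric(1L))
  .hist_table(x, breaks, log_bins)
}

#' Distribution of the stasis statistic M
#'
#' Each search contributes a single value of `M`, the mean number of
#' consecutive trials the population's minimal cost persists before a
#' change event.  In the low-cost cooperative regime the distribution is
#' peaked at a few trials (no string leads long enough to drag the whole
#' system to it); in the high-cost regime (too many agents) it develops a
#' plateau at hundreds to thousands of trials — the signature of following
#' a bad leader.
#'
#' @inheritParams cost_histogram
#' @return data.frame as in [cost_histogram()], over `stasis_M` values.
#' @export
stasis_distribution <- function(results, breaks = 30, log_bins = FALSE) {
  m <- vapply(results, function(r) r$stasis_M, numeric(1L))
  .hist_table(m, breaks, log_bins)
}

#' Exponential tail fit of a cost histogram
#'
#' Least-squares line fit of log density against bin midpoint for bins
#' above `threshold`, giving the parameters of an exponential tail
#' `density = amplitude * exp(-rate * x)`.  Using the density (not the raw
#' bin probability) makes the fitted parameters invariant to the binning.
#'
#' @param histogram a [cost_histogram()] data.frame.
#' @param threshold lower cutoff (on rescaled cost) for the fitted regime.
#' @return named numeric vector `c(amplitude, rate)`.
#' @export
tail_fit <- function(histogram, threshold) {
  mid <- (histogram$bin_left + histogram$bin_right) / 2
  sel <- mid > threshold & histogram$density > 0
  if (sum(sel) < 5L)
    stop("insufficient tail mass: need >= 5 non-empty bins above threshold")
  fit <- stats::lm(log(histogram$density[sel]) ~ mid[sel])
  cf <- stats::coef(fit)
  c(amplitude = exp(unname(cf[1L])), rate = -unname(cf[2L]))
}
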