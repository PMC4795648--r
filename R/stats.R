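# Resampling and nonparametric inference: the neuron-level paired
# bootstrap and the Wilcoxon signed-rank test.

#' Paired bootstrap over model neurons
#'
#' In each resample the neuron population is resampled uniformly with
#' replacement (or, when `subsample` is smaller than `n_neurons`, a random
#' subset of that size is drawn without replacement, as when compensating
#' for the larger coverage of big templates) and `stat_fn` evaluates the
#' paired experimental statistic on that one subset, so both conditions
#' always see the same neurons.  The p-value is the proportion of
#' resamples for which the test statistic is true under the null
#' hypothesis (directional: `statistic <= null_value`); the SEM is the
#' standard deviation of the resample statistics.
#'
#' @param stat_fn Function of a neuron-index vector returning the paired
#'   statistic: a scalar or a fixed-length named numeric vector.
#' @param n_neurons Size of the neuron population.
#' @param n_resamples Number of bootstrap resamples.
#' @param subsample If a number less than `n_neurons`, each resample uses
#'   a subset of that size drawn without replacement; otherwise resamples
#'   are drawn with replacement at full size.
#' @param seed Integer seed; the resample sequence is deterministic.
#' @param null_value Null boundary for the directional p-value.
#' @return A `boot_result`: `$draws` (n_resamples x n_stats matrix),
#'   `$estimate` (statistic on the full population), `$sem`, `$p_value`
#'   (per statistic), `$n_resamples`, `$seed`.
#' @export
paired_neuron_bootstrap <- function(stat_fn, n_neurons, n_resamples = 1000L,
                                    subsample = NULL, seed = 1L,
                                    null_value = 0) {
  stopifnot(n_resamples >= 1, n_neurons >= 1)
  est <- stat_fn(seq_len(n_neurons))
  draws <- with_local_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- if (!is.null(subsample) && subsample < n_neurons)
        sample.int(n_neurons, subsample, replace = FALSE)
      else sample.int(n_neurons, n_neurons, replace = TRUE)
      out <- tryCatch(stat_fn(idx), error = function(e)
        stop("stat_fn failed in resample ", b, ": ", conditionMessage(e)))
      as.numeric(out)
    }, numeric(length(est)))
  })
  draws <- if (length(est) == 1L) matrix(draws, ncol = 1L) else t(draws)
  colnames(draws) <- names(est)
  structure(list(draws = draws, estimate = est,
                 sem = apply(draws, 2, stats::sd),
                 p_value = colMeans(draws <= null_value),
                 n_resamples = as.integer(n_resamples),
                 subsample = subsample, seed = as.integer(seed)),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("<bootstrap> B = %d%s\n", x$n_resamples,
              if (!is.null(x$subsample)) paste0(", subsample = ", x$subsample) else ""))
  print(tibble::tibble(statistic = names(x$estimate) %||% "stat",
                       estimate = unname(x$estimate), sem = unname(x$sem),
                       p_value = unname(x$p_value)))
  invisible(x)
}

#' Wilcoxon signed-rank test
#'
#' Zeros are dropped, ties get mid-ranks.  For 15 or fewer nonzero
#' differences the p-value is computed by exact enumeration of all sign
#' assignments (valid under ties); otherwise by normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param diffs Paired differences.
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   shift).
#' @param exact_max Largest n for exact enumeration.
#' @return List: `statistic` (V, the positive-rank sum), `p_value`, `n`
#'   (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(diffs, alternative = c("two.sided", "greater"),
                                 exact_max = 15L) {
  alternative <- match.arg(alternative)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) stop("no signal: all differences are zero")
  if (n < 5) stop("fewer than 5 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of V over all 2^n equiprobable sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- drop(signs %*% r)
    p_ge <- mean(Vs >= V)
    p_le <- mean(Vs <= V)
    p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
    else 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method,
       alternative = alternative)
}
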