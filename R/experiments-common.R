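# Shared infrastructure for the three psychophysics simulations.

# C2 responses for a list of stimuli: one matrix (n_stimuli x n_templates)
# per size class.
c2_for_stimuli <- function(stims, bank, sizes, config) {
  rows <- lapply(stims, function(s) c2_responses(s, bank, sizes = sizes,
                                                 config = config))
  out <- lapply(sizes, function(sz)
    do.call(rbind, lapply(rows, function(r) r[[sz]])))
  names(out) <- sizes
  out
}

# Decision threshold giving a hit-rate as close as possible to `target`:
# candidates are midpoints between consecutive sorted dissimilarities plus
# both extremes; ties resolved toward the lower threshold.
calibrate_threshold <- function(d, target = 0.75) {
  u <- sort(unique(d))
  span <- max(u[length(u)] - u[1], u[1], 1e-9)
  cand <- c(u[1] - 0.5 * span,
            if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 0.5 * span)
  hr <- vapply(cand, function(th) mean(d < th), numeric(1))
  i <- which.min(abs(hr - target)) # which.min takes the first = lowest
  list(threshold = cand[i], hit_rate = hr[i])
}

new_holo_result <- function(class, summary, effects, comparisons, trials, meta) {
  structure(list(summary = summary, effects = effects,
                 comparisons = comparisons, trials = trials, meta = meta),
            class = c(class, "holo_result"))
}

#' @export
print.holo_result <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$meta$label, "\n", sep = "")
  print(x$summary)
  cat("Effect sizes:\n"); print(x$effects)
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("Comparisons:\n"); print(x$comparisons)
  }
  invisible(x)
}
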