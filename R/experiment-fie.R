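# Face inversion effect: behavioral (pairwise C2 dissimilarities) and
# neural (per-neuron response drop) levels.

# upright + inverted C2 matrices for a face set, all requested sizes
fie_c2 <- function(bank, faces, sizes, config) {
  list(upright = c2_for_stimuli(faces, bank, sizes, config),
       inverted = c2_for_stimuli(lapply(faces, invert_stimulus),
                                 bank, sizes, config))
}

#' Behavioral face inversion effect
#'
#' Mean C2 dissimilarity over all face pairs (n choose 2; 1225 pairs for
#' the standard 50 test faces), for upright and for inverted
#' presentations; the behavioral effect size is upright minus inverted
#' mean dissimilarity per tuning size.  Bootstrap runs use a random
#' neuron subset per resample (100 for large, 150 for medium, all 1000
#' for small) to compensate for the larger coverage of big templates;
#' cross-size p-values are the proportion of resamples in which the
#' larger tuning size's effect does not exceed the smaller one's.
#'
#' @inheritParams run_cfe
#' @param sizes Tuning size classes (order defines the expected
#'   decreasing-effect ordering for comparisons).
#' @param subsample Named per-size neuron subset size per bootstrap run
#'   (values >= bank size mean with-replacement resampling of the full
#'   population).
#' @param c2 Optional precomputed output of the internal upright+inverted
#'   extraction (reused by [run_fie_neural()]).
#' @return A `fie_result` with per-size condition means, effect sizes,
#'   bootstrap SEMs and p-values, and ordered pairwise comparisons.
#' @export
run_fie_behavioral <- function(bank, faces,
                               sizes = c("large", "medium", "small"),
                               subsample = c(large = 100L, medium = 150L,
                                             small = 1000L),
                               n_resamples = 1000L, seed = 1L,
                               config = bank$config, c2 = NULL) {
  stopifnot(length(faces) >= 2)
  if (is.null(c2)) c2 <- fie_c2(bank, faces, sizes, config)
  n <- length(faces)
  pairs <- utils::combn(n, 2)
  n_neuron <- nrow(bank$meta)

  sq <- lapply(c("upright", "inverted"), function(cond) {
    lapply(sizes, function(sz) {
      M <- c2[[cond]][[sz]]
      (M[pairs[1, ], , drop = FALSE] - M[pairs[2, ], , drop = FALSE])^2
    }) |> stats::setNames(sizes)
  }) |> stats::setNames(c("upright", "inverted"))

  cond_means <- function(sz, idx) {
    up <- mean(sqrt(rowSums(sq$upright[[sz]][, idx, drop = FALSE])))
    inv <- mean(sqrt(rowSums(sq$inverted[[sz]][, idx, drop = FALSE])))
    c(upright = up, inverted = inv, effect = up - inv)
  }

  boots <- lapply(sizes, function(sz) {
    k <- subsample[[sz]] %||% n_neuron
    paired_neuron_bootstrap(function(idx) cond_means(sz, idx),
                            n_neurons = n_neuron, n_resamples = n_resamples,
                            subsample = if (k < n_neuron) k else NULL,
                            seed = seed)
  })
  names(boots) <- sizes

  full <- lapply(sizes, function(sz) cond_means(sz, seq_len(n_neuron)))
  names(full) <- sizes
  summary <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, condition = c("upright", "inverted"),
    mean_dissimilarity = unname(full[[sz]][1:2]),
    sem = unname(boots[[sz]]$sem[1:2]))))
  effects <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, effect = unname(full[[sz]]["effect"]),
    sem = unname(boots[[sz]]$sem["effect"]),
    p_boot = unname(boots[[sz]]$p_value["effect"]))))
  comparisons <- if (length(sizes) >= 2) {
    prs <- utils::combn(seq_along(sizes), 2)
    dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(i) {
      a <- sizes[prs[1, i]]; b <- sizes[prs[2, i]]
      tibble::tibble(comparison = paste0(a, ">", b),
                     p = mean(boots[[a]]$draws[, "effect"] <=
                                boots[[b]]$draws[, "effect"]))
    }))
  } else tibble::tibble()
  new_holo_result("fie_result", summary, effects, comparisons,
                  trials = tibble::tibble(n_pairs = ncol(pairs)),
                  meta = list(label = "face inversion effect (behavioral)",
                              n_faces = n, n_pairs = ncol(pairs),
                              n_resamples = n_resamples, seed = seed,
                              subsample = as.list(subsample),
                              n_neurons = n_neuron))
}

#' Neural face inversion effect
#'
#' Only C2 neurons whose mean response to upright faces falls inside a
#' response band (default 0.75 to 0.80) are considered, after which
#' neurons are randomly dropped so every tuning size uses the same number
#' — controlling for the different mean response levels of the three
#' tuning sizes and avoiding ceiling and floor effects.  The neural
#' effect is the per-face drop (upright minus inverted) of the mean
#' selected-neuron response; within-size and cross-size significance use
#' Wilcoxon signed-rank tests over faces.
#'
#' With synthetic faces the fixed band can be empty for some size class
#' (small-template responses have a high floor); `band = NULL` then
#' selects the narrowest band of width `band_width` that contains at
#' least `n_min` neurons of every size class.
#'
#' @inheritParams run_fie_behavioral
#' @param band Numeric `c(lo, hi)` response band, or `NULL` for the
#'   automatic band described above.
#' @param band_width,n_min Width and minimum per-size neuron count of the
#'   automatic band.
#' @return A `fie_result` with per-size mean responses, per-face effect
#'   sizes, and Wilcoxon p-values.
#' @export
run_fie_neural <- function(bank, faces,
                           sizes = c("large", "medium", "small"),
                           band = c(0.75, 0.80), band_width = 0.05,
                           n_min = 5L, seed = 1L, config = bank$config,
                           c2 = NULL) {
  if (is.null(c2)) c2 <- fie_c2(bank, faces, sizes, config)
  mu <- lapply(sizes, function(sz) colMeans(c2$upright[[sz]]))
  names(mu) <- sizes
  if (is.null(band)) {
    # narrowest band (starting at band_width, widening if needed) that
    # holds at least n_min neurons of every size class
    w <- band_width
    repeat {
      centres <- seq(w / 2, 1 - w / 2, by = 0.005)
      counts <- vapply(centres, function(m) {
        min(vapply(mu, function(v)
          sum(v >= m - w / 2 & v <= m + w / 2), 1L))
      }, numeric(1))
      if (max(counts) >= n_min) break
      w <- w * 1.5
      if (w > 1)
        stop("no response band holds ", n_min, " neurons of every size ",
             "class; per-size response quartiles:\n",
             paste(vapply(sizes, function(sz) paste(sz, ":",
               paste(round(stats::quantile(mu[[sz]]), 3), collapse = " ")),
               character(1)), collapse = "\n"))
    }
    m <- centres[which.max(counts)]
    band <- c(m - w / 2, m + w / 2)
  }
  sel <- lapply(sizes, function(sz) which(mu[[sz]] >= band[1] & mu[[sz]] <= band[2]))
  names(sel) <- sizes
  n_sel <- min(lengths(sel))
  if (n_sel < 1) {
    stop("response band [", band[1], ", ", band[2], "] is empty for size ",
         "class '", sizes[which.min(lengths(sel))], "'; per-size response ",
         "quartiles:\n",
         paste(vapply(sizes, function(sz) paste(sz, ":",
           paste(round(stats::quantile(mu[[sz]]), 3), collapse = " ")),
           character(1)), collapse = "\n"),
         "\nConsider band = NULL (automatic band) or higher-contrast faces.")
  }
  sel <- with_local_seed(seed, lapply(sel, function(s)
    if (length(s) > n_sel) sort(sample(s, n_sel)) else s))

  per_face <- lapply(sizes, function(sz) {
    up <- rowMeans(c2$upright[[sz]][, sel[[sz]], drop = FALSE])
    inv <- rowMeans(c2$inverted[[sz]][, sel[[sz]], drop = FALSE])
    tibble::tibble(face = seq_along(up), upright = up, inverted = inv,
                   effect = up - inv, size_class = sz)
  })
  names(per_face) <- sizes

  nf <- nrow(per_face[[1]])
  summary <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, condition = c("upright", "inverted"),
    mean_response = c(mean(per_face[[sz]]$upright),
                      mean(per_face[[sz]]$inverted)),
    sem = c(stats::sd(per_face[[sz]]$upright),
            stats::sd(per_face[[sz]]$inverted)) / sqrt(nf))))
  effects <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, effect = mean(per_face[[sz]]$effect),
    sem = stats::sd(per_face[[sz]]$effect) / sqrt(nf),
    p_wilcoxon = wilcoxon_signed_rank(per_face[[sz]]$effect,
                                      alternative = "greater")$p_value)))
  comparisons <- if (length(sizes) >= 2) {
    prs <- utils::combn(seq_along(sizes), 2)
    dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(i) {
      a <- sizes[prs[1, i]]; b <- sizes[prs[2, i]]
      d <- per_face[[a]]$effect - per_face[[b]]$effect
      tibble::tibble(comparison = paste0(a, ">", b),
                     p = wilcoxon_signed_rank(d, alternative = "greater")$p_value)
    }))
  } else tibble::tibble()
  new_holo_result("fie_result", summary, effects, comparisons,
                  trials = dplyr::bind_rows(per_face),
                  meta = list(label = "face inversion effect (neural)",
                              n_faces = nf, band = band,
                              n_selected = n_sel, seed = seed,
                              n_neurons = nrow(bank$meta)))
}
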