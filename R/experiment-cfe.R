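#' Composite face effect simulation
#'
#' Same-trials only: two composites share an identical top half and carry
#' different bottom halves, presented aligned or misaligned (bottom half
#' shifted by half the face width).  Observers attending the top are
#' simulated by multiplying bottom-half pixels by 0.1 and recentring the
#' image on the top half.  Two composites are judged "same" when the
#' Euclidean distance between their C2 response vectors falls below a
#' threshold calibrated, per tuning size, so the aligned hit-rate is as
#' close to 75% as possible.  The composite effect is the misaligned
#' minus aligned hit-rate; its p-value is the proportion of neuron
#' bootstrap resamples (threshold recalibrated within each resample) in
#' which the misaligned hit-rate does not exceed the aligned one.  A
#' per-neuron variant treats every C2 neuron as a 1-D classifier with its
#' own calibrated threshold and tests the per-neuron effects with a
#' Wilcoxon signed-rank test.
#'
#' @param bank A [learn_bank()] template bank.
#' @param faces Named list of upright rendered test faces (20 identities
#'   in the standard design).
#' @param sizes Tuning size classes to run (first is used as reference in
#'   cross-size comparisons).
#' @param max_trials Cap on the number of same-trials; the full
#'   enumeration of (top, bottom-pair) combinations is subsampled
#'   uniformly (seeded) beyond it.
#' @param n_resamples Bootstrap resamples.
#' @param seed Experiment seed (trial subsampling and bootstrap).
#' @param stim_config A [stim_config()] for the composite construction.
#' @param config Model configuration (defaults to the bank's).
#' @return A `cfe_result` with per-condition hit-rates, effect sizes,
#'   bootstrap SEMs/p-values, per-neuron Wilcoxon p, calibrated
#'   thresholds and the trial table.
#' @export
run_cfe <- function(bank, faces, sizes = c("large", "small"),
                    max_trials = 60L, n_resamples = 1000L, seed = 1L,
                    stim_config = holoface::stim_config(),
                    config = bank$config) {
  stopifnot(length(faces) >= 3)
  n <- length(faces)
  ids <- names(faces) %||% as.character(seq_len(n))

  # Same-trials: top t with two different bottoms b1 < b2.  The full
  # enumeration (n * choose(n-1, 2) triples) is subsampled in a
  # stratified way: every top contributes a small random set of bottoms
  # and all bottom pairs within it, which balances tops and maximizes
  # stimulus reuse across trials.
  trials <- with_local_seed(seed, {
    per_top <- ceiling(max_trials / n)
    b_per_top <- max(2L, ceiling((1 + sqrt(1 + 8 * per_top)) / 2))
    out <- do.call(rbind, lapply(seq_len(n), function(t) {
      bots <- sample(setdiff(seq_len(n), t), min(b_per_top, n - 1L))
      prs <- utils::combn(sort(bots), 2)
      cbind(top = t, b1 = prs[1, ], b2 = prs[2, ])
    }))
    if (nrow(out) > max_trials)
      out <- out[sort(sample.int(nrow(out), max_trials)), , drop = FALSE]
    out
  })
  nt <- nrow(trials)

  # composite stimuli needed, per alignment
  att_region <- top_half_box(stim_config)
  pair_key <- unique(rbind(trials[, c("top", "b1")], trials[, c("top", "b2")]))
  make_weighted <- function(t, b, aligned) {
    comp <- make_composite(faces[[t]], faces[[b]], aligned = aligned,
                           config = stim_config)
    apply_attention(comp, att_region, stim_config$attention_cfe,
                    recenter = TRUE)
  }

  sq <- list() # per alignment, per size: n_trials x n_templates squared diffs
  for (al in c("aligned", "misaligned")) {
    stims <- lapply(seq_len(nrow(pair_key)), function(i)
      make_weighted(pair_key[i, 1], pair_key[i, 2], al == "aligned"))
    c2 <- c2_for_stimuli(stims, bank, sizes, config)
    row_of <- function(t, b) which(pair_key[, 1] == t & pair_key[, 2] == b)
    i1 <- vapply(seq_len(nt), function(i) row_of(trials[i, 1], trials[i, 2]), 1L)
    i2 <- vapply(seq_len(nt), function(i) row_of(trials[i, 1], trials[i, 3]), 1L)
    sq[[al]] <- lapply(c2, function(M) (M[i1, , drop = FALSE] - M[i2, , drop = FALSE])^2)
  }

  hit_rates <- function(sz, idx) {
    dal <- sqrt(rowSums(sq$aligned[[sz]][, idx, drop = FALSE]))
    dmi <- sqrt(rowSums(sq$misaligned[[sz]][, idx, drop = FALSE]))
    cal <- calibrate_threshold(dal)
    c(aligned = cal$hit_rate, misaligned = mean(dmi < cal$threshold),
      effect = mean(dmi < cal$threshold) - cal$hit_rate,
      threshold = cal$threshold)
  }

  n_neuron <- nrow(bank$meta)
  boots <- lapply(sizes, function(sz)
    paired_neuron_bootstrap(function(idx) hit_rates(sz, idx)[1:3],
                            n_neurons = n_neuron, n_resamples = n_resamples,
                            seed = seed))
  names(boots) <- sizes

  # per-neuron 1-D classifiers (each C2 neuron by itself)
  neuron_effect <- function(sz) {
    dal <- sqrt(sq$aligned[[sz]]); dmi <- sqrt(sq$misaligned[[sz]])
    vapply(seq_len(n_neuron), function(j) {
      cal <- calibrate_threshold(dal[, j])
      mean(dmi[, j] < cal$threshold) - cal$hit_rate
    }, numeric(1))
  }
  neuron_p <- vapply(sizes, function(sz) {
    ef <- neuron_effect(sz)
    if (all(ef == 0)) NA_real_
    else wilcoxon_signed_rank(ef, alternative = "greater")$p_value
  }, numeric(1))

  full <- lapply(sizes, function(sz) hit_rates(sz, seq_len(n_neuron)))
  names(full) <- sizes
  summary <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, condition = c("aligned", "misaligned"),
    hit_rate = unname(full[[sz]][1:2]),
    sem = unname(boots[[sz]]$sem[1:2]))))
  effects <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, effect = unname(full[[sz]]["effect"]),
    sem = unname(boots[[sz]]$sem["effect"]),
    p_boot = unname(boots[[sz]]$p_value["effect"]),
    p_neuron_wilcoxon = unname(neuron_p[sz]),
    threshold = unname(full[[sz]]["threshold"]))))
  comparisons <- if (length(sizes) >= 2) {
    ref <- sizes[1]
    dplyr::bind_rows(lapply(sizes[-1], function(sz) tibble::tibble(
      comparison = paste0(ref, ">", sz),
      p = mean(boots[[ref]]$draws[, "effect"] <= boots[[sz]]$draws[, "effect"]))))
  } else tibble::tibble()
  trial_tbl <- tibble::tibble(trial = seq_len(nt),
                              top = ids[trials[, 1]],
                              bottom_1 = ids[trials[, 2]],
                              bottom_2 = ids[trials[, 3]])
  new_holo_result("cfe_result", summary, effects, comparisons, trial_tbl,
                  meta = list(label = "composite face effect",
                              n_faces = n, n_trials = nt,
                              n_resamples = n_resamples, seed = seed,
                              n_neurons = n_neuron))
}
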