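#' Whole-part effect simulation
#'
#' Stimuli blend the eye region of one face with the rest of a different
#' face.  Each trial is an ordered triple of distinct identities (first
#' eye donor a, second eye donor b, rest-of-face c): the study face is
#' the un-weighted whole blend (eyes a, rest c); the two test choices —
#' matched to the study face by smaller C2 Euclidean distance — carry
#' eyes a (correct) or eyes b (foil) on rest c.  In the whole condition
#' the choices are full blends, attention-weighted on the eye region
#' (non-eye pixels times 0.5, recentred on the eyes); in the part
#' condition the eye regions are cropped out of the whole-condition
#' stimuli.  The whole-part effect is whole minus part accuracy; its
#' p-value is the proportion of neuron bootstrap resamples in which it is
#' not positive.  Distance ties are scored as half correct.
#'
#' @inheritParams run_cfe
#' @param max_trials Cap on the number of ordered triples (subsampled
#'   uniformly, seeded, from the full enumeration).
#' @return A `wpe_result` with per-size whole/part accuracies, effect
#'   sizes, bootstrap SEMs/p-values and cross-size comparisons.
#' @export
run_wpe <- function(bank, faces, sizes = c("large", "small"),
                    max_trials = 60L, n_resamples = 1000L, seed = 1L,
                    stim_config = holoface::stim_config(),
                    config = bank$config) {
  stopifnot(length(faces) >= 3)
  n <- length(faces)
  ids <- names(faces) %||% as.character(seq_len(n))

  # Ordered triples (eyes_a, eyes_b, rest) of distinct identities.  The
  # full enumeration (n (n-1) (n-2) triples) is subsampled stratified by
  # rest-of-face identity: each rest face gets a small random eye-donor
  # set and all ordered donor pairs within it, balancing rests and
  # maximizing stimulus reuse (trials grow quadratically in donors per
  # rest while stimuli grow linearly).
  full_n <- n * (n - 1L) * (n - 2L)
  trials <- with_local_seed(seed, {
    if (full_n <= max_trials) {
      do.call(rbind, lapply(seq_len(n), function(a) {
        do.call(rbind, lapply(setdiff(seq_len(n), a), function(b) {
          cbind(eyes_a = a, eyes_b = b, rest = setdiff(seq_len(n), c(a, b)))
        }))
      }))
    } else {
      per_rest <- ceiling(max_trials / n)
      k <- max(2L, ceiling((1 + sqrt(1 + 4 * per_rest)) / 2))
      out <- do.call(rbind, lapply(seq_len(n), function(r) {
        donors <- sample(setdiff(seq_len(n), r), min(k, n - 1L))
        prs <- expand.grid(eyes_a = donors, eyes_b = donors)
        prs <- prs[prs$eyes_a != prs$eyes_b, ]
        cbind(eyes_a = prs$eyes_a, eyes_b = prs$eyes_b, rest = r)
      }))
      if (nrow(out) > max_trials)
        out <- out[sort(sample.int(nrow(out), max_trials)), , drop = FALSE]
      out
    }
  })
  nt <- nrow(trials)

  er <- stim_config$eye_region
  npx <- stim_config$image_size
  dr <- round_half_up((npx + 1) / 2 - mean(er$rows))
  dc <- round_half_up((npx + 1) / 2 - mean(er$cols))
  er_centred <- list(rows = er$rows + dr, cols = er$cols + dc)

  # unique (eyes, rest) blends needed; study = plain whole, choices =
  # attention-weighted whole and its eye-region crop
  key <- unique(rbind(trials[, c("eyes_a", "rest")],
                      trials[, c("eyes_b", "rest")]))
  stims <- lapply(seq_len(nrow(key)), function(i) {
    wp <- make_whole_part_pair(faces[[key[i, 1]]], faces[[key[i, 2]]],
                               config = stim_config)
    weighted <- apply_attention(wp$whole, er, stim_config$attention_wpe,
                                recenter = TRUE)
    list(study = wp$whole, whole = weighted,
         part = crop_to_region(weighted, er_centred))
  })
  row_of <- function(e, r) which(key[, 1] == e & key[, 2] == r)

  c2 <- lapply(c("study", "whole", "part"), function(role)
    c2_for_stimuli(lapply(stims, `[[`, role), bank, sizes, config))
  names(c2) <- c("study", "whole", "part")

  i_study <- vapply(seq_len(nt), function(i)
    row_of(trials[i, "eyes_a"], trials[i, "rest"]), 1L)
  i_foil <- vapply(seq_len(nt), function(i)
    row_of(trials[i, "eyes_b"], trials[i, "rest"]), 1L)

  # per condition+size: squared per-neuron diffs choice-vs-study
  sq <- lapply(c("whole", "part"), function(cond) {
    lapply(sizes, function(sz) {
      S <- c2$study[[sz]][i_study, , drop = FALSE]
      list(correct = (c2[[cond]][[sz]][i_study, , drop = FALSE] - S)^2,
           foil = (c2[[cond]][[sz]][i_foil, , drop = FALSE] - S)^2)
    }) |> stats::setNames(sizes)
  }) |> stats::setNames(c("whole", "part"))

  acc <- function(sz, idx) {
    one <- function(cond) {
      dc2 <- rowSums(sq[[cond]][[sz]]$correct[, idx, drop = FALSE])
      df2 <- rowSums(sq[[cond]][[sz]]$foil[, idx, drop = FALSE])
      mean((dc2 < df2) + 0.5 * (dc2 == df2))
    }
    w <- one("whole"); p <- one("part")
    c(whole = w, part = p, effect = w - p)
  }

  n_neuron <- nrow(bank$meta)
  boots <- lapply(sizes, function(sz)
    paired_neuron_bootstrap(function(idx) acc(sz, idx),
                            n_neurons = n_neuron, n_resamples = n_resamples,
                            seed = seed))
  names(boots) <- sizes
  full <- lapply(sizes, function(sz) acc(sz, seq_len(n_neuron)))
  names(full) <- sizes

  summary <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, condition = c("whole", "part"),
    accuracy = unname(full[[sz]][1:2]), sem = unname(boots[[sz]]$sem[1:2]))))
  effects <- dplyr::bind_rows(lapply(sizes, function(sz) tibble::tibble(
    size_class = sz, effect = unname(full[[sz]]["effect"]),
    sem = unname(boots[[sz]]$sem["effect"]),
    p_boot = unname(boots[[sz]]$p_value["effect"]))))
  comparisons <- if (length(sizes) >= 2) {
    ref <- sizes[1]
    dplyr::bind_rows(lapply(sizes[-1], function(sz) tibble::tibble(
      comparison = paste0(ref, ">", sz),
      p = mean(boots[[ref]]$draws[, "effect"] <= boots[[sz]]$draws[, "effect"]))))
  } else tibble::tibble()
  trial_tbl <- tibble::tibble(trial = seq_len(nt),
                              eyes_correct = ids[trials[, "eyes_a"]],
                              eyes_foil = ids[trials[, "eyes_b"]],
                              rest = ids[trials[, "rest"]])
  new_holo_result("wpe_result", summary, effects, comparisons, trial_tbl,
                  meta = list(label = "whole-part effect", n_faces = n,
                              n_trials = nt, n_resamples = n_resamples,
                              seed = seed, n_neurons = n_neuron))
}
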