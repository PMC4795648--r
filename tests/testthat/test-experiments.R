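# Unit-level checks of the three simulations on reduced problem sizes;
# the directional science checks live in test-acceptance.R.

test_that("threshold calibration is monotone and lands nearest the target", {
  d <- c(0.1, 0.2, 0.3, 0.5, 0.9)
  cal <- holoface:::calibrate_threshold(d, target = 0.75)
  # hit-rate is non-decreasing in the threshold
  ths <- seq(0, 1.2, by = 0.01)
  hrs <- vapply(ths, function(t) mean(d < t), numeric(1))
  expect_true(all(diff(hrs) >= 0))
  # nearest achievable rate to 0.75 with 5 trials is 4/5
  expect_equal(cal$hit_rate, 0.8)
  expect_true(cal$threshold > 0.5 && cal$threshold < 0.9)
  # ties resolve toward the lower threshold: target 0.5 reachable twice
  cal2 <- holoface:::calibrate_threshold(c(1, 2, 3, 4), target = 0.5)
  expect_equal(cal2$hit_rate, 0.5)
  expect_lt(cal2$threshold, 3)

  # identical composites give dissimilarity 0: "same" at any threshold > 0
  expect_true(0 < cal$threshold)
})

test_that("cfe produces calibrated hit-rates and self-consistent effects", {
  bank <- tiny_bank()
  faces <- tiny_test()
  res <- run_cfe(bank, faces, max_trials = 12, n_resamples = 50, seed = 3)
  expect_s3_class(res, "cfe_result")
  # calibration: aligned hit-rate as close to 75% as the trial set allows
  al <- res$summary[res$summary$condition == "aligned", ]
  expect_true(all(abs(al$hit_rate - 0.75) <= 0.5 / 12 + 1e-9))
  # effect equals the difference of the stored condition estimates
  for (sz in res$effects$size_class) {
    s <- res$summary[res$summary$size_class == sz, ]
    e <- res$effects[res$effects$size_class == sz, ]
    expect_equal(e$effect,
                 s$hit_rate[s$condition == "misaligned"] -
                   s$hit_rate[s$condition == "aligned"])
  }
  expect_true(all(res$summary$hit_rate >= 0 & res$summary$hit_rate <= 1))
  expect_true(all(res$effects$p_boot >= 0 & res$effects$p_boot <= 1))
  # same seed reproduces every number
  res2 <- run_cfe(bank, faces, max_trials = 12, n_resamples = 50, seed = 3)
  expect_equal(res, res2)
  # tidy/glance accessors
  expect_identical(tidy(res), res$summary)
  expect_identical(glance(res), res$effects)
})

test_that("fie behavioral uses all pairs and is sensitive to inversion", {
  bank <- tiny_bank()
  faces <- tiny_test()
  c2 <- holoface:::fie_c2(bank, faces, c("large", "small"), bank$config)
  res <- run_fie_behavioral(bank, faces, sizes = c("large", "small"),
                            subsample = c(large = 20L, small = 60L),
                            n_resamples = 50, seed = 3, c2 = c2)
  expect_equal(res$meta$n_pairs, choose(length(faces), 2))
  # inverting both faces of a pair preserves pixel distance ...
  a <- stim_pixels(faces[[1]]); b <- stim_pixels(faces[[2]])
  ai <- stim_pixels(invert_stimulus(faces[[1]]))
  bi <- stim_pixels(invert_stimulus(faces[[2]]))
  expect_equal(sqrt(sum((a - b)^2)), sqrt(sum((ai - bi)^2)))
  # ... but changes C2 dissimilarity: templates are orientation-specific
  d_up <- c2_dissimilarity(c2$upright$large[1, ], c2$upright$large[2, ])
  d_inv <- c2_dissimilarity(c2$inverted$large[1, ], c2$inverted$large[2, ])
  expect_gt(abs(d_up - d_inv), 1e-6)
  # effect consistency
  for (sz in res$effects$size_class) {
    s <- res$summary[res$summary$size_class == sz, ]
    expect_equal(res$effects$effect[res$effects$size_class == sz],
                 diff(rev(s$mean_dissimilarity)))
  }
})

test_that("fie neural selects band neurons and equalizes counts", {
  bank <- tiny_bank()
  faces <- tiny_test()
  c2 <- holoface:::fie_c2(bank, faces, c("large", "medium", "small"),
                          bank$config)
  res <- run_fie_neural(bank, faces, band = NULL, n_min = 3, seed = 3, c2 = c2)
  band <- res$meta$band
  # every selected neuron's mean upright response lies inside the band
  for (sz in c("large", "medium", "small")) {
    mu <- colMeans(c2$upright[[sz]])
    expect_gte(sum(mu >= band[1] & mu <= band[2]), res$meta$n_selected)
  }
  # equalized counts: per-face means built from the same neuron count
  expect_gte(res$meta$n_selected, 3)
  counts <- table(res$trials$size_class)
  expect_true(all(counts == length(faces)))
  # an impossibly narrow fixed band errors informatively
  expect_error(run_fie_neural(bank, faces, band = c(0.9999, 1), c2 = c2),
               "empty|band")
})

test_that("wpe enumerates ordered distinct triples and scores consistently", {
  bank <- tiny_bank()
  faces <- tiny_test()
  # full enumeration for n identities is n (n-1) (n-2) ordered triples
  res <- run_wpe(bank, faces[1:4], max_trials = 1000, n_resamples = 50,
                 seed = 3)
  expect_equal(res$meta$n_trials, 4 * 3 * 2)
  expect_true(all(res$trials$eyes_correct != res$trials$eyes_foil))
  expect_true(all(res$trials$eyes_correct != res$trials$rest))
  expect_true(all(res$summary$accuracy >= 0 & res$summary$accuracy <= 1))
  for (sz in res$effects$size_class) {
    s <- res$summary[res$summary$size_class == sz, ]
    expect_equal(res$effects$effect[res$effects$size_class == sz],
                 s$accuracy[s$condition == "whole"] -
                   s$accuracy[s$condition == "part"])
  }
  res2 <- run_wpe(bank, faces[1:4], max_trials = 1000, n_resamples = 50,
                  seed = 3)
  expect_equal(res, res2)
})

test_that("the 2AFC choice rule is invariant to positive rescaling of C2", {
  # the chosen face minimizes Euclidean distance; scaling all response
  # vectors by c > 0 scales all distances by c and leaves the argmin
  with_local_seed_test(5, {
    for (i in 1:20) {
      study <- runif(30); ch1 <- runif(30); ch2 <- runif(30)
      pick <- c2_dissimilarity(ch1, study) < c2_dissimilarity(ch2, study)
      for (k in c(0.1, 3, 200)) {
        expect_identical(pick, c2_dissimilarity(k * ch1, k * study) <
                           c2_dissimilarity(k * ch2, k * study))
      }
    }
  })
})

test_that("the generator separates identities in C2 space", {
  bank <- tiny_bank()
  faces <- render_identity_set(seq(2, 40, 2), seed = 42) # 20 identities
  c2 <- sapply(faces, function(f) c2_responses(f, bank, sizes = "large")$large)
  prs <- utils::combn(ncol(c2), 2)
  d <- apply(prs, 2, function(p) c2_dissimilarity(c2[, p[1]], c2[, p[2]]))
  expect_gt(min(d), 0)
  expect_gt(sd(d) / mean(d), 0.05) # non-degenerate dissimilarity structure
})

test_that("autoplot and plot_effect_sizes return ggplot objects", {
  bank <- tiny_bank()
  res <- run_cfe(bank, tiny_test(), max_trials = 8, n_resamples = 20, seed = 1)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_effect_sizes(res), "ggplot")
})
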