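test_that("pyramid sizes follow the 2^(1/4) schedule with floor rounding", {
  cfg <- hmax_config()
  img <- matrix(0.5, 256, 256)
  pyr <- build_pyramid(img, cfg)
  sizes <- vapply(pyr, nrow, 1L)
  expect_identical(sizes, as.integer(floor(256 * 2^(-(0:9) / 4))))
  expect_identical(sizes[5], 128L) # one full octave below 256
  expect_true(all(diff(sizes) < 0))
  ratios <- sizes[-10] / sizes[-1]
  expect_true(all(abs(ratios - 2^(1 / 4)) < 0.02))
  expect_identical(pyr[[1]], img)

  tiny <- hmax_config(n_scales = 10)
  expect_error(build_pyramid(matrix(0.5, 32, 32), tiny), "Gabor")
})

test_that("gabor filters are zero-mean, unit-norm, and orientation selective", {
  gb <- gabor_bank(hmax_config())
  expect_length(gb, 4)
  for (f in gb) {
    expect_equal(sum(f), 0, tolerance = 1e-12)
    expect_equal(sum(f^2), 1, tolerance = 1e-12)
  }
})

test_that("S1 responses are normalized dot products in [0,1]", {
  cfg <- hmax_config(n_scales = 2)
  # constant image: zero-mean filter is orthogonal to it
  s1 <- s1_layer(build_pyramid(matrix(0.7, 64, 64), cfg), cfg)
  expect_lt(max(s1[[1]]), 1e-6) # zero up to FFT rounding

  # the 0-degree filter pasted on black responds 1 at its own location
  gb <- gabor_bank(cfg)
  img <- matrix(0, 64, 64)
  img[27:37, 27:37] <- gb[["0"]] # raw filter values: zero-mean patch
  s1 <- s1_layer(build_pyramid(img, cfg), cfg)
  r0 <- s1[[1]][, , 1]
  expect_equal(max(r0), 1, tolerance = 1e-6)
  peak <- which(r0 == max(r0), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(27, 27)) # valid-region coordinates
  expect_true(all(s1[[1]] >= 0 & s1[[1]] <= 1 + 1e-12))
})

test_that("rotating a grating by 90 degrees swaps the orientation channels", {
  cfg <- hmax_config(n_scales = 2)
  x <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  grating_v <- 0.5 + 0.4 * sin(2 * pi * x / 5.6) # vertical stripes
  s1v <- s1_layer(build_pyramid(grating_v, cfg), cfg)
  s1h <- s1_layer(build_pyramid(t(grating_v), cfg), cfg)
  # channel 1 (0 deg) of the vertical grating matches channel 3 (90 deg)
  # of the horizontal one, and vice versa
  expect_equal(mean(s1v[[1]][, , 1]), mean(s1h[[1]][, , 3]), tolerance = 1e-6)
  expect_equal(mean(s1v[[1]][, , 3]), mean(s1h[[1]][, , 1]), tolerance = 1e-6)
  expect_gt(mean(s1v[[1]][, , 1]), 2 * mean(s1v[[1]][, , 3]))
})

test_that("C1 equals the brute-force max over its pooled S1 window set", {
  cfg <- hmax_config()
  for (case in 1:4) {
    s1 <- random_s1(c(23, 19), n_or = 2, seed = case)
    c1 <- c1_layer(s1, cfg)
    expect_length(c1, 1)
    a <- c1[[1]]
    # brute force from the definition: 8x8 window on the fine grid plus
    # the proportionally mapped 8x8 window on the coarse grid
    nf <- (23 - 8) %/% 3 + 1
    nc_ <- (19 - 8) %/% 3 + 1
    expect_identical(dim(a), c(as.integer(nf), as.integer(nf), 2L))
    for (o in 1:2) for (i in seq_len(nf)) for (j in seq_len(nf)) {
      fi <- (i - 1) * 3 + 1; fj <- (j - 1) * 3 + 1
      ci <- (round(1 + (i - 1) * (nc_ - 1) / (nf - 1)) - 1) * 3 + 1
      cj <- (round(1 + (j - 1) * (nc_ - 1) / (nf - 1)) - 1) * 3 + 1
      pooled <- c(s1[[1]][fi:(fi + 7), fj:(fj + 7), o],
                  s1[[2]][ci:(ci + 7), cj:(cj + 7), o])
      expect_length(pooled, 128)
      expect_equal(a[i, j, o], max(pooled))
    }
  }
})

test_that("C1 propagates constant fields and localizes single activations", {
  cfg <- hmax_config()
  s1 <- list(array(0.4, c(20, 20, 1)), array(0.4, c(14, 14, 1)))
  expect_true(all(c1_layer(s1, cfg)[[1]] == 0.4))

  s1[[1]][] <- 0; s1[[2]][] <- 0
  s1[[1]][10, 10, 1] <- 0.9
  a <- c1_layer(s1, cfg)[[1]][, , 1]
  hit <- which(a == 0.9, arr.ind = TRUE)
  # exactly the windows whose 8x8 fine-grid extent covers (10,10)
  starts <- seq(1, by = 3, length.out = nrow(a))
  covers <- which(starts <= 10 & starts + 7 >= 10)
  expect_setequal(hit[, 1], covers)
  expect_setequal(hit[, 2], covers)
  expect_true(all(a[a != 0] == 0.9))
})

test_that("S2 is a Gaussian RBF of template-patch distance", {
  cfg <- hmax_config() # raw Euclidean distance, sigma = 1/3
  c1 <- list(array(stats::runif(5 * 5 * 4), c(5, 5, 4)))
  tmpl <- c1[[1]][2:3, 2:3, , drop = FALSE]
  s2 <- s2_layer(c1, tmpl, cfg)
  expect_equal(s2[[1]][2, 2], 1) # d = 0 at the source position
  expect_true(all(s2[[1]] > 0 & s2[[1]] <= 1))

  # pocket-calculator case: 2x2x1 template vs one printed patch
  patch <- array(c(0.2, 0.4, 0.6, 0.8), c(2, 2, 1))
  tmpl2 <- array(c(0.1, 0.5, 0.5, 0.6), c(2, 2, 1))
  d2 <- (0.2 - 0.1)^2 + (0.4 - 0.5)^2 + (0.6 - 0.5)^2 + (0.8 - 0.6)^2
  expect_equal(s2_layer(list(patch), tmpl2, cfg)[[1]][1, 1],
               exp(-d2 / (2 / 9)), tolerance = 1e-12)

  # monotone decreasing in distance
  base <- array(0.5, c(2, 2, 1))
  resp <- vapply(c(0, 0.1, 0.2, 0.3), function(eps)
    s2_layer(list(base + eps), base, cfg)[[1]][1, 1], numeric(1))
  expect_true(all(diff(resp) < 0))

  # bands smaller than the template are skipped, never padded
  c1b <- list(array(0.5, c(3, 3, 4)), array(0.5, c(2, 2, 4)))
  s2b <- s2_layer(c1b, array(0.5, c(3, 3, 4)), cfg)
  expect_null(s2b[[2]])
  expect_equal(dim(s2b[[1]]), c(1, 1))
})

test_that("fast C2 equals per-template S2 + global max on random instances", {
  cfg <- hmax_config()
  for (case in 1:3) {
    c1 <- with_local_seed_test(case, list(
      array(stats::runif(14 * 14 * 4), c(14, 14, 4)),
      array(stats::runif(9 * 9 * 4), c(9, 9, 4)),
      array(stats::runif(5 * 5 * 4), c(5, 5, 4))))
    bank <- tiny_bank()
    idx <- 1:12
    sub <- list(templates = lapply(bank$templates, function(m) m[idx, , drop = FALSE]),
                meta = bank$meta[idx, ], config = cfg)
    class(sub) <- "template_bank"
    fast <- c2_responses(c1, sub, config = cfg)
    for (sz in c("large", "medium", "small")) {
      k <- c(large = 12, medium = 8, small = 4)[[sz]]
      slow <- vapply(idx, function(t) {
        tmpl <- array(sub$templates[[sz]][t, ], c(k, k, 4))
        s2 <- s2_layer(c1, tmpl, cfg)
        if (all(vapply(s2, is.null, TRUE))) NA_real_ else c2_layer(s2)
      }, numeric(1))
      keep <- !is.na(slow)
      expect_equal(fast[[sz]][keep], slow[keep], tolerance = 1e-10)
    }
  }
})

test_that("C2 responds 1 to the exact training image and stays in (0,1]", {
  bank <- tiny_bank()
  train <- tiny_train()
  c2 <- c2_responses(train[[1]], bank)
  own <- bank$meta$template_id[bank$meta$source_image == 1]
  for (sz in c("large", "medium", "small")) {
    expect_true(mean(abs(c2[[sz]][own] - 1) < 1e-6) >= 0.99)
    expect_true(all(c2[[sz]] > 0 & c2[[sz]] <= 1 + 1e-12))
  }
})

test_that("dissimilarity is a Euclidean metric with index-subset support", {
  a <- c(0, 0, 0); b <- c(1, 1, 1)
  expect_equal(c2_dissimilarity(a, a), 0)
  expect_equal(c2_dissimilarity(a, b), sqrt(3))
  x <- runif(10); y <- runif(10)
  expect_equal(c2_dissimilarity(x, y), c2_dissimilarity(y, x))
  expect_equal(c2_dissimilarity(x, y, idx = 1:3), sqrt(sum((x[1:3] - y[1:3])^2)))
  expect_error(c2_dissimilarity(a, c(1, 2)), "length")
})

test_that("C2 degrades gracefully under shift and rescale of the input", {
  # In the raw-distance response regime, C2 position/scale tolerance
  # shows up as graceful, structure-preserving response change (the max
  # relocates), not bit-stability; bounds characterize the model on the
  # fixture faces and guard against regressions.
  bank <- tiny_bank()
  f <- tiny_test()[[1]]
  base <- c2_responses(f, bank)$large

  # shift by one C1 stride at the template band: 3 S1 units at scale 7
  shift_px <- round(3 * 2^((7 - 1) / 4))
  shifted <- holoface:::new_stimulus(
    holoface:::translate_pixels(stim_pixels(f), 0, shift_px), identity = 1L)
  resp_shift <- c2_responses(shifted, bank)$large
  expect_lt(median(abs(resp_shift - base)), 0.35)
  expect_gt(cor(base, resp_shift), 0.6) # response structure preserved
  # responses do not collapse: shifted face still drives the templates
  expect_gt(median(resp_shift), 0.25)

  # rescale by one pyramid step (2^(1/4)): weaker tolerance, documented
  px <- stim_pixels(f)
  scaled_sz <- round(256 / 2^(1 / 4))
  sc <- as.matrix(EBImage::resize(px, w = scaled_sz, h = scaled_sz,
                                  filter = "bilinear"))
  canvas <- matrix(0, 256, 256)
  off <- (256 - scaled_sz) %/% 2
  canvas[off + seq_len(scaled_sz), off + seq_len(scaled_sz)] <- sc
  resp_scale <- c2_responses(holoface:::new_stimulus(canvas, 1L), bank)$large
  expect_lt(median(abs(resp_scale - base)), 0.6)
  expect_gt(median(resp_scale), 0.05) # responses drop but are not abolished
})

test_that("the whole model chain is deterministic", {
  bank <- tiny_bank()
  f <- tiny_test()[[2]]
  expect_identical(c2_responses(f, bank), c2_responses(f, bank))
  expect_identical(learn_bank(tiny_train(), per_image = 10, seed = 99), bank)
})
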