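# Template learning: storing random C1 patches from training faces at
# three tuning sizes (large 12x12x4, medium 8x8x4, small 4x4x4 C1 units),
# all from one relatively coarse C1 band (default band 7 of 9).  Medium
# and small templates are the central sub-regions of their parent large
# template.

#' Face footprint in C1 band coordinates
#'
#' Bounding box of above-threshold C1 activity at the template band: the
#' region of C1 units (max over orientations) whose response exceeds a
#' fixed fraction of the band maximum.  Being relative, the threshold is
#' invariant to global contrast changes.
#'
#' @param img A stimulus, or a precomputed C1 list.
#' @param config An [hmax_config()].
#' @param band C1 band (default the config's template band).
#' @param rel_threshold Fraction of the band maximum (default 0.1).
#' @return `list(rows = c(lo, hi), cols = c(lo, hi), dims = c(h, w))` in
#'   C1 grid coordinates.
#' @export
face_footprint_c1 <- function(img, config = hmax_config(),
                              band = config$template_band,
                              rel_threshold = 0.1) {
  c1 <- if (inherits(img, "holo_stim") || is.matrix(img))
    c1_layer(s1_layer(build_pyramid(img, config), config), config)
  else img
  a <- c1[[band]]
  act <- apply(a, c(1, 2), max)
  mx <- max(act)
  if (mx <= 0) stop("blank image: no C1 activity at band ", band)
  on <- which(act > rel_threshold * mx, arr.ind = TRUE)
  list(rows = c(min(on[, 1]), max(on[, 1])),
       cols = c(min(on[, 2]), max(on[, 2])),
       dims = c(max(on[, 1]) - min(on[, 1]) + 1L,
                max(on[, 2]) - min(on[, 2]) + 1L))
}

#' Learn a template bank at all three tuning sizes
#'
#' Stores `per_image` C1 patches per training face, sampled uniformly at
#' random positions such that the full large (12 x 12) patch lies inside
#' the face's C1 footprint at the template band.  Medium (8 x 8) and
#' small (4 x 4) templates are the central sub-blocks of the same large
#' patch, so the three size classes are position-matched.  Deterministic
#' for a fixed seed.
#'
#' @param train_images List of upright rendered faces.
#' @param per_image Templates stored per training image (default 20).
#' @param seed Integer seed.
#' @param config An [hmax_config()].
#' @return A `template_bank`: `$templates`, a named list of matrices (one
#'   row per template: large `n x 576`, medium `n x 256`, small `n x 64`);
#'   `$meta`, a tibble with source identity, position, band and parent
#'   link; `$config`.
#' @export
learn_bank <- function(train_images, per_image = 20L, seed = 1L,
                       config = hmax_config()) {
  stopifnot(per_image >= 1)
  ts <- tuning_sizes()
  k_lg <- ts[["large"]]
  band <- config$template_band
  rows_list <- list(large = list(), medium = list(), small = list())
  meta <- vector("list", length(train_images))
  with_local_seed(seed, {
    for (i in seq_along(train_images)) {
      img <- train_images[[i]]
      c1 <- c1_layer(s1_layer(build_pyramid(img, config), config), config)
      fp <- face_footprint_c1(c1, config)
      max_r <- fp$rows[2] - k_lg + 1L
      max_c <- fp$cols[2] - k_lg + 1L
      if (max_r < fp$rows[1] || max_c < fp$cols[1])
        stop("face footprint of image ", i, " (identity ",
             img$meta$identity[[1]], ") too small at band ", band,
             " for a ", k_lg, "x", k_lg, " template")
      r0 <- sample(fp$rows[1]:max_r, per_image, replace = TRUE)
      c0 <- sample(fp$cols[1]:max_c, per_image, replace = TRUE)
      a <- c1[[band]]
      for (j in seq_len(per_image)) {
        lg <- a[r0[j]:(r0[j] + k_lg - 1L), c0[j]:(c0[j] + k_lg - 1L), , drop = FALSE]
        rows_list$large[[length(rows_list$large) + 1L]] <- as.vector(lg)
        rows_list$medium[[length(rows_list$medium) + 1L]] <-
          as.vector(central_block(lg, ts[["medium"]]))
        rows_list$small[[length(rows_list$small) + 1L]] <-
          as.vector(central_block(lg, ts[["small"]]))
      }
      meta[[i]] <- tibble::tibble(
        source_image = i,
        source_identity = img$meta$identity[[1]],
        source_row = r0, source_col = c0, band = band)
    }
  })
  meta <- dplyr::bind_rows(meta)
  meta$template_id <- seq_len(nrow(meta))
  meta$parent_id <- meta$template_id # size classes are position-matched
  structure(list(
    templates = lapply(rows_list, function(l) do.call(rbind, l)),
    meta = meta[, c("template_id", "parent_id", "source_image",
                    "source_identity", "source_row", "source_col", "band")],
    config = config,
    seed = as.integer(seed), per_image = as.integer(per_image)),
    class = "template_bank")
}

# central k x k sub-block of a larger square patch (equal margins)
central_block <- function(patch, k) {
  n <- dim(patch)[1]
  off <- (n - k) %/% 2L
  patch[(off + 1L):(off + k), (off + 1L):(off + k), , drop = FALSE]
}

# k x k x n_or array form of one stored template row
template_array <- function(bank, size_class, template_id) {
  k <- tuning_sizes()[[size_class]]
  v <- bank$templates[[size_class]][template_id, ]
  array(v, c(k, k, length(v) / (k * k)))
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d templates per size class (%s), band %d, seed %d\n",
              nrow(x$meta), paste(names(x$templates), collapse = "/"),
              x$config$template_band, x$seed))
  invisible(x)
}

#' Bank size and face-coverage arithmetic
#'
#' Recomputes, from the bank metadata and a measured face footprint, the
#' coverage statistics of the tuning-size manipulation: the total area of
#' all small templates relative to the face (how many times over the set
#' of small templates tiles the face), and the fraction of the face
#' covered by a single large template.
#'
#' @param bank A [learn_bank()] bank.
#' @param footprint A [face_footprint_c1()] footprint (C1 units).
#' @return A one-row tibble: template counts, footprint dimensions,
#'   `small_coverage` and `large_face_fraction`.
#' @export
coverage_stats <- function(bank, footprint) {
  ts <- tuning_sizes()
  n <- nrow(bank$meta)
  area <- prod(footprint$dims)
  tibble::tibble(
    n_templates = n,
    footprint_h = footprint$dims[1], footprint_w = footprint$dims[2],
    small_coverage = n * ts[["small"]]^2 / area,
    large_face_fraction = ts[["large"]]^2 / area)
}
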