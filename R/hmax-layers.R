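# The four-layer feedforward hierarchy.
#
# Representations:
#   pyramid : list of square matrices (scale 1 = input image)
#   S1      : list (per scale) of h x w x n_orient arrays, responses in [0,1]
#   C1      : list (per band)  of h x w x n_orient arrays, responses in [0,1]
#   S2      : per template, list (per band) of response matrices in (0,1]
#   C2      : numeric vector, one response in (0,1] per template

#' Multi-scale image pyramid
#'
#' Scale 1 is the input; each subsequent scale is the input bilinearly
#' resized down by one more factor of `scale_factor` (sizes rounded per
#' the config's rule, default floor).
#'
#' @param img A stimulus or plain matrix.
#' @param config An [hmax_config()].
#' @return List of matrices, largest first.
#' @export
build_pyramid <- function(img, config = hmax_config()) {
  px <- stim_pixels(img)
  stopifnot(nrow(px) == ncol(px))
  sizes <- pyramid_sizes(nrow(px), config)
  if (min(sizes) < config$gabor$size)
    stop("coarsest pyramid scale (", min(sizes),
         " px) is smaller than the Gabor filter (", config$gabor$size, " px)")
  lapply(seq_along(sizes), function(i) {
    if (sizes[i] == nrow(px)) px
    else as.matrix(EBImage::resize(px, w = sizes[i], h = sizes[i],
                                   filter = "bilinear"))
  })
}

#' S1 layer: oriented Gabor filtering
#'
#' At every scale and orientation the response is the absolute normalized
#' dot product between the zero-mean unit-norm Gabor and the local image
#' patch (patch divided by its own norm), computed over the valid
#' convolution region only; responses lie in \[0, 1\] and constant patches
#' give 0.
#'
#' @param pyramid Output of [build_pyramid()].
#' @param config An [hmax_config()].
#' @return List (per scale) of `h x w x n_orientations` arrays.
#' @export
s1_layer <- function(pyramid, config = hmax_config()) {
  filters <- gabor_bank(config)
  k <- config$gabor$size
  half <- (k - 1) / 2
  ones <- matrix(1, k, k)
  sat2 <- (config$s1_saturation %||% 0)^2 * k^2 # RMS units -> norm units
  lapply(pyramid, function(m) {
    n <- nrow(m)
    keep <- (half + 1):(n - half)
    norm2 <- EBImage::filter2(m^2, ones, boundary = 0)[keep, keep]
    norm <- sqrt(pmax(norm2 + sat2, 0))
    raw <- sqrt(pmax(norm2, 0))
    out <- array(0, c(length(keep), length(keep), length(filters)))
    for (o in seq_along(filters)) {
      num <- abs(EBImage::filter2(m, filters[[o]], boundary = 0)[keep, keep])
      r <- num / pmax(norm, 1e-9)
      r[raw < 1e-6] <- 0
      out[, , o] <- clamp01(r)
    }
    out
  })
}

# 2-D max pool (pool x pool window, given stride) of one matrix
pool_max <- function(m, pool, stride) {
  nr <- nrow(m); nc <- ncol(m)
  or <- (nr - pool) %/% stride + 1L
  oc <- (nc - pool) %/% stride + 1L
  if (or < 1 || oc < 1) return(NULL)
  acc <- matrix(-Inf, or, oc)
  ri <- seq.int(1L, by = stride, length.out = or)
  ci <- seq.int(1L, by = stride, length.out = oc)
  for (di in 0:(pool - 1L)) for (dj in 0:(pool - 1L)) {
    acc <- pmax(acc, m[ri + di, ci + dj, drop = FALSE])
  }
  acc
}

#' C1 layer: local max pooling over position and scale
#'
#' Each C1 unit takes the maximum over an 8 x 8 window of S1 units (stride
#' 3) in each of 2 adjacent scales — 128 S1 values per unit.  The C1 grid
#' of band b lives on the finer scale b; the coarser scale contributes its
#' pooled value at the proportionally mapped grid position.  10 S1 scales
#' give 9 C1 bands.
#'
#' @param s1 Output of [s1_layer()].
#' @param config An [hmax_config()].
#' @return List (per band) of `h x w x n_orientations` arrays.
#' @export
c1_layer <- function(s1, config = hmax_config()) {
  stopifnot(length(s1) >= config$c1_scale_pool)
  n_band <- length(s1) - config$c1_scale_pool + 1L
  pool <- config$c1_pool; stride <- config$c1_stride
  n_or <- dim(s1[[1]])[3]
  pooled <- lapply(s1, function(a) {
    lapply(seq_len(n_or), function(o) pool_max(a[, , o], pool, stride))
  })
  lapply(seq_len(n_band), function(b) {
    fine <- pooled[[b]]
    if (is.null(fine[[1]]))
      stop("C1 band ", b, ": pooling window does not fit the S1 grid")
    nr <- nrow(fine[[1]]); nc <- ncol(fine[[1]])
    out <- array(0, c(nr, nc, n_or))
    for (o in seq_len(n_or)) {
      acc <- fine[[o]]
      for (s in seq_len(config$c1_scale_pool - 1L)) {
        coarse <- pooled[[b + s]][[o]]
        if (is.null(coarse))
          stop("C1 band ", b, ": pooling window does not fit scale ", b + s)
        i2 <- map_index(nr, nrow(coarse))
        j2 <- map_index(nc, ncol(coarse))
        acc <- pmax(acc, coarse[i2, j2, drop = FALSE])
      }
      out[, , o] <- acc
    }
    out
  })
}

# nearest-index proportional mapping from a grid of size n onto size m
map_index <- function(n, m) {
  if (n == 1L) return(rep(1L, 1L))
  pmin(m, pmax(1L, as.integer(round(1 + (seq_len(n) - 1) * (m - 1) / (n - 1)))))
}

# Unfold every k x k x n_or patch of a C1 band into rows of a matrix.
# Column order matches as.vector() of a k x k x n_or template array.
unfold_c1 <- function(band, k) {
  d <- dim(band)
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  if (oh < 1 || ow < 1) return(NULL)
  P <- matrix(0, oh * ow, k * k * d[3])
  idx <- 0L
  for (o in seq_len(d[3])) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    idx <- idx + 1L
    P[, idx] <- band[dy:(dy + oh - 1L), dx:(dx + ow - 1L), o]
  }
  P
}

# RBF response from squared distances (sum over entries), per config rule
rbf_response <- function(d2, n_entries, config) {
  denom <- if (config$s2_normalize) n_entries else 1
  exp(-pmax(d2, 0) / (denom * 2 * config$s2_sigma^2))
}

#' S2 layer: Gaussian RBF template matching
#'
#' For one template, the response at each valid C1 position and band is
#' `exp(-d^2 / (2 sigma^2))` where `d` is the Euclidean distance between
#' the template and the C1 patch, divided by the square root of the number
#' of template entries when `s2_normalize` is on.  Bands too small for the
#' template are skipped, never padded.
#'
#' @param c1 Output of [c1_layer()].
#' @param template A `k x k x n_orientations` array of C1 values.
#' @param config An [hmax_config()].
#' @return List (per band) of response matrices; `NULL` for skipped bands.
#' @export
s2_layer <- function(c1, template, config = hmax_config()) {
  k <- dim(template)[1]
  stopifnot(dim(template)[2] == k, dim(template)[3] == dim(c1[[1]])[3])
  tv <- as.vector(template)
  t2 <- sum(tv^2)
  lapply(c1, function(band) {
    P <- unfold_c1(band, k)
    if (is.null(P)) return(NULL)
    d2 <- rowSums(P^2) + t2 - 2 * drop(P %*% tv)
    matrix(rbf_response(d2, length(tv), config),
           dim(band)[1] - k + 1L, dim(band)[2] - k + 1L)
  })
}

#' C2 layer: global max over an S2 pyramid
#'
#' @param s2 Output of [s2_layer()] (list of per-band response matrices).
#' @return The maximum response over all bands and positions.
#' @export
c2_layer <- function(s2) {
  vals <- unlist(lapply(s2, function(m) if (is.null(m)) numeric() else m))
  if (!length(vals)) stop("empty S2 pyramid: no band admits the template")
  max(vals)
}

#' C2 responses of a full template bank (fast path)
#'
#' Computes, for every template in the bank, the global max of its S2
#' response pyramid, without materializing the pyramids: for each band the
#' squared distances between all templates and all C1 patches are obtained
#' from one matrix product, and the RBF (monotone in distance) is applied
#' to the per-template minimum only.  Equivalent to
#' [s2_layer()] + [c2_layer()] per template (tested).
#'
#' @param c1 Output of [c1_layer()] (or a stimulus, which is run through
#'   the lower layers first).
#' @param bank A [learn_bank()] template bank.
#' @param sizes Tuning size classes to evaluate.
#' @param config An [hmax_config()].
#' @return Named list (per size class) of C2 vectors (one response in
#'   (0, 1\] per template, in bank order).
#' @export
c2_responses <- function(c1, bank, sizes = names(bank$templates),
                         config = hmax_config()) {
  if (inherits(c1, "holo_stim") || is.matrix(c1))
    c1 <- c1_layer(s1_layer(build_pyramid(c1, config), config), config)
  out <- lapply(sizes, function(sz) {
    Tm <- bank$templates[[sz]]
    k <- tuning_sizes()[[sz]]
    t2 <- rowSums(Tm^2)
    best <- rep(Inf, nrow(Tm))
    for (band in c1) {
      P <- unfold_c1(band, k)
      if (is.null(P)) next
      M <- -2 * (P %*% t(Tm)) + rowSums(P^2) # npos x n_templates
      best <- pmin(best, apply(M, 2, min) + t2)
    }
    if (all(!is.finite(best)))
      stop("no C1 band admits templates of size class '", sz, "'")
    rbf_response(best, ncol(Tm), config)
  })
  names(out) <- sizes
  out
}

#' Euclidean dissimilarity between two C2 vectors
#'
#' @param a,b Equal-length C2 vectors (aligned template order).
#' @param idx Optional neuron index subset (used by bootstrap resampling
#'   and neuron subsampling).
#' @return The Euclidean distance.
#' @export
c2_dissimilarity <- function(a, b, idx = NULL) {
  if (length(a) != length(b)) stop("C2 vector lengths differ")
  if (!is.null(idx)) { a <- a[idx]; b <- b[idx] }
  sqrt(sum((a - b)^2))
}
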