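#' Model configuration
#'
#' Parameters of the four-layer hierarchy.  The defaults implement the
#' standard configuration: a 10-scale image pyramid with downscaling
#' factor 2^(1/4); 11 x 11 Gabor filters (wavelength 5.6 px, envelope
#' sigma 4.5 px, aspect ratio 0.3) at 4 orientations; C1 max pooling over
#' 8 x 8 S1 units from 2 adjacent scales with stride 3; and Gaussian
#' radial-basis template matching with sigma = 1/3 on a per-entry
#' normalized Euclidean distance.
#'
#' @param n_scales Number of pyramid scales.
#' @param scale_factor Linear downscaling factor between adjacent scales.
#' @param rounding How scaled sizes are rounded (`"floor"` or `"round"`).
#' @param gabor Gabor filter parameters: `size` (odd, px), `lambda`
#'   (wavelength, px), `sigma` (Gaussian envelope, px), `aspect`
#'   (envelope aspect ratio) and `orientations` (degrees).
#' @param s1_saturation Semi-saturation constant added in quadrature to
#'   the patch norm in the S1 normalization (RMS-intensity units per
#'   filter pixel; 0 = pure normalized dot product).  A positive value
#'   makes S1 responses fall off at low absolute signal levels, so that
#'   multiplicative attenuation of image regions (attentional
#'   down-weighting) actually reduces responses; with 0 the normalized
#'   dot product is fully contrast-invariant and such weighting only
#'   acts through region-boundary edges.
#' @param c1_pool,c1_stride,c1_scale_pool Spatial pooling extent (S1
#'   units), stride (S1 units) and number of adjacent scales pooled by
#'   each C1 unit.
#' @param s2_sigma Width of the Gaussian radial basis function.
#' @param s2_normalize If `TRUE` the Euclidean distance between template
#'   and C1 patch is divided by the square root of the number of template
#'   entries.  The default is `FALSE` (raw Euclidean distance, as in the
#'   reference implementation of the architecture): with normalization the
#'   distances are so small that all template responses saturate near 1,
#'   whereas the raw distance puts mean responses to upright faces in the
#'   working range the neural-level analyses assume (around 0.75-0.80 for
#'   large templates).
#' @param template_band C1 scale band (of `n_scales - 1`) from which
#'   templates are sampled.
#' @return A list of class `hmax_config`.
#' @export
hmax_config <- function(n_scales = 10L, scale_factor = 2^(1 / 4),
                        rounding = c("floor", "round"),
                        gabor = list(size = 11L, lambda = 5.6, sigma = 4.5,
                                     aspect = 0.3,
                                     orientations = c(0, 45, 90, 135)),
                        s1_saturation = 0,
                        c1_pool = 8L, c1_stride = 3L, c1_scale_pool = 2L,
                        s2_sigma = 1 / 3, s2_normalize = FALSE,
                        template_band = 7L) {
  stopifnot(n_scales >= 2, s2_sigma > 0, gabor$size %% 2 == 1)
  cfg <- list(n_scales = as.integer(n_scales), scale_factor = scale_factor,
              rounding = match.arg(rounding), gabor = gabor,
              s1_saturation = s1_saturation,
              c1_pool = as.integer(c1_pool), c1_stride = as.integer(c1_stride),
              c1_scale_pool = as.integer(c1_scale_pool),
              s2_sigma = s2_sigma, s2_normalize = isTRUE(s2_normalize),
              template_band = as.integer(template_band))
  class(cfg) <- "hmax_config"
  cfg
}

# template side length (in C1 units) per tuning size class
tuning_sizes <- function() c(large = 12L, medium = 8L, small = 4L)

#' Gabor filter bank
#'
#' One zero-mean, unit-norm Gabor per orientation, restricted to a
#' circular aperture.
#'
#' @param config An [hmax_config()].
#' @return List of `size` x `size` matrices, named by orientation
#'   (degrees).
#' @export
gabor_bank <- function(config = hmax_config()) {
  g <- config$gabor
  half <- (g$size - 1) / 2
  xs <- matrix(-half:half, g$size, g$size, byrow = TRUE) # column offset
  ys <- matrix(-half:half, g$size, g$size)               # row offset
  ap <- sqrt(xs^2 + ys^2) <= half + 0.5
  out <- lapply(g$orientations, function(theta) {
    th <- theta * pi / 180
    x <- xs * cos(th) + ys * sin(th)
    y <- -xs * sin(th) + ys * cos(th)
    f <- exp(-(x^2 + (g$aspect * y)^2) / (2 * g$sigma^2)) * cos(2 * pi * x / g$lambda)
    f[!ap] <- 0
    f[ap] <- f[ap] - mean(f[ap])
    f / sqrt(sum(f^2))
  })
  names(out) <- as.character(g$orientations)
  out
}

# pyramid scale sizes for a square base image
pyramid_sizes <- function(base, config) {
  i <- seq_len(config$n_scales)
  raw <- base * config$scale_factor^(-(i - 1))
  if (config$rounding == "floor") as.integer(floor(raw)) else as.integer(round(raw))
}
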