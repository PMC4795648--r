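#' @importFrom rlang .data
NULL

new_stimulus <- function(pixels, identity, transforms = character(), extra = list()) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels,
                 meta = c(list(identity = identity, transforms = transforms), extra)),
            class = "holo_stim")
}

#' @export
print.holo_stim <- function(x, ...) {
  cat(sprintf("<stimulus %dx%d> identity: %s; transforms: %s\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(x$meta$identity, collapse = ","),
              if (length(x$meta$transforms)) paste(x$meta$transforms, collapse = " -> ") else "none"))
  invisible(x)
}

#' Pixel matrix of a stimulus
#' @param x A stimulus created by [render_face()] or a transform.
#' @return The 256 x 256 numeric matrix of intensities in \[0, 1\]
#'   (row 1 = top of the image).
#' @export
stim_pixels <- function(x) {
  if (inherits(x, "holo_stim")) x$pixels else x
}

#' Draw the parameters of one synthetic face identity
#'
#' Each identity is a deterministic function of `(identity_id, seed)`: the
#' base part layout (eyes, brows, nose, mouth) receives independent
#' Gaussian jitter in position, size, orientation and intensity, so any two
#' identities differ (almost surely) in every part, in both the top and the
#' bottom half of the face.
#'
#' @param identity_id Non-negative integer identity label.
#' @param seed Integer seed for the whole stimulus set.
#' @param config A [stim_config()].
#' @return A `face_spec`: the jittered part table plus oval geometry and
#'   the pixel-normalization target.
#' @export
generate_identity <- function(identity_id, seed = 1L, config = stim_config()) {
  stopifnot(identity_id >= 0)
  parts <- config$parts %||% base_part_table()
  j <- config$jitter
  # jitter truncated at +/- 2 SD so parts stay inside the oval and the
  # rendered intensity range stays normalizable
  rtrunc <- function(n, sd) pmin(2 * sd, pmax(-2 * sd, stats::rnorm(n, 0, sd)))
  parts <- with_local_seed(mix_seed(seed, identity_id), {
    n <- nrow(parts)
    parts$dx <- parts$dx + rtrunc(n, j$pos)
    parts$dy <- parts$dy + rtrunc(n, j$pos)
    parts$w <- parts$w * (1 + rtrunc(n, j$size))
    parts$h <- parts$h * (1 + rtrunc(n, j$size))
    parts$angle <- parts$angle + rtrunc(n, j$angle)
    parts$intensity <- parts$intensity + rtrunc(n, j$intensity)
    parts
  })
  # identity-specific smooth surface structure (skin/shape variation):
  # a coarse Gaussian field, bilinearly upsampled at render time
  texture <- with_local_seed(mix_seed(seed, identity_id) + 1L,
    matrix(pmin(2, pmax(-2, stats::rnorm(config$texture$grid^2))),
           config$texture$grid, config$texture$grid))
  structure(list(identity_id = as.integer(identity_id), seed = as.integer(seed),
                 part_params = parts, texture = texture,
                 texture_amp = config$texture$amp, oval = config$oval,
                 shading = config$shading,
                 norm_target = config$norm_target),
            class = "face_spec")
}

# Anti-aliased coverage (in [0,1]) of one primitive over pixel grid
# (R = row coords, C = col coords as matrices).
part_coverage <- function(shape, cx, cy, w, h, angle, R, C) {
  th <- angle * pi / 180
  x <- (C - cx) * cos(th) + (R - cy) * sin(th)
  y <- -(C - cx) * sin(th) + (R - cy) * cos(th)
  if (shape == "ellipse") {
    r <- sqrt((x / w)^2 + (y / h)^2)
    clamp01((1 - r) * min(w, h) + 0.5)
  } else { # soft bar
    d <- pmax(abs(x) - w, abs(y) - h)
    clamp01(0.5 - d)
  }
}

#' Render a face specification to a stimulus image
#'
#' Draws the parts on a uniform skin tone inside the face oval, then
#' standardizes the in-oval pixels to the face specification's target
#' mean and standard deviation.  Pixels outside the oval are exactly 0 (black background).
#' The renderer refuses degenerate specs: parts falling outside the oval,
#' in-oval contrast too low to normalize (standard deviation below 1e-3
#' before standardization), or normalized intensities escaping \[0, 1\].
#'
#' @param spec A `face_spec` from [generate_identity()].
#' @param config A [stim_config()].
#' @return A stimulus (`holo_stim`) with a 256 x 256 pixel matrix.
#' @export
render_face <- function(spec, config = stim_config()) {
  stopifnot(inherits(spec, "face_spec"))
  n <- config$image_size
  ov <- spec$oval
  px <- matrix(0, n, n)
  R <- matrix(seq_len(n), n, n)
  C <- matrix(seq_len(n), n, n, byrow = TRUE)
  inside <- ((C - ov$cx) / ov$a)^2 + ((R - ov$cy) / ov$b)^2 <= 1

  # base skin tone with radial shading (darker toward the oval boundary),
  # emulating the smooth illumination gradient of a photographed face
  sh <- spec$shading %||% list(base = 0.62, depth = 0.20)
  rr <- ((C - ov$cx) / ov$a)^2 + ((R - ov$cy) / ov$b)^2
  face <- sh$base - sh$depth * pmin(rr, 1)
  for (i in seq_len(nrow(spec$part_params))) {
    p <- spec$part_params[i, ]
    cx <- ov$cx + p$dx; cy <- ov$cy + p$dy
    # the part (centre +/- extents) must sit inside the oval
    ext <- max(p$w, p$h)
    if (((abs(p$dx) + ext) / ov$a)^2 > 1 || ((abs(p$dy) + ext) / ov$b)^2 > 1) {
      if (((p$dx / ov$a)^2 + (p$dy / ov$b)^2) > 1)
        stop("part '", p$part, "' of identity ", spec$identity_id,
             " lies outside the face oval")
    }
    cov <- part_coverage(p$shape, cx, cy, p$w, p$h, p$angle, R, C)
    face <- face + p$intensity * cov
  }

  if (!is.null(spec$texture) && spec$texture_amp > 0) {
    tex <- as.matrix(EBImage::resize(spec$texture, w = n, h = n,
                                     filter = "bilinear"))
    face <- face + spec$texture_amp * tex
  }

  v <- clamp01(face[inside]) # overlapping parts saturate rather than stack
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-3)
    stop("degenerate face: in-oval contrast too low to normalize (sd = ",
         signif(s, 3), ")")
  v <- (v - mean(v)) / s * spec$norm_target$sd + spec$norm_target$mean
  if (any(v < 0 | v > 1))
    stop("normalized intensities escape [0, 1]; lower norm_target$sd or ",
         "part intensity offsets")
  px[inside] <- v
  new_stimulus(px, identity = spec$identity_id, transforms = character(),
               extra = list(seed = spec$seed))
}

#' Generate and render a set of face identities
#'
#' @param identity_ids Integer vector of identity labels.
#' @inheritParams generate_identity
#' @return Named list of stimuli (names = identity ids).
#' @export
render_identity_set <- function(identity_ids, seed = 1L, config = stim_config()) {
  out <- lapply(identity_ids, function(id)
    render_face(generate_identity(id, seed, config), config))
  names(out) <- as.character(identity_ids)
  out
}
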