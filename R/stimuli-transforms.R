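# Stimulus transforms: composites, attention weighting, inversion,
# whole-part blends.  All transforms keep the 256 x 256 geometry and the
# [0,1] intensity range, and record themselves in the stimulus metadata.

check_same_geometry <- function(a, b) {
  if (!identical(dim(stim_pixels(a)), dim(stim_pixels(b))))
    stop("stimulus geometries differ: ",
         paste(dim(stim_pixels(a)), collapse = "x"), " vs ",
         paste(dim(stim_pixels(b)), collapse = "x"))
}

#' Build a composite face
#'
#' Pairs the top half of one face with the bottom half of another, with a
#' 2-pixel background-coloured gap centred on the face midline.  In the
#' misaligned variant the bottom half is shifted horizontally by half the
#' face width (`misalign_offset`, default 40 px).
#'
#' @param top_src,bottom_src Upright rendered faces of equal geometry.
#' @param aligned Logical; `FALSE` shifts the bottom half.
#' @param config A [stim_config()].
#' @return A composite stimulus; metadata records both source identities.
#' @export
make_composite <- function(top_src, bottom_src, aligned = TRUE,
                           config = stim_config()) {
  check_same_geometry(top_src, bottom_src)
  a <- stim_pixels(top_src); b <- stim_pixels(bottom_src)
  n <- nrow(a)
  mid <- midline_row(config)
  gap <- config$gap_px
  out <- matrix(0, n, n)
  out[seq_len(mid - 1L), ] <- a[seq_len(mid - 1L), ]
  bot_rows <- (mid + gap):n
  bot <- b[bot_rows, , drop = FALSE]
  if (!aligned) {
    off <- config$misalign_offset
    shifted <- matrix(0, length(bot_rows), n)
    if (off >= 0) shifted[, (1 + off):n] <- bot[, 1:(n - off)]
    else shifted[, 1:(n + off)] <- bot[, (1 - off):n]
    bot <- shifted
  }
  out[bot_rows, ] <- bot
  new_stimulus(out,
               identity = c(top = top_src$meta$identity[[1]],
                            bottom = bottom_src$meta$identity[[1]]),
               transforms = c(top_src$meta$transforms,
                              sprintf("composite(%s)",
                                      if (aligned) "aligned" else "misaligned")))
}

#' Attentional weighting of an image region
#'
#' Multiplies every pixel outside the attended rectangle by `factor`
#' (0 to 1) and, if `recenter = TRUE`, translates the image so that the
#' attended region's centre lands on the image centre (simulating fixation
#' on that region).
#'
#' @param img A stimulus.
#' @param region `list(rows = c(lo, hi), cols = c(lo, hi))`, inclusive
#'   pixel bounds; must lie inside the image.
#' @param factor Multiplier in \[0, 1\] for unattended pixels.
#' @param recenter Logical; translate so the region is centred.
#' @param feather Width (px) of the graded transition between full and
#'   attenuated weighting, centred on the region boundary (0 = hard
#'   step).  A graded edge mimics the smooth fall-off of a spatial
#'   attention field and avoids introducing sharp contrast borders that
#'   the model's oriented filters would respond to.
#' @return The weighted (and possibly recentred) stimulus.
#' @export
apply_attention <- function(img, region, factor, recenter = FALSE,
                            feather = 0) {
  px <- stim_pixels(img)
  n <- nrow(px); m <- ncol(px)
  r <- as.integer(region$rows); cl <- as.integer(region$cols)
  if (r[1] < 1 || r[2] > n || cl[1] < 1 || cl[2] > m || r[1] > r[2] || cl[1] > cl[2])
    stop("attended region out of image bounds")
  stopifnot(factor >= 0, factor <= 1)
  if (feather > 0) {
    # signed distance to the region boundary (positive inside)
    di <- pmin(seq_len(n) - r[1], r[2] - seq_len(n))
    dj <- pmin(seq_len(m) - cl[1], cl[2] - seq_len(m))
    d <- pmin(matrix(di, n, m), matrix(dj, n, m, byrow = TRUE))
    w <- pmin(1, pmax(0, 0.5 + d / feather))
    px <- px * (factor + (1 - factor) * w)
  } else {
    mask <- matrix(TRUE, n, m)
    mask[r[1]:r[2], cl[1]:cl[2]] <- FALSE
    px[mask] <- px[mask] * factor
  }
  tr <- sprintf("attend(factor=%g)", factor)
  if (recenter) {
    dr <- round_half_up((n + 1) / 2 - mean(r))
    dc <- round_half_up((m + 1) / 2 - mean(cl))
    px <- translate_pixels(px, dr, dc)
    tr <- sprintf("attend(factor=%g,recenter=%+d%+d)", factor, dr, dc)
  }
  new_stimulus(px, identity = img$meta$identity,
               transforms = c(img$meta$transforms, tr))
}

# integer translation with zero fill (dr > 0 moves content down)
translate_pixels <- function(px, dr, dc) {
  n <- nrow(px); m <- ncol(px)
  out <- matrix(0, n, m)
  src_r <- seq_len(n) - dr; src_c <- seq_len(m) - dc
  ok_r <- src_r >= 1 & src_r <= n; ok_c <- src_c >= 1 & src_c <= m
  out[ok_r, ok_c] <- px[src_r[ok_r], src_c[ok_c]]
  out
}

#' Invert a stimulus (upside-down flip)
#'
#' Reverses the row order of the full 256 x 256 field, so
#' `invert(invert(x)) = x`.
#'
#' @param img A stimulus.
#' @return The inverted stimulus.
#' @export
invert_stimulus <- function(img) {
  px <- stim_pixels(img)
  new_stimulus(px[rev(seq_len(nrow(px))), , drop = FALSE],
               identity = img$meta$identity,
               transforms = c(img$meta$transforms, "inverted"))
}

#' Whole-part stimulus pair
#'
#' `whole` is `base` with its eye region (both eyes and brows) replaced by
#' `eye_donor`'s eye region; a 1-px linear feather (configurable) blends
#' the two inside the region boundary, so the non-eye region equals `base`
#' exactly.  `part` is `whole` with every pixel outside the eye region set
#' to background (the eye region stays in place).
#'
#' @param eye_donor,base Upright rendered faces of equal geometry.
#' @param config A [stim_config()]; `config$eye_region` defines the
#'   rectangle, `config$feather_px` the feather width.
#' @return `list(whole = , part = )` of stimuli.
#' @export
make_whole_part_pair <- function(eye_donor, base, config = stim_config()) {
  check_same_geometry(eye_donor, base)
  d <- stim_pixels(eye_donor); b <- stim_pixels(base)
  er <- config$eye_region
  r <- er$rows[1]:er$rows[2]; cl <- er$cols[1]:er$cols[2]
  w <- eye_region_weight(er, config$feather_px)
  out <- b
  out[r, cl] <- w * d[r, cl] + (1 - w) * b[r, cl]
  whole <- new_stimulus(out,
                        identity = c(eyes = eye_donor$meta$identity[[1]],
                                     rest = base$meta$identity[[1]]),
                        transforms = "whole(eyes,rest)")
  part <- crop_to_region(whole, er)
  list(whole = whole, part = part)
}

# donor weight inside the eye rectangle: 0 on the border rows/cols,
# ramping linearly to 1 over `feather` pixels
eye_region_weight <- function(er, feather) {
  nr <- er$rows[2] - er$rows[1] + 1L
  nc <- er$cols[2] - er$cols[1] + 1L
  di <- pmin(seq_len(nr) - 1L, nr - seq_len(nr))
  dj <- pmin(seq_len(nc) - 1L, nc - seq_len(nc))
  dmat <- pmin(matrix(di, nr, nc), matrix(dj, nr, nc, byrow = TRUE))
  if (feather <= 0) matrix(1, nr, nc) else pmin(1, dmat / feather)
}

#' Crop a stimulus to a rectangular region (in place)
#'
#' Pixels outside the region are set to background (0); the region itself
#' is left where it is.
#'
#' @param img A stimulus.
#' @param region `list(rows =, cols =)` inclusive pixel bounds.
#' @return The cropped stimulus.
#' @export
crop_to_region <- function(img, region) {
  px <- stim_pixels(img)
  out <- matrix(0, nrow(px), ncol(px))
  r <- region$rows[1]:region$rows[2]; cl <- region$cols[1]:region$cols[2]
  out[r, cl] <- px[r, cl]
  new_stimulus(out, identity = img$meta$identity,
               transforms = c(img$meta$transforms, "crop(eye-region)"))
}
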