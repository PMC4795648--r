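#' Stimulus generator configuration
#'
#' Geometry and rendering parameters for the synthetic face stimuli.  Faces
#' are drawn inside an oval (about 80 x 120 px) centred in a 256 x 256 black
#' field, from anti-aliased geometric primitives (ellipses and soft bars)
#' standing in for the eyes, brows, nose and mouth.  In-oval pixels are
#' normalized to a common mean and standard deviation so that identities
#' differ in shape, not in global pixel statistics; the background stays
#' exactly black.
#'
#' @param image_size Side of the square image in pixels.
#' @param oval Face oval: centre (`cx`, `cy`, in pixel coordinates, row =
#'   `cy`) and semi-axes (`a` across columns, `b` across rows).  The
#'   defaults give an 80 x 120 px face region.
#' @param norm_target In-oval pixel mean and standard deviation imposed on
#'   every rendered face.
#' @param misalign_offset Horizontal shift (px) of the bottom half in
#'   misaligned composites; half the face width by convention.
#' @param gap_px Height (px) of the background-coloured gap inserted at the
#'   face midline of composite stimuli.
#' @param eye_region Rectangle (`rows`, `cols`, inclusive pixel bounds)
#'   covering both eyes and brows: the upper third of the oval at full oval
#'   width.
#' @param attention_cfe,attention_wpe Multiplier applied to pixels outside
#'   the attended region in the composite-face and whole-part paradigms.
#' @param feather_px Width of the linear feather blending the donor eye
#'   region into the base face (0 = hard edge).
#' @param jitter Standard deviations of the identity-specific parameter
#'   jitter: part position (px), relative size, orientation (degrees) and
#'   intensity offset.  All jitter is truncated at 2 SD.  The defaults
#'   are chosen so that identity differences exceed the position
#'   tolerance of the model's mid-level pooling and are therefore visible
#'   at the template scale.
#' @param parts Base (pre-jitter) part layout table; defaults to
#'   [base_part_table()].  Override to draw a different face family.
#' @param shading Skin base tone and radial shading depth (the face
#'   darkens toward the oval boundary, like an illuminated 3-D surface).
#' @param texture Identity-specific smooth surface structure: a
#'   `grid` x `grid` Gaussian field upsampled over the face, scaled by
#'   `amp`.  Emulates the idiosyncratic shape/shading variation of real
#'   faces that makes every region of a face informative about identity.
#'
#' @return A list of class `stim_config`.
#' @export
stim_config <- function(image_size = 256L,
                        oval = list(cx = 128.5, cy = 128.5, a = 40, b = 60),
                        norm_target = list(mean = 0.5, sd = 0.08),
                        misalign_offset = 40L,
                        gap_px = 2L,
                        eye_region = list(rows = c(69L, 114L), cols = c(89L, 168L)),
                        attention_cfe = 0.1,
                        attention_wpe = 0.5,
                        feather_px = 1,
                        jitter = list(pos = 2.5, size = 0.18, angle = 6, intensity = 0.06),
                        parts = base_part_table(),
                        shading = list(base = 0.62, depth = 0.20),
                        texture = list(grid = 16L, amp = 0.035)) {
  cfg <- list(image_size = as.integer(image_size), oval = oval,
              norm_target = norm_target,
              misalign_offset = as.integer(misalign_offset),
              gap_px = as.integer(gap_px), eye_region = eye_region,
              attention_cfe = attention_cfe, attention_wpe = attention_wpe,
              feather_px = feather_px, jitter = jitter, parts = parts,
              shading = shading, texture = texture)
  class(cfg) <- "stim_config"
  cfg
}

#' Base (pre-jitter) face part layout
#'
#' Part positions relative to the oval centre (`dx` across columns, `dy`
#' down rows), semi-extents `w`/`h` in px, and `intensity` as an offset
#' from the shaded skin base.
#'
#' @return A tibble with one row per part.
#' @export
base_part_table <- function() {
  tibble::tribble(
    ~part,         ~shape,    ~dx,  ~dy, ~w,   ~h,   ~angle, ~intensity,
    "left_eye",    "ellipse", -16, -26,  7,    4,    0,      -0.28,
    "right_eye",   "ellipse",  16, -26,  7,    4,    0,      -0.28,
    "left_brow",   "bar",     -16, -38, 10,    1.8,  -6,     -0.22,
    "right_brow",  "bar",      16, -38, 10,    1.8,   6,     -0.22,
    "nose",        "bar",       0,   4,  3.5, 12,     0,     -0.10,
    "mouth",       "ellipse",   0,  32, 13,    4,     0,     -0.25
  )
}

# Parts above the face midline (used by the identity-distinctness check)
top_half_parts <- function() c("left_eye", "right_eye", "left_brow", "right_brow")
bottom_half_parts <- function() c("nose", "mouth")

# Face bounding box implied by the oval, inclusive pixel bounds.
face_box <- function(config) {
  list(rows = c(ceiling(config$oval$cy - config$oval$b + 0.5),
                floor(config$oval$cy + config$oval$b - 0.5)),
       cols = c(ceiling(config$oval$cx - config$oval$a + 0.5),
                floor(config$oval$cx + config$oval$a - 0.5)))
}

# Top half of the face (rows above the composite gap), used as the
# attended region in the composite paradigm.
top_half_box <- function(config) {
  fb <- face_box(config)
  mid <- midline_row(config)
  list(rows = c(fb$rows[1], mid - 1L), cols = fb$cols)
}

# Row index just below which the composite split runs: the gap occupies
# rows mid .. mid + gap_px - 1, centred on the face's horizontal midline.
midline_row <- function(config) {
  as.integer(round(config$oval$cy - config$gap_px / 2 + 1))
}
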