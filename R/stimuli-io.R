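# PNG input/output and the loader hook for user-supplied face images.

#' Write a stimulus as 8-bit grayscale PNG with a JSON sidecar
#'
#' @param img A stimulus.
#' @param path Output `.png` path; the metadata sidecar is written next to
#'   it as `<path>.json` (identity, transform chain, seed if present).
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(stim_pixels(img), path)
  jsonlite::write_json(img$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a grayscale PNG as a stimulus
#'
#' @param path PNG path. RGB(A) input is averaged to grayscale.
#' @param identity Identity label to attach (read from the JSON sidecar if
#'   present and `identity` is `NULL`).
#' @return A stimulus.
#' @export
read_stimulus_png <- function(path, identity = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  sidecar <- paste0(path, ".json")
  if (is.null(identity) && file.exists(sidecar))
    identity <- jsonlite::read_json(sidecar)$identity
  new_stimulus(px, identity = identity %||% NA_integer_)
}

#' Load a directory of face images in place of the synthetic generator
#'
#' The loader hook: a directory of 256 x 256 grayscale face PNGs plus a
#' manifest CSV with columns `file` and `identity` replaces
#' [render_identity_set()] wherever a list of identity stimuli is needed.
#'
#' @param dir Directory containing the images.
#' @param manifest Path to the manifest CSV (default `manifest.csv` inside
#'   `dir`).
#' @return Named list of stimuli (names = identity ids).
#' @export
load_stimulus_dir <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "identity") %in% names(man)))
  out <- lapply(seq_len(nrow(man)), function(i)
    read_stimulus_png(file.path(dir, man$file[i]), identity = man$identity[i]))
  names(out) <- as.character(man$identity)
  out
}
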