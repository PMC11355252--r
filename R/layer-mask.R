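#' Annotated OCT layer mask
#'
#' A `layer_mask` wraps a 2-D integer label image of a colour-annotated OCT
#' crop together with its pixel pitch. Exactly the classes of [mh_palette()]
#' (0 background, 1 green ILM-OPL, 2 yellow ONL, 3 sky-blue ELM-EZ, 4 blue
#' EZ-RPE, 5 red IRF) may appear.
#'
#' @param labels integer matrix of class labels (rows = depth, columns =
#'   lateral position, top-left origin).
#' @param pitch_x,pitch_y pixel pitch in micrometres per pixel (lateral,
#'   axial), both > 0.
#' @param provenance free-text description of where the mask came from.
#' @return An object of class `layer_mask`.
#' @export
layer_mask <- function(labels, pitch_x = mh_default_pitch(),
                       pitch_y = pitch_x, provenance = "") {
  if (!is.matrix(labels) || length(labels) == 0)
    mh_stop("mh_invalid", "labels must be a non-empty matrix")
  lab <- labels
  storage.mode(lab) <- "integer"
  if (anyNA(lab) || any(!lab %in% 0:5))
    mh_stop("mh_invalid", "mask classes must be integers in 0..5")
  if (pitch_x <= 0 || pitch_y <= 0)
    mh_stop("mh_invalid", "pixel pitches must be positive")
  structure(list(labels = lab, pitch_x = pitch_x, pitch_y = pitch_y,
                 provenance = provenance),
            class = "layer_mask")
}

#' @export
print.layer_mask <- function(x, ...) {
  cat(sprintf("layer_mask %dx%d px, pitch %.3f x %.3f um/px\n",
              nrow(x$labels), ncol(x$labels), x$pitch_x, x$pitch_y))
  tab <- table(factor(x$labels, levels = 0:5))
  names(tab) <- mh_palette()$band
  print(tab)
  invisible(x)
}

#' Crop a source B-scan annotation to the standard trimmed window
#'
#' Extracts the 256 x 256 pixel analysis window (0.98 x 0.98 mm at the axial
#' pitch of the source scan, 3.26 degrees) centred on a chosen pixel,
#' normally the outer retina at the fovea. The result carries the axial pitch
#' (1.9 mm / 496 px) on both axes, matching the physical size quoted for the
#' trimmed image.
#'
#' @param image an integer label matrix or a [layer_mask()].
#' @param center numeric of length 2, `(row, col)` of the window centre in the
#'   source image.
#' @param size window side in pixels (default 256).
#' @return A [layer_mask()] of dimension `size x size`.
#' @export
crop_to_trim <- function(image, center, size = 256L) {
  lab <- if (inherits(image, "layer_mask")) image$labels else image
  if (!is.matrix(lab)) mh_stop("mh_invalid", "image must be a matrix")
  size <- as.integer(size)
  half <- size %/% 2L
  r0 <- as.integer(center[1]) - half + 1L
  c0 <- as.integer(center[2]) - half + 1L
  r1 <- r0 + size - 1L
  c1 <- c0 + size - 1L
  if (r0 < 1 || c0 < 1 || r1 > nrow(lab) || c1 > ncol(lab))
    mh_stop("mh_out_of_bounds",
            "%dx%d window at (%d, %d) exceeds the %dx%d source image",
            size, size, as.integer(center[1]), as.integer(center[2]),
            nrow(lab), ncol(lab))
  layer_mask(lab[r0:r1, c0:c1, drop = FALSE],
             pitch_x = oct_axial_pitch_um(), pitch_y = oct_axial_pitch_um(),
             provenance = sprintf("crop_to_trim(center = c(%d, %d))",
                                  as.integer(center[1]), as.integer(center[2])))
}

#' Read and write layer masks as PNG with the fixed palette
#'
#' Masks are stored as RGB PNG files using the exact palette colours of
#' [mh_palette()]; `read_layer_mask()` maps those colours back to class
#' indices and fails on any unknown colour. When a ground-truth record is
#' supplied to `write_layer_mask()` it is written to a JSON sidecar file
#' (`<path>.json`).
#'
#' @param mask a [layer_mask()].
#' @param path PNG file path.
#' @param ground_truth optional named list of ground-truth morphometry to
#'   store alongside the mask.
#' @param pitch_x,pitch_y pixel pitch to attach on read.
#' @return `read_layer_mask()` returns a [layer_mask()]; if a sidecar file is
#'   present its content is attached as attribute `ground_truth`.
#' @export
write_layer_mask <- function(mask, path, ground_truth = NULL) {
  stopifnot(inherits(mask, "layer_mask"))
  pal <- mh_palette()
  lab <- mask$labels
  arr <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  arr[, , 1] <- pal$r[lab + 1L] / 255
  arr[, , 2] <- pal$g[lab + 1L] / 255
  arr[, , 3] <- pal$b[lab + 1L] / 255
  png::writePNG(arr, path)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_layer_mask
#' @export
read_layer_mask <- function(path, pitch_x = mh_default_pitch(),
                            pitch_y = pitch_x) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  pal <- mh_palette()
  key <- round(arr[, , 1] * 255) * 1e6 + round(arr[, , 2] * 255) * 1e3 +
    round(arr[, , 3] * 255)
  pal_key <- pal$r * 1e6 + pal$g * 1e3 + pal$b
  cls <- match(key, pal_key) - 1L
  if (anyNA(cls))
    mh_stop("mh_invalid", "PNG contains colours outside the 6-entry palette")
  mask <- layer_mask(matrix(cls, nrow = dim(arr)[1]), pitch_x, pitch_y,
                     provenance = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(mask, "ground_truth") <- jsonlite::read_json(sidecar,
                                                      simplifyVector = TRUE)
  mask
}
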