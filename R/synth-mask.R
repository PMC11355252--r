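#' Parametric macular-hole mask geometry
#'
#' Describes a synthetic colour-annotated OCT crop: four horizontal retinal
#' bands (green ILM-OPL, yellow ONL, sky-blue ELM-EZ, blue EZ-RPE) crossed by
#' a central full-thickness hole whose width is specified at five boundary
#' levels (ILM, OPL, ELM, EZ and the base at the RPE) and interpolated
#' linearly in between, plus optional elliptical intraretinal-fluid blobs.
#' The renderer emulates the annotation layer of a trimmed B-scan, not the
#' raw OCT texture.
#'
#' @param image_size image side in pixels (square).
#' @param pixel_pitch isotropic pixel pitch, um/pixel.
#' @param band_thickness_um named numeric: thickness of `green`, `yellow`,
#'   `sky_blue`, `blue` bands in um.
#' @param gap_um named numeric: hole width in um at levels `ilm`, `opl`,
#'   `elm`, `ez`, `base`. `base` is the base diameter at the RPE; all gaps
#'   must be non-negative and no wider than the image.
#' @param top_margin_px first image row of the green band; `NULL` centres the
#'   retina vertically.
#' @param irf_blobs list of ellipses, each `list(row, col, r_row, r_col)` in
#'   pixel units, painted red where they fall strictly inside a band.
#' @return An object of class `mh_mask_geometry`.
#' @export
mask_geometry <- function(image_size = 256L,
                          pixel_pitch = mh_default_pitch(),
                          band_thickness_um = c(green = 115, yellow = 84,
                                                sky_blue = 27, blue = 31),
                          gap_um = c(ilm = 500, opl = 465, elm = 320,
                                     ez = 360, base = 725),
                          top_margin_px = NULL,
                          irf_blobs = list()) {
  image_size <- as.integer(image_size)
  stopifnot(image_size >= 16, pixel_pitch > 0)
  need_bands <- c("green", "yellow", "sky_blue", "blue")
  need_gaps <- c("ilm", "opl", "elm", "ez", "base")
  if (!all(need_bands %in% names(band_thickness_um)) ||
      any(band_thickness_um[need_bands] <= 0))
    mh_stop("mh_invalid", "band_thickness_um needs positive %s",
            paste(need_bands, collapse = "/"))
  if (!all(need_gaps %in% names(gap_um)))
    mh_stop("mh_invalid", "gap_um needs %s", paste(need_gaps, collapse = "/"))
  width_um <- image_size * pixel_pitch
  if (any(gap_um[need_gaps] < 0) || any(gap_um[need_gaps] > width_um))
    mh_stop("mh_invalid",
            "gaps must lie in [0, %.0f] um (image physical width)", width_um)
  th_px <- stats::setNames(
    pmax(1L, as.integer(round(band_thickness_um[need_bands] / pixel_pitch))),
    need_bands)
  total <- sum(th_px)
  if (is.null(top_margin_px))
    top_margin_px <- as.integer((image_size - total) %/% 2)
  top_margin_px <- as.integer(top_margin_px)
  if (top_margin_px < 1 || top_margin_px + total - 1 > image_size)
    mh_stop("mh_invalid", "retina (%d rows at row %d) does not fit in %d rows",
            total, top_margin_px, image_size)
  structure(list(image_size = image_size, pixel_pitch = pixel_pitch,
                 band_thickness_um = band_thickness_um[need_bands],
                 band_thickness_px = th_px,
                 gap_um = gap_um[need_gaps],
                 top_margin_px = top_margin_px,
                 irf_blobs = irf_blobs),
            class = "mh_mask_geometry")
}

#' Render a synthetic macular-hole layer mask with ground truth
#'
#' Rasterises a [mask_geometry()] into a [layer_mask()] and returns the
#' morphometry the geometry implies: boundary defect lengths (gap width at
#' the OPL/ELM/EZ interfaces), per-band shortest defect lengths (narrowest
#' gap across the band; 0 when the band is unbroken), minimum linear diameter
#' and base diameter of the hole, and per-band pixel areas, together with the
#' combination features computed from them. Lengths are rasterised widths
#' multiplied by the pixel pitch, so extraction on the rendered mask recovers
#' them up to the 1-pixel convention difference between gap width and
#' centre-to-centre pixel distance.
#'
#' @param geometry a [mask_geometry()].
#' @return A list with elements `mask` ([layer_mask()]) and `ground_truth`
#'   (named list of morphometric features).
#' @export
render_synthetic_mask <- function(geometry) {
  stopifnot(inherits(geometry, "mh_mask_geometry"))
  n <- geometry$image_size
  pitch <- geometry$pixel_pitch
  th <- geometry$band_thickness_px
  r0 <- geometry$top_margin_px
  # first row of each band and the boundary knot rows
  band_start <- r0 + c(0L, cumsum(th))[1:4]
  band_end <- band_start + th - 1L
  names(band_start) <- names(band_end) <- names(th)
  # width knots sit on the rows just above each interface, so the bottom row
  # of a band carries exactly that boundary's configured gap
  knot_rows <- c(ilm = band_start[["green"]], opl = band_end[["green"]],
                 elm = band_end[["yellow"]], ez = band_end[["sky_blue"]],
                 base = band_end[["blue"]])
  knot_w_um <- geometry$gap_um[c("ilm", "opl", "elm", "ez", "base")]
  rows <- band_start[["green"]]:band_end[["blue"]]
  w_um <- stats::approx(knot_rows, knot_w_um, xout = rows, rule = 2,
                        ties = mean)$y
  w_px <- as.integer(round(w_um / pitch))
  w_px <- pmin(w_px, n)
  names(w_px) <- rows

  lab <- matrix(0L, n, n)
  left_count <- (n - w_px) %/% 2L  # columns left of the gap, per retinal row
  band_class <- c(green = 1L, yellow = 2L, sky_blue = 3L, blue = 4L)
  for (b in names(band_class)) {
    for (r in band_start[[b]]:band_end[[b]]) {
      lab[r, ] <- band_class[[b]]
      w <- w_px[[as.character(r)]]
      if (w > 0) {
        lc <- left_count[[as.character(r)]]
        lab[r, (lc + 1L):(lc + w)] <- 0L
      }
    }
  }

  # IRF blobs: painted only where the full 8-neighbourhood is one band class,
  # so band interfaces and the hole walls are left intact
  irf_px <- 0L
  irf_by_band <- c(green = 0L, yellow = 0L, sky_blue = 0L, blue = 0L)
  for (blob in geometry$irf_blobs) {
    rr <- max(2L, floor(blob$row - blob$r_row)):min(n - 1L, ceiling(blob$row + blob$r_row))
    cc <- max(2L, floor(blob$col - blob$r_col)):min(n - 1L, ceiling(blob$col + blob$r_col))
    for (r in rr) for (c in cc) {
      if (((r - blob$row) / blob$r_row)^2 + ((c - blob$col) / blob$r_col)^2 > 1)
        next
      cls <- lab[r, c]
      if (cls < 1L || cls > 4L) next
      nb <- lab[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
      if (all(nb == cls | nb == 5L)) {
        lab[r, c] <- 5L
        irf_px <- irf_px + 1L
        bname <- names(band_class)[cls]
        irf_by_band[bname] <- irf_by_band[bname] + 1L
      }
    }
  }

  broken <- any(w_px > 0)
  # ground-truth boundary defect lengths: union of the gaps on the two rows
  # forming each interface
  gap_cols <- function(r) {
    w <- w_px[[as.character(r)]]
    if (w == 0) return(integer(0))
    lc <- left_count[[as.character(r)]]
    (lc + 1L):(lc + w)
  }
  interface_gap <- function(upper_band, lower_band) {
    length(union(gap_cols(band_end[[upper_band]]),
                 gap_cols(band_start[[lower_band]])))
  }
  gt <- list()
  gt[["OPL-DL"]] <- interface_gap("green", "yellow") * pitch
  gt[["ELM-DL"]] <- interface_gap("yellow", "sky_blue") * pitch
  gt[["EZ-DL"]] <- interface_gap("sky_blue", "blue") * pitch

  band_sdl <- function(b) {
    w <- w_px[as.character(band_start[[b]]:band_end[[b]])]
    if (any(w == 0)) return(0)  # band is connected: no defect
    min(w) * pitch
  }
  gt[["Green-sDL"]] <- band_sdl("green")
  gt[["ONL-DL"]] <- band_sdl("yellow")
  gt[["Sky blue-sDL"]] <- band_sdl("sky_blue")
  gt[["Blue-sDL"]] <- band_sdl("blue")

  cavity <- w_px > 0
  gt[["Hole-min"]] <- if (any(cavity)) min(w_px[cavity]) * pitch else 0
  gt[["BDM"]] <- if (any(cavity)) w_px[[max(which(cavity))]] * pitch else 0

  counts <- tabulate(lab + 1L, nbins = 6L)
  gt[["Area IRF"]] <- counts[6]
  gt[["Area-green"]] <- counts[2]
  gt[["Area-yellow"]] <- counts[3]
  gt[["Area-sky_blue"]] <- counts[4]
  gt[["Area-blue"]] <- counts[5]

  # combination features implied by the geometry (NA where undefined)
  for (def in mh_combination_defs()) {
    x <- gt[[def$x]]; y <- gt[[def$y]]
    gt[[def$name]] <- if (def$op == "diff") x - y
    else if (y != 0) x / y else NA_real_
  }

  mask <- layer_mask(lab, pitch_x = pitch, pitch_y = pitch,
                     provenance = "render_synthetic_mask")
  # the blobs must not have changed the band topology
  for (b in names(band_class)) {
    comps <- EBImage::bwlabel(mask$labels == band_class[[b]])
    ncomp <- max(comps)
    expected <- if (band_sdl(b) > 0) 2L else 1L
    if (ncomp != expected)
      mh_stop("mh_invalid",
              "IRF blobs break the %s band into %d components", b, ncomp)
  }
  list(mask = mask, ground_truth = gt)
}

#' Draw a random plausible macular-hole geometry
#'
#' Samples hole widths, band thicknesses and up to two marginal IRF blobs in
#' ranges consistent with the calibrated cohort tables. Used for round-trip
#' testing of the feature extractor against renderer ground truth.
#'
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [mask_geometry()].
#' @export
random_mask_geometry <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pitch <- mh_default_pitch()
  th <- c(green = stats::runif(1, 100, 130), yellow = stats::runif(1, 70, 100),
          sky_blue = stats::runif(1, 23, 35), blue = stats::runif(1, 27, 42))
  opl <- stats::runif(1, 260, 650)
  gaps <- c(ilm = opl + stats::runif(1, 0, 150),
            opl = opl,
            elm = stats::runif(1, 200, 600),
            ez = stats::runif(1, 220, 650),
            base = stats::runif(1, 550, 900))
  geom <- mask_geometry(band_thickness_um = th, gap_um = gaps)
  # place 0-2 IRF blobs inside the yellow band flanks, clear of the walls
  n_blob <- sample(0:2, 1)
  if (n_blob > 0) {
    yellow_rows_px <- geom$band_thickness_px[["yellow"]]
    r_top <- geom$top_margin_px + geom$band_thickness_px[["green"]]
    max_gap_px <- ceiling(max(gaps) / pitch)
    flank <- (256 - max_gap_px) %/% 2  # columns available left of any gap
    blobs <- lapply(seq_len(n_blob), function(i) {
      side <- sample(c(-1, 1), 1)
      col <- if (side < 0) stats::runif(1, 12, max(13, flank - 12))
      else stats::runif(1, min(243, 256 - flank + 12), 244)
      list(row = r_top + yellow_rows_px / 2,
           col = col,
           r_row = stats::runif(1, 1.5, max(2, yellow_rows_px / 2 - 3)),
           r_col = stats::runif(1, 2, 6))
    })
    geom$irf_blobs <- blobs
  }
  geom
}
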