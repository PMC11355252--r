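# Feature extraction from colour-annotated layer masks: the three handcrafted
# families (boundary defect lengths, per-band shortest defect lengths, hole
# diameters) plus band areas, and the composition of the full 41-feature
# record from morphometry and clinical data.

band_class_of <- function(band) {
  cls <- c(green = 1L, yellow = 2L, sky_blue = 3L, blue = 4L, irf = 5L)
  if (is.character(band)) {
    if (!band %in% names(cls)) mh_stop("mh_invalid", "unknown band '%s'", band)
    cls[[band]]
  } else as.integer(band)
}

#' Split a coloured band into the components flanking the hole
#'
#' Labels the connected components of one band class. A broken band yields
#' the two components flanking the central hole (ordered left, right); an
#' unbroken band yields a single component and a `no_defect` flag. More than
#' two components signal a malformed annotation.
#'
#' @param mask a [layer_mask()].
#' @param band_class class id 1-5 or band name (`"green"`, `"yellow"`,
#'   `"sky_blue"`, `"blue"`, `"irf"`).
#' @return A list with `components` (list of two-column `(row, col)` pixel
#'   matrices) and `no_defect` (logical).
#' @export
split_band <- function(mask, band_class) {
  stopifnot(inherits(mask, "layer_mask"))
  cls <- band_class_of(band_class)
  sel <- mask$labels == cls
  if (!any(sel))
    mh_stop("mh_missing_layer", "class %d absent from mask", cls)
  labs <- EBImage::bwlabel(sel)
  ncomp <- max(labs)
  comps <- lapply(seq_len(ncomp), function(i) which(labs == i, arr.ind = TRUE))
  if (ncomp > 2)
    mh_stop("mh_ambiguous_band",
            "band class %d splits into %d components", cls, ncomp)
  if (ncomp == 1)
    return(list(components = comps, no_defect = TRUE))
  # order left / right by centroid column
  ord <- order(vapply(comps, function(m) mean(m[, 2]), numeric(1)))
  list(components = comps[ord], no_defect = FALSE)
}

# Interface pixels between two vertically adjacent band classes: positions
# (row, col) of the upper-class pixel lying directly above a lower-class
# pixel.
interface_pixels <- function(mask, upper, lower) {
  lab <- mask$labels
  n <- nrow(lab)
  hit <- lab[-n, , drop = FALSE] == upper & lab[-1, , drop = FALSE] == lower
  which(hit, arr.ind = TRUE)
}

#' Defect length along a layer boundary
#'
#' The inter-edge distance across the hole for the OPL (green/yellow
#' interface), ELM (yellow/sky-blue) or EZ (sky-blue/blue) boundary: the
#' Euclidean distance between the two interface endpoints flanking the
#' central gap, measured edge-to-edge horizontally (gap width) and
#' centre-to-centre vertically, scaled by the pixel pitch. 0 when the
#' interface is unbroken at the central column.
#'
#' @param mask a [layer_mask()].
#' @param boundary `"OPL"`, `"ELM"` or `"EZ"`.
#' @param horizontal_only if `TRUE`, ignore the vertical offset between the
#'   endpoints (sensitivity analysis).
#' @return Length in micrometres.
#' @export
defect_length <- function(mask, boundary = c("OPL", "ELM", "EZ"),
                          horizontal_only = FALSE) {
  stopifnot(inherits(mask, "layer_mask"))
  boundary <- match.arg(boundary)
  pair <- switch(boundary, OPL = c(1L, 2L), ELM = c(2L, 3L), EZ = c(3L, 4L))
  for (cls in pair) if (!any(mask$labels == cls))
    mh_stop("mh_missing_layer", "class %d absent from mask", cls)
  ip <- interface_pixels(mask, pair[1], pair[2])
  if (nrow(ip) == 0)
    mh_stop("mh_missing_layer", "no %s interface found in mask", boundary)
  center <- (ncol(mask$labels) + 1L) %/% 2L
  cols <- ip[, 2]
  if (center %in% cols) return(0)
  left_cols <- cols[cols < center]
  right_cols <- cols[cols > center]
  if (!length(left_cols) || !length(right_cols))
    mh_stop("mh_ambiguous_band",
            "%s interface does not flank the central column", boundary)
  lc <- max(left_cols)
  rc <- min(right_cols)
  lr <- ip[ip[, 2] == lc, 1][1]
  rr <- ip[ip[, 2] == rc, 1][1]
  dx <- (rc - lc - 1L) * mask$pitch_x
  dy <- if (horizontal_only) 0 else (rr - lr) * mask$pitch_y
  unname(sqrt(dx^2 + dy^2))
}

# Pixels of a component lying on its boundary (some 4-neighbour outside the
# component or the image); the minimum inter-component distance is always
# attained between boundary pixels.
component_boundary <- function(px, dims) {
  keys <- px[, 1] + (px[, 2] - 1) * dims[1]
  inside <- rep(FALSE, prod(dims))
  inside[keys] <- TRUE
  at <- function(r, c) {
    ok <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2]
    res <- rep(FALSE, length(r))
    res[ok] <- inside[r[ok] + (c[ok] - 1) * dims[1]]
    res
  }
  full <- at(px[, 1] - 1, px[, 2]) & at(px[, 1] + 1, px[, 2]) &
    at(px[, 1], px[, 2] - 1) & at(px[, 1], px[, 2] + 1)
  px[!full, , drop = FALSE]
}

#' Shortest defect length of a coloured band
#'
#' Minimum Euclidean distance (pixel centre to pixel centre, scaled by the
#' pixel pitch) between the two components of a band flanking the hole.
#' Returns 0 with attribute `no_defect` when the band is unbroken.
#'
#' @inheritParams split_band
#' @return Length in micrometres.
#' @export
shortest_defect_length <- function(mask, band_class) {
  stopifnot(inherits(mask, "layer_mask"))
  sp <- split_band(mask, band_class)
  if (sp$no_defect) return(structure(0, no_defect = TRUE))
  dims <- dim(mask$labels)
  a <- component_boundary(sp$components[[1]], dims)
  b <- component_boundary(sp$components[[2]], dims)
  dr <- outer(a[, 1], b[, 1], `-`) * mask$pitch_y
  dc <- outer(a[, 2], b[, 2], `-`) * mask$pitch_x
  sqrt(min(dr^2 + dc^2))
}

#' Hole diameters: minimum linear diameter and base diameter
#'
#' The hole cavity is the background seen at the central column within the
#' retinal span (from the top of the green band down to the deepest blue
#' row, the RPE level). `Hole-min` is the narrowest horizontal background run
#' through the central column over those rows; `BDM` is the run width at the
#' deepest cavity row, immediately above the RPE. Both are scaled by the
#' lateral pitch.
#'
#' @param mask a [layer_mask()].
#' @return Named numeric `c("Hole-min" = ..., "BDM" = ...)` in micrometres.
#' @export
hole_diameters <- function(mask) {
  stopifnot(inherits(mask, "layer_mask"))
  lab <- mask$labels
  retinal <- lab >= 1L & lab <= 4L
  if (!any(lab == 4L))
    mh_stop("mh_missing_layer", "blue band (EZ-RPE) absent: no RPE level")
  rows_ret <- range(which(apply(retinal, 1, any)))
  rpe_row <- max(which(apply(lab == 4L, 1, any)))
  center <- (ncol(lab) + 1L) %/% 2L
  runs <- integer(0)
  deepest <- NA_integer_
  for (r in rows_ret[1]:rpe_row) {
    if (lab[r, center] != 0L) next
    row <- lab[r, ] == 0L
    lo <- center
    while (lo > 1 && row[lo - 1]) lo <- lo - 1
    hi <- center
    while (hi < ncol(lab) && row[hi + 1]) hi <- hi + 1
    runs <- c(runs, hi - lo + 1L)
    deepest <- r
  }
  if (!length(runs))
    mh_stop("mh_no_hole", "no background cavity at the central column")
  bdm_row <- lab[deepest, ] == 0L
  lo <- center; while (lo > 1 && bdm_row[lo - 1]) lo <- lo - 1
  hi <- center; while (hi < ncol(lab) && bdm_row[hi + 1]) hi <- hi + 1
  c("Hole-min" = min(runs) * mask$pitch_x,
    "BDM" = (hi - lo + 1) * mask$pitch_x)
}

#' Per-band pixel areas
#'
#' Pixel counts of the green, yellow, sky-blue and blue bands and of the red
#' intraretinal fluid, in pixels squared of the trimmed image. Absent classes
#' count 0.
#'
#' @param mask a [layer_mask()].
#' @return Named numeric vector.
#' @export
band_areas <- function(mask) {
  stopifnot(inherits(mask, "layer_mask"))
  counts <- tabulate(mask$labels + 1L, nbins = 6L)
  c("Area-green" = counts[2], "Area-yellow" = counts[3],
    "Area-sky_blue" = counts[4], "Area-blue" = counts[5],
    "Area IRF" = counts[6])
}

#' Extract all mask-derived morphometric features
#'
#' Runs the three handcrafted feature families plus band areas on one mask
#' and returns the 14 morphometric base features under their canonical names.
#' The yellow-band shortest defect length is reported as `ONL-DL`.
#'
#' @param mask a [layer_mask()].
#' @return Named list of 14 features.
#' @export
extract_mask_features <- function(mask) {
  hd <- hole_diameters(mask)
  ar <- band_areas(mask)
  out <- list(
    "BDM" = unname(hd[["BDM"]]),
    "Hole-min" = unname(hd[["Hole-min"]]),
    "OPL-DL" = defect_length(mask, "OPL"),
    "ELM-DL" = defect_length(mask, "ELM"),
    "EZ-DL" = defect_length(mask, "EZ"),
    "Green-sDL" = as.numeric(shortest_defect_length(mask, "green")),
    "ONL-DL" = as.numeric(shortest_defect_length(mask, "yellow")),
    "Sky blue-sDL" = as.numeric(shortest_defect_length(mask, "sky_blue")),
    "Blue-sDL" = as.numeric(shortest_defect_length(mask, "blue")),
    "Area IRF" = unname(ar[["Area IRF"]]),
    "Area-green" = unname(ar[["Area-green"]]),
    "Area-yellow" = unname(ar[["Area-yellow"]]),
    "Area-sky_blue" = unname(ar[["Area-sky_blue"]]),
    "Area-blue" = unname(ar[["Area-blue"]])
  )
  out
}

#' Compose the full 41-feature record
#'
#' Merges mask morphometry with a clinical record and computes the 16
#' combination features exactly from their defining arithmetic. A zero ratio
#' denominator raises a condition of class `mh_missing_data`; such records
#' are excluded downstream, mirroring the cohort's no-missing-data inclusion
#' criterion.
#'
#' @param morphometrics named list or one-row data.frame with the 14 base
#'   morphometric features.
#' @param clinical named list or one-row data.frame with the 11 background
#'   features (7 categorical, 4 continuous).
#' @return One-row data.frame with the 41 canonical feature columns.
#' @export
compose_features <- function(morphometrics, clinical) {
  fn <- mh_feature_names()
  morphometrics <- as.list(morphometrics)
  clinical <- as.list(clinical)
  need_m <- c(fn$lengths, fn$areas)
  need_c <- c(fn$categorical, fn$clinical_continuous)
  miss <- c(setdiff(need_m, names(morphometrics)),
            setdiff(need_c, names(clinical)))
  if (length(miss))
    mh_stop("mh_invalid", "missing features: %s", paste(miss, collapse = ", "))
  vals <- c(clinical[need_c], morphometrics[need_m])
  num <- unlist(vals[c(fn$clinical_continuous, need_m)])
  if (any(!is.finite(num)))
    mh_stop("mh_missing_data", "non-finite base feature value")
  d <- as.data.frame(vals, check.names = FALSE)
  for (def in mh_combination_defs()) {
    if (def$op == "ratio" && d[[def$y]] == 0)
      mh_stop("mh_missing_data",
              "zero denominator in %s: record has missing data", def$name)
  }
  d <- add_combination_features(d)
  d <- d[, fn$all, drop = FALSE]
  if (ncol(d) != 41L) mh_stop("mh_invalid", "expected 41 features")
  d
}
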