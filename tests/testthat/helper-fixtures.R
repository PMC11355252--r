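# Shared fixture builders: small constructed masks and clinical records.

# Horizontal-band mask: bands = list(list(class=, rows=, gap=<cols or NULL>))
make_band_mask <- function(nr, nc, bands, pitch = 3.83) {
  lab <- matrix(0L, nr, nc)
  for (b in bands) {
    lab[b$rows, ] <- as.integer(b$class)
    if (!is.null(b$gap)) lab[b$rows, b$gap] <- 0L
  }
  layer_mask(lab, pitch_x = pitch, pitch_y = pitch)
}

# A four-band retina with per-band centred gaps (in columns), hole through all
make_retina_mask <- function(nc = 256, gaps = c(green = 80, yellow = 80,
                                                sky_blue = 80, blue = 80),
                             pitch = 3.83) {
  rows <- list(green = 11:40, yellow = 41:62, sky_blue = 63:69, blue = 70:77)
  bands <- lapply(names(rows), function(b) {
    w <- gaps[[b]]
    gap <- if (w > 0) {
      lc <- (nc - w) %/% 2
      (lc + 1):(lc + w)
    } else NULL
    list(class = match(b, c("green", "yellow", "sky_blue", "blue")),
         rows = rows[[b]], gap = gap)
  })
  make_band_mask(90, nc, bands, pitch)
}

demo_clinical <- function() {
  list("Sex" = "Man", "Method" = "Phacovitrectomy", "Affected eye" = "Right",
       "Stage" = "3", "ILM" = "Peel", "VMT" = "Present", "PVD" = "Complete",
       "Age" = 65, "Preoperative BCVA" = 0.5, "Axial length" = 24,
       "Disease duration" = 2)
}

# small cohort quickly: defaults but reduced CV effort
fast_config <- function(seed = 1, ...) {
  pipeline_config(n_repeats = 10L, n_pretests = 10L, seed = seed, ...)
}
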