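test_that("crop_to_trim extracts the standard window with axial pitch", {
  src <- matrix(0L, 496, 768)
  src[240:260, ] <- 1L
  m <- crop_to_trim(src, center = c(248, 384))
  expect_s3_class(m, "layer_mask")
  expect_equal(dim(m$labels), c(256L, 256L))
  expect_equal(m$pitch_x, 1900 / 496, tolerance = 1e-12)
  # idempotence: cropping the crop about its own centre reproduces it
  m2 <- crop_to_trim(m$labels, center = c(128, 128))
  expect_identical(m2$labels, m$labels)
  expect_error(crop_to_trim(src, center = c(1, 1)),
               class = "mh_out_of_bounds")
})

test_that("split_band distinguishes broken, unbroken and malformed bands", {
  m <- make_band_mask(20, 256, list(list(class = 3, rows = 5:8,
                                         gap = 101:180)))
  sp <- split_band(m, 3)
  expect_false(sp$no_defect)
  expect_length(sp$components, 2)
  expect_lt(max(sp$components[[1]][, 2]), 101)
  expect_gt(min(sp$components[[2]][, 2]), 180)

  mu <- make_band_mask(20, 256, list(list(class = 3, rows = 5:8)))
  expect_true(split_band(mu, 3)$no_defect)
  expect_error(split_band(mu, 4), class = "mh_missing_layer")

  m3 <- make_band_mask(20, 256, list(list(class = 3, rows = 5:8,
                                          gap = c(40:60, 101:180))))
  expect_error(split_band(m3, 3), class = "mh_ambiguous_band")
})

test_that("defect_length measures gap width and endpoint offset", {
  # flat OPL interface with an 80-column central gap
  m <- make_band_mask(20, 256, list(
    list(class = 1, rows = 1:5, gap = 101:180),
    list(class = 2, rows = 6:10, gap = 101:180)))
  expect_equal(defect_length(m, "OPL"), 80 * 3.83, tolerance = 1e-9)

  # unbroken interface
  mu <- make_band_mask(20, 256, list(list(class = 1, rows = 1:5),
                                     list(class = 2, rows = 6:10)))
  expect_equal(defect_length(mu, "OPL"), 0)
  expect_error(defect_length(mu, "EZ"), class = "mh_missing_layer")

  # 18-pixel vertical offset between the endpoints: Pythagorean oracle
  lab <- matrix(0L, 60, 256)
  lab[1:5, 1:100] <- 1L; lab[6:10, 1:100] <- 2L
  lab[19:23, 181:256] <- 1L; lab[24:28, 181:256] <- 2L
  mo <- layer_mask(lab, pitch_x = 3.83, pitch_y = 3.83)
  expect_equal(defect_length(mo, "OPL"), sqrt(80^2 + 18^2) * 3.83,
               tolerance = 1e-9)
  expect_equal(defect_length(mo, "OPL", horizontal_only = TRUE), 80 * 3.83,
               tolerance = 1e-9)
})

test_that("shortest_defect_length equals pixel centre-to-centre distance", {
  # two single-pixel components 10 columns apart on the same row
  lab <- matrix(0L, 16, 32)
  lab[8, 10] <- 2L; lab[8, 20] <- 2L
  m <- layer_mask(lab, pitch_x = 3.83, pitch_y = 3.83)
  expect_equal(shortest_defect_length(m, 2), 10 * 3.83, tolerance = 1e-9)

  # nearest pixels (row 120, col 99) and (row 124, col 180)
  lab2 <- matrix(0L, 200, 256)
  lab2[110:120, 1:99] <- 3L
  lab2[124:130, 180:256] <- 3L
  m2 <- layer_mask(lab2, pitch_x = 3.83, pitch_y = 3.83)
  expect_equal(shortest_defect_length(m2, 3), sqrt(81^2 + 4^2) * 3.83,
               tolerance = 1e-9)

  mu <- make_band_mask(20, 64, list(list(class = 2, rows = 5:8)))
  r <- shortest_defect_length(mu, 2)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "no_defect"))
})

test_that("shortest_defect_length matches the exhaustive pairwise oracle", {
  oracle <- function(mask, cls) {
    px <- which(mask$labels == cls, arr.ind = TRUE)
    labs <- EBImage::bwlabel(mask$labels == cls)
    a <- which(labs == 1, arr.ind = TRUE)
    b <- which(labs == 2, arr.ind = TRUE)
    best <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      d <- sqrt(((a[i, 1] - b[j, 1]) * mask$pitch_y)^2 +
                  ((a[i, 2] - b[j, 2]) * mask$pitch_x)^2)
      best <- min(best, d)
    }
    best
  }
  set.seed(42)
  for (rep in 1:8) {
    lab <- matrix(0L, 48, 64)
    # irregular left and right blobs with ragged facing edges
    for (r in 10:30) {
      wl <- sample(3:20, 1); lab[r, 1:wl] <- 2L
      wr <- sample(3:20, 1); lab[r, (64 - wr):64] <- 2L
    }
    m <- layer_mask(lab, pitch_x = 3.83, pitch_y = 3.83)
    expect_equal(as.numeric(shortest_defect_length(m, 2)), oracle(m, 2),
                 tolerance = 1e-9)
  }
})

test_that("hole diameters read the cavity runs", {
  # straight-walled (rectangular) hole: Hole-min equals BDM
  m <- make_retina_mask(gaps = c(green = 77, yellow = 77, sky_blue = 77,
                                 blue = 77))
  hd <- hole_diameters(m)
  expect_equal(unname(hd["Hole-min"]), unname(hd["BDM"]))
  expect_equal(unname(hd["Hole-min"]), 77 * 3.83, tolerance = 1e-9)

  # waisted hole: narrow at the sky-blue level, wide base
  m2 <- make_retina_mask(gaps = c(green = 120, yellow = 100, sky_blue = 77,
                                  blue = 189))
  hd2 <- hole_diameters(m2)
  expect_equal(unname(hd2["Hole-min"]), 77 * 3.83, tolerance = 1e-9)
  expect_equal(unname(hd2["BDM"]), 189 * 3.83, tolerance = 1e-9)

  m3 <- make_retina_mask(gaps = c(green = 0, yellow = 0, sky_blue = 0,
                                  blue = 0))
  expect_error(hole_diameters(m3), class = "mh_no_hole")
})

test_that("band areas count pixels per class", {
  m <- make_band_mask(40, 256, list(list(class = 1, rows = 1:30)))
  m$labels[1:30, 101:256] <- 0L  # leave a 100x30 green rectangle
  ar <- band_areas(m)
  expect_equal(unname(ar["Area-green"]), 3000)
  expect_equal(unname(ar["Area IRF"]), 0)
  expect_equal(unname(ar["Area-blue"]), 0)
})

test_that("pitch scaling doubles lengths and leaves pixel areas unchanged", {
  out <- render_synthetic_mask(random_mask_geometry(seed = 12))
  m1 <- out$mask
  m2 <- layer_mask(m1$labels, pitch_x = 2 * m1$pitch_x,
                   pitch_y = 2 * m1$pitch_y)
  f1 <- extract_mask_features(m1)
  f2 <- extract_mask_features(m2)
  for (f in mh_feature_names()$lengths)
    expect_equal(f2[[f]], 2 * f1[[f]], tolerance = 1e-9)
  for (f in mh_feature_names()$areas)
    expect_identical(f2[[f]], f1[[f]])
})

test_that("rendered stenosis ordering is preserved by extraction", {
  pitch <- 3.83
  for (s in 1:5) {
    set.seed(s)
    opl <- runif(1, 400, 650)
    elm <- runif(1, 200, opl - 60)
    g <- mask_geometry(gap_um = c(ilm = opl, opl = opl, elm = elm,
                                  ez = elm, base = 750))
    f <- extract_mask_features(render_synthetic_mask(g)$mask)
    expect_gt(f[["OPL-DL"]], f[["ONL-DL"]])
  }
})

test_that("compose_features emits the exact 41-feature record", {
  morpho <- extract_mask_features(make_retina_mask())
  morpho[["OPL-DL"]] <- 465.09
  morpho[["ONL-DL"]] <- 313.28
  rec <- compose_features(morpho, demo_clinical())
  expect_equal(ncol(rec), 41L)
  expect_identical(names(rec), mh_feature_names()$all)
  expect_equal(rec[["(OPL-DL) - (ONL-DL)"]], 151.81)
  expect_equal(rec[["(OPL-DL)/(ONL-DL)"]], 465.09 / 313.28)

  morpho[["ONL-DL"]] <- morpho[["OPL-DL"]]
  rec2 <- compose_features(morpho, demo_clinical())
  expect_equal(rec2[["(OPL-DL) - (ONL-DL)"]], 0)
  expect_equal(rec2[["(OPL-DL)/(ONL-DL)"]], 1)

  morpho[["Hole-min"]] <- 0
  expect_error(compose_features(morpho, demo_clinical()),
               class = "mh_missing_data")
})

test_that("extraction recovers renderer ground truth on random geometries", {
  # short module-level check; the 50-geometry suite runs in the acceptance
  # tests
  for (s in c(2, 5, 9)) {
    out <- render_synthetic_mask(random_mask_geometry(seed = s))
    f <- extract_mask_features(out$mask)
    gt <- out$ground_truth
    for (k in mh_feature_names()$lengths)
      expect_lt(abs(f[[k]] - gt[[k]]), 2 * out$mask$pitch_x + 1e-9)
    for (k in mh_feature_names()$areas)
      if (gt[[k]] > 0) expect_lt(abs(f[[k]] - gt[[k]]) / gt[[k]], 0.03)
  }
})
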