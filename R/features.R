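#' Canonical feature names
#'
#' The prognosis pipeline works on a fixed table of 41 named features per
#' patient plus a binary prognosis label (`Group`, levels `"A"` good /
#' `"B"` poor). The 41 features comprise 7 categorical background variables,
#' 4 continuous clinical variables, 9 morphometric lengths (micrometres),
#' 5 band areas (pixels squared of the 256x256 trimmed mask), and 16
#' combination features (differences and ratios) computed deterministically
#' from the base lengths.
#'
#' `mh_feature_names()` returns the canonical column names grouped by kind;
#' `clinical_features()` returns the 9 preoperative clinical variables used by
#' the clinical-only control model; `morphometric_features()` returns the 14
#' mask-derived base features. The yellow-band shortest defect length is
#' canonically named `"ONL-DL"` (the yellow band is the outer nuclear layer).
#'
#' @return For `mh_feature_names()`, a list with elements `categorical`,
#'   `clinical_continuous`, `lengths`, `areas`, `combinations`, `all` and
#'   `label`. The other helpers return character vectors.
#' @export
#' @examples
#' length(mh_feature_names()$all)  # 41
mh_feature_names <- function() {
  categorical <- c("Sex", "Method", "Affected eye", "Stage", "ILM", "VMT", "PVD")
  clinical_continuous <- c("Age", "Preoperative BCVA", "Axial length",
                           "Disease duration")
  lengths <- c("BDM", "Hole-min", "OPL-DL", "ELM-DL", "EZ-DL",
               "Green-sDL", "ONL-DL", "Sky blue-sDL", "Blue-sDL")
  areas <- c("Area IRF", "Area-green", "Area-yellow", "Area-sky_blue",
             "Area-blue")
  combinations <- vapply(mh_combination_defs(), `[[`, character(1), "name")
  # Table order: background block, then lengths, then areas, then combinations
  all <- c("Sex", "Age", "Preoperative BCVA", "Method", "Affected eye",
           "Axial length", "Stage", "Disease duration", "ILM", "VMT", "PVD",
           lengths, areas, combinations)
  list(categorical = categorical,
       clinical_continuous = clinical_continuous,
       lengths = lengths,
       areas = areas,
       combinations = combinations,
       all = all,
       label = "Group")
}

# Definitions of the 16 combination features. Each entry gives the canonical
# column name, the operation and the two base features it combines.
mh_combination_defs <- function() {
  d <- function(x, y) list(name = sprintf("(%s) - (%s)", x, y),
                           op = "diff", x = x, y = y)
  r <- function(x, y) list(name = sprintf("(%s)/(%s)", x, y),
                           op = "ratio", x = x, y = y)
  # BDM combinations are printed without parentheses around BDM
  list(
    d("OPL-DL", "ONL-DL"),
    d("ELM-DL", "ONL-DL"),
    d("OPL-DL", "Green-sDL"),
    d("ELM-DL", "Sky blue-sDL"),
    d("EZ-DL", "Sky blue-sDL"),
    d("EZ-DL", "Blue-sDL"),
    list(name = "BDM - (Blue-sDL)", op = "diff", x = "BDM", y = "Blue-sDL"),
    list(name = "BDM - (Hole-min)", op = "diff", x = "BDM", y = "Hole-min"),
    r("Green-sDL", "OPL-DL"),
    r("OPL-DL", "ONL-DL"),
    r("ELM-DL", "ONL-DL"),
    r("ELM-DL", "Sky blue-sDL"),
    r("EZ-DL", "Sky blue-sDL"),
    r("EZ-DL", "Blue-sDL"),
    list(name = "BDM/(Blue-sDL)", op = "ratio", x = "BDM", y = "Blue-sDL"),
    list(name = "BDM/(Hole-min)", op = "ratio", x = "BDM", y = "Hole-min")
  )
}

#' @rdname mh_feature_names
#' @export
clinical_features <- function() {
  # Preoperative clinical information: the surgical-choice variables (Method,
  # ILM peeling) are excluded, leaving 9 variables known before surgery.
  c("Sex", "Age", "Preoperative BCVA", "Affected eye", "Axial length",
    "Stage", "Disease duration", "VMT", "PVD")
}

#' @rdname mh_feature_names
#' @export
morphometric_features <- function() {
  fn <- mh_feature_names()
  c(fn$lengths, fn$areas)
}

# Levels of the categorical features.
mh_categorical_levels <- function() {
  list(
    "Sex" = c("Man", "Woman"),
    "Method" = c("Vitrectomy", "Phacovitrectomy"),
    "Affected eye" = c("Right", "Left"),
    "Stage" = c("2", "3", "4"),
    "ILM" = c("Peel", "Invert", "Not peel"),
    "VMT" = c("Present", "Absent"),
    "PVD" = c("Complete", "Not complete")
  )
}

#' Mask palette and acquisition geometry constants
#'
#' Annotated layer masks use a fixed 6-class palette: 0 background,
#' 1 green (ILM to OPL), 2 yellow (outer nuclear layer, OPL to ELM),
#' 3 sky-blue (ELM to EZ), 4 blue (EZ to RPE), 5 red (intraretinal fluid).
#' `mh_palette()` returns the class table with the RGB colours used when
#' masks are written to PNG.
#'
#' `oct_axial_pitch_um()` is the axial pixel pitch of the source B-scan
#' (1.9 mm over 496 pixels, about 3.83 um/pixel); `oct_lateral_pitch_um()`
#' the lateral pitch of the full scan (9 mm over 768 pixels). `trim_geometry()`
#' describes the 256x256 trimmed crop: physical width in mm (256 axial-pitch
#' pixels) and its angular subtense given the 30 degree / 9 mm scan field.
#'
#' @return `mh_palette()`: a data.frame with columns `class`, `band`, `r`,
#'   `g`, `b`. `trim_geometry()`: a list with `px`, `pitch_um`, `width_mm`,
#'   `angle_deg`.
#' @export
mh_palette <- function() {
  data.frame(
    class = 0:5,
    band = c("background", "green", "yellow", "sky_blue", "blue", "irf"),
    r = c(0, 0, 255, 0, 0, 255),
    g = c(0, 255, 255, 191, 0, 0),
    b = c(0, 0, 0, 255, 255, 0)
  )
}

#' @rdname mh_palette
#' @export
oct_axial_pitch_um <- function() 1900 / 496

#' @rdname mh_palette
#' @export
oct_lateral_pitch_um <- function() 9000 / 768

#' @rdname mh_palette
#' @export
trim_geometry <- function() {
  px <- 256L
  pitch <- oct_axial_pitch_um()
  width_mm <- px * pitch / 1000
  # angular subtense: the 9 mm scan covers 30 degrees
  angle_deg <- width_mm / 9 * 30
  list(px = px, pitch_um = pitch, width_mm = width_mm, angle_deg = angle_deg)
}

# Default isotropic pixel pitch of the trimmed mask, um/pixel (0.98 mm/256 px).
mh_default_pitch <- function() 3.83

# Internal condition helper
mh_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
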