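# Pipeline orchestration, file I/O and the reproducibility manifest.

#' Read and write patient feature tables
#'
#' Feature tables are CSV files with a header of canonical feature names (see
#' [mh_feature_names()]) and a `Group` label column. On read, categorical
#' columns are coerced to their known levels, continuous columns to numeric,
#' and records with missing explanatory values are dropped with a warning
#' (the cohort inclusion criteria admit no missing data).
#'
#' @param path CSV file path.
#' @param table feature data.frame.
#' @return `read_feature_table()` returns the typed data.frame.
#' @export
read_feature_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fn <- mh_feature_names()
  want <- c(fn$all, "Group")
  missing <- setdiff(want, names(d))
  if (length(missing))
    mh_stop("mh_schema", "missing columns: %s", paste(missing, collapse = ", "))
  unknown <- setdiff(names(d), want)
  if (length(unknown))
    mh_stop("mh_schema", "unknown columns: %s", paste(unknown, collapse = ", "))
  lev <- mh_categorical_levels()
  for (f in fn$categorical) {
    bad <- !is.na(d[[f]]) & !d[[f]] %in% lev[[f]]
    if (any(bad))
      mh_stop("mh_schema", "unknown level '%s' in column '%s'",
              d[[f]][bad][1], f)
    d[[f]] <- factor(d[[f]], levels = lev[[f]])
  }
  cont <- setdiff(fn$all, fn$categorical)
  for (f in cont) {
    if (!is.numeric(d[[f]])) {
      v <- suppressWarnings(as.numeric(d[[f]]))
      if (any(is.na(v) & !is.na(d[[f]]) & d[[f]] != ""))
        mh_stop("mh_schema", "non-numeric values in continuous column '%s'", f)
      d[[f]] <- v
    }
  }
  d$Group <- factor(d$Group, levels = c("A", "B"))
  keep <- stats::complete.cases(d[, want])
  if (any(!keep)) {
    warning(sprintf("dropped %d record(s) with missing data", sum(!keep)))
    d <- d[keep, , drop = FALSE]
  }
  rownames(d) <- NULL
  d[, want]
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Extract feature records from a directory of mask PNGs
#'
#' Reads every annotated mask PNG in a directory, extracts the 14
#' morphometric base features, joins the clinical record matched by file stem
#' against the `id` column of the clinical CSV, and composes full 41-feature
#' records. Records failing composition (missing data, zero denominators) are
#' dropped with a warning.
#'
#' @param mask_dir directory of palette PNG masks.
#' @param clinical clinical records: CSV path or data.frame with an `id`
#'   column plus the 11 background features (and optionally `Group`).
#' @param pitch_um isotropic pixel pitch of the masks.
#' @return Feature data.frame (with `Group` when provided).
#' @export
extract_features <- function(mask_dir, clinical, pitch_um = mh_default_pitch()) {
  files <- sort(list.files(mask_dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) mh_stop("mh_invalid", "no PNG masks in %s", mask_dir)
  if (is.character(clinical))
    clinical <- utils::read.csv(clinical, check.names = FALSE,
                                stringsAsFactors = FALSE)
  if (!"id" %in% names(clinical))
    mh_stop("mh_schema", "clinical records need an 'id' column")
  rows <- list()
  dropped <- 0L
  for (f in files) {
    id <- sub("\\.png$", "", basename(f))
    cl <- clinical[clinical$id == id, , drop = FALSE]
    if (nrow(cl) != 1) {
      warning(sprintf("no unique clinical record for mask '%s'; skipped", id))
      next
    }
    mask <- read_layer_mask(f, pitch_x = pitch_um)
    rec <- tryCatch(
      compose_features(extract_mask_features(mask),
                       cl[, setdiff(names(cl), c("id", "Group"))]),
      mh_missing_data = function(e) NULL)
    if (is.null(rec)) {
      dropped <- dropped + 1L
      next
    }
    rec$id <- id
    if ("Group" %in% names(cl)) rec$Group <- cl$Group
    rows[[length(rows) + 1L]] <- rec
  }
  if (dropped > 0)
    warning(sprintf("dropped %d record(s) with missing data", dropped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Reproducibility manifest: configuration hash, input digests and seeds.
# Wall-clock timestamps are deliberately omitted so that rerunning a
# configuration yields byte-identical artifacts.
run_manifest <- function(config, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  cfg <- unclass(config)
  list(tool = "octmh",
       version = as.character(utils::packageVersion("octmh")),
       config = cfg,
       config_hash = unname(tools::md5sum(
         {tf <- tempfile(); writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                        digits = NA), tf); tf})),
       input_digests = digests,
       seed = config$seed)
}

#' Run the full prognosis pipeline and write its artifacts
#'
#' Orchestrates the pipeline end to end: obtain a feature table (read from
#' `features` or simulated from the calibrated generator when absent), select
#' explanatory variables, fix the regularisation constant, evaluate by
#' repeated stratified cross-validation, optionally run the clinical-only
#' control, and write the selection result, a final model bundle trained on
#' the full cohort, the CV report and a reproducibility manifest as JSON to
#' `out_dir`. Rerunning the same configuration reproduces the artifacts
#' byte for byte.
#'
#' @param config an [pipeline_config()], a YAML file path, or a list with
#'   elements accepted by [pipeline_config()] plus optionally `features`
#'   (input CSV path), `out_dir`, `run_control`, `generator` (arguments for
#'   [generator_config()]).
#' @param features optional feature CSV path (overrides `config$features`).
#' @param out_dir output directory (default `"."`).
#' @param run_control also run the clinical-only control experiment.
#' @return Invisibly, a list with `table`, `analysis`, `control`,
#'   `artifacts` (file paths).
#' @export
run_pipeline <- function(config = pipeline_config(), features = NULL,
                         out_dir = ".", run_control = FALSE) {
  extra <- list()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "mh_pipeline_config")) {
    config <- as.list(config)
    extra <- config[setdiff(names(config),
                            names(formals(pipeline_config)))]
    config <- do.call(pipeline_config,
                      config[intersect(names(config),
                                       names(formals(pipeline_config)))])
  }
  if (is.null(features) && !is.null(extra$features))
    features <- extra$features
  if (!is.null(extra$out_dir) && missing(out_dir)) out_dir <- extra$out_dir
  if (!is.null(extra$run_control) && missing(run_control))
    run_control <- isTRUE(extra$run_control)
  inputs <- character(0)
  if (is.null(features)) {
    gen_args <- if (!is.null(extra$generator)) extra$generator else list()
    gen_args$seed <- config$seed
    table <- sample_feature_table(do.call(generator_config, gen_args))
  } else {
    table <- read_feature_table(features)
    inputs <- features
  }
  analysis <- run_analysis(table, config)
  control <- if (run_control) control_experiment(table, config) else NULL

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  wj <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  sel <- analysis$selection
  art$selection <- wj(list(
    p_values = sel$p_values,
    candidates = sel$candidates,
    trace = lapply(sel$trace, function(tr)
      list(iteration = tr$iteration, r2 = as.list(tr$r2),
           dropped = tr$dropped)),
    final_variables = sel$final_variables), "selection.json")

  # final bundle trained on the full cohort at the fixed constant
  y <- as.integer(table$Group == config$positive_class)
  X <- design_matrix(table, sel$final_variables)
  bundle <- fit_model_bundle(X, y, analysis$tuning$c_star,
                             alignment_rule = config$alignment_rule)
  art$model <- wj(list(
    feature_means = as.list(bundle$feature_means),
    feature_sds = as.list(bundle$feature_sds),
    coefficients = as.list(bundle$coefficients),
    intercept = bundle$intercept,
    c_value = bundle$c_value,
    threshold = bundle$threshold,
    hyperparameter_frequencies = as.list(stats::setNames(
      as.integer(analysis$tuning$frequencies),
      names(analysis$tuning$frequencies)))), "model.json")

  report_json <- function(rep) list(
    per_repeat = rep$per_repeat, summary = rep$summary,
    coefficients = rep$coefficients, c_value = rep$c_value,
    variables = rep$variables, seed = rep$config$seed)
  art$report <- wj(report_json(analysis$report), "report.json")
  if (!is.null(control))
    art$control <- wj(report_json(control$report), "control.json")
  art$features <- file.path(out_dir, "features.csv")
  write_feature_table(table, art$features)
  art$manifest <- wj(run_manifest(config, inputs), "manifest.json")
  invisible(list(table = table, analysis = analysis, control = control,
                 artifacts = art))
}
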