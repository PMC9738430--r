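#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the phantom plan, the
#' acquisition defaults, classifier and cross-validation settings, output
#' directory and a single global seed. The global seed fans out to per-stage
#' seeds by a fixed derivation, so stages can be re-run independently yet
#' reproducibly.
#'
#' @param output_dir Run directory (created by [run_pipeline()]).
#' @param seed Global integer seed.
#' @param stages Stages to execute, in order, from
#'   `c("simulate", "extract", "stats", "classify")`.
#' @param plan Phantom plan data frame (see [write_fixture_set()]); `NULL`
#'   selects a default two-tissue, three-magnification plan built by
#'   [default_phantom_plan()].
#' @param wavelength,thickness Acquisition defaults (um).
#' @param classifiers Character vector of algorithms for the classify stage.
#' @param folds,repeats Cross-validation settings.
#' @param alpha Significance level for the ANOVA screen.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L,
                       stages = c("simulate", "extract", "stats", "classify"),
                       plan = NULL, wavelength = 0.55, thickness = 6,
                       classifiers = c("LDA", "QDA", "NB", "kNB", "kNN",
                                       "SVM", "DT", "ANN"),
                       folds = 10L, repeats = 5L, alpha = 0.005) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(plan)) plan <- default_phantom_plan(seed)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = stages, plan = as_tibble(plan),
                 wavelength = wavelength, thickness = thickness,
                 classifiers = classifiers, folds = as.integer(folds),
                 repeats = as.integer(repeats), alpha = alpha),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' The file holds the scalar fields of [run_config()] plus an optional
#' `plan` record list.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  plan <- if (!is.null(cfg$plan)) as_tibble(as.data.frame(cfg$plan)) else NULL
  run_config(output_dir = cfg$output_dir,
             seed = cfg$seed %||% 1L,
             stages = cfg$stages %||% c("simulate", "extract", "stats",
                                        "classify"),
             plan = plan,
             wavelength = cfg$wavelength %||% 0.55,
             thickness = cfg$thickness %||% 6,
             classifiers = cfg$classifiers %||% c("LDA", "QDA", "NB", "kNB",
                                                  "kNN", "SVM", "DT", "ANN"),
             folds = cfg$folds %||% 10L, repeats = cfg$repeats %||% 5L,
             alpha = cfg$alpha %||% 0.005)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default phantom plan: two tissue archetypes, two states, three
#' magnifications
#'
#' The healthy and tumoral archetypes differ in index variance, outer scale
#' and spectral exponent (tumoral: higher variance, shorter outer scale,
#' shallower spectrum), echoing the direction of the reference group
#' statistics for ganglion.
#'
#' @param seed Global seed; per-image seeds are derived from it.
#' @param images_per_cell Phantom images per (tissue, state, magnification)
#'   cell.
#' @return A plan tibble for [write_fixture_set()].
#' @export
default_phantom_plan <- function(seed = 1L, images_per_cell = 1L) {
  cells <- expand.grid(tissue = c("alpha", "beta"),
                       state = c("healthy", "tumoral"),
                       magnification = .magnifications,
                       rep = seq_len(images_per_cell),
                       stringsAsFactors = FALSE)
  sigma <- ifelse(cells$state == "healthy", 0.010, 0.016)
  sigma <- sigma * ifelse(cells$tissue == "beta", 1.3, 1)
  l0 <- ifelse(cells$state == "healthy", 12, 7)
  m <- ifelse(cells$state == "healthy", 1.45, 1.25)
  tibble(tissue = cells$tissue, state = cells$state,
         magnification = cells$magnification,
         sigma_n2 = sigma, outer_scale = l0, exponent = m,
         shape = 256L,
         seed = vapply(seq_len(nrow(cells)),
                       function(i) derive_seed(seed, 100 + i), integer(1)))
}

# provenance header written at the top of every output CSV
provenance_header <- function(config) {
  hash <- rlang::hash(config[setdiff(names(config), "output_dir")])
  c(sprintf("# pcparams %s", as.character(utils::packageVersion("pcparams"))),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %d", config$seed))
}

write_output_csv <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output CSV, skipping the provenance header
#'
#' @param path CSV written by [run_pipeline()].
#' @return A tibble.
#' @export
read_output_csv <- function(path) {
  as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Execute the pipeline
#'
#' Runs the requested stages in order: `simulate` (phantom images +
#' manifest), `extract` (per-image feature table), `stats` (group summary
#' and ANOVA screen) and `classify` (classifier evaluation report). Every
#' output CSV carries a provenance header (package version, config hash,
#' seed); re-running with an identical configuration reproduces identical
#' files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the produced file paths and the
#'   in-memory tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(paths = character())
  log_lines <- provenance_header(config)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if ("simulate" %in% config$stages) {
    acq <- acquisition_config("20x", wavelength = config$wavelength,
                              thickness = config$thickness)
    manifest <- write_fixture_set(config$plan, acq, config$output_dir,
                                  overwrite = TRUE)
    out$manifest <- manifest
    out$paths["manifest"] <- file.path(config$output_dir, "manifest.csv")
    say("simulate: wrote %d images", nrow(manifest))
  }

  if ("extract" %in% config$stages) {
    manifest_path <- file.path(config$output_dir, "manifest.csv")
    if (!file.exists(manifest_path)) stop("extract stage needs a manifest; ",
                                          "run the simulate stage first")
    features <- extract_features_batch(manifest_path)
    n_warn <- sum(nzchar(features$warnings))
    if (n_warn) say("extract: %d image(s) had warnings", n_warn)
    say("extract: %d feature records", nrow(features))
    out$features <- features
    out$paths["features"] <- write_output_csv(
      features, file.path(config$output_dir, "features.csv"), config)
  }

  if ("stats" %in% config$stages) {
    if (is.null(out$features)) stop("stats stage needs extracted features")
    feats <- rename_feature_cols(out$features)
    out$summary <- group_summary(feats)
    out$paths["summary"] <- write_output_csv(
      out$summary, file.path(config$output_dir, "group_summary.csv"), config)
    out$anova <- withCallingHandlers(
      significance_table(feats, alpha = config$alpha),
      warning = function(w) { say("stats: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    out$paths["anova"] <- write_output_csv(
      out$anova, file.path(config$output_dir, "anova.csv"), config)
    say("stats: %d tests at alpha = %g", attr(out$anova, "n_tests"),
        config$alpha)
  }

  if ("classify" %in% config$stages) {
    if (is.null(out$features)) stop("classify stage needs extracted features")
    feats <- rename_feature_cols(out$features)
    specs <- lapply(config$classifiers, classifier_spec,
                    seed = derive_seed(config$seed, 7L))
    names(specs) <- config$classifiers
    out$report <- withCallingHandlers(
      error_report(feats, specs, folds = config$folds,
                   repeats = config$repeats),
      warning = function(w) { say("classify: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    out$paths["report"] <- write_output_csv(
      out$report, file.path(config$output_dir, "classification_report.csv"),
      config)
    say("classify: %d report rows, %d flagged", nrow(out$report),
        sum(out$report$flagged))
  }

  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  out$paths["log"] <- file.path(config$output_dir, "run.log")
  invisible(out)
}

# map per-image extraction column names onto the canonical parameter names
rename_feature_cols <- function(df) {
  map <- c(sc = "sc_rad2_per_mm", os = "os_um")
  for (nm in names(map)) {
    if (map[[nm]] %in% names(df) && !nm %in% names(df))
      names(df)[names(df) == map[[nm]]] <- nm
  }
  df
}

#' Validate an acquisition manifest
#'
#' Checks that the manifest has the required columns, that `state` and
#' `magnification` take allowed values, that numeric fields are positive and
#' that every referenced image file exists.
#'
#' @param path Path to a manifest CSV.
#' @param dir Directory for resolving image paths (default: the manifest's).
#' @return A list with `valid` (flag) and `errors` (tibble `row`, `problem`;
#'   zero rows when valid).
#' @export
validate_manifest <- function(path, dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("path", "tissue", "state", "magnification", "pixel_size_um",
                "thickness_um", "wavelength_um", "seed")
  errors <- list()
  flag <- function(row, problem)
    errors[[length(errors) + 1L]] <<- tibble(row = row, problem = problem)
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    flag(NA_integer_, paste("missing columns:",
                            paste(missing_cols, collapse = ", ")))
  } else {
    for (i in seq_len(nrow(m))) {
      if (!m$state[i] %in% c("healthy", "tumoral"))
        flag(i, sprintf("state '%s' not allowed (use: healthy, tumoral)",
                        m$state[i]))
      if (!m$magnification[i] %in% .magnifications)
        flag(i, sprintf("magnification '%s' not allowed (use: %s)",
                        m$magnification[i],
                        paste(.magnifications, collapse = ", ")))
      if (!is.finite(m$pixel_size_um[i]) || m$pixel_size_um[i] <= 0)
        flag(i, "pixel_size_um must be positive")
      if (!file.exists(file.path(dir, m$path[i])))
        flag(i, sprintf("image file not found: %s", m$path[i]))
    }
  }
  errors <- if (length(errors)) dplyr::bind_rows(errors)
            else tibble(row = integer(), problem = character())
  list(valid = nrow(errors) == 0L, errors = errors, manifest = as_tibble(m))
}
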