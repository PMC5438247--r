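# Canonical tabular formats (CSV: comma, UTF-8, "." decimal, header required)
# with schema validation. Times are seconds everywhere; latencies are converted
# to ms only for display.

table_schemas <- list(
  spikes = list(
    cols = c(unit_id = "character", time_s = "numeric"),
    checks = list(
      function(d) if (any(d$time_s < 0))
        sprintf("negative time_s in row %d", which(d$time_s < 0)[1]),
      function(d) if (any(!nzchar(d$unit_id)))
        sprintf("empty unit_id in row %d", which(!nzchar(d$unit_id))[1]))),
  trials = list(
    cols = c(trial_id = "character", odorant = "character",
             concentration = "numeric", inhalation_onset_s = "numeric",
             odor_onset_s = "numeric", is_blank = "logical"),
    checks = list(
      function(d) if (anyDuplicated(d$trial_id))
        sprintf("duplicate trial_id in row %d", anyDuplicated(d$trial_id)),
      function(d) if (any(!d$is_blank & d$concentration <= 0))
        sprintf("non-blank trial with concentration <= 0 in row %d",
                which(!d$is_blank & d$concentration <= 0)[1]),
      function(d) if (any(!is.finite(d$inhalation_onset_s)))
        sprintf("missing inhalation onset in row %d",
                which(!is.finite(d$inhalation_onset_s))[1]))),
  units = list(
    cols = c(unit_id = "character", region = "character",
             population_id = "character"),
    checks = list(
      function(d) if (anyDuplicated(d$unit_id))
        sprintf("duplicate unit_id in row %d", anyDuplicated(d$unit_id)))),
  ground_truth = list(
    cols = c(unit_id = "character", odorant = "character",
             polarity = "character"),
    checks = list()),
  breaths = list(
    cols = c(onset_type = "character", time_s = "numeric"),
    checks = list(
      function(d) if (!all(d$onset_type %in% c("inhalation", "exhalation")))
        "onset_type must be 'inhalation' or 'exhalation'"))
)

coerce_cols <- function(d, cols, what, path) {
  missing <- setdiff(names(cols), names(d))
  if (length(missing))
    stopf("%s (%s): missing column(s) %s", what, path,
          paste(missing, collapse = ", "))
  for (nm in names(cols)) {
    v <- d[[nm]]
    cast <- switch(cols[[nm]],
                   character = as.character,
                   numeric = function(z) suppressWarnings(as.numeric(z)),
                   logical = function(z) {
                     if (is.character(z)) toupper(z) %in% c("TRUE", "T", "1")
                     else as.logical(z)
                   })
    w <- cast(v)
    if (cols[[nm]] == "numeric" && any(is.na(w) & !is.na(v)))
      stopf("%s (%s): unparseable value in column '%s', row %d", what, path,
            nm, which(is.na(w) & !is.na(v))[1])
    d[[nm]] <- w
  }
  d
}

#' Read a schema-validated table
#'
#' Loads one of the package's canonical CSV formats (`"spikes"`, `"trials"`,
#' `"units"`, `"ground_truth"`, `"breaths"`), coercing column types and
#' checking invariants; violations raise errors naming the offending row and
#' column. An empty-but-headered file yields an empty valid table.
#'
#' @param path CSV path.
#' @param schema schema name.
#' @return validated data.frame.
#' @export
read_table_checked <- function(path, schema) {
  if (!schema %in% names(table_schemas)) stopf("unknown schema '%s'", schema)
  sc <- table_schemas[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- coerce_cols(d, sc$cols, schema, path)
  if (nrow(d)) {
    for (chk in sc$checks) {
      msg <- chk(d)
      if (!is.null(msg)) stopf("%s (%s): %s", schema, path, msg)
    }
  }
  d
}

#' Write a table in the canonical CSV dialect
#'
#' @param x data.frame (validated against `schema` when given).
#' @param path output path.
#' @param schema optional schema name for validation before writing.
#' @export
write_table_checked <- function(x, path, schema = NULL) {
  if (!is.null(schema)) {
    sc <- table_schemas[[schema]]
    x <- coerce_cols(x, sc$cols, schema, path)
    for (chk in sc$checks) {
      msg <- chk(x)
      if (!is.null(msg)) stopf("%s (%s): %s", schema, path, msg)
    }
  }
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a respiration trace from a single-column CSV
#'
#' @param path CSV with one numeric column of airflow samples (negative =
#'   inhalation); a header row is expected.
#' @param sampling_rate sampling rate in Hz (default 2000).
#' @return a `respiration_trace` list usable with [detect_breaths()].
#' @export
read_respiration_trace <- function(path, sampling_rate = 2000) {
  d <- utils::read.csv(path)
  if (ncol(d) != 1) stopf("respiration CSV must have a single column")
  x <- suppressWarnings(as.numeric(d[[1]]))
  if (any(is.na(x))) stopf("unparseable sample in row %d", which(is.na(x))[1])
  structure(list(samples = x, sampling_rate = sampling_rate),
            class = "respiration_trace")
}

#' Write a dataset to a directory of canonical tables
#'
#' Emits spikes.csv, trials.csv, units.csv, ground_truth.csv (responsive
#' pairs), breaths.csv and config.yaml.
#'
#' @param dataset an `odor_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_checked(dataset$spikes, file.path(dir, "spikes.csv"), "spikes")
  write_table_checked(dataset$trials, file.path(dir, "trials.csv"), "trials")
  write_table_checked(dataset$units, file.path(dir, "units.csv"), "units")
  write_table_checked(dataset$ground_truth$pairs,
                      file.path(dir, "ground_truth.csv"), "ground_truth")
  br <- dataset$breaths
  breaths <- rbind(
    data.frame(onset_type = "inhalation", time_s = br$inhalation_onsets),
    data.frame(onset_type = "exhalation", time_s = br$exhalation_onsets))
  breaths <- breaths[order(breaths$time_s), ]
  write_table_checked(breaths, file.path(dir, "breaths.csv"), "breaths")
  cfg <- dataset$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the canonical tables.
#' @return an `odor_dataset` (ground-truth latency/suppression details are not
#'   round-tripped; the responsive-pair table is).
#' @export
read_dataset <- function(dir) {
  spikes <- read_table_checked(file.path(dir, "spikes.csv"), "spikes")
  trials <- read_table_checked(file.path(dir, "trials.csv"), "trials")
  units <- read_table_checked(file.path(dir, "units.csv"), "units")
  pairs <- read_table_checked(file.path(dir, "ground_truth.csv"), "ground_truth")
  breaths_df <- read_table_checked(file.path(dir, "breaths.csv"), "breaths")
  breaths <- breath_events(
    breaths_df$time_s[breaths_df$onset_type == "inhalation"],
    breaths_df$time_s[breaths_df$onset_type == "exhalation"])
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  structure(list(spikes = spikes, units = units, trials = trials,
                 breaths = breaths, ground_truth = list(pairs = pairs),
                 config = cfg),
            class = "odor_dataset")
}
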