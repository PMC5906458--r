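# Session bundles on disk ----------------------------------------------------
#
# A bundle directory holds plain-text files:
#   trials.csv              one row per trial
#   unit_<id>_spikes.csv    one spike timestamp (s) per line
#   headpose.csv            frame, t, x1, y1, x2, y2 (blank = missing)
#   manifest.json           parameters, seed, unit metadata, schema version

BUNDLE_SCHEMA_VERSION <- 1L

#' Write a session bundle to a directory
#'
#' @param bundle a list with elements `trials` (trial table), `units` (list
#'   of [spike_train()] objects), optional `headpose` (head-pose frame
#'   table), and optional `meta` (named list stored verbatim in the
#'   manifest).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  assert_trial_table(bundle$trials)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  units <- bundle$units %||% list()
  unit_meta <- lapply(units, function(u) {
    file <- sprintf("unit_%s_spikes.csv", u$unit_id)
    writeLines(format(u$spike_times, digits = 15, trim = TRUE, scientific = FALSE),
               file.path(dir, file))
    list(unit_id = u$unit_id, hemisphere = u$hemisphere, file = file)
  })
  if (!is.null(bundle$headpose))
    write.csv(as.data.frame(bundle$headpose)[, c("frame", "t", "x1", "y1", "x2", "y2")],
              file.path(dir, "headpose.csv"), row.names = FALSE)
  manifest <- list(schema_version = BUNDLE_SCHEMA_VERSION,
                   n_trials = nrow(bundle$trials),
                   units = unit_meta,
                   has_headpose = !is.null(bundle$headpose),
                   meta = bundle$meta %||% list())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' @param dir bundle directory written by [write_session_bundle()].
#' @return A list with `trials`, `units`, `headpose` (or `NULL`), `meta`.
#' @export
read_session_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stopf("no manifest.json in `%s`", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  if (!identical(as.integer(manifest$schema_version), BUNDLE_SCHEMA_VERSION))
    stopf("unsupported bundle schema version in `%s`", man_path)
  trials <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  trials <- new_trial_table(trials)
  assert_trial_table(trials)
  units <- lapply(manifest$units, function(u) {
    path <- file.path(dir, u$file)
    if (!file.exists(path)) stopf("malformed bundle: missing `%s`", path)
    txt <- readLines(path)
    spike_train(as.numeric(txt[nzchar(txt)]),
                unit_id = u$unit_id, hemisphere = u$hemisphere)
  })
  headpose <- NULL
  if (isTRUE(manifest$has_headpose)) {
    headpose <- read.csv(file.path(dir, "headpose.csv"))
    class(headpose) <- c("head_pose", "data.frame")
  }
  list(trials = trials, units = units, headpose = headpose,
       meta = manifest$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
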