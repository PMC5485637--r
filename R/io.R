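# Readers and writers for the pipeline's plain-text artifact formats.
# Gaze and event tables are CSV; AOI definitions are JSON
# (scene id -> list of {x, y, w, h} rectangles in scene pixels).

gaze_schema <- c(
  "t_ms", "lx_px", "ly_px", "rx_px", "ry_px",
  "lpupil_mm", "rpupil_mm", "valid_flag"
)

#' Read and write gaze CSV files
#'
#' The gaze CSV schema is one row per sample with columns `t_ms, lx_px,
#' ly_px, rx_px, ry_px, lpupil_mm, rpupil_mm, valid_flag`. Columns are
#' matched by header name, so column order is free; values round-trip at
#' full double precision.
#'
#' @param path File path.
#' @return `read_gaze_csv()` returns a [gaze_stream()].
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(gaze_schema, names(df))
  if (length(missing) > 0) {
    stop("gaze CSV ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  df <- df[, gaze_schema]
  df$valid_flag <- as.logical(df$valid_flag)
  gaze_stream(df)
}

#' @param stream A [gaze_stream()].
#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(stream, path) {
  df <- as.data.frame(stream)[, gaze_schema]
  write_csv_precise(df, path)
}

# write.csv at full double precision (deterministic, locale-independent)
write_csv_precise <- function(df, path) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- trimws(formatC(df[[col]], format = "g", digits = 17))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Read and write trial event logs
#'
#' Events CSV: `participant_id`, `trial_id`, `event`, `t_ms`.
#'
#' @param path File path.
#' @param events Events tibble.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  write_csv_precise(as.data.frame(events), path)
}

#' Read and write AOI definitions
#'
#' JSON object mapping scene id to a list of `{x, y, w, h}` rectangles in
#' scene pixel coordinates.
#'
#' @param path File path.
#' @param aois Named list of rectangle tables.
#' @export
read_aoi_json <- function(path) {
  if (!file.exists(path)) stop("AOI file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, tibble::as_tibble)
}

#' @rdname read_aoi_json
#' @export
write_aoi_json <- function(aois, path) {
  jsonlite::write_json(
    lapply(aois, as.data.frame), path,
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
}

#' Write a simulated study to a directory of plain-text files
#'
#' Writes `design.csv`, `participants.csv`, `ratings.csv`, `aois.json`,
#' `events.csv`, one `gaze_<participant>.csv` per participant, and
#' `ground_truth.json` (truth events and true AOI dwell times).
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_precise(as.data.frame(study$design), file.path(dir, "design.csv"))
  p <- as.data.frame(study$participants)
  p$sasa_cutoff_status <- as.character(p$sasa_cutoff_status)
  write_csv_precise(p, file.path(dir, "participants.csv"))
  write_csv_precise(as.data.frame(study$ratings), file.path(dir, "ratings.csv"))
  write_aoi_json(study$aois, file.path(dir, "aois.json"))
  write_events_csv(
    study$events[, c("participant_id", "trial_id", "event", "t_ms")],
    file.path(dir, "events.csv")
  )
  for (pid in names(study$streams)) {
    write_gaze_csv(study$streams[[pid]], file.path(dir, paste0("gaze_", pid, ".csv")))
  }
  jsonlite::write_json(
    list(
      truth_events = as.data.frame(study$truth_events),
      true_aoi_time = study$true_aoi_time,
      seed = study$seed
    ),
    file.path(dir, "ground_truth.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory path.
#' @return A list shaped like the in-memory study (without truth events).
#' @export
read_study <- function(dir) {
  need <- c("design.csv", "participants.csv", "ratings.csv", "aois.json", "events.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("study directory ", dir, " lacks ", f)
    }
  }
  design <- tibble::as_tibble(utils::read.csv(file.path(dir, "design.csv")))
  participants <- tibble::as_tibble(utils::read.csv(file.path(dir, "participants.csv")))
  gaze_files <- list.files(dir, "^gaze_.*\\.csv$", full.names = TRUE)
  streams <- lapply(gaze_files, read_gaze_csv)
  names(streams) <- sub("^gaze_(.*)\\.csv$", "\\1", basename(gaze_files))
  list(
    design = design,
    participants = participants,
    ratings = tibble::as_tibble(utils::read.csv(file.path(dir, "ratings.csv"))),
    aois = read_aoi_json(file.path(dir, "aois.json")),
    events = read_events_csv(file.path(dir, "events.csv")),
    streams = streams
  )
}

#' Write model-averaging results as CSV
#'
#' `results_<covariate>.csv` mirrors the published table layout (term,
#' label, estimate, ci_low, ci_high, p, significant, weight_sum);
#' `candidates_<covariate>.csv` lists each candidate model's term set, k,
#' log-likelihood, AIC and Akaike weight.
#'
#' @param result A `model_averaging_result` from [run_analysis()].
#' @param outdir Output directory.
#' @param covariate Covariate tag for the file names.
#' @return Paths of the written files, invisibly.
#' @export
write_results <- function(result, outdir, covariate = result$which %||% "anxiety") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(outdir, paste0("results_", covariate, ".csv"))
  cp <- file.path(outdir, paste0("candidates_", covariate, ".csv"))
  write_csv_precise(as.data.frame(result$coefficients), rp)
  write_csv_precise(as.data.frame(result$candidates), cp)
  invisible(c(results = rp, candidates = cp))
}
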