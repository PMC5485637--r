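#' Construct a gaze stream
#'
#' A gaze stream is a tibble with one row per tracker sample and the fixed
#' schema: `t_ms`, `lx_px`, `ly_px`, `rx_px`, `ry_px`, `lpupil_mm`,
#' `rpupil_mm`, `valid_flag`. `valid_flag` is the tracker's own
#' both-eyes-found indicator; the derived validity mask produced by
#' [flag_validity()] is stored, when present, in a `valid` column.
#'
#' @param df A data frame with the columns above.
#' @return A tibble of class `gaze_stream`.
#' @export
gaze_stream <- function(df) {
  required <- c(
    "t_ms", "lx_px", "ly_px", "rx_px", "ry_px",
    "lpupil_mm", "rpupil_mm", "valid_flag"
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("gaze stream is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.unsorted(df$t_ms, strictly = TRUE)) {
    stop("gaze stream timestamps must be strictly increasing")
  }
  out <- tibble::as_tibble(df)
  class(out) <- unique(c("gaze_stream", class(out)))
  out
}

#' Nominal sample period of a stream, in ms
#'
#' @param stream A gaze stream (or any table with `t_ms`).
#' @return Median inter-sample interval in ms.
#' @export
sample_period_ms <- function(stream) {
  if (nrow(stream) < 2) stop("need at least 2 samples to infer a sample period")
  stats::median(diff(stream$t_ms))
}

gaze_cols <- c("lx_px", "ly_px", "rx_px", "ry_px")
pupil_cols <- c("lpupil_mm", "rpupil_mm")

eye_cols <- function(eye = c("left", "right")) {
  eye <- match.arg(eye)
  if (eye == "left") c(x = "lx_px", y = "ly_px") else c(x = "rx_px", y = "ry_px")
}
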