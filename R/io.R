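# CSV writing with enough digits that a read-back reproduces values to 12
# significant digits (round-trip contract for all report artifacts).
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an EEG recording from EDF or long CSV
#'
#' The CSV layout is long format with columns `time`, `channel`, `value_uV`
#' (one row per channel sample) plus an events sidecar (`sample`, `scene_id`,
#' `repeat_idx`). EDF files are read with the package's minimal 16-bit EDF
#' codec.
#'
#' @param path data file.
#' @param format `"auto"` (by extension), `"edf"`, or `"csv"`.
#' @param events events sidecar: CSV path or data.frame.
#' @param hemispheres optional override map passed to
#'   [make_eeg_recording()].
#' @return a `landemo_eeg`.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv"), events = NULL,
                     hemispheres = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "edf") "edf" else "csv"
  ev <- if (is.character(events)) {
    e <- utils::read.csv(events, stringsAsFactors = FALSE)
    if ("sample_index" %in% names(e) && !"sample" %in% names(e))
      names(e)[names(e) == "sample_index"] <- "sample"
    e
  } else events
  if (format == "edf") {
    edf <- read_edf(path)
    return(make_eeg_recording(edf$samples, edf$labels, edf$rate, ev, hemispheres))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "channel", "value_uV")
  if (!all(need %in% names(df)))
    stop("long CSV needs columns: ", paste(need, collapse = ", "))
  chans <- unique(df$channel)
  mats <- lapply(chans, function(ch) {
    d <- df[df$channel == ch, ]
    d$value_uV[order(d$time)]
  })
  lens <- vapply(mats, length, integer(1))
  if (length(unique(lens)) != 1L) stop("channels have unequal lengths")
  times <- sort(unique(df$time))
  rate <- if (length(times) > 1L) round(1 / stats::median(diff(times))) else 1
  make_eeg_recording(do.call(rbind, mats), chans, rate, ev, hemispheres)
}

#' Write an EEG recording as long CSV (+ events sidecar)
#'
#' @param rec a `landemo_eeg`.
#' @param path output CSV path.
#' @param events_path optional path for the events sidecar CSV.
#' @export
write_eeg_csv <- function(rec, path, events_path = NULL) {
  n <- ncol(rec$samples)
  df <- data.frame(
    time = rep((0:(n - 1)) / rec$rate, times = nrow(rec$samples)),
    channel = rep(rec$labels, each = n),
    value_uV = as.vector(t(rec$samples)))
  write_csv_precise(df, path)
  if (!is.null(events_path) && !is.null(rec$events))
    write_csv_precise(rec$events, events_path)
  invisible(path)
}

#' Write the evaluation report bundle
#'
#' Emits one CSV per result table (compromise scores, levels, obstacle
#' degrees, threshold estimates) plus a JSON manifest echoing the
#' configuration and seed. The manifest is deterministic: a rerun with the
#' same inputs is byte-identical. Re-reading any CSV reproduces the numbers
#' to at least 12 significant digits.
#'
#' @param decision result list from [evaluate_scenes()] (or NULL).
#' @param scene_ids scene identifiers in matrix row order.
#' @param thresholds threshold report data.frame (or NULL).
#' @param dir output directory (created if needed).
#' @param config `landemo_config` to echo.
#' @param seed seed to record.
#' @return invisible character vector of files written.
#' @export
write_results <- function(decision, scene_ids, thresholds = NULL, dir,
                          config = pipeline_config(), seed = config$rng_seed) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  if (!is.null(decision)) {
    vik <- decision$vikor
    scores <- data.frame(scene_id = scene_ids, S = vik$S, R = vik$R,
                         Q = vik$Q, rank = vik$rank)
    f <- file.path(dir, "scores.csv"); write_csv_precise(scores, f)
    files <- c(files, f)
    levels_df <- data.frame(scene_id = scene_ids,
                            level = as.character(vik$level))
    f <- file.path(dir, "levels.csv"); write_csv_precise(levels_df, f)
    files <- c(files, f)
    obs <- as.data.frame(decision$obstacle$degrees)
    obs <- cbind(data.frame(scene_id = scene_ids,
                            no_obstacle = decision$obstacle$no_obstacle), obs)
    f <- file.path(dir, "obstacles.csv"); write_csv_precise(obs, f)
    files <- c(files, f)
    wdf <- data.frame(criterion = names(decision$weights) %||%
                        paste0("C", seq_along(decision$weights)),
                      weight = as.numeric(decision$weights))
    f <- file.path(dir, "weights.csv"); write_csv_precise(wdf, f)
    files <- c(files, f)
  }
  if (!is.null(thresholds)) {
    f <- file.path(dir, "thresholds.csv"); write_csv_precise(thresholds, f)
    files <- c(files, f)
  }
  manifest <- list(package = "landemo",
                   rng_seed = as.integer(seed),
                   config = unclass(config),
                   files = basename(files))
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
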