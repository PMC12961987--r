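#' Pipeline configuration with field-protocol defaults
#'
#' Defaults reproduce the acquisition and model constants of the field
#' protocol: 512 Hz sampling, 1-45 Hz band-pass, +/-100 uV rejection
#' threshold, epochs -200..1000 ms with -200..0 ms baseline, alpha 8-12 Hz,
#' beta 13-28 Hz, grey distinguishing coefficient rho = 0.5, VIKOR decision
#' coefficient v = 0.5, 3 repeats per scene, FDR alpha 0.05.
#'
#' @param sampling_rate Hz.
#' @param bandpass length-2 numeric, band-pass edges in Hz.
#' @param amplitude_threshold uV, absolute rejection threshold.
#' @param epoch_window length-2 numeric, ms relative to scene onset.
#' @param baseline_window length-2 numeric, ms; must lie within `epoch_window`.
#' @param alpha_band,beta_band length-2 numeric, Hz; disjoint, inside bandpass.
#' @param rho grey distinguishing coefficient in (0, 1].
#' @param v VIKOR decision coefficient in \[0, 1\].
#' @param n_repeats scene repetitions.
#' @param fdr_alpha FDR level for multiple-comparison control.
#' @param rng_seed integer seed driving all pipeline randomness.
#' @return validated list of class `landemo_config`.
#' @export
pipeline_config <- function(sampling_rate = 512,
                            bandpass = c(1, 45),
                            amplitude_threshold = 100,
                            epoch_window = c(-200, 1000),
                            baseline_window = c(-200, 0),
                            alpha_band = c(8, 12),
                            beta_band = c(13, 28),
                            rho = 0.5,
                            v = 0.5,
                            n_repeats = 3,
                            fdr_alpha = 0.05,
                            rng_seed = 1L) {
  cfg <- list(sampling_rate = as.numeric(sampling_rate),
              bandpass = as.numeric(bandpass),
              amplitude_threshold = as.numeric(amplitude_threshold),
              epoch_window = as.numeric(epoch_window),
              baseline_window = as.numeric(baseline_window),
              alpha_band = as.numeric(alpha_band),
              beta_band = as.numeric(beta_band),
              rho = as.numeric(rho),
              v = as.numeric(v),
              n_repeats = as.integer(n_repeats),
              fdr_alpha = as.numeric(fdr_alpha),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "landemo_config"
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `landemo_config`.
#' @export
validate_config <- function(cfg) {
  fail <- function(key, msg) stop("invalid config '", key, "': ", msg, call. = FALSE)
  pair <- function(key) {
    x <- cfg[[key]]
    if (!is.numeric(x) || length(x) != 2L || anyNA(x)) fail(key, "must be a numeric pair")
    x
  }
  if (cfg$sampling_rate <= 0) fail("sampling_rate", "must be > 0")
  bp <- pair("bandpass")
  if (!(bp[1] > 0 && bp[1] < bp[2] && bp[2] < cfg$sampling_rate / 2))
    fail("bandpass", "needs 0 < low < high < sampling_rate/2")
  if (cfg$amplitude_threshold <= 0) fail("amplitude_threshold", "must be > 0")
  ew <- pair("epoch_window"); bw <- pair("baseline_window")
  if (ew[1] >= ew[2]) fail("epoch_window", "start must precede end")
  if (bw[1] < ew[1] || bw[2] > ew[2] || bw[1] >= bw[2])
    fail("baseline_window", "must be an increasing pair inside epoch_window")
  ab <- pair("alpha_band"); bb <- pair("beta_band")
  for (key in c("alpha_band", "beta_band")) {
    b <- cfg[[key]]
    if (b[1] >= b[2]) fail(key, "low must be < high")
    if (b[1] < bp[1] || b[2] > bp[2]) fail(key, "must lie within bandpass")
  }
  if (max(ab[1], bb[1]) <= min(ab[2], bb[2]))
    fail("alpha_band", "alpha and beta bands must be disjoint")
  if (!(cfg$rho > 0 && cfg$rho <= 1)) fail("rho", "must be in (0, 1]")
  if (!(cfg$v >= 0 && cfg$v <= 1)) fail("v", "must be in [0, 1]")
  if (cfg$n_repeats < 1L) fail("n_repeats", "must be >= 1")
  if (!(cfg$fdr_alpha > 0 && cfg$fdr_alpha < 1)) fail("fdr_alpha", "must be in (0, 1)")
  cfg
}

#' Load a pipeline configuration from JSON or flat YAML
#'
#' JSON is parsed with jsonlite. YAML support covers the flat subset
#' `key: value` (numbers, strings, `[a, b]` pairs, `#` comments), which is all
#' a pipeline config needs. Unset keys take the protocol defaults of
#' [pipeline_config()]; unknown keys are an error.
#'
#' @param path file path (`.json`, `.yaml`, or `.yml`; an empty file gives all
#'   defaults).
#' @return a validated `landemo_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml", "")) {
    parse_flat_yaml(path)
  } else {
    stop("unsupported config format: .", ext, " (use JSON or YAML)")
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  do.call(pipeline_config, raw)
}

# Minimal flat YAML: scalar or [a, b] values, one mapping level, '#' comments.
parse_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("malformed config line (expected 'key: value'): ", trimws(ln))
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (!nzchar(key)) stop("malformed config line (empty key): ", trimws(ln))
    out[[key]] <- parse_yaml_scalar(val, key)
  }
  out
}

parse_yaml_scalar <- function(val, key) {
  if (!nzchar(val)) stop("config key '", key, "' has no value")
  if (grepl("^\\[.*\\]$", val)) {
    parts <- trimws(strsplit(sub("\\]$", "", sub("^\\[", "", val)), ",")[[1]])
    return(vapply(parts, parse_yaml_scalar, numeric(1), key = key, USE.NAMES = FALSE))
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  gsub("^['\"]|['\"]$", "", val)
}
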