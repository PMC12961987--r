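#' Registry of quantitative scene indicators
#'
#' The observed-element system distinguishes physical elements (A), spatial
#' perception (B), and cultural cognition (C). This registry carries the
#' quantitative operationalizations the pipeline works with: each indicator
#' has a stable snake_case id, the element code it descends from, a unit, a
#' benefit/cost direction for the decision model, and its availability per
#' village archetype (the observed-element menu differs between villages).
#'
#' @return data.frame with columns `id`, `code`, `label`, `unit`,
#'   `direction`, `is_percent`, `xiangmiao`, `xiaoqiyuan`, `xiedian`.
#' @export
indicator_registry <- function() {
  data.frame(
    id = c("gvi_pct", "hard_pavement_pct", "symbol_density",
           "local_material_pct", "vegetation_layers", "water_visibility_pct",
           "spatial_visual_field_m"),
    code = c("B21", "A31", "C22", "A22", "A43", "A51", "B22"),
    label = c("Green View Index", "Hard pavement share",
              "Cultural symbol density", "Local material share",
              "Plant layers", "Water visibility", "Spatial visual field"),
    unit = c("%", "%", "count/100m2", "%", "layers", "%", "m"),
    direction = c("benefit", "cost", "benefit", "benefit", "benefit",
                  "benefit", "benefit"),
    is_percent = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    xiangmiao = TRUE,
    xiaoqiyuan = TRUE,
    xiedian = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Construct a scene-indicator matrix
#'
#' @param data data.frame with `scene_id`, `village`, and indicator columns
#'   named by registry id (or element code, which is translated).
#' @param registry indicator registry; defaults to [indicator_registry()].
#' @return object of class `landemo_scenes`: list with `data` (row order
#'   preserved) and `indicators` (registry rows present, in column order).
#' @export
scene_indicator_matrix <- function(data, registry = indicator_registry()) {
  if (!all(c("scene_id", "village") %in% names(data)))
    stop("scene table needs 'scene_id' and 'village' columns")
  other <- setdiff(names(data), c("scene_id", "village"))
  if (!length(other)) stop("scene table has no indicator columns")
  # translate element codes to ids
  code_idx <- match(other, registry$code)
  names(data)[match(other, names(data))] <-
    ifelse(is.na(code_idx), other, registry$id[code_idx])
  other <- setdiff(names(data), c("scene_id", "village"))
  unknown <- setdiff(other, registry$id)
  if (length(unknown))
    stop("unknown indicator column(s): ", paste(unknown, collapse = ", "),
         "; known codes/ids: ",
         paste(paste0(registry$code, "/", registry$id), collapse = ", "))
  meta <- registry[match(other, registry$id), , drop = FALSE]
  for (k in seq_len(nrow(meta))) {
    col <- meta$id[k]
    v <- data[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(vn) & !anyNA(v))
        stop("non-numeric cell in numeric column '", col, "' at row ",
             which(is.na(vn))[1L])
      v <- vn
      data[[col]] <- v
    }
    if (meta$is_percent[k] && any(v < 0 | v > 100, na.rm = TRUE))
      stop("indicator '", col, "' declared as percentage has value(s) outside [0, 100]")
  }
  # availability bookkeeping: registered indicators expected for each village
  villages <- intersect(unique(as.character(data$village)),
                        c("xiangmiao", "xiaoqiyuan", "xiedian"))
  missing_by_village <- lapply(villages, function(vl) {
    expected <- registry$id[registry[[vl]]]
    setdiff(expected, other)
  })
  names(missing_by_village) <- villages
  structure(list(data = data, indicators = meta,
                 missing_by_village = missing_by_village),
            class = "landemo_scenes")
}

#' @export
print.landemo_scenes <- function(x, ...) {
  cat("<landemo_scenes> ", nrow(x$data), " scenes, ",
      nrow(x$indicators), " indicators (",
      paste(x$indicators$id, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

scene_data <- function(scenes) {
  if (inherits(scenes, "landemo_scenes")) scenes$data else as.data.frame(scenes)
}

scene_indicator_meta <- function(scenes) {
  if (inherits(scenes, "landemo_scenes")) return(scenes$indicators)
  reg <- indicator_registry()
  ids <- intersect(names(scenes), reg$id)
  reg[match(ids, reg$id), , drop = FALSE]
}

#' Read a scene-indicator table from CSV
#'
#' Expects a header with `scene_id`, `village`, and at least one registered
#' indicator column (by id such as `gvi_pct` or element code such as `B21`).
#' Values are validated against declared units (percentages must lie in
#' \[0, 100\]); row order is preserved.
#'
#' @param path CSV file (UTF-8, comma separator, `.` decimal).
#' @param registry indicator registry.
#' @return a `landemo_scenes` object.
#' @export
read_scene_table <- function(path, registry = indicator_registry()) {
  if (!file.exists(path)) stop("scene table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  scene_indicator_matrix(df, registry)
}

#' Write a scene-indicator table to CSV
#'
#' @param scenes `landemo_scenes` object.
#' @param path output CSV path.
#' @export
write_scene_table <- function(scenes, path) {
  write_csv_precise(scene_data(scenes), path)
}
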