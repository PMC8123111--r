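#' @title Formats, configuration and reports
#'
#' @description
#' CSV interfaces for feature tables (Table-2-style schema, order
#' insensitive), virtual lines and soundings, YAML pipeline configuration,
#' JSON run manifests, and plain-text classification reports. CSV dialect:
#' UTF-8, comma separator, "." decimal; a `sep` argument accepts
#' semicolon-delimited regional exports.
#'
#' @name cli_io
NULL

.ID_COLS <- c("slice_id", "ping_id", "object_id", "label", "label_source")

#' Write / read a slice feature table as CSV
#'
#' The header uses the exact 24 schema names plus the bookkeeping columns.
#' On read, the header is validated order-insensitively: missing metric
#' columns raise an error naming them; unknown extra columns are dropped
#' with a warning.
#'
#' @param table feature data.frame.
#' @param path CSV file path.
#' @return `write_feature_csv()`: the path, invisibly;
#'   `read_feature_csv()`: the validated data.frame.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param sep field separator (`","` or `";"` for regional exports).
#' @export
read_feature_csv <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  miss <- setdiff(feature_schema(), names(df))
  if (length(miss))
    stop("schema error; missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(feature_schema(), .ID_COLS))
  if (length(extra)) {
    warning(sprintf("ignoring %d unknown column(s): %s", length(extra),
                    paste(extra, collapse = ", ")))
    df <- df[setdiff(names(df), extra)]
  }
  if (!is.null(df$label)) df$label[df$label %in% c("", "NA")] <- NA_character_
  df
}

#' Export a virtual line as a two-column CSV
#'
#' @param line a `virtual_line`.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_line_csv <- function(line, path) {
  utils::write.csv(data.frame(ping_id = line$ping_ids, range_m = line$range),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export soundings as x,y,z CSV
#' @param soundings data.frame with `x`, `y`, `depth`.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_soundings_csv <- function(soundings, path) {
  utils::write.csv(soundings, path, row.names = FALSE)
  invisible(path)
}

#' Slice polygons as well-known-text strings
#'
#' @param slices list of `slice_region`s.
#' @return character vector of `POLYGON ((across depth, ...))` strings.
#' @export
slice_polygons_wkt <- function(slices) {
  vapply(slices, function(s) {
    p <- rbind(s$polygon, s$polygon[1, , drop = FALSE])
    sprintf("POLYGON ((%s))",
            paste(sprintf("%.3f %.3f", p[, 1], p[, 2]), collapse = ", "))
  }, "")
}

#' Read / write a pipeline configuration file (YAML)
#'
#' The file holds a `survey:` block (any [survey_config()] field), an
#' optional `noise:` block, a `targets:` list (klass, anchor, dims,
#' sv_offset, velocity, persistence) and an optional `ml:` block
#' (label_fraction, knn_k, ratio).
#'
#' @param path YAML file path.
#' @return list with `config` (`survey_config`), `targets`, `noise`, `ml`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(survey_config, y$survey %||% list())
  noise <- if (is.null(y$noise)) noise_config(seed = cfg$seed)
           else do.call(noise_config, y$noise)
  targets <- lapply(y$targets %||% list(), function(t) {
    target_spec(klass = t$klass, anchor = unlist(t$anchor),
                dims = unlist(t$dims), sv_offset = t$sv_offset,
                velocity = unlist(t$velocity %||% c(0, 0, 0)),
                persistence = t$persistence %||% Inf)
  })
  list(config = cfg, targets = targets, noise = noise, ml = y$ml %||% list())
}

#' Format a classification report as aligned text
#'
#' @param cr a [classification_report()] result.
#' @return character scalar (multi-line).
#' @export
format_report <- function(cr) {
  r <- cr$report
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  lines <- sprintf("%-14s %9s %9s %9s %9s", r$Class, fmt(r$Precision),
                   fmt(r$Recall), fmt(r$`F1-Score`), r$Support)
  paste(c(sprintf("%-14s %9s %9s %9s %9s", "Class", "Precision", "Recall",
                  "F1-Score", "Support"), lines), collapse = "\n")
}

#' Write a run manifest as JSON
#'
#' @param run a `wc_run` from [run_pipeline()].
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
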