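# CSV schemas and plain-text configuration. Dialect: comma-separated, UTF-8,
# mandatory header row, '.' decimal.

position_cols <- c("well", "cell_id", "cell_type", "t_min", "x_um", "y_um",
                   "z_um", "dye_intensity")
event_cols <- c("well", "event_id", "kind", "dye_intensity", "viability_dye")

#' Write / read per-cell position tables
#'
#' Schema: `well, cell_id, cell_type, t_min, x_um, y_um, z_um,
#' dye_intensity`. Round-trips losslessly for all fields.
#'
#' @param cells Observation tibble (missing schema columns are filled with
#'   NA).
#' @param path File path.
#' @return `write_position_csv` returns `path` invisibly; `read_position_csv`
#'   returns the tibble.
#' @export
write_position_csv <- function(cells, path) {
  for (cc in setdiff(position_cols, names(cells))) cells[[cc]] <- NA
  write.csv(cells[, position_cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_position_csv
#' @export
read_position_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  assert_cols(df, position_cols, "position table")
  as_tibble(df)
}

#' Write / read cytometry-style event tables
#'
#' Schema: `well, event_id, kind, dye_intensity, viability_dye` with
#' `kind` in `{cell, bead}`.
#'
#' @param events Event tibble.
#' @param path File path.
#' @export
write_event_csv <- function(events, path) {
  assert_cols(events, event_cols, "events")
  bad <- setdiff(unique(events$kind), c("cell", "bead"))
  if (length(bad)) abort(paste0("unknown event kind: ", paste(bad, collapse = ", ")))
  write.csv(events[, event_cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  assert_cols(df, event_cols, "event table")
  as_tibble(df)
}

#' Write / read a run configuration as plain-text key = value lines
#'
#' Scalars and numeric/character vectors only; vectors are comma-joined.
#' Numbers survive the round trip at full double precision.
#'
#' @param config Named list of scalars/vectors.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  if (is.null(names(config)) || any(names(config) == "")) {
    abort("config entries must be named")
  }
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    val <- if (is.numeric(v)) {
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = ",")
    } else {
      paste(as.character(v), collapse = ",")
    }
    paste0(k, " = ", val)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) abort(paste0("malformed config line: ", ln))
    parts <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[m[2]]] <- if (!anyNA(num)) num else trimws(parts)
  }
  out
}

#' Append machine-readable run-log lines
#'
#' One `key=value` pair set per line with a timestamp-free, diff-stable
#' format (stage, seed, counts in/out), so identical runs produce identical
#' logs.
#'
#' @param path Log file path.
#' @param stage Stage name.
#' @param ... Named scalar fields to record.
#' @export
log_run <- function(path, stage, ...) {
  fields <- list(...)
  kv <- if (length(fields)) {
    paste(names(fields), vapply(fields, function(v) paste(v, collapse = ";"),
                                character(1)),
          sep = "=", collapse = " ")
  } else ""
  cat(paste0("stage=", stage, if (nzchar(kv)) " ", kv, "\n"),
      file = path, append = TRUE)
  invisible(path)
}
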