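# CSV/YAML/image I/O. CSV everywhere for tabular data, TIFF/PNG for label
# masks, YAML for configuration; readers validate and report the offending
# line where they can.

.read_csv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("empty file: ", path)
  utils::read.csv(text = paste(lines[keep], collapse = "\n"),
                  check.names = FALSE)
}

#' Write / read a temperature log CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `time_s,t_dish_c,t_block_c,duty,setpoint_c`, '.' decimal separator, one
#' row per sample. The reader tolerates extra columns and `#` comment lines,
#' and a `column_map` can adapt foreign headers (named character vector
#' mapping standard names to the file's names).
#'
#' @param log A [temperature_log()].
#' @param path File path.
#' @param column_map Optional named character vector, e.g.
#'   `c(time_s = "t", t_dish_c = "dish")`.
#' @return `read_temperature_log()` returns a validated
#'   [temperature_log()]; `write_temperature_log()` returns `path`
#'   invisibly.
#' @export
write_temperature_log <- function(log, path) {
  stopifnot(inherits(log, "temperature_log"))
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature_log
#' @export
read_temperature_log <- function(path, column_map = NULL) {
  df <- .read_csv_lines(path)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stop("read_temperature_log: mapped column '", src, "' not in file")
      df[[std]] <- df[[src]]
    }
  }
  needed <- c("time_s", "t_dish_c", "t_block_c", "duty", "setpoint_c")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("read_temperature_log: missing columns: ",
         paste(missing, collapse = ", "))
  for (cn in needed) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v)))
      stop("read_temperature_log: non-numeric value in '", cn, "' at row ",
           which(is.na(v))[1L])
    df[[cn]] <- v
  }
  temperature_log(df)
}

#' Write / read per-cell trace tables
#'
#' Wide format: first column `time_s`, one column per cell id. Long format:
#' columns `time_s,cell_id,value`. Conversion between the two is lossless.
#'
#' @param traces List of [fluor_trace()] objects sharing `fs` and length.
#' @param path File path.
#' @param format `"wide"` or `"long"`.
#' @param fs Sampling rate override for the reader; by default inferred from
#'   the time column.
#' @return `read_traces()` returns a list of [fluor_trace()];
#'   `write_traces()` returns `path` invisibly.
#' @export
write_traces <- function(traces, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(length(traces) > 0)
  fs <- traces[[1L]]$fs
  n <- length(traces[[1L]]$values)
  tt <- (seq_len(n) - 1L) / fs
  if (format == "wide") {
    df <- data.frame(time_s = tt)
    for (tr in traces) df[[as.character(tr$cell_id)]] <- tr$values
  } else {
    df <- do.call(rbind, lapply(traces, function(tr)
      data.frame(time_s = tt, cell_id = tr$cell_id, value = tr$values)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, format = c("wide", "long"), fs = NULL) {
  format <- match.arg(format)
  df <- .read_csv_lines(path)
  if (!"time_s" %in% names(df))
    stop("read_traces: missing 'time_s' column")
  tt <- suppressWarnings(as.numeric(df$time_s))
  if (any(is.na(tt)))
    stop("read_traces: non-numeric time at row ", which(is.na(tt))[1L])
  if (is.null(fs)) {
    dt <- stats::median(diff(sort(unique(tt))))
    if (!is.finite(dt) || dt <= 0)
      stop("read_traces: cannot infer sampling rate from 'time_s'")
    fs <- 1 / dt
  }
  if (format == "wide") {
    ids <- setdiff(names(df), "time_s")
    if (!length(ids)) stop("read_traces: no cell columns")
    lapply(ids, function(id) {
      v <- suppressWarnings(as.numeric(df[[id]]))
      if (any(is.na(v)))
        stop("read_traces: non-numeric value in column '", id, "' at row ",
             which(is.na(v))[1L])
      cid <- suppressWarnings(as.integer(id))
      fluor_trace(v, fs = fs, cell_id = if (is.na(cid)) id else cid)
    })
  } else {
    if (!all(c("cell_id", "value") %in% names(df)))
      stop("read_traces: long format needs columns time_s,cell_id,value")
    ids <- unique(df$cell_id)
    lapply(ids, function(id) {
      sub <- df[df$cell_id == id, ]
      sub <- sub[order(sub$time_s), ]
      v <- suppressWarnings(as.numeric(sub$value))
      if (any(is.na(v)))
        stop("read_traces: non-numeric value for cell ", id)
      fluor_trace(v, fs = fs, cell_id = id)
    })
  }
}

#' Write / read detected transient events
#'
#' CSV header `cell_id,start_s,end_s,width_s,height_dff,auc`.
#'
#' @param events A `transient_events` data frame.
#' @param path File path.
#' @return `read_events()` returns a `transient_events` data frame;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "height"] <- "height_dff"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- .read_csv_lines(path)
  needed <- c("cell_id", "start_s", "end_s", "width_s", "height_dff", "auc")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("read_events: missing columns: ", paste(missing, collapse = ", "))
  names(df)[names(df) == "height_dff"] <- "height"
  class(df) <- c("transient_events", "data.frame")
  df
}

#' Write / read per-cell kinetics summaries
#'
#' CSV header `cell_id,n_events,freq_per_min,mean_width_s,mean_auc,active`.
#'
#' @param kinetics A `cell_kinetics` data frame.
#' @param path File path.
#' @return `read_kinetics()` returns a `cell_kinetics` data frame;
#'   `write_kinetics()` returns `path` invisibly.
#' @export
write_kinetics <- function(kinetics, path) {
  utils::write.csv(as.data.frame(kinetics), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  df <- .read_csv_lines(path)
  needed <- c("cell_id", "n_events", "freq_per_min", "mean_width_s",
              "mean_auc", "active")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("read_kinetics: missing columns: ", paste(missing, collapse = ", "))
  df$active <- as.logical(df$active)
  class(df) <- c("cell_kinetics", "data.frame")
  df
}

#' Write / read an integer label mask image
#'
#' Greyscale TIFF (16-bit, labels up to 65535) or PNG (8-bit, labels up to
#' 255); pixel values are the integer labels.
#'
#' @param mask Integer matrix of labels (0 = background).
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_mask()` returns an integer matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  if (any(mask < 0))
    stop("write_mask: labels must be non-negative")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (any(mask > 65535)) stop("write_mask: TIFF labels must be <= 65535")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (any(mask > 255)) stop("write_mask: PNG labels must be <= 255")
    png::writePNG(mask / 255, path)
  } else stop("write_mask: unsupported extension '", ext, "'")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    depth <- 65535
  } else if (ext == "png") {
    img <- png::readPNG(path)
    depth <- 255
  } else stop("read_mask: unsupported extension '", ext, "'")
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- round(img * depth)
  storage.mode(m) <- "integer"
  m
}

#' Read a run configuration YAML
#'
#' Sections `pid`, `plant`, `detector`, `synth` and `paths` configure the
#' corresponding constructors; unknown sections or keys are rejected so
#' typos cannot silently fall back to defaults. The PID key `dt_s` maps to
#' the `dt` argument of [pid_params()].
#'
#' @param path YAML file path.
#' @return A list with any of `pid` (`pid_params`), `plant`
#'   (`plant_params`), `detector` (`detector_config`), `synth`
#'   (`trace_gen_config`), `paths` (list).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("pid", "plant", "detector", "synth", "paths")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("read_run_config: unknown section(s): ", paste(extra, collapse = ", "))
  out <- list()
  check_keys <- function(x, allowed, section) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("read_run_config: unknown key(s) in '", section, "': ",
           paste(extra, collapse = ", "))
    x
  }
  if (!is.null(raw$pid)) {
    p <- check_keys(raw$pid, c("kp", "ki", "kd", "dt_s", "u_min", "u_max",
                               "integral_limit"), "pid")
    names(p)[names(p) == "dt_s"] <- "dt"
    out$pid <- do.call(pid_params, p)
  }
  if (!is.null(raw$plant))
    out$plant <- do.call(plant_params, check_keys(
      raw$plant, names(formals(plant_params)), "plant"))
  if (!is.null(raw$detector))
    out$detector <- do.call(detector_config, check_keys(
      raw$detector, names(formals(detector_config)), "detector"))
  if (!is.null(raw$synth))
    out$synth <- do.call(trace_gen_config, check_keys(
      raw$synth, names(formals(trace_gen_config)), "synth"))
  if (!is.null(raw$paths)) out$paths <- raw$paths
  out
}
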