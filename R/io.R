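# Shared CSV plumbing. All dialects are plain comma-separated text with an
# optional block of "# key=value" metadata lines before the header. Readers
# report parse errors with the offending line number.

parse_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z0-9_.-]+)\\s*=\\s*(.*)\\s*$",
                           meta_lines))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
}

read_delim_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body_idx) < 2L)
    stop("parse error in ", path, ": no data rows found", call. = FALSE)
  header_line <- body_idx[1]
  header <- trimws(strsplit(lines[header_line], ",", fixed = TRUE)[[1]])
  missing <- setdiff(required, header)
  if (length(missing) > 0L)
    stop(sprintf("parse error at line %d of %s: missing column(s) %s",
                 header_line, path, paste(missing, collapse = ", ")),
         call. = FALSE)
  unknown <- setdiff(header, c(required, optional))
  if (length(unknown) > 0L)
    stop(sprintf("parse error at line %d of %s: unknown column(s) %s",
                 header_line, path, paste(unknown, collapse = ", ")),
         call. = FALSE)
  rows <- body_idx[-1]
  cells <- lapply(rows, function(i) {
    fields <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(fields) != length(header))
      stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                   i, path, length(header), length(fields)), call. = FALSE)
    fields
  })
  out <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(out) <- header
  numeric_cols <- setdiff(header, "group")
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop(sprintf("parse error at line %d of %s: non-numeric value '%s' in column %s",
                   rows[bad[1]], path, out[[col]][bad[1]], col), call. = FALSE)
    out[[col]] <- v
  }
  list(data = out, meta = parse_meta(lines[seq_len(header_line - 1L)]))
}

meta_header <- function(extra = character()) {
  c(sprintf("# monofil %s",
            as.character(utils::packageVersion("monofil"))),
    extra)
}

#' Read and write force-displacement curve CSV files
#'
#' The curve dialect has the header `displacement_mm,force_gf`, optionally
#' preceded by `#`-prefixed metadata lines (`# device_id=`, `# speed_mm_s=`,
#' `# cycle=`). A long-format file with an additional `cycle` column holds
#' several cycles in one file; `read_curve_csv()` then returns a list of
#' curves, one per cycle.
#'
#' @param path Path to the CSV file.
#' @param curve An [force_displacement_curve()] object.
#' @return `read_curve_csv()` returns an `"fd_curve"` object, or a list of
#'   them for long-format files. `write_curve_csv()` returns `path`
#'   invisibly.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_curve_csv(generate_curve(15, 7.5, noise_sd = 0), f)
#' cu <- read_curve_csv(f)
#' @export
read_curve_csv <- function(path) {
  parsed <- read_delim_checked(path, required = c("displacement_mm", "force_gf"),
                               optional = "cycle")
  d <- parsed$data
  m <- parsed$meta
  speed <- if (!is.null(m$speed_mm_s)) as.numeric(m$speed_mm_s) else NA_real_
  device <- if (!is.null(m$device_id)) m$device_id else NA_character_
  make <- function(sub, cyc) {
    force_displacement_curve(sub$displacement_mm, sub$force_gf,
                             speed = speed, device_id = device, cycle = cyc)
  }
  if ("cycle" %in% names(d)) {
    cycles <- sort(unique(d$cycle))
    if (length(cycles) == 1L) return(make(d, as.integer(cycles)))
    return(lapply(cycles, function(cy) make(d[d$cycle == cy, ], as.integer(cy))))
  }
  cyc <- if (!is.null(m$cycle)) as.integer(m$cycle) else 1L
  make(d, cyc)
}

#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  meta <- meta_header(c(
    if (!is.na(curve$device_id)) sprintf("# device_id=%s", curve$device_id),
    if (!is.na(curve$speed)) sprintf("# speed_mm_s=%g", curve$speed),
    sprintf("# cycle=%d", curve$cycle)))
  writeLines(c(meta, "displacement_mm,force_gf",
               sprintf("%.10g,%.10g", curve$displacement, curve$force)), path)
  invisible(path)
}

#' Read and write fatigue-series CSV files
#'
#' Dialect: header `cycle,critical_force_gf`, optional `#` metadata lines
#' (`# speed_mm_s=`, `# interval_s=`). Rows are sorted by cycle on read.
#'
#' @param path Path to the CSV file.
#' @param series A [fatigue_series()] object.
#' @return `read_fatigue_csv()` returns a `"fatigue_series"` object;
#'   `write_fatigue_csv()` returns `path` invisibly.
#' @export
read_fatigue_csv <- function(path) {
  parsed <- read_delim_checked(path, required = c("cycle", "critical_force_gf"))
  d <- parsed$data[order(parsed$data$cycle), ]
  m <- parsed$meta
  fatigue_series(
    d$critical_force_gf,
    speed = if (!is.null(m$speed_mm_s)) as.numeric(m$speed_mm_s) else NA_real_,
    inter_cycle_interval =
      if (!is.null(m$interval_s)) as.numeric(m$interval_s) else 3)
}

#' @rdname read_fatigue_csv
#' @export
write_fatigue_csv <- function(series, path) {
  stopifnot(inherits(series, "fatigue_series"))
  meta <- meta_header(c(
    if (!is.na(series$speed)) sprintf("# speed_mm_s=%g", series$speed),
    sprintf("# interval_s=%g", series$inter_cycle_interval)))
  n <- length(series$critical_forces)
  writeLines(c(meta, "cycle,critical_force_gf",
               sprintf("%d,%.10g", seq_len(n), series$critical_forces)), path)
  invisible(path)
}

#' Read and write paired-measurement CSV files
#'
#' Dialect: header `reference_gf,measured_gf` with an optional `group`
#' column naming the reference point of each pair.
#'
#' @param path Path to the CSV file.
#' @param pairs A data frame with columns `reference_gf`, `measured_gf`
#'   and optionally `group`.
#' @return `read_pairs_csv()` returns the pairs data frame;
#'   `write_pairs_csv()` returns `path` invisibly.
#' @export
read_pairs_csv <- function(path) {
  parsed <- read_delim_checked(path, required = c("reference_gf", "measured_gf"),
                               optional = "group")
  parsed$data
}

#' @rdname read_pairs_csv
#' @export
write_pairs_csv <- function(pairs, path) {
  stopifnot(is.data.frame(pairs),
            all(c("reference_gf", "measured_gf") %in% names(pairs)))
  has_group <- "group" %in% names(pairs)
  header <- paste(c("reference_gf", "measured_gf", if (has_group) "group"),
                  collapse = ",")
  rows <- if (has_group) {
    sprintf("%.10g,%.10g,%s", pairs$reference_gf, pairs$measured_gf,
            pairs$group)
  } else {
    sprintf("%.10g,%.10g", pairs$reference_gf, pairs$measured_gf)
  }
  writeLines(c(meta_header(), header, rows), path)
  invisible(path)
}

#' Export a critical-force grid as CSV
#'
#' Writes the grid as a matrix table: first column the diameters (mm),
#' header row the lengths (mm), cells in gf, preceded by `#` metadata
#' naming the modulus and k factor.
#'
#' @param grid A `"parameter_grid"` from [critical_force_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "parameter_grid"))
  meta <- meta_header(c(sprintf("# young_modulus_pa=%.10g", grid$young_modulus),
                        sprintf("# k_factor=%g", grid$k)))
  header <- paste(c("d_mm\\L_mm", sprintf("%.10g", grid$lengths_mm)),
                  collapse = ",")
  rows <- vapply(seq_along(grid$diameters_mm), function(i) {
    paste(c(sprintf("%.10g", grid$diameters_mm[i]),
            sprintf("%.10g", grid$values_gf[i, ])), collapse = ",")
  }, "")
  writeLines(c(meta, header, rows), path)
  invisible(path)
}
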