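# Plain-text tilt metadata (.tlt / .xf dialects), particle tables and run
# configuration.

#' Read and write tilt-angle files (.tlt dialect: one angle per line)
#'
#' @param path file path.
#' @return `read_tlt()`: numeric vector of angles (degrees).
#' @export
read_tlt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    stop_bisectr("%s: non-numeric tilt angle at line %d", path, which(is.na(vals))[1])
  }
  vals
}

#' @rdname read_tlt
#' @param angles numeric vector, degrees.
#' @param sort_by `"acquisition"` keeps the given order (how dose and
#'   weights accumulate); `"angle"` sorts ascending.
#' @export
write_tlt <- function(angles, path, sort_by = c("acquisition", "angle")) {
  sort_by <- match.arg(sort_by)
  if (sort_by == "angle") angles <- sort(angles)
  writeLines(sprintf("%g", angles), path)
  invisible(path)
}

#' Read and write in-plane transform files (.xf dialect)
#'
#' Six whitespace-separated numbers per line: `a11 a12 a21 a22 dx dy`.
#'
#' @param path file path.
#' @return `read_xf()`: numeric matrix with 6 columns, one row per tilt.
#' @export
read_xf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 6 || anyNA(v)) {
      stop_bisectr("%s: line %d does not contain 6 numbers", path, i)
    }
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("a11", "a12", "a21", "a22", "dx", "dy")
  m
}

#' @rdname read_xf
#' @param xf matrix with 6 columns.
#' @export
write_xf <- function(xf, path) {
  if (ncol(xf) != 6) stop_bisectr("xf must have 6 columns")
  writeLines(apply(xf, 1, function(r) paste(sprintf("%.7g", r), collapse = "  ")),
             path)
  invisible(path)
}

#' Read tilt geometry from .tlt (+ optional .xf) files
#'
#' @param tlt_path angle file. @param xf_path optional transform file; row
#'   count must match.
#' @param tilt_axis_angle in-plane axis orientation, degrees.
#' @return list of [tilt_geometry()], one per tilt, in file order.
#' @export
read_tilt_metadata <- function(tlt_path, xf_path = NULL, tilt_axis_angle = 0) {
  angles <- read_tlt(tlt_path)
  xf <- if (is.null(xf_path)) NULL else read_xf(xf_path)
  if (!is.null(xf) && nrow(xf) != length(angles)) {
    stop_bisectr("row count mismatch: %d angles in %s vs %d transforms in %s",
                 length(angles), tlt_path, nrow(xf), xf_path)
  }
  lapply(seq_along(angles), function(i) {
    tilt_geometry(tilt_axis_angle, angles[i],
                  xf = if (is.null(xf)) NULL else xf[i, ])
  })
}

#' Read and write particle projection tables
#'
#' Tab-separated with a commented header. Coordinates are physical
#' (micrometres from the tomogram centre), pixel quantities are 0-based
#' with half-open box intervals; defocus in Angstrom, underfocus positive.
#'
#' @param meta data frame (any columns; the conventional set is
#'   `particle_id, tilt_series_id, tilt_index, x_um, y_um, z_um,
#'   e1_deg, e2_deg, e3_deg, defocus1, defocus2, astig_angle, score`).
#' @param path file path.
#' @export
write_particle_table <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bisectr particle table",
               "# coordinates: um from tomogram centre; angles: degrees (ZYZ);",
               "# defocus: Angstrom, underfocus positive; pixels 0-based",
               paste0("# ", paste(names(meta), collapse = "\t"))), con)
  write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_particle_table
#' @export
read_particle_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# [a-zA-Z_]+(\t|$)", lines, value = TRUE)
  cols <- strsplit(sub("^# ", "", tail(hdr, 1)), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, sep = "\t", col.names = cols,
                   stringsAsFactors = FALSE)
  df
}

#' Load a run configuration
#'
#' YAML file merged over the given defaults; unknown keys are kept. The
#' effective configuration should be echoed verbatim into any run log
#' (`as.yaml` of the return value).
#'
#' @param path YAML file (may be NULL for pure defaults).
#' @param defaults base configuration list.
#' @export
read_run_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop_bisectr("config %s did not parse to a mapping", path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Write an acquisition log or summary as a tab-separated table
#' @param x data frame. @param path output path.
#' @export
write_tsv_log <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
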