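#' Generate a grouped dose-symmetric tilt scheme
#'
#' Produces the acquisition order of a dose-symmetric tilt-series over
#' `[-max_tilt, +max_tilt]` in steps of `increment`, starting at 0 and
#' alternating between the positive and negative branches. The group
#' schedule controls how far a branch runs before switching: the k-th
#' branch visit collects angles until its branch leads the other by
#' `group_schedule[k]` increments (the schedule repeats its last value once
#' exhausted). With a schedule of all 1s this reproduces the classic
#' dose-symmetric order `0, +3, -3, -6, +6, +9, -9, ...`; larger groups
#' trade some symmetry for fewer stage reversals.
#'
#' @param max_tilt maximum tilt magnitude, degrees; a non-negative multiple
#'   of `increment`.
#' @param increment tilt step, degrees (> 0).
#' @param group_schedule integer vector of per-switch group sizes (>= 1).
#' @param dose_per_tilt electron dose per tilt image, e-/A^2.
#' @param start_positive logical; take the first step on the positive branch.
#' @return An object of class `tilt_scheme`: list with `angles` (acquisition
#'   order), `increment`, `max_tilt`, `group_schedule`, `dose_per_tilt`.
#' @examples
#' generate_grouped_dose_symmetric(6, 3, 1)$angles  # 0  3 -3 -6  6
#' @export
generate_grouped_dose_symmetric <- function(max_tilt, increment,
                                            group_schedule = 1,
                                            dose_per_tilt = 3,
                                            start_positive = TRUE) {
  check_finite(max_tilt); check_finite(increment)
  if (increment <= 0) stop_bisectr("increment must be > 0")
  n_steps <- max_tilt / increment
  if (max_tilt < 0 || abs(n_steps - round(n_steps)) > 1e-9) {
    stop_bisectr("max_tilt (%g) must be a non-negative multiple of increment (%g)",
                 max_tilt, increment)
  }
  n_steps <- round(n_steps)
  group_schedule <- as.integer(group_schedule)
  if (any(group_schedule < 1)) stop_bisectr("group sizes must be >= 1")

  pos <- seq_len(n_steps) * increment          # pending positive angles
  neg <- -seq_len(n_steps) * increment         # pending negative angles
  angles <- 0
  lead_pos <- 0; lead_neg <- 0                 # covered extent per branch
  on_pos <- start_positive
  k <- 1L
  while (length(pos) > 0 || length(neg) > 0) {
    g <- group_schedule[min(k, length(group_schedule))]
    target <- (if (on_pos) lead_neg else lead_pos) + g * increment
    if (on_pos) {
      if (length(pos) == 0) { on_pos <- FALSE; next }
      take <- which(pos <= target + 1e-9)
      if (length(take) == 0) take <- 1L
      angles <- c(angles, pos[take]); lead_pos <- max(pos[take])
      pos <- pos[-take]
    } else {
      if (length(neg) == 0) { on_pos <- TRUE; next }
      take <- which(-neg <= target + 1e-9)
      if (length(take) == 0) take <- 1L
      angles <- c(angles, neg[take]); lead_neg <- max(-neg[take])
      neg <- neg[-take]
    }
    on_pos <- !on_pos
    k <- k + 1L
  }
  structure(list(angles = angles, increment = increment, max_tilt = max_tilt,
                 group_schedule = group_schedule, dose_per_tilt = dose_per_tilt),
            class = "tilt_scheme")
}

#' Coerce an externally supplied angle sequence into a tilt scheme
#'
#' @param angles numeric vector in acquisition order.
#' @param dose_per_tilt e-/A^2 per tilt.
#' @export
as_tilt_scheme <- function(angles, dose_per_tilt = 3) {
  check_finite(angles)
  rep_ <- validate_scheme(angles)
  structure(list(angles = angles, increment = rep_$inferred_increment,
                 max_tilt = max(abs(angles)), group_schedule = NA,
                 dose_per_tilt = dose_per_tilt),
            class = "tilt_scheme")
}

#' @export
print.tilt_scheme <- function(x, ...) {
  cat(sprintf("tilt scheme: %d angles, +/-%g deg in %g deg steps, %g e-/A^2 per tilt\n",
              length(x$angles), x$max_tilt, x$increment, x$dose_per_tilt))
  cat(" order:", paste(x$angles, collapse = " "), "\n")
  invisible(x)
}

#' Validate a tilt-angle sequence against the scheme invariants
#'
#' Checks that an acquisition-ordered angle list starts at 0, contains every
#' multiple of the inferred increment in its range exactly once, and has no
#' duplicates.
#'
#' @param angles numeric vector (acquisition order), non-empty.
#' @return list with `count`, `coverage_ok`, `duplicates`, `first_is_zero`,
#'   `inferred_increment`, `max_tilt`.
#' @export
validate_scheme <- function(angles) {
  check_finite(angles)
  if (length(angles) == 0) stop_bisectr("empty angle list")
  dup <- unique(angles[duplicated(angles)])
  s <- sort(unique(angles))
  inc <- if (length(s) > 1) min(diff(s)) else NA_real_
  mx <- max(abs(angles))
  coverage <- length(dup) == 0 && length(s) > 1 &&
    isTRUE(all.equal(s, seq(-mx, mx, by = inc), tolerance = 1e-9)) &&
    length(s) == length(angles)
  if (length(angles) == 1) coverage <- angles[1] == 0
  list(count = length(angles),
       coverage_ok = coverage,
       duplicates = dup,
       first_is_zero = angles[1] == 0,
       inferred_increment = inc,
       max_tilt = mx)
}

#' Accumulated electron dose per tilt
#'
#' Cumulative dose in acquisition order, assuming a constant dose per tilt;
#' the result can be re-indexed by tilt angle via its names.
#'
#' @param scheme a [tilt_scheme][generate_grouped_dose_symmetric] object.
#' @return Named numeric vector (names = angles) of cumulative e-/A^2.
#' @export
accumulated_dose <- function(scheme) {
  if (!inherits(scheme, "tilt_scheme")) stop_bisectr("expected a tilt_scheme")
  if (!is.numeric(scheme$dose_per_tilt) || scheme$dose_per_tilt <= 0) {
    stop_bisectr("dose_per_tilt must be > 0")
  }
  cum <- seq_along(scheme$angles) * scheme$dose_per_tilt
  names(cum) <- scheme$angles
  cum
}

#' Bundled reference tilt schemes
#'
#' Returns the path of (or reads) one of the grouped dose-symmetric angle
#' sequences shipped with the package: `"pm60"` is a 41-tilt +/-60 degree
#' series and `"pm36"` a 25-tilt +/-36 degree series, both with 3 degree
#' increments and the irregular, throughput-oriented group structure used on
#' real instruments. These are data files, not generator output.
#'
#' @param name `"pm60"` or `"pm36"`.
#' @param dose_per_tilt e-/A^2 per tilt used when reading into a scheme
#'   (defaults: 3 for pm60, 5 for pm36 as used at acquisition).
#' @return `scheme_fixture_path()`: file path. `scheme_fixture()`: a
#'   `tilt_scheme`.
#' @export
scheme_fixture_path <- function(name = c("pm60", "pm36")) {
  name <- match.arg(name)
  system.file("extdata", paste0("grouped_", name, ".tlt"),
              package = "bisectr", mustWork = TRUE)
}

#' @rdname scheme_fixture_path
#' @export
scheme_fixture <- function(name = c("pm60", "pm36"), dose_per_tilt = NULL) {
  name <- match.arg(name)
  dose <- dose_per_tilt %||% if (name == "pm60") 3 else 5
  as_tilt_scheme(read_tlt(scheme_fixture_path(name)), dose_per_tilt = dose)
}
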