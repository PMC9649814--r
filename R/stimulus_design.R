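# Stimulus design for the numerosity categorization task: a geometric ladder
# of dot numerosities spanning one octave either side of 16 dots, an anchored
# randomized trial schedule, and non-overlapping dot-field layouts.

#' Geometrically spaced numerosity levels
#'
#' Builds the test ladder for a numerosity categorization experiment: levels
#' are log-uniformly (geometrically) spaced between `n_min` and `n_max` and
#' rounded half-away-from-zero to integers. With the defaults (8, 32, 11) the
#' ladder is 8, 9, 11, 12, 14, 16, 18, 21, 24, 28, 32 and the geometric mean
#' of the extremes is 16 dots.
#'
#' @param n_min Smallest numerosity (dots), a positive integer.
#' @param n_max Largest numerosity (dots), greater than `n_min`.
#' @param n_levels Number of levels in the ladder, at least 2.
#'
#' @return An object of class `stimulus_range`: a list with `n_min`, `n_max`,
#'   `n_levels`, the integer `levels`, and `levels_raw` (the unrounded
#'   geometric positions, useful for checking the constant-ratio property).
#'
#' @details Rounding collisions (two levels mapping to the same integer) are a
#'   degenerate design and raise an error of class
#'   `numsense_degenerate_design`; pick fewer levels or a wider range.
#'
#' @examples
#' make_levels(8, 32, 11)$levels
#' @export
make_levels <- function(n_min = 8, n_max = 32, n_levels = 11) {
  if (!is_count(n_min, positive = TRUE) || !is_count(n_max, positive = TRUE)) {
    abort_ns("`n_min` and `n_max` must be positive integers", "numsense_invalid_argument")
  }
  if (n_max <= n_min) abort_ns("`n_max` must exceed `n_min`", "numsense_invalid_argument")
  if (!is_count(n_levels) || n_levels < 2) {
    abort_ns("`n_levels` must be an integer >= 2", "numsense_invalid_argument")
  }
  raw <- 10^seq(log10(n_min), log10(n_max), length.out = n_levels)
  lv <- as.integer(round_half_up(raw))
  if (anyDuplicated(lv)) {
    abort_ns("rounded levels collide; the design is degenerate (use fewer levels or a wider range)",
             "numsense_degenerate_design")
  }
  structure(
    list(n_min = as.integer(n_min), n_max = as.integer(n_max),
         n_levels = as.integer(n_levels), levels = lv, levels_raw = raw),
    class = "stimulus_range"
  )
}

#' @export
print.stimulus_range <- function(x, ...) {
  cat(sprintf("<stimulus_range> %d levels, %d..%d dots\n", x$n_levels, x$n_min, x$n_max))
  cat(" levels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Dot-field display parameters
#'
#' Geometry and timing of the dot display: dot diameter and field diameter in
#' degrees of visual angle, the fraction of white (vs black) dots used to
#' balance luminance, and the presentation duration (brief, to prevent serial
#' counting).
#'
#' @param dot_diameter_deg Dot diameter in visual degrees.
#' @param field_diameter_deg Diameter of the virtual circular field.
#' @param fraction_white Proportion of white dots, in `[0, 1]`.
#' @param duration_ms Stimulus duration in milliseconds.
#' @return An object of class `dot_field_spec`.
#' @export
dot_field_spec <- function(dot_diameter_deg = 0.25, field_diameter_deg = 12,
                           fraction_white = 0.5, duration_ms = 500) {
  if (!is_scalar_num(dot_diameter_deg) || !is_scalar_num(field_diameter_deg) ||
      dot_diameter_deg <= 0 || dot_diameter_deg >= field_diameter_deg) {
    abort_ns("need 0 < dot_diameter_deg < field_diameter_deg", "numsense_invalid_argument")
  }
  if (!is_scalar_num(fraction_white) || fraction_white < 0 || fraction_white > 1) {
    abort_ns("`fraction_white` must be in [0, 1]", "numsense_invalid_argument")
  }
  if (!is_scalar_num(duration_ms) || duration_ms <= 0) {
    abort_ns("`duration_ms` must be positive", "numsense_invalid_argument")
  }
  structure(list(dot_diameter_deg = dot_diameter_deg,
                 field_diameter_deg = field_diameter_deg,
                 fraction_white = fraction_white,
                 duration_ms = duration_ms),
            class = "dot_field_spec")
}

#' Anchored, randomized trial schedule
#'
#' Produces the session schedule: four unscored "anchoring" trials presenting
#' the two range extremes twice each (order max, min, max, min), followed by
#' every ladder level repeated `reps` times in a seeded random permutation.
#' With the default 11-level ladder and `reps = 4` the test phase has 44
#' trials.
#'
#' @param range A `stimulus_range`, e.g. from [make_levels()].
#' @param reps Repetitions of each level in the test phase.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#'
#' @return An object of class `trial_schedule` with a `trials` data frame
#'   (`trial_index` starting at 0, `numerosity`, `is_anchor`).
#' @export
make_schedule <- function(range = make_levels(), reps = 4, seed = 1L) {
  if (!inherits(range, "stimulus_range")) {
    abort_ns("`range` must be a stimulus_range", "numsense_invalid_argument")
  }
  if (!is_count(reps, positive = TRUE)) {
    abort_ns("`reps` must be a positive integer", "numsense_invalid_argument")
  }
  anchors <- c(range$n_max, range$n_min, range$n_max, range$n_min)
  test <- rep(range$levels, times = reps)
  test <- with_seed(seed, test[sample.int(length(test))])
  num <- c(anchors, test)
  trials <- data.frame(
    trial_index = seq_along(num) - 1L,
    numerosity = as.integer(num),
    is_anchor = c(rep(TRUE, length(anchors)), rep(FALSE, length(test)))
  )
  structure(list(trials = trials, range = range, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d anchor + %d test trials (seed %d)\n",
              sum(x$trials$is_anchor), sum(!x$trials$is_anchor), x$seed))
  invisible(x)
}

#' Place non-overlapping dots in a circular field
#'
#' Scatters `numerosity` dot centers uniformly at random within the virtual
#' circular field, rejection-sampling positions so that no two dot centers lie
#' closer than one dot diameter (no overlap) and every dot lies fully inside
#' the field. Polarities alternate white/black and are then shuffled, so white
#' and black counts never differ by more than one when `fraction_white` is
#' 0.5.
#'
#' @param numerosity Number of dots to place.
#' @param spec A [dot_field_spec()].
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling retry cap per dot; exceeding it raises
#'   an error of class `numsense_placement_failure`.
#'
#' @return A data frame of class `dot_array` with columns `dot_index` (0
#'   based), `x_deg`, `y_deg` (degrees, origin at field center) and `polarity`
#'   (`"white"` or `"black"`).
#' @export
place_dots <- function(numerosity, spec = dot_field_spec(), seed = 1L,
                       max_tries = 10000L) {
  if (!is_count(numerosity, positive = TRUE)) {
    abort_ns("`numerosity` must be a positive integer", "numsense_invalid_argument")
  }
  if (!inherits(spec, "dot_field_spec")) {
    abort_ns("`spec` must be a dot_field_spec", "numsense_invalid_argument")
  }
  r_max <- spec$field_diameter_deg / 2 - spec$dot_diameter_deg / 2
  min_d2 <- spec$dot_diameter_deg^2
  xs <- ys <- numeric(numerosity)
  with_seed(seed, {
    for (i in seq_len(numerosity)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        rad <- r_max * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        x <- rad * cos(ang); y <- rad * sin(ang)
        if (i == 1L ||
            all((xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2 >= min_d2)) {
          xs[i] <- x; ys[i] <- y
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort_ns(sprintf("could not place dot %d of %d after %d tries (packing too dense)",
                         i, numerosity, max_tries),
                 "numsense_placement_failure")
      }
    }
    n_white <- round_half_up(spec$fraction_white * numerosity)
    pol <- c(rep("white", n_white), rep("black", numerosity - n_white))
    pol <- pol[sample.int(numerosity)]
    out <- data.frame(dot_index = seq_len(numerosity) - 1L,
                      x_deg = xs, y_deg = ys, polarity = pol)
    class(out) <- c("dot_array", "data.frame")
    out
  })
}

#' Export a trial schedule to CSV
#'
#' Writes `trial_index, numerosity, is_anchor` (0-based index, header row).
#' @param schedule A `trial_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  if (!inherits(schedule, "trial_schedule")) {
    abort_ns("`schedule` must be a trial_schedule", "numsense_invalid_argument")
  }
  write_csv_ns(schedule$trials, path)
}

#' Export a dot array to CSV
#'
#' Writes `dot_index, x_deg, y_deg, polarity`.
#' @param dots A `dot_array` from [place_dots()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot_array <- function(dots, path) {
  if (!inherits(dots, "dot_array")) {
    abort_ns("`dots` must be a dot_array", "numsense_invalid_argument")
  }
  write_csv_ns(as.data.frame(dots), path)
}
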