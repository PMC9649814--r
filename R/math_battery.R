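# Age-normative scoring of the six-task symbolic math battery. Raw scores
# are standardized against a (task, age band) normative table; the aggregate
# index is the mean of the z-scores a participant actually completed, defined
# only when at least `min_tasks` tasks are available. Missing scores stay
# missing (cases are excluded per dependent variable) unless group-mean
# imputation is explicitly requested.

#' Names of the six math battery tasks
#' @return Character vector of task identifiers.
#' @export
math_tasks <- function() {
  c("counting", "reading", "writing", "multiplications",
    "addition_subtraction", "choose_largest")
}

#' Read a normative table
#'
#' Loads a `task, age_lo, age_hi, mean, sd` CSV. Bands are half-open
#' `[age_lo, age_hi)` except the oldest band of each task, which includes its
#' upper edge. The packaged default (`synthetic_norms.csv`) is a synthetic
#' table with one-year bands from 8 to 16; real battery norms are proprietary
#' and must be supplied by the user in the same format.
#'
#' @param path CSV path; defaults to the packaged synthetic table.
#' @return A data frame of class `normative_table`.
#' @export
read_norms <- function(path = system.file("extdata", "synthetic_norms.csv",
                                          package = "numsense")) {
  tb <- read_csv_ns(path)
  req <- c("task", "age_lo", "age_hi", "mean", "sd")
  if (!all(req %in% names(tb))) {
    abort_ns(sprintf("normative table must have columns: %s", paste(req, collapse = ", ")),
             "numsense_parse_error")
  }
  validate_norms(tb)
  class(tb) <- c("normative_table", "data.frame")
  tb
}

validate_norms <- function(tb) {
  if (any(tb$sd <= 0)) abort_ns("normative sd must be > 0 in every band", "numsense_invalid_argument")
  for (task in unique(tb$task)) {
    b <- tb[tb$task == task, , drop = FALSE]
    b <- b[order(b$age_lo), , drop = FALSE]
    if (any(b$age_hi <= b$age_lo)) {
      abort_ns(sprintf("task '%s': bands must have age_hi > age_lo", task), "numsense_invalid_argument")
    }
    if (nrow(b) > 1 && any(abs(b$age_lo[-1] - b$age_hi[-nrow(b)]) > 1e-9)) {
      abort_ns(sprintf("task '%s': age bands must tile the range with no gaps", task),
               "numsense_invalid_argument")
    }
  }
  invisible(tb)
}

norm_band <- function(table, task, age_yr) {
  b <- table[table$task == task, , drop = FALSE]
  if (nrow(b) == 0L) {
    abort_ns(sprintf("unknown task '%s' in normative table", task), "numsense_invalid_argument")
  }
  top <- max(b$age_hi)
  hit <- b$age_lo <= age_yr & (age_yr < b$age_hi | (b$age_hi == top & age_yr <= top))
  if (!any(hit)) {
    abort_ns(sprintf("no normative band covers age %.2f for task '%s'", age_yr, task),
             "numsense_no_norm")
  }
  b[which(hit)[1], , drop = FALSE]
}

#' Age-normative z-score for one raw score
#'
#' `z = (raw - norm_mean) / norm_sd` using the normative band containing the
#' participant's age.
#'
#' @param raw Raw task score.
#' @param task Task name (see [math_tasks()], or any task in the table).
#' @param age_yr Age in years.
#' @param table A [read_norms()] normative table.
#' @return The z-score; `NA` if `raw` is `NA` (a missing score stays missing).
#' @export
zscore <- function(raw, task, age_yr, table) {
  b <- norm_band(table, task, age_yr)
  if (is.na(raw)) return(NA_real_)
  (raw - b$mean) / b$sd
}

# Inverse of zscore(); used by the cohort generator to emit raw scores whose
# standardization lands on a configured z.
raw_from_z <- function(z, task, age_yr, table) {
  b <- norm_band(table, task, age_yr)
  b$mean + z * b$sd
}

#' Aggregate math index from per-task z-scores
#'
#' The aggregate is the arithmetic mean of the z-scores that are present. It
#' is defined only when at least `min_tasks` tasks are available, mirroring
#' the retention of participants who completed four of the six tasks;
#' otherwise it is `NA`.
#'
#' @param z Named numeric vector of per-task z-scores (`NA` = missing).
#' @param min_tasks Minimum number of available tasks for the aggregate.
#' @return A list of class `math_scores`: `z`, `aggregate`, `n_available`.
#' @export
aggregate_index <- function(z, min_tasks = 4) {
  if (length(z) > length(math_tasks())) {
    abort_ns("more task scores than known tasks", "numsense_invalid_argument")
  }
  n_avail <- sum(!is.na(z))
  agg <- if (n_avail >= min_tasks) mean(z[!is.na(z)]) else NA_real_
  structure(list(z = z, aggregate = agg, n_available = as.integer(n_avail)),
            class = "math_scores")
}

#' Standardize the math battery for a whole cohort
#'
#' Applies [zscore()] per task and participant and builds the aggregate
#' index. Missing raw scores propagate to missing z-scores; per-task analyses
#' downstream use each task's own available cases.
#'
#' @param participants Participants data frame (columns `id`, `group`,
#'   `age_yr` and one raw-score column per task).
#' @param norms A [read_norms()] table.
#' @param min_tasks Minimum tasks for the aggregate (default 4).
#' @return Data frame with `id`, `group`, one `z_<task>` column per task,
#'   `aggregate` and `n_available`.
#' @export
score_math <- function(participants, norms, min_tasks = 4) {
  tasks <- intersect(math_tasks(), names(participants))
  if (length(tasks) == 0L) abort_ns("no task score columns found", "numsense_invalid_input")
  out <- participants[, c("id", "group"), drop = FALSE]
  zm <- matrix(NA_real_, nrow(participants), length(tasks),
               dimnames = list(NULL, tasks))
  for (i in seq_len(nrow(participants))) {
    for (t in tasks) {
      zm[i, t] <- zscore(participants[[t]][i], t, participants$age_yr[i], norms)
    }
  }
  for (t in tasks) out[[paste0("z_", t)]] <- zm[, t]
  agg <- apply(zm, 1, function(zz) aggregate_index(zz, min_tasks))
  out$aggregate <- vapply(agg, function(a) a$aggregate, numeric(1))
  out$n_available <- vapply(agg, function(a) a$n_available, integer(1))
  out
}

#' Group-mean imputation of missing raw task scores
#'
#' Replaces each missing raw score by the mean of the observed scores for the
#' same task within the same group, and flags the imputed cells in
#' `imputed_<task>` columns. Group-mean imputation leaves every group's
#' per-task mean unchanged by construction; it is off by default throughout
#' the pipeline and provided for sensitivity analyses.
#'
#' @param participants Participants data frame.
#' @param tasks Tasks to impute (default: all present task columns).
#' @return The data frame with missing scores filled and flag columns added.
#' @export
impute_group_mean <- function(participants, tasks = NULL) {
  tasks <- tasks %||% intersect(math_tasks(), names(participants))
  out <- participants
  for (t in tasks) {
    if (!t %in% names(out)) abort_ns(sprintf("unknown task '%s'", t), "numsense_invalid_argument")
    flag <- is.na(out[[t]])
    for (g in unique(out$group)) {
      sel <- out$group == g
      obs <- out[[t]][sel & !flag]
      if (any(sel & flag)) {
        if (length(obs) == 0L) {
          abort_ns(sprintf("no observed '%s' scores in group '%s' to impute from", t, g),
                   "numsense_no_data")
        }
        out[[t]][sel & flag] <- mean(obs)
      }
    }
    out[[paste0("imputed_", t)]] <- flag
  }
  out
}

#' Write per-participant math z-scores to CSV
#' @param scores Data frame from [score_math()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_math_z <- function(scores, path) write_csv_ns(scores, path)
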