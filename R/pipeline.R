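# End-to-end study analysis: load or simulate a cohort, fit psychometric
# functions, standardize the math battery, and run the full Bayesian
# comparison suite (demographics, normality-gated group comparisons,
# precision-math correlations, ANCOVA inclusion BFs, clinical correlations),
# writing a machine-readable JSON report plus CSV tables.

#' Analysis configuration
#'
#' Either `simulate` (a list of [cohort_config()] overrides) or `inputs` (a
#' list with `dir` pointing at `participants.csv`/`trials.csv`, and
#' optionally `norms`, a normative-table CSV path) must be given — not both.
#'
#' @param simulate `NULL` or a named list passed to [cohort_config()].
#' @param inputs `NULL` or a list with `dir` and optionally `norms`.
#' @param priors Prior scales used throughout: `r_ttest`, `r_fixed`,
#'   `r_cov`, `kendall_width`, `pearson_width`, `dirichlet_a`.
#' @param min_tasks Minimum available tasks for the aggregate math index.
#' @param thresholds Evidence thresholds for [classify_evidence()].
#' @param alpha_norm Significance level of the Shapiro-Wilk normality gate.
#' @param mw_draws,mw_warmup Gibbs sampler size for the rank-based test.
#' @param impute Use group-mean imputation of missing math scores instead of
#'   per-variable case exclusion (sensitivity analysis; default `FALSE`).
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory for report artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(simulate = NULL, inputs = NULL,
                            priors = list(), min_tasks = 4,
                            thresholds = c(substantial = 0.5, strong = 1, definitive = 2),
                            alpha_norm = 0.05,
                            mw_draws = 4000, mw_warmup = 1000,
                            impute = FALSE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) == is.null(inputs)) {
    abort_ns("exactly one of `simulate` and `inputs` must be given", "numsense_invalid_config")
  }
  defaults <- list(r_ttest = sqrt(2) / 2, r_fixed = 0.5, r_cov = sqrt(2) / 4,
                   kendall_width = 1, pearson_width = 1, dirichlet_a = 1)
  priors <- utils::modifyList(defaults, priors)
  structure(list(simulate = simulate, inputs = inputs, priors = priors,
                 min_tasks = min_tasks, thresholds = thresholds,
                 alpha_norm = alpha_norm, mw_draws = mw_draws,
                 mw_warmup = mw_warmup, impute = impute,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file whose top-level keys are the
#'   arguments of [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_ns(sprintf("config file not found: %s", path), "numsense_io_error")
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_ns(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "numsense_invalid_config")
  }
  if (!is.null(raw$thresholds)) raw$thresholds <- unlist(raw$thresholds)
  do.call(analysis_config, raw)
}

# Recode raw CGAS functioning scores (1-100, higher = better functioning)
# into 1-10 severity categories (1 = top functioning decile, i.e. no
# symptoms; 10 = most severe). Values already in 1..10 are passed through.
recode_cgas <- function(score) {
  if (all(is.na(score)) || all(score[!is.na(score)] %in% 1:10)) return(score)
  out <- 10 - (ceiling(score / 10) - 1)
  out[score < 1 | score > 100] <- NA
  out
}

bf_entry <- function(bf, extra = list()) {
  c(list(method = bf$method, lbf = bf$lbf, label = bf$label,
         statistic = as.list(bf$statistic), n = as.list(as.list(bf$n)),
         prior = bf$prior),
    if (!is.null(bf$mc_se)) list(mc_se = bf$mc_se),
    extra)
}

stage_error <- function(stage, e) {
  abort_ns(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           "numsense_stage_error")
}

#' Run the full study analysis
#'
#' Executes the complete analysis chain on a simulated or loaded cohort:
#' (1) cohort acquisition; (2) per-participant psychometric fits (skipped
#' for participants without trial data, whose precomputed `wf_true` /
#' `pse_true` are used directly); (3) math-battery standardization and
#' aggregate index; (4) demographic checks (age t-test BF, sex-ratio
#' contingency BF); (5) per-measure group comparisons with the Shapiro-Wilk
#' gate selecting the parametric or rank-based Bayes factor; (6) Kendall
#' correlation between Weber fraction and the math aggregate within each
#' group; (7) ANCOVA inclusion BFs for every markedly impaired measure
#' (group-comparison LBF above the `strong` threshold) plus the aggregate,
#' with covariate sets `{Wf}` and `{Wf, irp_z, age, sex}`; (8) Kendall
#' correlations with clinical scores within the clinical group; (9) report
#' writing. Fully deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @return A list of class `study_report` (also written to
#'   `config$out_dir` as `report.json` plus CSV tables when set).
#' @export
run_study <- function(config) {
  if (!inherits(config, "analysis_config")) {
    abort_ns("`config` must be an analysis_config", "numsense_invalid_config")
  }
  pr <- config$priors
  seeds <- derive_seeds(config$seed, 64)

  # (1) acquire cohort
  cohort <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- sim$seed %||% seeds[1]
      generate_cohort(do.call(cohort_config, sim))
    } else {
      read_cohort(config$inputs$dir)
    }
  }, error = function(e) stage_error("cohort", e))
  norms <- tryCatch({
    if (!is.null(config$inputs$norms)) read_norms(config$inputs$norms) else read_norms()
  }, error = function(e) stage_error("norms", e))
  pp <- cohort$participants

  # (2) psychometric fits where trials exist; precomputed values otherwise
  measures <- tryCatch({
    m <- pp[, c("id", "group", "age_yr", "sex"), drop = FALSE]
    m$wf <- pp$wf_true %||% rep(NA_real_, nrow(pp))
    m$pse <- pp$pse_true %||% rep(NA_real_, nrow(pp))
    m$wf_source <- "precomputed"
    fits <- NULL
    if (!is.null(cohort$trials)) {
      fits <- fit_cohort(cohort)
      idx <- match(fits$id, m$id)
      m$wf[idx] <- fits$wf
      m$pse[idx] <- fits$pse
      m$wf_source[idx] <- "fitted"
    }
    list(table = m, fits = fits)
  }, error = function(e) stage_error("psychometric_fit", e))
  mt <- measures$table

  # (3) math z-scores and aggregate
  math <- tryCatch({
    ppm <- pp
    if (isTRUE(config$impute)) ppm <- impute_group_mean(ppm)
    score_math(ppm, norms, min_tasks = config$min_tasks)
  }, error = function(e) stage_error("math_battery", e))

  grp <- function(df, g) df[df$group == g, , drop = FALSE]
  adhd <- "ADHD"; ctrl <- "control"

  # (4) demographics
  demographics <- tryCatch({
    sex_tab <- rbind(ADHD = table(factor(grp(pp, adhd)$sex, c("M", "F"))),
                     control = table(factor(grp(pp, ctrl)$sex, c("M", "F"))))
    list(
      age = bf_entry(lbf_ttest_two_sample(grp(pp, adhd)$age_yr,
                                          grp(pp, ctrl)$age_yr, r = pr$r_ttest)),
      sex_ratio = bf_entry(lbf_contingency_2x2(sex_tab, a = pr$dirichlet_a),
                           extra = list(counts = as.list(as.data.frame(sex_tab))))
    )
  }, error = function(e) stage_error("demographics", e))

  # assemble the per-measure table used by stages 5-9
  meas_cols <- c("wf", "pse", paste0("z_", math_tasks()), "aggregate", "irp_z")
  full <- merge(mt, math[, c("id", grep("^z_|^aggregate$|^n_available$", names(math), value = TRUE))],
                by = "id", sort = FALSE)
  full$irp_z <- pp$irp_z[match(full$id, pp$id)]

  # (5) group comparisons with the normality gate
  comparisons <- tryCatch({
    out <- list()
    for (i in seq_along(meas_cols)) {
      mc <- meas_cols[i]
      x <- grp(full, adhd)[[mc]]; y <- grp(full, ctrl)[[mc]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      gate <- check_normality_and_select(x, y, config$alpha_norm)
      bf <- if (gate$choice == "parametric") {
        lbf_ttest_two_sample(x, y, r = pr$r_ttest)
      } else {
        lbf_mannwhitney(x, y, r = pr$r_ttest, draws = config$mw_draws,
                        warmup = config$mw_warmup, seed = seeds[4 + i])
      }
      out[[mc]] <- bf_entry(bf, extra = list(
        test_selected = gate$choice,
        selection_reason = sprintf(
          "Shapiro-Wilk W = %.3f/%.3f, p = %.4f/%.4f (gate alpha %.2f)",
          gate$W[1], gate$W[2], gate$p[1], gate$p[2], gate$alpha_norm),
        n_adhd = length(x), n_control = length(y)))
    }
    out
  }, error = function(e) stage_error("group_comparisons", e))

  # (6) Wf vs math aggregate, Kendall, within each group
  wf_math <- tryCatch({
    lapply(stats::setNames(c(adhd, ctrl), c(adhd, ctrl)), function(g) {
      d <- grp(full, g)
      bf_entry(lbf_kendall(d$wf, d$aggregate, width = pr$kendall_width))
    })
  }, error = function(e) stage_error("wf_math_correlation", e))

  # (7) ANCOVA inclusion for impaired measures + aggregate
  ancova <- tryCatch({
    strong <- config$thresholds[["strong"]]
    task_cols <- paste0("z_", math_tasks())
    impaired <- task_cols[vapply(task_cols, function(mc) comparisons[[mc]]$lbf > strong,
                                 logical(1))]
    targets <- unique(c(impaired, "aggregate"))
    cov_sets <- list(wf_only = "wf", all_covariates = c("wf", "irp_z", "age_yr", "sex"))
    lapply(stats::setNames(targets, targets), function(dvc) {
      lapply(cov_sets, function(cv) {
        res <- lbf_ancova_inclusion(full, dv = dvc, group = "group",
                                    covariates = cv, r_fixed = pr$r_fixed,
                                    r_cov = pr$r_cov)
        lapply(res$terms, bf_entry, extra = list(n_complete = res$n))
      })
    })
  }, error = function(e) stage_error("ancova", e))

  # (8) clinical correlations (clinical group only)
  clinical <- tryCatch({
    d <- grp(full, adhd)
    d$cgas_cat <- recode_cgas(pp$cgas[match(d$id, pp$id)])
    d$cgi_s <- pp$cgi_s[match(d$id, pp$id)]
    d$cprs <- pp$cprs[match(d$id, pp$id)]
    scales <- c("cgi_s", "cgas_cat", "cprs")
    meas <- c(wf = "wf", pse = "pse", math_aggregate = "aggregate")
    out <- list()
    for (mn in names(meas)) {
      out[[mn]] <- lapply(stats::setNames(scales, scales), function(sc) {
        bf_entry(lbf_kendall(d[[meas[[mn]]]], d[[sc]], width = pr$kendall_width))
      })
    }
    out
  }, error = function(e) stage_error("clinical_correlations", e))

  # (9) descriptives per group per measure
  descriptives <- tryCatch({
    out <- list()
    for (mc in meas_cols) {
      out[[mc]] <- lapply(stats::setNames(c(adhd, ctrl), c(adhd, ctrl)), function(g) {
        v <- grp(full, g)[[mc]]
        unclass(describe(v[!is.na(v)]))
      })
    }
    out
  }, error = function(e) stage_error("descriptives", e))

  report <- structure(
    list(meta = list(package = "numsense", seed = config$seed,
                     priors = pr, thresholds = as.list(config$thresholds),
                     min_tasks = config$min_tasks, impute = config$impute,
                     cohort_source = if (is.null(config$simulate)) "files" else "simulated",
                     n = as.list(table(pp$group))),
         demographics = demographics,
         descriptives = descriptives,
         group_comparisons = comparisons,
         wf_math_correlation = wf_math,
         ancova_inclusion = ancova,
         clinical_correlations = clinical),
    class = "study_report"
  )
  attr(report, "tables") <- list(measures = full, fits = measures$fits, math = math)

  if (!is.null(config$out_dir)) {
    write_study_report(report, config$out_dir)
  }
  report
}

#' Write a study report to disk
#'
#' Writes `report.json` (the full report; deterministic content, no
#' timestamps) and CSV side tables (`measures.csv`, `fits.csv`, `math_z.csv`)
#' into `dir`.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  tb <- attr(report, "tables")
  if (!is.null(tb)) {
    write_csv_ns(tb$measures, file.path(dir, "measures.csv"))
    if (!is.null(tb$fits)) write_csv_ns(tb$fits, file.path(dir, "fits.csv"))
    write_csv_ns(tb$math, file.path(dir, "math_z.csv"))
  }
  invisible(dir)
}

#' Render a report JSON as human-readable tables
#'
#' @param path Path to a `report.json` written by [run_study()].
#' @param file Connection or path for the rendered text (default stdout).
#' @return Invisibly, the parsed report list.
#' @export
render_report <- function(path, file = stdout()) {
  rep <- jsonlite::read_json(path)
  lines <- c(sprintf("Study report (seed %s)", rep$meta$seed), "")
  lines <- c(lines, "== Demographics ==",
             sprintf("  age: LBF = %.2f [%s]", rep$demographics$age$lbf,
                     rep$demographics$age$label),
             sprintf("  sex ratio: LBF = %.2f [%s]", rep$demographics$sex_ratio$lbf,
                     rep$demographics$sex_ratio$label), "")
  lines <- c(lines, "== Group comparisons ==")
  for (nm in names(rep$group_comparisons)) {
    gc <- rep$group_comparisons[[nm]]
    lines <- c(lines, sprintf("  %-24s LBF = %6.2f  [%s, %s]", nm, gc$lbf,
                              gc$label, gc$test_selected))
  }
  lines <- c(lines, "", "== Wf vs math aggregate (Kendall) ==")
  for (g in names(rep$wf_math_correlation)) {
    k <- rep$wf_math_correlation[[g]]
    lines <- c(lines, sprintf("  %-10s tau = %5.2f, LBF = %6.2f [%s]", g,
                              k$statistic$tau, k$lbf, k$label))
  }
  lines <- c(lines, "", "== ANCOVA inclusion (group term) ==")
  for (dv in names(rep$ancova_inclusion)) {
    for (cs in names(rep$ancova_inclusion[[dv]])) {
      lines <- c(lines, sprintf("  %-24s [%s] group LBF_incl = %6.2f", dv, cs,
                                rep$ancova_inclusion[[dv]][[cs]]$group$lbf))
    }
  }
  writeLines(lines, con = file)
  invisible(rep)
}
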