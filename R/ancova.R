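# Bayesian ANCOVA with inclusion Bayes factors. Every additive subset of the
# terms {group, covariates} is a model; each model's marginal likelihood uses
# a JZS-style mixture-of-g prior (a single g per model with an inverse-gamma
# (1/2, 1/2) mixing density, so each standardized effect is marginally
# Cauchy), with fixed-effect columns on scale r_fixed and covariate columns
# on scale r_cov. The inclusion Bayes factor of a term compares the averaged
# marginal likelihood of the models containing it against those without it,
# with equal prior probability on every model.

# Design column for one term: two-level factors become a centered +/- 1/2
# contrast (so the effect is the standardized group difference); numeric
# covariates are centered and scaled to unit variance (so the effect is per
# SD of the covariate).
term_column <- function(v, name) {
  if (is.character(v) || is.factor(v) || is.logical(v)) {
    f <- factor(v)
    if (nlevels(f) != 2) {
      abort_ns(sprintf("factor term '%s' must have exactly 2 levels", name),
               "numsense_invalid_argument")
    }
    col <- ifelse(as.integer(f) == 2L, 0.5, -0.5)
    list(col = col - mean(col), fixed = TRUE)
  } else {
    s <- stats::sd(v)
    if (s == 0) abort_ns(sprintf("covariate '%s' has zero variance", name),
                         "numsense_invalid_argument")
    list(col = (v - mean(v)) / s, fixed = FALSE)
  }
}

# log10 Bayes factor of one g-prior model against the intercept-only model.
g_model_logbf10 <- function(yc, Xc, scales) {
  n <- length(yc)
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  yty <- sum(yc^2)
  k <- ncol(Xc)

  log_bf_g <- function(g) {
    G <- diag(scales^2 * g, k)
    A <- diag(k) + XtX %*% G
    quad <- yty - sum(Xty * solve(diag(1 / (scales^2 * g), k) + XtX, Xty))
    -0.5 * determinant(A, logarithm = TRUE)$modulus -
      (n - 1) / 2 * (log(quad) - log(yty))
  }
  # integrate over u = log g against the inverse-gamma(1/2, 1/2) mixing
  # density; offset by the value at g = 1 for overflow safety
  off <- log_bf_g(1)
  f <- function(u) {
    vapply(u, function(ui) {
      g <- exp(ui)
      dens <- sqrt(0.5) / gamma(0.5) * g^(-1.5) * exp(-0.5 / g)
      exp(log_bf_g(g) - off) * dens * g
    }, numeric(1))
  }
  val <- stats::integrate(f, -34, 34, rel.tol = 1e-10, abs.tol = 0)$value
  (off + log(val)) / log(10)
}

#' Inclusion Bayes factors for a Bayesian ANCOVA
#'
#' Compares a dependent variable across groups while adjusting for
#' covariates, reporting for each term a log10 inclusion Bayes factor: how
#' much more likely the data are under models that include the term than
#' under models that do not, averaging over the full additive model space
#' with equal prior model probabilities. Only complete cases for the
#' dependent variable, group and covariates enter (listwise per dependent
#' variable).
#'
#' @param data Data frame.
#' @param dv Name of the numeric dependent variable column.
#' @param group Name of the group column (two-level factor).
#' @param covariates Character vector of covariate column names (numeric, or
#'   two-level factors such as sex).
#' @param r_fixed Cauchy scale for fixed (factor) effects (default 0.5).
#' @param r_cov Cauchy scale for covariate effects (default `sqrt(2)/4`,
#'   0.354).
#' @param method `"across_all"` or `"matched"`. For a purely additive model
#'   space the two coincide (they differ only when interactions are present),
#'   so both return the same value here.
#'
#' @return A list of class `ancova_result`: `terms` (named list of
#'   `bf_result`, one per term, with the inclusion LBF), and `models` (data
#'   frame of every model with its log10 BF against the intercept-only
#'   model).
#' @export
lbf_ancova_inclusion <- function(data, dv, group = "group",
                                 covariates = character(),
                                 r_fixed = 0.5, r_cov = sqrt(2) / 4,
                                 method = c("across_all", "matched")) {
  method <- match.arg(method)
  terms <- c(group, covariates)
  need <- c(dv, terms)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort_ns(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")),
             "numsense_invalid_argument")
  }
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  d <- data[cc, need, drop = FALSE]
  n <- nrow(d)
  if (n < length(terms) + 3) abort_ns("too few complete cases", "numsense_invalid_input")

  cols <- lapply(terms, function(tm) term_column(d[[tm]], tm))
  X <- do.call(cbind, lapply(cols, `[[`, "col"))
  colnames(X) <- terms
  fixed <- vapply(cols, `[[`, logical(1), "fixed")
  scales <- ifelse(fixed, r_fixed, r_cov)

  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    # name the culprits: columns whose removal restores full rank
    bad <- terms[vapply(seq_along(terms), function(j) {
      qr(cbind(1, X[, -j, drop = FALSE]))$rank == ncol(X) - 1 + 1
    }, logical(1))]
    abort_ns(sprintf("design is rank deficient (collinear terms: %s)",
                     paste(if (length(bad)) bad else terms, collapse = ", ")),
             "numsense_collinear")
  }

  yc <- d[[dv]] - mean(d[[dv]])
  k <- length(terms)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(subsets) <- terms
  logbf <- apply(subsets, 1, function(inc) {
    if (!any(inc)) return(0)  # intercept-only reference model
    g_model_logbf10(yc, X[, inc, drop = FALSE], scales[inc])
  })
  model_label <- apply(subsets, 1, function(inc) {
    if (!any(inc)) "1" else paste(terms[inc], collapse = " + ")
  })

  # Equal prior mass on every model: inclusion BF is the ratio of mean
  # marginal likelihoods with vs without the term. For an additive space the
  # matched-models restriction selects exactly the same model pairs.
  term_results <- stats::setNames(lapply(seq_len(k), function(j) {
    has <- subsets[[j]]
    ln10 <- log(10)
    num <- logsumexp(logbf[has] * ln10) - log(sum(has))
    den <- logsumexp(logbf[!has] * ln10) - log(sum(!has))
    new_bf_result((num - den) / ln10, "ancova_inclusion",
                  prior = list(family = "jzs_mixture_g", r_fixed = r_fixed,
                               r_cov = r_cov, method = method),
                  statistic = c(n_models = nrow(subsets)), n = n)
  }), terms)

  structure(list(terms = term_results,
                 models = data.frame(model = model_label, logbf10 = logbf,
                                     stringsAsFactors = FALSE),
                 n = n),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> n = %d complete cases, %d models\n", x$n, nrow(x$models)))
  for (nm in names(x$terms)) {
    cat(sprintf("  %-24s LBF_inclusion = %.3f [%s]\n", nm, x$terms[[nm]]$lbf,
                x$terms[[nm]]$label))
  }
  invisible(x)
}
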