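## standardized coefficients: beta_j * sd(x_j) / sd(y) on the estimation
## sample, computed from the fitted model's own design matrix
.std_betas <- function(fit) {
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  b <- stats::coef(fit)
  sds <- apply(X, 2L, stats::sd)
  out <- b * sds / stats::sd(y)
  out["(Intercept)"] <- NA_real_
  out
}

.coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  sb <- .std_betas(fit)
  data.frame(term = rownames(sm),
             estimate = sm[, "Estimate"],
             ci_lo = ci[rownames(sm), 1],
             ci_hi = ci[rownames(sm), 2],
             std_beta = unname(sb[rownames(sm)]),
             t = sm[, "t value"],
             df = fit$df.residual,
             p = sm[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

## backward elimination of two-way interactions: refit after removing, among
## the interactions not significantly different from zero (two-sided t,
## p >= alpha), the one with the smallest |standardized beta|; repeat until
## only main effects and significant interactions remain
.backward_eliminate <- function(data, outcome, mains, alpha) {
  interactions <- utils::combn(mains, 2L, paste, collapse = ":")
  terms_now <- c(mains, interactions)
  trace <- list()
  repeat {
    fml <- stats::reformulate(terms_now, response = outcome)
    fit <- stats::lm(fml, data = data)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design: aliased term(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab <- .coef_table(fit)
    inter_now <- intersect(terms_now, interactions)
    if (!length(inter_now)) break
    cand <- tab[tab$term %in% inter_now & tab$p >= alpha, ]
    if (!nrow(cand)) break
    drop <- cand$term[which.min(abs(cand$std_beta))]
    trace[[length(trace) + 1L]] <- cand[cand$term == drop,
                                        c("term", "std_beta", "t", "p")]
    terms_now <- setdiff(terms_now, drop)
  }
  list(fit = fit, table = tab, trace = do.call(rbind, trace),
       terms = terms_now)
}

#' Regress a center-of-mass coordinate on injection location and age
#'
#' Fits the topography model: the chosen center-of-mass coordinate as a
#' linear function of the normalized rostrocaudal (`rc`) and dorsoventral
#' (`dv`) injection coordinates and postnatal age in days, starting from the
#' model with all two-way interactions. Interactions not significantly
#' different from zero (two-sided t-test at `alpha`) are removed one at a
#' time — always the one with the smallest absolute standardized beta — and
#' the model is refitted until only main effects and significant interactions
#' remain. Experiments without labeled axons (undefined center of mass) and
#' animals older than `age_max` days are excluded before fitting.
#' Coefficients are reported unstandardized with 95% confidence intervals.
#'
#' @param data data.frame with columns `rc`, `dv`, `age` and the outcome.
#' @param outcome name of the outcome column (a CoM coordinate in `[0, 1]`).
#' @param alpha significance criterion for retaining an interaction.
#' @param age_max oldest age (days) included.
#' @return a `topo_regression`: list with the coefficient `table` (term,
#'   estimate, 95% CI, standardized beta, t, df, p), `n`, `n_excluded`, the
#'   elimination `trace`, retained `terms`, the underlying `fit`, and the
#'   estimation `data`.
#' @export
fit_topography <- function(data, outcome, alpha = 0.05, age_max = 19) {
  stopifnot(all(c("rc", "dv", "age", outcome) %in% names(data)))
  keep <- !is.na(data[[outcome]]) & data$age <= age_max
  n_excluded <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 10L)
    stop("need at least 10 usable experiments, have ", nrow(d),
         call. = FALSE)
  res <- .backward_eliminate(d, outcome, c("rc", "dv", "age"), alpha)
  structure(list(outcome = outcome, table = res$table, n = nrow(d),
                 n_excluded = n_excluded, trace = res$trace,
                 terms = res$terms, alpha = alpha, age_max = age_max,
                 fit = res$fit, data = d),
            class = "topo_regression")
}

#' Regression with age dichotomized at one week
#'
#' As [fit_topography()], but the continuous age predictor is replaced by an
#' indicator of whether the animal is at or past the cut (default 7 days),
#' testing whether animals younger and older than a week form two groups.
#'
#' @inheritParams fit_topography
#' @param cut age (days) at which the indicator switches to 1.
#' @return a `topo_regression` with predictor `age_group` in place of `age`.
#' @export
fit_age_dichotomized <- function(data, outcome, cut = 7, alpha = 0.05,
                                 age_max = 19) {
  stopifnot(all(c("rc", "dv", "age", outcome) %in% names(data)))
  keep <- !is.na(data[[outcome]]) & data$age <= age_max
  d <- data[keep, , drop = FALSE]
  d$age_group <- as.numeric(d$age >= cut)
  if (length(unique(d$age_group)) < 2L)
    stop("all animals fall on one side of the age cut", call. = FALSE)
  if (nrow(d) < 10L)
    stop("need at least 10 usable experiments, have ", nrow(d),
         call. = FALSE)
  res <- .backward_eliminate(d, outcome, c("rc", "dv", "age_group"), alpha)
  structure(list(outcome = outcome, table = res$table, n = nrow(d),
                 n_excluded = sum(!keep), trace = res$trace,
                 terms = res$terms, alpha = alpha, age_max = age_max,
                 fit = res$fit, data = d),
            class = "topo_regression")
}

#' @export
print.topo_regression <- function(x, ...) {
  cat(sprintf("<topo_regression> %s ~ %s  (n=%d, df=%d)\n", x$outcome,
              paste(x$terms, collapse = " + "), x$n, x$fit$df.residual))
  tab <- x$table
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("eliminated:",
        paste(x$trace$term, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Collinearity and residual diagnostics for a fitted topography model
#'
#' Computes pairwise Pearson correlations among the main predictors (no
#' multicollinearity is assumed while all lie within -0.70 and 0.70), the
#' variance inflation factor of every retained term from auxiliary
#' regressions (`VIF_j = 1 / (1 - R2_j)` of term j on the other terms), and
#' exports standardized residual-versus-prediction and normal-probability
#' tables for visual assessment of linearity, homoscedasticity and
#' normality.
#'
#' @param result a [fit_topography()] result.
#' @return a `topo_diagnostics`: list with `predictor_cor`,
#'   `collinearity_ok`, `vif` (named, `Inf` flags an aliased duplicate),
#'   `residuals` (data.frame of standardized predictions and residuals) and
#'   `qq` (theoretical vs sample quantiles).
#' @export
regression_diagnostics <- function(result) {
  stopifnot(inherits(result, "topo_regression"))
  mains <- intersect(c("rc", "dv", "age", "age_group"),
                     colnames(result$data))
  mains <- mains[vapply(result$data[mains], is.numeric, logical(1))]
  pc <- stats::cor(result$data[, mains])
  ok <- all(abs(pc[upper.tri(pc)]) < 0.70)
  X <- stats::model.matrix(result$fit)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  fitted <- stats::fitted(result$fit)
  resid <- stats::residuals(result$fit)
  std <- function(v) if (stats::sd(v) == 0) v * 0 else
    (v - mean(v)) / stats::sd(v)
  qq <- stats::qqnorm(std(resid), plot.it = FALSE)
  structure(list(predictor_cor = pc, collinearity_ok = ok, vif = vif,
                 residuals = data.frame(std_prediction = std(fitted),
                                        std_residual = std(resid)),
                 qq = data.frame(theoretical = qq$x, sample = qq$y)),
            class = "topo_diagnostics")
}

#' @export
print.topo_diagnostics <- function(x, ...) {
  cat("<topo_diagnostics>\n  predictor correlations within +-0.70:",
      x$collinearity_ok, "\n  max VIF:", round(max(x$vif), 3), "\n")
  invisible(x)
}
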