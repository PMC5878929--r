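#' Logistic model of correct disperser identification
#'
#' Fits the probability that a simulated disperser's status is correctly
#' identified (binary response) against predictors such as panel size,
#' ranking direction, placement population or pairwise mutual
#' information, with a binomial error distribution and logit link.
#' Random intercepts (typically for treatment and individual, to absorb
#' the non-independence of repeated assignment runs) are fitted with
#' \pkg{lme4} when requested and available; otherwise the model is the
#' maximum-likelihood fixed-effects fit via iteratively reweighted least
#' squares, with a message.
#'
#' @param data data.frame of grid-derived records (e.g. an
#'   \code{sda_grid} with a logical/0-1 \code{correct} column).
#' @param formula fixed-effects formula, response on the left
#'   (e.g. \code{correct ~ panel_size + direction}).
#' @param random optional character vector of grouping-factor column
#'   names for random intercepts, e.g. \code{c("treatment", "disperser")}.
#' @return object of class \code{power_fit}: list with
#'   \code{coefficients} (data.frame: term, estimate, se, z),
#'   \code{fitted} (response-scale), \code{linear_predictor_fixed},
#'   \code{random_variances} (named numeric, empty for pure fixed
#'   effects), \code{deviance}, \code{converged}, \code{separation}
#'   (logical: quasi-separation detected) and the underlying \code{model}.
#' @export
fit_logistic <- function(data, formula, random = NULL) {
  resp <- all.vars(formula)[1]
  y <- data[[resp]]
  if (is.logical(y)) data[[resp]] <- as.integer(y)
  if (!all(data[[resp]] %in% c(0, 1)))
    stop("response must be binary (0/1 or logical)")

  use_lme4 <- !is.null(random) && requireNamespace("lme4", quietly = TRUE)
  if (!is.null(random) && !use_lme4)
    message("mixed-model backend unavailable; fitting fixed effects only")

  if (length(unique(data[[resp]])) == 1L) {
    # degenerate: constant response — intercept-only fit
    fit <- stats::glm(stats::reformulate("1", response = resp),
                      family = stats::binomial(), data = data)
    co <- summary(fit)$coefficients
    return(structure(list(
      coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                se = co[, 2], z = co[, 3],
                                row.names = NULL),
      fitted = stats::fitted(fit),
      linear_predictor_fixed = stats::predict(fit, type = "link"),
      random_variances = numeric(0),
      deviance = stats::deviance(fit), converged = fit$converged,
      separation = FALSE, model = fit), class = "power_fit"))
  }

  if (use_lme4) {
    re_terms <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    f <- stats::as.formula(paste(deparse(formula), "+", re_terms))
    model <- lme4::glmer(f, data = data, family = stats::binomial())
    co <- summary(model)$coefficients
    vc <- as.data.frame(lme4::VarCorr(model))
    rv <- stats::setNames(vc$vcov, vc$grp)
    eta_f <- drop(lme4::getME(model, "X") %*% lme4::fixef(model))
    conv <- length(model@optinfo$conv$lme4) == 0
    fitted_v <- stats::fitted(model)
    dev <- stats::deviance(model)
  } else {
    model <- stats::glm(formula, family = stats::binomial(), data = data)
    # rank deficiency: aliased coefficients
    if (any(is.na(stats::coef(model)))) {
      aliased <- names(stats::coef(model))[is.na(stats::coef(model))]
      stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
    }
    co <- summary(model)$coefficients
    rv <- numeric(0)
    eta_f <- stats::predict(model, type = "link")
    conv <- model$converged
    fitted_v <- stats::fitted(model)
    dev <- stats::deviance(model)
  }
  sep <- any(abs(eta_f) > 15) || any(co[, 2] > 100)
  if (sep) warning("possible complete/quasi separation; estimates unstable")
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], z = co[, 3], row.names = NULL),
    fitted = fitted_v, linear_predictor_fixed = eta_f,
    random_variances = rv, deviance = dev, converged = conv,
    separation = sep, model = model), class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat("power_fit (logistic", if (length(x$random_variances))
    " mixed" else "", " model)\n", sep = "")
  print(x$coefficients, digits = 3)
  if (length(x$random_variances)) {
    cat("random-intercept variances:\n")
    print(x$random_variances, digits = 3)
  }
  r2 <- r2_glmm(x)
  cat(sprintf("R2 marginal = %.4f, conditional = %.4f\n",
              r2[["r2_marginal"]], r2[["r2_conditional"]]))
  invisible(x)
}

#' Marginal and conditional R-squared for a logistic (mixed) model
#'
#' Nakagawa-Schielzeth coefficients of determination:
#' \deqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sum \sigma^2_u + \sigma^2_d)}
#' \deqn{R^2_c = (\sigma^2_f + \sum \sigma^2_u) /
#'   (\sigma^2_f + \sum \sigma^2_u + \sigma^2_d)}
#' with \eqn{\sigma^2_f} the variance of the fixed-effect linear
#' predictor over the data, \eqn{\sigma^2_u} the random-intercept
#' variances, and \eqn{\sigma^2_d = \pi^2/3} the logit-link distribution
#' variance. With no random effects the two coincide.
#'
#' @param fit a \code{power_fit}, or a list with elements
#'   \code{linear_predictor_fixed} and \code{random_variances}.
#' @return named numeric vector \code{c(r2_marginal=, r2_conditional=)}.
#' @export
r2_glmm <- function(fit) {
  s2f <- stats::var(fit$linear_predictor_fixed)
  s2u <- sum(fit$random_variances)
  s2d <- pi^2 / 3
  total <- s2f + s2u + s2d
  if (total <= 0) stop("zero total variance")
  c(r2_marginal = s2f / total, r2_conditional = (s2f + s2u) / total)
}

#' Mean, SD and count of a numeric column
#'
#' Plain summary used for literature-table reproductions: sample standard
#' deviation (n - 1 denominator), missing values dropped.
#'
#' @param x numeric vector.
#' @return list with \code{mean}, \code{sd} (\code{NA} when n = 1) and
#'   \code{n} (non-missing count).
#' @export
summarize_table <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("all values missing")
  list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       n = length(x))
}

#' Poisson regression of locus count on global F_ST
#'
#' Log-link generalised linear model of how many loci studies used
#' against the global differentiation of their system — the
#' literature-review question of whether weakly structured systems
#' compensate with more markers.
#'
#' @param records data.frame with columns \code{n_loci} (positive
#'   integer counts) and \code{fst}.
#' @return a \code{power_fit}; the slope's test statistic is in the
#'   coefficient table.
#' @export
fit_loci_vs_fst <- function(records) {
  if (!all(c("n_loci", "fst") %in% names(records)))
    stop("records need columns n_loci and fst")
  keep <- !is.na(records$n_loci) & !is.na(records$fst)
  records <- records[keep, ]
  if (nrow(records) < 3) stop("need >= 3 complete records")
  if (any(records$n_loci <= 0)) stop("locus counts must be positive")
  model <- stats::glm(n_loci ~ fst, family = stats::poisson(),
                      data = records)
  co <- summary(model)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], z = co[, 3], row.names = NULL),
    fitted = stats::fitted(model),
    linear_predictor_fixed = stats::predict(model, type = "link"),
    random_variances = numeric(0), deviance = stats::deviance(model),
    converged = model$converged, separation = FALSE, model = model),
    class = "power_fit")
}

#' Export a power-model coefficient table as CSV
#'
#' @param fit a \code{power_fit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_power_csv <- function(fit, path) {
  utils::write.csv(fit$coefficients, path, row.names = FALSE)
  invisible(path)
}
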