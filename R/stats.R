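## Cohort-level statistics for regional T2 metrics.
##
## Chain: z-normalize metrics to each study's reference group, compare
## groups by ANCOVA (age covariate, Type-III group F, estimated marginal
## means, Sidak-corrected pairwise tests, Levene's variance check), and
## assess prediction of cognitive decline with the follow-up regression,
## partial residuals and simple age regressions.

#' Z-score values against a per-study reference subgroup
#'
#' Within each study, values are centred and scaled by the mean and sample
#' SD (n - 1 denominator) of that study's reference subgroup (typically
#' healthy controls), then pooled. The reference subgroup of every study
#' therefore has mean 0 and sample SD 1 by construction.
#'
#' @param values numeric vector.
#' @param reference logical vector flagging reference-group members.
#' @param study study label per value (a single study when omitted).
#' @return numeric z-score vector.
#' @export
zscore_to_reference <- function(values, reference, study = NULL) {
  if (is.null(study)) study <- rep("study", length(values))
  stopifnot(length(values) == length(reference),
            length(values) == length(study))
  z <- rep(NA_real_, length(values))
  for (s in unique(study)) {
    in_s <- study == s
    ref <- values[in_s & reference]
    if (length(ref) < 2)
      stop(sprintf("study '%s' has fewer than 2 reference subjects", s))
    sd_ref <- stats::sd(ref)
    if (!is.finite(sd_ref) || sd_ref == 0)
      stop(sprintf("zero reference SD in study '%s'", s))
    z[in_s] <- (values[in_s] - mean(ref)) / sd_ref
  }
  z
}

#' Intracranial-volume correction of regional volumes
#'
#' @param volume regional volume (mm^3).
#' @param icv intracranial volume (mm^3), > 0.
#' @param method \code{"ratio"} (volume/icv, default) or
#'   \code{"residual"} (volume minus its OLS prediction from icv, plus the
#'   mean volume).
#' @return corrected volume vector.
#' @export
icv_correct <- function(volume, icv, method = c("ratio", "residual")) {
  method <- match.arg(method)
  if (any(icv <= 0)) stop("icv must be > 0")
  if (method == "ratio") return(volume / icv)
  fit <- stats::lm(volume ~ icv)
  mean(volume) + stats::residuals(fit)
}

#' ANCOVA group comparison with estimated marginal means
#'
#' Fits \code{outcome ~ group + covariates} by least squares with
#' sum-to-zero group coding and reports the Type-III F for the group
#' factor (nested-model RSS comparison), estimated marginal means per
#' group at the grand covariate mean with their SEs, Sidak-corrected
#' pairwise comparisons between all group pairs (pooled error variance,
#' residual df), and Levene's homogeneity-of-variance test.
#'
#' @param outcome numeric outcome (typically a z-scored T2 metric).
#' @param group factor of group membership.
#' @param covariates data.frame (or named list) of numeric covariates;
#'   default a single \code{age} column must be supplied by the caller.
#' @return object of class \code{"ancova_result"}: list with \code{F},
#'   \code{df1}, \code{df2}, \code{p}, \code{emm} (data.frame group, emm,
#'   se), \code{pairwise} (data.frame pair, estimate, t, p_raw, p_sidak),
#'   \code{levene} (list W, df1, df2, p), \code{n}.
#' @export
ancova_group <- function(outcome, group, covariates) {
  group <- droplevels(as.factor(group))
  if (is.null(dim(covariates))) covariates <- as.data.frame(covariates)
  stopifnot(length(outcome) == length(group),
            nrow(covariates) == length(outcome))
  g <- nlevels(group)
  if (g < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  cn <- ncol(covariates)
  n <- length(outcome)

  # design with sum-to-zero (effects) coding so Type-III F is well-defined
  C <- stats::contr.sum(g)
  G <- C[as.integer(group), , drop = FALSE]
  X1 <- cbind(1, G, as.matrix(covariates))
  X0 <- cbind(1, as.matrix(covariates))
  if (qr(X1)$rank < ncol(X1)) stop("rank-deficient design matrix")
  fit1 <- stats::lm.fit(X1, outcome)
  fit0 <- stats::lm.fit(X0, outcome)
  rss1 <- sum(fit1$residuals^2)
  rss0 <- sum(fit0$residuals^2)
  df1 <- g - 1
  df2 <- n - g - cn
  Fg <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(Fg, df1, df2, lower.tail = FALSE)

  # estimated marginal means at the grand covariate mean
  sigma2 <- rss1 / df2
  XtXinv <- chol2inv(chol(crossprod(X1)))
  cbar <- colMeans(as.matrix(covariates))
  emm_rows <- lapply(seq_len(g), function(k) {
    cvec <- c(1, C[k, ], cbar)
    list(emm = sum(cvec * fit1$coefficients),
         se = sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec)),
         cvec = cvec)
  })
  emm <- data.frame(group = levels(group),
                    emm = vapply(emm_rows, `[[`, 0, "emm"),
                    se = vapply(emm_rows, `[[`, 0, "se"))

  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dvec <- emm_rows[[a]]$cvec - emm_rows[[b]]$cvec
    est <- sum(dvec * fit1$coefficients)
    se <- sqrt(sigma2 * drop(t(dvec) %*% XtXinv %*% dvec))
    tval <- est / se
    p_raw <- 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)
    data.frame(pair = paste(levels(group)[a], "vs", levels(group)[b]),
               estimate = est, t = tval, p_raw = p_raw)
  })
  pw <- do.call(rbind, pw)
  pw$p_sidak <- sidak_pairwise(pw$p_raw, m)

  structure(list(F = Fg, df1 = df1, df2 = df2, p = p, emm = emm,
                 pairwise = pw,
                 levene = levene_test(outcome, group),
                 n = n),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group effect: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$df1, x$df2, x$F, x$p, x$n))
  cat(sprintf("Levene: W = %.3f, p = %.3f\n", x$levene$W, x$levene$p))
  print(x$emm, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Sidak correction for multiple comparisons
#'
#' \eqn{p' = 1 - (1 - p)^m}, monotone in p and m, capped at 1; the
#' identity for m = 1.
#'
#' @param p_raw raw p-value(s) in [0, 1].
#' @param m number of comparisons.
#' @return corrected p-value(s).
#' @export
sidak_pairwise <- function(p_raw, m) {
  if (any(p_raw < 0 | p_raw > 1)) stop("p_raw must lie in [0, 1]")
  if (any(m < 1)) stop("m must be >= 1")
  pmin(1, 1 - (1 - p_raw)^m)
}

#' Levene's test of homogeneity of variances
#'
#' Classic Levene: one-way ANOVA on absolute deviations from the group
#' centre (mean by default; \code{center = "median"} gives the
#' Brown-Forsythe variant).
#'
#' @param outcome numeric vector.
#' @param group factor.
#' @param center \code{"mean"} or \code{"median"}.
#' @return list with \code{W}, \code{df1}, \code{df2}, \code{p}.
#' @export
levene_test <- function(outcome, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("Levene's test needs >= 2 groups with n >= 2 each")
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(outcome, group, cfun)
  d <- abs(outcome - centers[as.integer(group)])
  a <- stats::anova(stats::lm(d ~ group))
  list(W = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}

#' Follow-up cognition regression
#'
#' OLS of follow-up cognition on age, baseline cognition and one
#' structural marker, after z-scoring every variable (sample SD), so the
#' coefficients are standardized betas. Reports the model R^2, overall
#' F(3, n - 4), and per-coefficient standardized beta with two-tailed p.
#'
#' @param followup,age,baseline,marker numeric vectors (MCI follow-up
#'   subsample; the marker is conventionally z-scored to the study's MCI
#'   reference before entry, which standardization makes immaterial to the
#'   reported betas).
#' @param marker_name label for the marker coefficient.
#' @return object of class \code{"followup_regression"}: list with
#'   \code{r2}, \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{coefficients} (data.frame term, beta, se, t, p), \code{n}.
#' @export
followup_regression <- function(followup, age, baseline, marker,
                                marker_name = "marker") {
  n <- length(followup)
  stopifnot(length(age) == n, length(baseline) == n, length(marker) == n)
  if (n <= 4) stop("need n > predictors + 1 (= 4) observations")
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("constant variable in regression")
    (v - mean(v)) / s
  }
  d <- data.frame(y = zs(followup), age = zs(age), baseline = zs(baseline),
                  marker = zs(marker))
  fit <- stats::lm(y ~ age + baseline + marker, data = d)
  sm <- summary(fit)
  if (any(!is.finite(stats::coef(fit)))) stop("singular design")
  co <- sm$coefficients[-1, , drop = FALSE]  # drop intercept (0 by construction)
  coefs <- data.frame(term = c("age", "baseline", marker_name),
                      beta = co[, 1], se = co[, 2], t = co[, 3], p = co[, 4],
                      row.names = NULL)
  df1 <- 3L
  df2 <- n - 4L
  Fv <- (sm$r.squared / df1) / ((1 - sm$r.squared) / df2)
  structure(list(r2 = sm$r.squared, F = Fv, df1 = df1, df2 = df2,
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 coefficients = coefs, n = n),
            class = "followup_regression")
}

#' @export
print.followup_regression <- function(x, ...) {
  cat(sprintf("Follow-up regression: R^2 = %.3f, F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$r2, x$df1, x$df2, x$F, x$p, x$n))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Partial (added-variable) residuals for the marker's contribution
#'
#' Returns standardized residuals of follow-up on (age, baseline) against
#' standardized residuals of the marker on the same covariates. By the
#' Frisch-Waugh theorem the OLS slope of the unstandardized y-residuals on
#' the unstandardized x-residuals equals the marker's coefficient in the
#' full model.
#'
#' @inheritParams followup_regression
#' @return list with \code{x_resid}, \code{y_resid} (standardized, SD 1),
#'   \code{x_resid_raw}, \code{y_resid_raw}, and \code{slope} (raw
#'   residual-on-residual OLS slope).
#' @export
partial_residuals <- function(followup, age, baseline, marker) {
  ry <- stats::residuals(stats::lm(followup ~ age + baseline))
  rx <- stats::residuals(stats::lm(marker ~ age + baseline))
  slope <- sum(rx * ry) / sum(rx^2)
  list(x_resid = rx / stats::sd(rx), y_resid = ry / stats::sd(ry),
       x_resid_raw = rx, y_resid_raw = ry, slope = slope)
}

#' Simple age regression of a structural metric
#'
#' OLS of a metric on age in a reference subsample (conventionally the
#' cognitively normal group); two-tailed p for the slope.
#'
#' @param metric numeric vector.
#' @param age numeric vector, non-constant, n >= 3.
#' @return list with \code{r2}, \code{slope}, \code{intercept}, \code{p},
#'   \code{n}.
#' @export
age_regression <- function(metric, age) {
  n <- length(metric)
  stopifnot(length(age) == n)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(age) == 0) stop("age is constant")
  fit <- stats::lm(metric ~ age)
  sm <- summary(fit)
  list(r2 = sm$r.squared, slope = stats::coef(fit)[["age"]],
       intercept = stats::coef(fit)[["(Intercept)"]],
       p = sm$coefficients["age", 4], n = n)
}
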