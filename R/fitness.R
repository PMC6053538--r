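#' First principal axis of the environmental covariates
#'
#' Standardizes the covariates and returns scores on the leading
#' eigenvector of their correlation matrix; the sign is fixed by making
#' the loading of the first variable non-negative, so scores are
#' reproducible across runs.
#'
#' @param env Numeric matrix or `data.frame` of environmental covariates
#'   (individuals x variables, >= 2 individuals).
#' @return List: `scores` (PC1 per individual), `loadings`,
#'   `var_explained` (fraction of total variance on PC1).
#' @export
env_pca <- function(env) {
  env <- as.matrix(env)
  stopifnot(nrow(env) >= 2)
  if (any(apply(env, 2, sd) == 0)) stop("constant environmental variable(s)")
  pr <- prcomp(env, center = TRUE, scale. = TRUE)
  flip <- if (pr$rotation[1, 1] < 0) -1 else 1
  list(
    scores = flip * pr$x[, 1],
    loadings = flip * pr$rotation[, 1],
    var_explained = pr$sdev[1]^2 / sum(pr$sdev^2)
  )
}

tidy_fit <- function(fit, test = c("z", "t")) {
  test <- match.arg(test)
  s <- summary(fit)$coefficients
  out <- data.frame(
    term = rownames(s), estimate = s[, 1], se = s[, 2],
    statistic = s[, 3], p_value = s[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  crit <- if (test == "z") qnorm(0.975) else qt(0.975, df = fit$df.residual)
  out$ci_lo <- out$estimate - crit * out$se
  out$ci_hi <- out$estimate + crit * out$se
  out
}

#' Poisson regression of reproductive success on inbreeding
#'
#' Fits `log E[offspring] = alpha + beta1 * X1 + gamma * I` by Poisson
#' GLM (log link, iteratively reweighted least squares via
#' [stats::glm()]). Covariates are centered so the intercept corresponds
#' to the population phenotypic mean; centering leaves the slopes, their
#' standard errors and p-values unchanged.
#'
#' @param offspring Non-negative integer offspring counts.
#' @param x1 Environmental covariate (PC1 scores from [env_pca()]).
#' @param inbreeding Genomic inbreeding per individual.
#' @param center Center the covariates (default `TRUE`).
#' @return List of class `fitness_fit`: `coefficients` (tidy table with
#'   Wald z CIs), `fit` (the `glm` object), `converged`.
#' @export
fit_offspring_glm <- function(offspring, x1, inbreeding, center = TRUE) {
  stopifnot(length(offspring) == length(x1),
            length(offspring) == length(inbreeding))
  if (any(offspring < 0) || any(offspring != round(offspring)))
    stop("offspring counts must be non-negative integers")
  if (all(offspring == 0)) stop("degenerate response: all counts zero")
  if (center) {
    x1 <- x1 - mean(x1)
    inbreeding <- inbreeding - mean(inbreeding)
  }
  fit <- glm(offspring ~ x1 + inbreeding, family = poisson())
  if (!fit$converged) warning("Poisson IRLS did not converge")
  structure(list(
    coefficients = tidy_fit(fit, "z"), fit = fit,
    converged = fit$converged
  ), class = "fitness_fit")
}

#' Linear regression of growth on inbreeding
#'
#' Ordinary least squares of stem circumference on the environmental
#' covariate, inbreeding, and age at cutting (circumference being a
#' normally distributed trait); covariates centered as in
#' [fit_offspring_glm()].
#'
#' @param circumference Stem circumference (cm).
#' @param x1 Environmental covariate (PC1 scores).
#' @param inbreeding Genomic inbreeding per individual.
#' @param age Age at cutting (years).
#' @param center Center the covariates (default `TRUE`).
#' @return List of class `fitness_fit`: `coefficients` (tidy table with t
#'   CIs), `fit` (the `lm` object).
#' @export
fit_growth_lm <- function(circumference, x1, inbreeding, age, center = TRUE) {
  stopifnot(length(circumference) == length(x1),
            length(circumference) == length(inbreeding),
            length(circumference) == length(age))
  if (center) {
    x1 <- x1 - mean(x1)
    inbreeding <- inbreeding - mean(inbreeding)
    age <- age - mean(age)
  }
  fit <- lm(circumference ~ x1 + inbreeding + age)
  if (any(is.na(coef(fit)))) stop("rank-deficient design")
  structure(list(coefficients = tidy_fit(fit, "t"), fit = fit,
                 converged = TRUE), class = "fitness_fit")
}
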