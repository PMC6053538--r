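#' Simulate fitness traits with a tunable inbreeding effect
#'
#' Generates, per individual, five correlated environmental covariates (a
#' one-factor model: `env_j = loading_j * Z + sqrt(1 - loading_j^2) * noise`),
#' a reproductive-success count drawn as
#' `Poisson(exp(alpha + beta1 * Z + gamma * I))`, an age at cutting, and a
#' stem circumference that is linear in the environmental factor, inbreeding
#' and age with Gaussian residuals. `Z` is the latent environmental factor
#' recovered downstream as the first principal component of the five
#' covariates; `I` is the individual's true inbreeding level.
#'
#' Default magnitudes mirror a century-old mixed oak stand: mean
#' reproductive success of a few offspring per adult, ages 78-102 years,
#' circumferences around 1.7 m, and an inbreeding effect on reproductive
#' success of `gamma = -3.6`.
#'
#' @param pedigree Pedigree `data.frame` (only ids/species are used).
#' @param inbreeding_true Numeric vector, one inbreeding value per
#'   individual.
#' @param gamma Inbreeding coefficient on log reproductive success.
#' @param beta1 Environmental-factor coefficient on log reproductive success.
#' @param alpha Intercept on the log scale.
#' @param env_loadings Loadings of the five covariates on the latent factor,
#'   each in `(-1, 1]`.
#' @param noise Residual standard deviation of circumference (cm); `0` makes
#'   circumference an exact linear function of factor, inbreeding and age.
#' @param growth Coefficients for circumference: list with `intercept` (cm),
#'   `beta1` (cm per factor unit), `gamma` (cm per inbreeding unit),
#'   `age_slope` (cm/year), applied to age centered at 90 years.
#' @param age_range Integer range of tree ages at cutting (years).
#' @param seed Optional integer seed.
#' @return `data.frame` of class `fitness_table`: `id`, `species`,
#'   `inbreeding_true`, `env_factor` (latent `Z`), `env1..env5`,
#'   `offspring_count`, `age_at_cut`, `circumference`.
#' @export
simulate_fitness <- function(pedigree, inbreeding_true,
                             gamma = -3.6, beta1 = 0.2, alpha = log(9),
                             env_loadings = c(0.9, 0.8, 0.7, 0.6, 0.5),
                             noise = 20,
                             growth = list(intercept = 170, beta1 = 5,
                                           gamma = -36, age_slope = 1.5),
                             age_range = c(78L, 102L), seed = NULL) {
  n <- nrow(pedigree)
  stopifnot(length(inbreeding_true) == n, length(env_loadings) == 5,
            all(abs(env_loadings) <= 1))
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n)
  env <- sapply(env_loadings, function(l) l * z + sqrt(1 - l^2) * rnorm(n))
  colnames(env) <- paste0("env", seq_len(5))
  eta <- alpha + beta1 * z + gamma * inbreeding_true
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  offspring <- rpois(n, exp(eta))
  age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
  circ <- growth$intercept + growth$beta1 * z + growth$gamma * inbreeding_true +
    growth$age_slope * (age - 90) + rnorm(n, sd = noise)
  out <- data.frame(
    id = pedigree$id, species = pedigree$species,
    inbreeding_true = inbreeding_true, env_factor = z,
    env, offspring_count = offspring, age_at_cut = age,
    circumference = circ, stringsAsFactors = FALSE
  )
  class(out) <- c("fitness_table", "data.frame")
  out
}
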