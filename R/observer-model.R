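#' Variance-component model of repeated investigator readings
#'
#' Two-way random-effects generative model for a subjects x raters matrix
#' of biomarker readings:
#' `y_ij = mu + s_i + r_j + e_ij`, with subject effects
#' `s_i ~ N(0, between_subject_sd^2)`, rater effects
#' `r_j ~ N(0, rater_bias_sd^2)` and residual investigator-analysis error
#' `e_ij ~ N(0, error_sd^2)`, all independent.  The implied population
#' single-measures absolute-agreement ICC is
#' `between^2 / (between^2 + rater_bias^2 + error^2)`.
#'
#' @param between_subject_sd SD of the true biomarker across subjects.
#' @param error_sd SD of the per-reading investigator analysis error.
#' @param rater_bias_sd SD of systematic rater offsets (0 = no rater bias,
#'   in which case agreement and consistency ICC coincide in expectation).
#' @param seed default RNG seed used by [generate_observation_matrix()].
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(between_subject_sd, error_sd,
                           rater_bias_sd = 0, seed = 1L) {
  assert_number(between_subject_sd, "between_subject_sd", lower = 0)
  assert_number(error_sd, "error_sd", lower = 0)
  assert_number(rater_bias_sd, "rater_bias_sd", lower = 0)
  structure(
    list(between_subject_sd = between_subject_sd, error_sd = error_sd,
         rater_bias_sd = rater_bias_sd, seed = seed),
    class = "observer_model")
}

#' Population ICC implied by an observer model
#'
#' @param model an [observer_model()].
#' @return The population absolute-agreement single-measures ICC in `[0, 1]`
#'   (NaN when all three variance components are zero).
#' @export
population_icc <- function(model) {
  stopifnot(inherits(model, "observer_model"))
  b2 <- model$between_subject_sd^2
  b2 / (b2 + model$rater_bias_sd^2 + model$error_sd^2)
}

#' Generate a subjects x raters observation matrix
#'
#' @param model an [observer_model()].
#' @param n_subjects number of subjects (>= 2).
#' @param n_raters number of raters/occasions (>= 2).
#' @param mean grand mean `mu` of the biomarker.
#' @param seed RNG seed; defaults to the model's seed.
#' @return A numeric `n_subjects x n_raters` matrix with subject/rater
#'   dimnames; the realised effects and generating components are attached
#'   as attribute `"truth"`.
#' @export
generate_observation_matrix <- function(model, n_subjects, n_raters,
                                        mean = 0, seed = model$seed) {
  stopifnot(inherits(model, "observer_model"),
            n_subjects >= 2L, n_raters >= 2L)
  with_seed(seed, {
    s <- rnorm(n_subjects, 0, model$between_subject_sd)
    r <- rnorm(n_raters, 0, model$rater_bias_sd)
    e <- matrix(rnorm(n_subjects * n_raters, 0, model$error_sd),
                n_subjects, n_raters)
  })
  y <- mean + outer(s, r, "+") + e
  dimnames(y) <- list(sprintf("S%02d", seq_len(n_subjects)),
                      sprintf("R%d", seq_len(n_raters)))
  attr(y, "truth") <- list(
    mean = mean, subject_effects = s, rater_effects = r,
    between_subject_sd = model$between_subject_sd,
    rater_bias_sd = model$rater_bias_sd, error_sd = model$error_sd,
    population_icc = population_icc(model))
  y
}
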