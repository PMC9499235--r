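#' Run configuration for the CEBP pipeline
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' are the method's reference settings: correlation significance cutoff
#' `alpha = 1e-3`, 200 observed confounder genes, a 1\% mutation-rate floor,
#' a 20-dimensional latent confounder, 3-layer 200-wide ELU networks, Adam
#' with learning rate 1e-3 and weight decay 1e-4, 70/10/20
#' train/validation/test splits, and 10 independent replicate runs.
#'
#' @param alpha significance cutoff for correlation gating, in (0,1).
#' @param n_confounders number of highest-mutation-rate genes used as the
#'   observed confounder matrix X.
#' @param min_mutation_rate minimum cohort mutation rate for the treatment
#'   gene and every confounder gene.
#' @param latent_dim dimension of the latent confounder z.
#' @param hidden_width width of the hidden layers of every network.
#' @param hidden_depth number of hidden layers of the main networks
#'   (the treatment networks q(m|x) and p(m|z) always use a single layer).
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay applied to all parameters.
#' @param split_fractions length-3 train/validation/test fractions (sum 1).
#' @param n_replicates independent training replicates aggregated into the
#'   reported ATE mean and standard deviation.
#' @param outcome_sd fixed standard deviation of the Gaussian outcome model.
#'   The default (2.0, roughly twice the spread of a unit-scale outcome)
#'   deliberately sits above the residual noise level: if it is at or below
#'   that level, memorizing outcome noise in the latent code becomes
#'   profitable for the objective and counterfactual predictions destabilize
#'   (see the methods vignette).
#' @param n_mc_samples Monte Carlo posterior draws per sample for
#'   counterfactual prediction.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size (full batch when the training split is
#'   smaller).
#' @param patience early-stopping patience on the validation objective.
#' @param base_seed base RNG seed for replicate runs.
#' @param activity_direction `"as_printed"` (activity is the coefficient of
#'   the sample profile regressed toward the cohort-mean profile) or
#'   `"reversed"`.
#'
#' @return an object of class `cebp_config` (a named list).
#' @examples
#' cfg <- cebp_config(hidden_width = 64, epochs = 50)
#' cfg$alpha
#' @export
cebp_config <- function(alpha = 1e-3,
                        n_confounders = 200L,
                        min_mutation_rate = 0.01,
                        latent_dim = 20L,
                        hidden_width = 200L,
                        hidden_depth = 3L,
                        learning_rate = 1e-3,
                        weight_decay = 1e-4,
                        split_fractions = c(0.7, 0.1, 0.2),
                        n_replicates = 10L,
                        outcome_sd = 2.0,
                        n_mc_samples = 100L,
                        epochs = 300L,
                        batch_size = 128L,
                        patience = 30L,
                        base_seed = 1L,
                        activity_direction = c("as_printed", "reversed")) {
  activity_direction <- match.arg(activity_direction)
  stopifnot(
    alpha > 0, alpha < 1,
    n_confounders >= 1, min_mutation_rate >= 0, min_mutation_rate < 1,
    latent_dim >= 1, hidden_width >= 1, hidden_depth >= 1,
    learning_rate > 0, weight_decay >= 0,
    length(split_fractions) == 3, all(split_fractions > 0),
    n_replicates >= 1, outcome_sd > 0, n_mc_samples >= 1,
    epochs >= 1, batch_size >= 1, patience >= 1
  )
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split_fractions must sum to 1", call. = FALSE)
  structure(list(
    alpha = alpha,
    n_confounders = as.integer(n_confounders),
    min_mutation_rate = min_mutation_rate,
    latent_dim = as.integer(latent_dim),
    hidden_width = as.integer(hidden_width),
    hidden_depth = as.integer(hidden_depth),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    split_fractions = split_fractions,
    n_replicates = as.integer(n_replicates),
    outcome_sd = outcome_sd,
    n_mc_samples = as.integer(n_mc_samples),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    patience = as.integer(patience),
    base_seed = as.integer(base_seed),
    activity_direction = activity_direction
  ), class = "cebp_config")
}

#' @export
print.cebp_config <- function(x, ...) {
  cat("CEBP run configuration\n")
  cat(sprintf("  alpha %.2g | confounders %d (rate floor %.2g)\n",
              x$alpha, x$n_confounders, x$min_mutation_rate))
  cat(sprintf("  latent dim %d | nets %d x %d (ELU)\n",
              x$latent_dim, x$hidden_depth, x$hidden_width))
  cat(sprintf("  Adam lr %.2g, weight decay %.2g | splits %s\n",
              x$learning_rate, x$weight_decay,
              paste(x$split_fractions, collapse = "/")))
  cat(sprintf("  replicates %d | MC draws %d | activity direction %s\n",
              x$n_replicates, x$n_mc_samples, x$activity_direction))
  invisible(x)
}
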