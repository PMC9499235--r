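#' Configuration for the confounded causal-data generator
#'
#' Realizes the structural causal model Z -> X, Z -> M, (Z, M) -> Y:
#' a d-dimensional standard-normal latent confounder drives binary proxy
#' mutations X, a binary treatment M, and a linear-Gaussian outcome
#' Y = tau * M + w'z + noise, so the true ATE equals `tau` exactly.
#'
#' The default strengths are the package's strong-confounding study
#' conditions: treatment loading `c_scale = 0.8` and outcome loading
#' `w_scale = 0.4` aligned along the same latent direction, giving a naive
#' difference-in-means bias of roughly 0.28 outcome units (verified by the
#' Monte Carlo oracle in [naive_bias_oracle()]); proxy loadings of norm
#' ~`b_scale = 3` make the latent confounder recoverable from X (the proxy
#' sufficiency the causal model assumes); per-gene baseline logits are
#' spread so mutation rates range over roughly 1--40\%.
#'
#' @param n_samples cohort size (>= 50).
#' @param n_confounder_genes K, number of proxy mutation genes.
#' @param latent_dim d, latent confounder dimension.
#' @param tau true treatment effect in outcome units.
#' @param c_scale confounder-to-treatment strength (sd of the treatment
#'   logit contribution).
#' @param w_scale confounder-to-outcome strength (sd of the latent
#'   contribution to Y).
#' @param b_scale confounder-to-proxy strength (norm of each gene's latent
#'   loading).
#' @param treatment_intercept intercept of the treatment logit.
#' @param baseline_logit_range range the per-gene baseline logits are drawn
#'   from (defaults give ~1--40\% mutation rates).
#' @param outcome_sd sd of the Gaussian outcome noise.
#' @param seed RNG seed.
#' @return object of class `causal_sim_config`.
#' @export
causal_sim_config <- function(n_samples = 2000L,
                              n_confounder_genes = 50L,
                              latent_dim = 5L,
                              tau = 0.5,
                              c_scale = 0.8,
                              w_scale = 0.4,
                              b_scale = 3,
                              treatment_intercept = -0.5,
                              baseline_logit_range = c(-4.6, -0.4),
                              outcome_sd = 1.0,
                              seed = 1L) {
  stopifnot(n_samples >= 50, n_confounder_genes >= 1, latent_dim >= 1,
            outcome_sd > 0, length(baseline_logit_range) == 2)
  structure(list(n_samples = as.integer(n_samples),
                 n_confounder_genes = as.integer(n_confounder_genes),
                 latent_dim = as.integer(latent_dim),
                 tau = tau, c_scale = c_scale, w_scale = w_scale,
                 b_scale = b_scale,
                 treatment_intercept = treatment_intercept,
                 baseline_logit_range = baseline_logit_range,
                 outcome_sd = outcome_sd, seed = as.integer(seed)),
            class = "causal_sim_config")
}

# structural coefficients implied by a config (deterministic given seed)
sim_coefficients_ <- function(cfg) {
  with_seed(cfg$seed, {
    d <- cfg$latent_dim
    K <- cfg$n_confounder_genes
    a <- stats::runif(K, cfg$baseline_logit_range[1],
                      cfg$baseline_logit_range[2])
    B <- matrix(stats::rnorm(d * K, sd = cfg$b_scale / sqrt(d)), d, K)
    cvec <- rep(cfg$c_scale / sqrt(d), d)
    wvec <- rep(cfg$w_scale / sqrt(d), d)
    list(a = a, B = B, cvec = cvec, wvec = wvec)
  })
}

#' Simulate a confounded causal dataset with known true ATE
#'
#' Draws z_i ~ N(0, I_d), proxies x_ij ~ Bern(sigmoid(a_j + b_j'z_i)),
#' treatment m_i ~ Bern(sigmoid(c0 + c'z_i)) and outcome
#' y_i = tau * m_i + w'z_i + N(0, sigma_y^2). Because treatment and
#' outcome load on the same latent direction, the naive difference in
#' means is biased while the true ATE is exactly `tau`.
#'
#' @param cfg a [causal_sim_config()].
#' @return list with `dataset` (a `cebp_dataset`), `z_true` (n x d),
#'   `tau_true`, and the structural coefficients `coef`.
#' @examples
#' sim <- simulate_confounded(causal_sim_config(n_samples = 200, seed = 7))
#' naive_ate(sim$dataset) # biased away from tau_true
#' @export
simulate_confounded <- function(cfg = causal_sim_config()) {
  stopifnot(inherits(cfg, "causal_sim_config"))
  co <- sim_coefficients_(cfg)
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_samples
    d <- cfg$latent_dim
    K <- cfg$n_confounder_genes
    z <- matrix(stats::rnorm(n * d), n, d)
    logits_x <- z %*% co$B + rep(co$a, each = n)
    X <- matrix(as.numeric(stats::rbinom(n * K, 1, sigmoid_(logits_x))),
                n, K)
    pm <- sigmoid_(cfg$treatment_intercept + drop(z %*% co$cvec))
    M <- stats::rbinom(n, 1, pm)
    if (sum(M) == 0 || sum(M) == n)
      stop("realized treatment is single-arm; change the seed or weaken ",
           "the confounding strengths", call. = FALSE)
    Y <- cfg$tau * M + drop(z %*% co$wvec) +
      stats::rnorm(n, sd = cfg$outcome_sd)
    dimnames(X) <- list(sprintf("S%04d", seq_len(n)),
                        sprintf("BG%03d", seq_len(K)))
    list(dataset = causal_dataset(X, M, Y),
         z_true = z, tau_true = cfg$tau, coef = co)
  })
}

#' Naive difference-in-means treatment effect
#'
#' mean(Y | M = 1) - mean(Y | M = 0); the confounded baseline contrast.
#'
#' @param ds a `cebp_dataset` (or list with `M`, `Y`).
#' @return numeric scalar.
#' @export
naive_ate <- function(ds) {
  m <- as.numeric(ds$M)
  y <- as.numeric(ds$Y)
  if (sum(m) == 0 || sum(m) == length(m))
    stop("both treatment arms must be nonempty", call. = FALSE)
  mean(y[m == 1]) - mean(y[m == 0])
}

#' Monte Carlo oracle for the naive bias of a generator configuration
#'
#' Evaluates E[Y | M=1] - E[Y | M=0] - tau under the generative law by
#' drawing `n_draws` fresh samples (independent of any realized dataset).
#'
#' @param cfg a [causal_sim_config()].
#' @param n_draws Monte Carlo draws (default 1e6).
#' @param seed RNG seed for the oracle draws.
#' @return the bias of the naive contrast, in outcome units.
#' @export
naive_bias_oracle <- function(cfg, n_draws = 1e6, seed = 999L) {
  co <- sim_coefficients_(cfg)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_draws * cfg$latent_dim), n_draws,
                cfg$latent_dim)
    u <- drop(z %*% co$cvec)
    w <- drop(z %*% co$wvec)
    m <- stats::rbinom(n_draws, 1, sigmoid_(cfg$treatment_intercept + u))
    # outcome noise is mean-zero and independent of m: it drops from the
    # contrast, so E[Y|M=a] - tau*a = E[w'z | M=a]
    mean(w[m == 1]) - mean(w[m == 0])
  })
}

#' Configuration for the planted-pathway expression generator
#'
#' Core genes share a per-sample factor t_i ~ N(0,1):
#' u_ij = baseline + loading * t_i + N(0, noise_sd^2); non-core genes are
#' independent noise around the baseline. Defaults are the strong preset
#' (P = 40 genes, N = 100 samples, loading/noise = 9) under which the
#' correlation-based core selection should recover the planted block.
#'
#' @param n_samples N.
#' @param n_genes P.
#' @param core_size planted block size (default floor(P/2)).
#' @param loading factor loading on core genes.
#' @param noise_sd per-gene noise sd.
#' @param baseline mean expression level (FPKM-like units).
#' @param seed RNG seed.
#' @return object of class `pathway_sim_config`.
#' @export
pathway_sim_config <- function(n_samples = 100L,
                               n_genes = 40L,
                               core_size = n_genes %/% 2,
                               loading = 1.8,
                               noise_sd = 0.2,
                               baseline = 10,
                               seed = 1L) {
  stopifnot(core_size <= n_genes, loading >= 0, noise_sd > 0,
            n_samples >= 3, n_genes >= 4)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 core_size = as.integer(core_size),
                 loading = loading, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "pathway_sim_config")
}

#' Simulate pathway expression with a planted core-gene block
#'
#' @param cfg a [pathway_sim_config()].
#' @return list with `u` (N x P nonnegative expression matrix),
#'   `core_indices` (planted block), `factor` (planted per-sample factor).
#' @export
simulate_pathway <- function(cfg = pathway_sim_config()) {
  stopifnot(inherits(cfg, "pathway_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    p <- cfg$n_genes
    core <- seq_len(cfg$core_size)
    t_i <- stats::rnorm(n)
    u <- matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p) + cfg$baseline
    u[, core] <- u[, core] + cfg$loading * t_i
    # keep expression nonnegative with a constant shift (preserves all
    # correlations exactly)
    if (min(u) < 0) u <- u - min(u)
    dimnames(u) <- list(sprintf("S%04d", seq_len(n)),
                        sprintf("PW%03d", seq_len(p)))
    list(u = u, core_indices = core, factor = t_i)
  })
}

#' Simulate a full cohort for end-to-end pipeline runs
#'
#' Builds a mutation table containing named candidate genes with specified
#' true effects plus background proxy genes, together with the activity
#' outcome they generate. All genes' mutation probabilities are driven by
#' the shared latent confounder, so every candidate is confounded; the
#' outcome is Y = sum_g tau_g * M_g + w'z + noise.
#'
#' @param taus named numeric vector: candidate gene names and their true
#'   effects (e.g. `c(KEY1 = 0.5, NUL1 = 0, NUL2 = 0)`).
#' @param cfg a [causal_sim_config()] providing cohort size, background
#'   gene count and confounding strengths.
#' @return list with `mutation` (samples x genes binary matrix: candidates
#'   then background), `activity` (named outcome vector), `taus`,
#'   `z_true`.
#' @export
simulate_cohort <- function(taus = c(KEY1 = 0.5, NUL1 = 0, NUL2 = 0),
                            cfg = causal_sim_config()) {
  stopifnot(length(taus) >= 1, !is.null(names(taus)))
  co <- sim_coefficients_(cfg)
  with_seed(cfg$seed + 2L, {
    n <- cfg$n_samples
    d <- cfg$latent_dim
    K <- cfg$n_confounder_genes
    z <- matrix(stats::rnorm(n * d), n, d)
    logits_x <- z %*% co$B + rep(co$a, each = n)
    X <- matrix(as.numeric(stats::rbinom(n * K, 1, sigmoid_(logits_x))),
                n, K)
    colnames(X) <- sprintf("BG%03d", seq_len(K))
    Mc <- sapply(names(taus), function(g) {
      as.numeric(stats::rbinom(n, 1, sigmoid_(cfg$treatment_intercept +
                                                drop(z %*% co$cvec))))
    })
    y <- drop(Mc %*% taus) + drop(z %*% co$wvec) +
      stats::rnorm(n, sd = cfg$outcome_sd)
    mut <- cbind(Mc, X)
    rownames(mut) <- sprintf("S%04d", seq_len(n))
    names(y) <- rownames(mut)
    list(mutation = mut, activity = y, taus = taus, z_true = z)
  })
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Writes the mutation matrix as TSV, the activity vector as TSV, and a
#' JSON truth sidecar (true effects, config) so end-to-end runs need no
#' external data.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulated_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sample_gene_matrix(cohort$mutation, file.path(dir, "mutation.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$activity),
               activity = cohort$activity),
    file.path(dir, "activity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(taus = as.list(cohort$taus)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
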