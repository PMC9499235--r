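#' Per-gene cohort mutation rates
#'
#' @param mut binary mutation matrix (samples x genes).
#' @return named numeric vector: fraction of mutated samples per gene.
#' @export
mutation_rates <- function(mut) {
  check_sample_gene_matrix(mut, "mutation table")
  if (nrow(mut) == 0) stop("mutation table has no samples", call. = FALSE)
  colMeans(mut)
}

#' Candidate-selection rule
#'
#' Standard cohort-size-dependent cutoffs: either the `k` genes with the highest
#' mutation rates (e.g. top 200) or all genes at or above a rate threshold
#' (e.g. >= 7\% or >= 1\%).
#'
#' @param kind `"top_k_by_rate"` or `"rate_at_least"`.
#' @param k number of genes (for `top_k_by_rate`).
#' @param threshold rate threshold in (0,1) (for `rate_at_least`).
#' @return object of class `candidate_rule`.
#' @export
candidate_rule <- function(kind = c("top_k_by_rate", "rate_at_least"),
                           k = 200L, threshold = 0.07) {
  kind <- match.arg(kind)
  if (kind == "top_k_by_rate") stopifnot(k >= 1)
  else stopifnot(threshold > 0, threshold < 1)
  structure(list(kind = kind, k = as.integer(k), threshold = threshold),
            class = "candidate_rule")
}

#' Select candidate key-mutation genes by mutation rate
#'
#' @param rates named rate vector from [mutation_rates()].
#' @param rule a [candidate_rule()].
#' @return character vector of gene ids, rate-descending (ties broken by
#'   ascending gene id).
#' @export
select_candidates <- function(rates, rule) {
  stopifnot(inherits(rule, "candidate_rule"))
  ord <- order(-rates, names(rates))
  sel <- if (rule$kind == "top_k_by_rate") {
    ord[seq_len(min(rule$k, length(rates)))]
  } else {
    ord[rates[ord] >= rule$threshold]
  }
  if (!length(sel))
    stop("no genes satisfy the candidate rule; lower the threshold",
         call. = FALSE)
  names(rates)[sel]
}

#' Build the causal dataset for one target gene
#'
#' Treatment M is the target gene's mutation column; the observed
#' confounders X are the `cfg$n_confounders` highest-mutation-rate genes
#' excluding the target, all with rate >= `cfg$min_mutation_rate` (fewer
#' are retained, with a warning, when the table is smaller). Sample order
#' is preserved from the inputs.
#'
#' @param mut binary mutation matrix (samples x genes).
#' @param y activity vector named by sample, aligned with `mut`.
#' @param target_gene gene id of the treatment.
#' @param cfg a [cebp_config()].
#' @return a `cebp_dataset`.
#' @export
build_causal_dataset <- function(mut, y, target_gene, cfg = cebp_config()) {
  check_sample_gene_matrix(mut, "mutation table")
  if (!target_gene %in% colnames(mut))
    stop("target gene '", target_gene, "' absent from mutation table",
         call. = FALSE)
  if (!is.null(names(y))) {
    if (!all(rownames(mut) %in% names(y)))
      stop("activity vector does not cover all samples", call. = FALSE)
    y <- y[rownames(mut)]
  } else if (length(y) != nrow(mut)) {
    stop("activity vector length does not match samples", call. = FALSE)
  }
  rates <- mutation_rates(mut)
  if (rates[target_gene] < cfg$min_mutation_rate)
    stop("target gene '", target_gene, "' mutation rate ",
         signif(rates[target_gene], 3), " is below the floor ",
         cfg$min_mutation_rate, call. = FALSE)
  pool <- setdiff(names(rates)[rates >= cfg$min_mutation_rate],
                  target_gene)
  pool <- pool[order(-rates[pool], pool)]
  if (length(pool) < cfg$n_confounders)
    warning("only ", length(pool), " eligible confounder genes ",
            "(requested ", cfg$n_confounders, ")", call. = FALSE)
  conf <- pool[seq_len(min(cfg$n_confounders, length(pool)))]
  if (!length(conf))
    stop("no eligible confounder genes at rate floor ",
         cfg$min_mutation_rate, call. = FALSE)
  causal_dataset(mut[, conf, drop = FALSE], mut[, target_gene],
                 as.numeric(y), sample_ids = rownames(mut))
}

#' Mann-Whitney U test between mutated and non-mutated groups
#'
#' Compares the activity of the mutated (m = 1) group against the
#' non-mutated group. The U statistic is reported for the mutated group.
#' The p-value is exact (enumeration) when min(n1, n2) <= 8 with no ties,
#' and otherwise uses the normal approximation with midrank tie handling
#' and continuity correction; always two-sided.
#'
#' @param y numeric activity vector.
#' @param m binary group vector (1 = mutated).
#' @return list with `u` and `p`.
#' @examples
#' mann_whitney_u(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
#' @export
mann_whitney_u <- function(y, m) {
  m <- as.numeric(m)
  stopifnot(length(y) == length(m), all(m %in% c(0, 1)))
  y1 <- y[m == 1]
  y0 <- y[m == 0]
  if (!length(y1) || !length(y0))
    stop("both groups must be nonempty", call. = FALSE)
  ties <- anyDuplicated(y) > 0
  exact <- min(length(y1), length(y0)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(y1, y0, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(u = unname(ht$statistic), p = ht$p.value)
}

#' Rank candidate mutations by their causal effect
#'
#' For each candidate gene: builds the causal dataset, runs the
#' replicate-aggregated ATE estimate, and attaches the mutation rate and
#' the Mann-Whitney comparison of activity between mutated and
#' non-mutated groups. Genes that fail (for example a single-arm training
#' split) are skipped with a logged reason rather than aborting the run.
#' Each candidate's replicates use a seed offset folded from its position
#' so different genes do not share identical network initializations.
#'
#' @param mut binary mutation matrix (samples x genes).
#' @param y activity vector aligned with `mut`.
#' @param candidates character vector of candidate gene ids.
#' @param cfg a [cebp_config()].
#' @param verbose emit per-gene progress.
#' @return data.frame with columns `gene`, `ate_mean`, `ate_std`,
#'   `mutation_rate`, `mw_u`, `mw_p`, `rank`, sorted by `ate_mean`
#'   descending (rank 1 = largest effect).
#' @export
rank_mutations <- function(mut, y, candidates, cfg = cebp_config(),
                           verbose = FALSE) {
  stopifnot(length(candidates) >= 1)
  rates <- mutation_rates(mut)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    g <- candidates[i]
    res <- tryCatch({
      ds <- build_causal_dataset(mut, y, g, cfg)
      cfg_g <- cfg
      cfg_g$base_seed <- cfg$base_seed + 7919L * (i - 1L)
      est <- run_replicates(ds, cfg_g)
      mw <- mann_whitney_u(ds$Y, ds$M)
      data.frame(gene = g, ate_mean = est$ate_mean,
                 ate_std = est$ate_std, mutation_rate = unname(rates[g]),
                 mw_u = mw$u, mw_p = mw$p, stringsAsFactors = FALSE)
    }, error = function(e) {
      cebp_log(sprintf("skipping gene %s: %s", g, conditionMessage(e)))
      NULL
    })
    if (verbose && !is.null(res))
      cebp_log(sprintf("[%d/%d] %s: ATE %.4f +/- %.4f", i,
                       length(candidates), g, res$ate_mean, res$ate_std))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("every candidate gene failed", call. = FALSE)
  out <- out[order(-out$ate_mean, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a ranking table as TSV
#'
#' @param ranking data.frame from [rank_mutations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
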