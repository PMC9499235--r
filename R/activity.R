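#' Pairwise Pearson correlations with two-sided p-values
#'
#' Computes the P x P Pearson correlation matrix of the pathway genes over
#' samples together with two-sided p-values from the t transform
#' t = r * sqrt((N-2) / (1-r^2)) on N-2 degrees of freedom. Genes with zero
#' variance get r = 0 and p = 1 against every partner, so they can never be
#' promoted to core genes through the significance gate.
#'
#' @param u expression matrix, N samples x P genes (P >= 2, N >= 3).
#' @return list with `r` (correlations, unit diagonal) and `p`
#'   (p-values, zero diagonal), both P x P symmetric.
#' @export
correlation_with_pvalues <- function(u) {
  stopifnot(is.matrix(u), is.numeric(u))
  n <- nrow(u); p <- ncol(u)
  if (n < 3) stop("need at least 3 samples for correlation p-values",
                  call. = FALSE)
  if (p < 2) stop("need at least 2 genes", call. = FALSE)
  sds <- apply(u, 2, stats::sd)
  zero_var <- sds == 0
  r <- suppressWarnings(stats::cor(u))
  r[zero_var, ] <- 0
  r[, zero_var] <- 0
  # t-based two-sided p; |r| = 1 maps to p = 0
  rr <- pmin(pmax(r, -1), 1)
  tval <- abs(rr) * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  pv <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  pv[abs(rr) >= 1 - 1e-12] <- 0
  pv[zero_var, ] <- 1
  pv[, zero_var] <- 1
  diag(r) <- 1
  diag(pv) <- 0
  dimnames(r) <- dimnames(pv) <- list(colnames(u), colnames(u))
  list(r = r, p = pv)
}

#' Significance-gated correlation scores per gene
#'
#' For gene j, sums the signed correlations r_ij over all partners i != j
#' whose p-value passes the cutoff: score_j = sum_i r_ij * 1[p_ij < alpha].
#' The diagonal is excluded (it would add a constant 1 to every gene and
#' cannot change the ranking).
#'
#' @param corr result of [correlation_with_pvalues()].
#' @param alpha significance cutoff in (0,1); default 1e-3.
#' @return named numeric vector of per-gene scores.
#' @export
core_scores <- function(corr, alpha = 1e-3) {
  stopifnot(alpha > 0, alpha < 1)
  gate <- corr$p < alpha
  diag(gate) <- FALSE
  colSums(corr$r * gate)
}

#' Select the core genes of a pathway
#'
#' Takes the floor(P/2) genes with the highest scores; ties are broken by
#' ascending gene index so the selection is deterministic.
#'
#' @param scores per-gene score vector (from [core_scores()]), P >= 4.
#' @return list with `core_indices` (ordered integer vector of length
#'   floor(P/2)), `scores` and `alpha_note`-free metadata.
#' @export
select_core_genes <- function(scores) {
  p <- length(scores)
  n_core <- p %/% 2
  if (p < 4 || n_core < 2)
    stop("core selection needs at least 4 pathway genes", call. = FALSE)
  ord <- order(-scores, seq_len(p))
  idx <- sort(ord[seq_len(n_core)])
  list(core_indices = idx,
       core_genes = if (!is.null(names(scores))) names(scores)[idx] else NULL,
       scores = scores)
}

#' Cohort-mean expression profile of the core genes
#'
#' @param u expression matrix (samples x genes).
#' @param core_indices integer indices of the selected core genes.
#' @return numeric vector: per-core-gene mean over samples.
#' @export
reference_profile <- function(u, core_indices) {
  stopifnot(all(core_indices >= 1), all(core_indices <= ncol(u)))
  colMeans(u[, core_indices, drop = FALSE])
}

#' Activity of one sample from its core-gene expression
#'
#' The activity is the scalar regression coefficient linking the sample's
#' core-gene vector u to the cohort-mean profile K. Under the default
#' `as_printed` direction it minimizes ||y*u - K||^2, giving
#' y = <u,K>/<u,u>; under `reversed` it minimizes ||u - y*K||^2, giving
#' y = <u,K>/<K,K>. Note the printed direction scales inversely with the
#' sample: y(c*u) = y(u)/c.
#'
#' @param u_core core-gene expression of one sample.
#' @param profile reference profile from [reference_profile()].
#' @param direction `"as_printed"` or `"reversed"`.
#' @return activity scalar.
#' @export
sample_activity <- function(u_core, profile,
                            direction = c("as_printed", "reversed")) {
  direction <- match.arg(direction)
  stopifnot(length(u_core) == length(profile))
  denom <- if (direction == "as_printed") sum(u_core^2) else sum(profile^2)
  if (denom <= 0)
    stop("degenerate ", if (direction == "as_printed") "sample" else
         "reference profile", ": all-zero vector", call. = FALSE)
  sum(u_core * profile) / denom
}

#' Per-sample biological-process activity by core-gene regression
#'
#' Full activity pipeline for one pathway: correlation matrix with
#' p-values, significance-gated scores, selection of the floor(P/2) core
#' genes, cohort-mean reference profile, then one regression coefficient
#' per sample. The result is the outcome vector Y of the causal model.
#'
#' @param u expression matrix restricted to the pathway (samples x genes).
#' @param cfg a [cebp_config()]; `alpha` and `activity_direction` are used.
#' @return object of class `cebp_activity`: list with `y` (named activity
#'   vector), `direction`, `core_indices`, `core_genes`, `scores`, `alpha`,
#'   `profile`.
#' @examples
#' set.seed(1)
#' u <- matrix(rexp(200, 1 / 10), 20, 10,
#'             dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
#' act <- estimate_activity(u, cebp_config())
#' head(act$y)
#' @export
estimate_activity <- function(u, cfg = cebp_config()) {
  stopifnot(inherits(cfg, "cebp_config"))
  corr <- correlation_with_pvalues(u)
  scores <- core_scores(corr, cfg$alpha)
  sel <- select_core_genes(scores)
  prof <- reference_profile(u, sel$core_indices)
  uc <- u[, sel$core_indices, drop = FALSE]
  y <- vapply(seq_len(nrow(uc)), function(i)
    sample_activity(uc[i, ], prof, cfg$activity_direction), numeric(1))
  names(y) <- rownames(u)
  structure(list(y = y,
                 direction = cfg$activity_direction,
                 core_indices = sel$core_indices,
                 core_genes = sel$core_genes,
                 scores = scores,
                 alpha = cfg$alpha,
                 profile = prof),
            class = "cebp_activity")
}

#' @export
print.cebp_activity <- function(x, ...) {
  cat(sprintf("Pathway activity for %d samples (%d core genes, alpha %.2g, %s)\n",
              length(x$y), length(x$core_indices), x$alpha, x$direction))
  print(utils::head(x$y))
  invisible(x)
}

#' Write an activity vector with its provenance sidecar
#'
#' Writes a two-column TSV (sample_id, activity) and a JSON sidecar
#' recording the core genes, alpha and regression direction.
#'
#' @param act a `cebp_activity` object.
#' @param path output TSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_activity <- function(act, path) {
  stopifnot(inherits(act, "cebp_activity"))
  utils::write.table(
    data.frame(sample_id = names(act$y), activity = act$y),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(core_genes = act$core_genes, core_indices = act$core_indices,
         alpha = act$alpha, direction = act$direction),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an activity vector written by [write_activity()]
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_activity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$activity), df$sample_id)
}
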