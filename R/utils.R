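#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
cebp_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

# samples-by-genes numeric matrix with unique dimnames; shared validator for
# expression and mutation tables
check_sample_gene_matrix <- function(x, what = "table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (samples x genes)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry sample rownames and gene colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifier: ",
         rownames(x)[duplicated(rownames(x))][1], call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifier: ",
         colnames(x)[duplicated(colnames(x))][1], call. = FALSE)
  invisible(x)
}
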