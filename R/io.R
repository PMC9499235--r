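#' Read an expression table
#'
#' Reads a TSV expression matrix (one header row, one identifier column,
#' numeric body) and returns it in samples x genes orientation regardless of
#' how the file is laid out.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`;
#'   tells the reader which way the file is stored.
#' @return numeric matrix, samples in rows, genes in columns, nonnegative.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(id = c("s1", "s2"), gA = c(1, 2), gB = c(3, 4)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' read_expression(tf)
#' @export
read_expression <- function(path,
                            orientation = c("samples_in_rows",
                                            "genes_in_rows")) {
  orientation <- match.arg(orientation)
  m <- read_id_matrix(path, what = "expression")
  if (orientation == "genes_in_rows") m <- t(m)
  check_sample_gene_matrix(m, "expression table")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at sample '", rownames(m)[bad[1]],
         "', gene '", colnames(m)[bad[2]], "'", call. = FALSE)
  }
  m
}

# shared TSV -> named numeric matrix reader with location-bearing errors
read_id_matrix <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2)
    stop(what, " file must have an identifier column plus data columns",
         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate identifier '", ids[duplicated(ids)][1], "' in ", what,
         " file ", path, call. = FALSE)
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate identifier '",
         colnames(df)[-1][duplicated(colnames(df)[-1])][1], "' in ", what,
         " file header", call. = FALSE)
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num) && !anyNA(body)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", body[bad[1], bad[2]], "' at row '",
         ids[bad[1]], "', column '", colnames(body)[bad[2]], "' in ", path,
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  num
}

#' Read a binary somatic-mutation matrix
#'
#' @param path TSV of 0/1 entries, samples in rows, genes in columns, with
#'   one identifier column and a header row.
#' @return binary numeric matrix (samples x genes).
#' @export
read_mutation_matrix <- function(path) {
  m <- read_id_matrix(path, what = "mutation")
  check_sample_gene_matrix(m, "mutation table")
  bad <- !(m %in% c(0, 1))
  if (any(bad)) {
    loc <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    stop("non-binary entry ", m[loc[1], loc[2]], " at sample '",
         rownames(m)[loc[1]], "', gene '", colnames(m)[loc[2]], "'",
         call. = FALSE)
  }
  m
}

#' Write a samples-by-genes matrix as TSV
#'
#' Inverse of [read_expression()] / [read_mutation_matrix()] with
#' samples in rows; round-trips exactly.
#'
#' @param m named numeric matrix (samples x genes).
#' @param path output path.
#' @param id_col name of the identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_sample_gene_matrix <- function(m, path, id_col = "sample_id") {
  check_sample_gene_matrix(m, "table")
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize a MAF file into a mutation matrix
#'
#' Marks (sample, gene) = 1 when at least one retained variant record exists.
#' Variant classes listed in `excluded_classes` (by default silent mutations)
#' are dropped before binarization.
#'
#' @param path MAF file with at least `Hugo_Symbol`, `Tumor_Sample_Barcode`
#'   and `Variant_Classification` columns.
#' @param excluded_classes character vector of `Variant_Classification`
#'   values that do not count as mutations.
#' @return binary numeric matrix (samples x genes).
#' @export
binarize_maf <- function(path, excluded_classes = "Silent") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("MAF file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  keep <- !(df$Variant_Classification %in% excluded_classes)
  df <- df[keep, , drop = FALSE]
  samples <- sort(unique(df$Tumor_Sample_Barcode))
  genes <- sort(unique(df$Hugo_Symbol))
  m <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  if (nrow(df)) {
    m[cbind(match(df$Tumor_Sample_Barcode, samples),
            match(df$Hugo_Symbol, genes))] <- 1
  }
  m
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene identifiers.
#' Duplicate genes inside a line are removed with a warning.
#'
#' @param path GMT file.
#' @return named list of gene sets; each element is a list with `name`,
#'   `description` and `genes` (character vector, no duplicates).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[1], "' (line ", i,
              ") contains duplicated genes; deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- list(name = fields[1], description = fields[2],
                      genes = genes)
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Restrict expression and mutation tables to their shared samples
#'
#' Keeps the intersection of sample identifiers, sorted lexicographically,
#' so both outputs carry samples in the identical order.
#'
#' @param expr expression matrix (samples x genes).
#' @param mut binary mutation matrix (samples x genes).
#' @return list with elements `expression` and `mutation`.
#' @export
align_cohort <- function(expr, mut) {
  check_sample_gene_matrix(expr, "expression table")
  check_sample_gene_matrix(mut, "mutation table")
  common <- sort(intersect(rownames(expr), rownames(mut)))
  if (!length(common))
    stop("no samples shared between expression and mutation tables",
         call. = FALSE)
  list(expression = expr[common, , drop = FALSE],
       mutation = mut[common, , drop = FALSE])
}

#' Drop non-expressed genes
#'
#' Removes genes whose expression falls below `threshold` (default 10,
#' FPKM-like units). Under the default `mean_below` rule a gene is dropped
#' when its cohort mean is below the threshold; under `all_below` only when
#' every sample is below it.
#'
#' @param expr expression matrix (samples x genes).
#' @param threshold nonnegative expression cutoff.
#' @param rule `"mean_below"` or `"all_below"`.
#' @return the filtered expression matrix; retained values are untouched.
#' @export
filter_expressed_genes <- function(expr, threshold = 10,
                                   rule = c("mean_below", "all_below")) {
  rule <- match.arg(rule)
  check_sample_gene_matrix(expr, "expression table")
  stopifnot(threshold >= 0)
  drop <- switch(rule,
    mean_below = colMeans(expr) < threshold,
    all_below  = apply(expr < threshold, 2, all)
  )
  if (all(drop))
    stop("all genes removed at threshold ", threshold,
         "; lower the threshold or use rule = 'all_below'", call. = FALSE)
  expr[, !drop, drop = FALSE]
}
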