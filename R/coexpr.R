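# Hepatic coexpression screen: non-tumor filtering, all-vs-all correlation,
# resampled null with a +/-2 SD gate, top-20 query summary, and hypergeometric
# gene-set over-representation.

#' Construct an expression matrix with sample metadata
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be finite.
#' @param sample_meta data.frame with columns `sample_id` and logical `tumor`
#'   covering every sample.
#' @return An `expr_matrix` object (list with `values` and `sample_meta`).
#' @export
expression_matrix <- function(values, sample_meta) {
  assert_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "values must have unique gene ids as rownames")
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "values must have unique sample ids as colnames")
  assert_that(all(is.finite(values)), "all expression values must be finite")
  assert_that(all(c("sample_id", "tumor") %in% names(sample_meta)),
              "sample_meta needs sample_id and tumor columns")
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  assert_that(length(missing_meta) == 0,
              paste("samples missing from metadata:", paste(missing_meta, collapse = ", ")))
  meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, sample_meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d tumor, %d non-tumor)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_meta$tumor), sum(!x$sample_meta$tumor)))
  invisible(x)
}

#' Keep only non-tumor samples
#'
#' @param expr An [expression_matrix()].
#' @return An `expr_matrix` restricted to samples with `tumor == FALSE`; the
#'   gene set is unchanged.
#' @export
filter_nontumor <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  keep <- !expr$sample_meta$tumor
  if (!any(keep)) stop(errorCondition("no non-tumor samples in cohort",
                                      class = c("acylomics_empty_cohort", "error")))
  expression_matrix(expr$values[, keep, drop = FALSE],
                    expr$sample_meta[keep, , drop = FALSE])
}

#' All-vs-all gene correlation matrix
#'
#' Product-moment (or rank) correlation of every gene with every gene across
#' samples. Genes with zero variance cannot be correlated and are dropped
#' with a warning.
#'
#' @param expr An [expression_matrix()].
#' @param method `"pearson"` (default, the microarray convention on
#'   log-scale data) or `"spearman"`.
#' @return A `corr_matrix` object: list with `gene_ids`, symmetric matrix
#'   `r` (unit diagonal), and `method`.
#' @export
correlation_matrix <- function(expr, method = c("pearson", "spearman")) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  if (ncol(expr$values) < 3)
    stop(errorCondition("need at least 3 samples to correlate",
                        class = c("acylomics_insufficient_data", "error")))
  v <- apply(expr$values, 1, stats::var)
  flat <- v == 0 | !is.finite(v)
  if (any(flat)) {
    warning(sprintf("dropping %d zero-variance gene(s): %s", sum(flat),
                    paste(utils::head(rownames(expr$values)[flat], 5), collapse = ", ")))
  }
  m <- expr$values[!flat, , drop = FALSE]
  r <- stats::cor(t(m), method = method)
  structure(list(gene_ids = rownames(m), r = r, method = method),
            class = "corr_matrix")
}

# Off-diagonal upper-triangle coefficients; the pool the null resamples from.
offdiag_pool <- function(corr, stat = c("r", "r2")) {
  stat <- match.arg(stat)
  x <- corr$r[upper.tri(corr$r)]
  if (stat == "r2") x^2 else x
}

#' Resampled null distribution of correlation coefficients
#'
#' Draws `B` "virtual gene lists" of `list_size` coefficients from the
#' off-diagonal upper triangle of the correlation matrix (without replacement
#' within a list, with replacement across lists), pools the `B * list_size`
#' draws, and sets significance bounds at `mean +/- k * sd`. Coefficients
#' beyond these bounds are considered unlikely by chance.
#'
#' @param corr A [correlation_matrix()] result.
#' @param B Number of virtual lists (default 1000).
#' @param list_size Coefficients per list (default 20, the query-list size).
#' @param k SD multiplier for the bounds (default 2).
#' @param stat Resample signed `"r"` (default; a two-sided gate needs a
#'   signed statistic) or literal `"r2"`.
#' @param seed Integer seed.
#' @return A `corr_null` list: `B`, `list_size`, `k`, `stat`, `mean`, `sd`,
#'   `lower`, `upper`, `seed`.
#' @export
resample_null <- function(corr, B = 1000, list_size = 20, k = 2,
                          stat = c("r", "r2"), seed = 1L) {
  stopifnot(inherits(corr, "corr_matrix"))
  stat <- match.arg(stat)
  pool <- offdiag_pool(corr, stat)
  assert_that(list_size <= length(pool),
              "list_size exceeds the number of off-diagonal coefficients")
  draws <- with_seed(seed, {
    unlist(lapply(seq_len(B), function(b) sample(pool, list_size)))
  })
  m <- mean(draws); s <- stats::sd(draws)
  if (s == 0) warning("degenerate null: resampled coefficients have zero spread")
  structure(list(B = as.integer(B), list_size = as.integer(list_size), k = k,
                 stat = stat, mean = m, sd = s,
                 lower = m - k * s, upper = m + k * s, seed = as.integer(seed)),
            class = "corr_null")
}

#' Top correlates of a query gene, flagged against the resampled null
#'
#' Ranks all other genes by absolute correlation with the query and returns
#' the top `top_n`, each flagged `beyond_threshold` when its coefficient
#' falls outside the null's `mean +/- k*sd` bounds. Ties in |r| are broken
#' lexicographically by gene id.
#'
#' @param corr A [correlation_matrix()] result.
#' @param query Query gene id (must be present in the matrix).
#' @param null A [resample_null()] result.
#' @param top_n Number of correlates to report (default 20).
#' @return A `query_result`: list with `query_gene`, `top_n`, and a
#'   data.frame `ranked` (gene_id, r, r2, beyond_threshold).
#' @export
query_top <- function(corr, query, null, top_n = 20) {
  stopifnot(inherits(corr, "corr_matrix"), inherits(null, "corr_null"))
  if (!query %in% corr$gene_ids)
    stop(errorCondition(sprintf("query gene '%s' not in matrix", query),
                        class = c("acylomics_lookup_error", "error")))
  r <- corr$r[query, ]
  r <- r[names(r) != query]
  if (top_n > length(r)) {
    message(sprintf("top_n = %d exceeds %d available genes; truncating", top_n, length(r)))
    top_n <- length(r)
  }
  ord <- order(-abs(r), names(r))
  top <- r[ord][seq_len(top_n)]
  stat_val <- if (null$stat == "r2") top^2 else top
  ranked <- data.frame(gene_id = names(top), r = unname(top), r2 = unname(top^2),
                       beyond_threshold = unname(stat_val < null$lower | stat_val > null$upper),
                       stringsAsFactors = FALSE)
  structure(list(query_gene = query, top_n = as.integer(top_n), ranked = ranked,
                 null = null),
            class = "query_result")
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the realized overlap between `gene_list` and the set, given the
#' universe; Benjamini--Hochberg adjustment across sets.
#'
#' @param gene_list Character vector of hit genes (must lie in `universe`).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: all genes that could have been hits.
#' @return data.frame sorted by p: set_name, overlap, set_size, list_size,
#'   universe_size, p, q.
#' @export
enrich <- function(gene_list, gene_sets, universe) {
  assert_that(length(universe) > 0, "universe must be non-empty")
  assert_that(length(gene_sets) > 0, "gene_sets must be non-empty")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  assert_that(all(gene_list %in% universe), "gene_list must be a subset of universe")
  n_list <- length(gene_list)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(set, gene_list))
    # P(X >= ov), upper tail including the observed overlap
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       n_list, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(set),
               list_size = n_list, universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
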