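# Differential statistics for metabolite peak-area tables: log2 fold
# changes, unpaired t tests, Benjamini-Hochberg adjustment, volcano-style
# hit calling.

#' Benjamini--Hochberg step-up adjusted p-values
#'
#' Authored step-up procedure: order the p-values, compute `p_(i) * m / i`,
#' enforce monotonicity by a cumulative minimum from the largest rank down,
#' and cap at 1. Invariant under permutation of the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  assert_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1)))[ro]
  }
  q
}

#' Group-versus-group differential statistics for a metabolite table
#'
#' Log2-transforms peak areas, computes per-metabolite log2 fold change as
#' the difference of group means on the log2 scale (a ratio of geometric
#' means), tests with a two-tailed unpaired t (pooled variance by default,
#' mirroring the acyl-site statistics; Welch available), adjusts across all
#' features with Benjamini--Hochberg, and calls hits at `q < q_max` and
#' `|log2fc| > lfc_min`.
#'
#' @param table Long data.frame: `metabolite`, `group`, `replicate`, `area`
#'   (positive), e.g. from [gen_metabolite_table()].
#' @param pair Character pair `c(A, B)`: reference group then comparison.
#' @param q_max q-value gate (default 0.015).
#' @param lfc_min Absolute log2 fold-change gate (default 1).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return data.frame: metabolite, log2fc, t, p, q, hit; one row per
#'   metabolite, ordered by id. Features with < 2 replicates in either group
#'   or zero variance in both get `p = NA`, `hit = NA` (not testable).
#' @export
group_differential <- function(table, pair, q_max = 0.015, lfc_min = 1,
                               var_equal = TRUE) {
  assert_that(all(c("metabolite", "group", "replicate", "area") %in% names(table)),
              "table needs metabolite, group, replicate, area columns")
  assert_that(all(table$area > 0, na.rm = TRUE), "peak areas must be positive")
  assert_that(length(pair) == 2 && all(pair %in% table$group),
              "pair must name two groups present in the table")
  ids <- sort(unique(table$metabolite))
  rows <- lapply(ids, function(id) {
    a <- log2(table$area[table$metabolite == id & table$group == pair[1]])
    b <- log2(table$area[table$metabolite == id & table$group == pair[2]])
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    lfc <- mean(b) - mean(a)
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(metabolite = id, log2fc = lfc, t = NA_real_, p = NA_real_))
    if (var_equal) {
      tt <- student_t_pooled(a, b)
      data.frame(metabolite = id, log2fc = lfc, t = tt$t, p = tt$p)
    } else {
      res <- tryCatch(stats::t.test(b, a, var.equal = FALSE),
                      error = function(e) NULL)
      data.frame(metabolite = id, log2fc = lfc,
                 t = if (is.null(res)) NA_real_ else unname(res$statistic),
                 p = if (is.null(res)) NA_real_ else res$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$hit <- ifelse(is.na(out$q), NA, out$q < q_max & abs(out$log2fc) > lfc_min)
  attr(out, "thresholds") <- list(q_max = q_max, lfc_min = lfc_min,
                                  transform = "log2", pair = pair)
  rownames(out) <- NULL
  out
}
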