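# Coexpression screen: filtering, correlation, resampled null, query, ORA.

make_expr <- function(values) {
  expression_matrix(values, data.frame(sample_id = colnames(values),
                                       tumor = FALSE, stringsAsFactors = FALSE))
}

test_that("filter_nontumor keeps exactly the non-tumor samples", {
  v <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  meta <- data.frame(sample_id = colnames(v), tumor = rep(c(TRUE, FALSE), 5))
  expr <- expression_matrix(v, meta)
  nt <- filter_nontumor(expr)
  expect_equal(ncol(nt$values), 5)
  expect_equal(nrow(nt$values), 4)
  expect_false(any(nt$sample_meta$tumor))
  # all non-tumor: identity
  all_nt <- make_expr(v)
  expect_identical(filter_nontumor(all_nt)$values, v)
  # none left: empty-cohort error
  meta$tumor <- TRUE
  expect_error(filter_nontumor(expression_matrix(v, meta)),
               class = "acylomics_empty_cohort")
})

test_that("filtering removes the tumor-driven mean structure", {
  sim <- gen_expression(sim_config(seed = 4, n_genes = 200, n_samples = 100,
                                   frac_tumor = 0.5, planted_module_size = 5), "Q")
  cm <- colMeans(sim$expr$values)
  before <- abs(mean(cm[sim$expr$sample_meta$tumor]) - mean(cm[!sim$expr$sample_meta$tumor]))
  expect_gt(before, 0.3)
  nt <- filter_nontumor(sim$expr)
  expect_false(any(nt$sample_meta$tumor))
  expect_equal(nrow(nt$values), 200)
})

test_that("correlation_matrix matches the brute-force oracle", {
  set.seed(42)
  # hand-sized fixed case
  m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  corr <- correlation_matrix(make_expr(m))
  expect_lt(max(abs(corr$r - oracle_cor(m))), 1e-12)
  # property: random matrices up to 10 x 10
  for (i in 1:8) {
    ng <- sample(3:10, 1); ns <- sample(3:10, 1)
    m <- matrix(rnorm(ng * ns), ng, ns,
                dimnames = list(paste0("g", seq_len(ng)), paste0("s", seq_len(ns))))
    corr <- correlation_matrix(make_expr(m))
    expect_lt(max(abs(corr$r - oracle_cor(m))), 1e-12)
    expect_true(isSymmetric(corr$r))
    expect_equal(unname(diag(corr$r)), rep(1, ng))
  }
})

test_that("correlation_matrix handles duplicates, negation, degenerate input", {
  base <- rnorm(8)
  v <- rbind(g1 = base, g2 = base, g3 = -base, g4 = rnorm(8))
  colnames(v) <- paste0("s", 1:8)
  corr <- correlation_matrix(make_expr(v))
  expect_equal(corr$r["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(corr$r["g1", "g3"], -1, tolerance = 1e-12)
  # zero-variance gene dropped with a warning
  v2 <- rbind(v, flat = rep(2, 8))
  expect_warning(c2 <- correlation_matrix(make_expr(v2)), "zero-variance")
  expect_false("flat" %in% c2$gene_ids)
  # too few samples
  expect_error(correlation_matrix(make_expr(v[, 1:2])),
               class = "acylomics_insufficient_data")
})

test_that("resample_null: determinism, degenerate case, config guards", {
  set.seed(1)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  corr <- correlation_matrix(make_expr(m))
  n1 <- resample_null(corr, B = 50, list_size = 10, seed = 7)
  n2 <- resample_null(corr, B = 50, list_size = 10, seed = 7)
  expect_identical(n1, n2)
  expect_lt(n1$lower, n1$mean); expect_gt(n1$upper, n1$mean)
  expect_false(identical(n1$mean, resample_null(corr, B = 50, list_size = 10, seed = 8)$mean))
  expect_error(resample_null(corr, list_size = 1e6), class = "acylomics_invalid_config")
  # constant off-diagonal: degenerate null warning, sd = 0
  v <- outer(rep(1, 4), rnorm(6))    # identical genes -> r = 1 everywhere
  dimnames(v) <- list(paste0("g", 1:4), paste0("s", 1:6))
  cc <- correlation_matrix(make_expr(v))
  expect_warning(nd <- resample_null(cc, B = 10, list_size = 3, seed = 1), "degenerate")
  expect_equal(nd$sd, 0)
})

test_that("query_top ranks by |r|, breaks ties lexicographically, flags threshold", {
  r <- diag(1, 4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- -0.9   # tie in |r| with gene b
  r[1, 4] <- r[4, 1] <- 0.1
  dimnames(r) <- list(c("q", "b", "a", "z"), c("q", "b", "a", "z"))
  corr <- structure(list(gene_ids = rownames(r), r = r, method = "pearson"),
                    class = "corr_matrix")
  null <- structure(list(B = 10L, list_size = 3L, k = 2, stat = "r",
                         mean = 0, sd = 0.2, lower = -0.4, upper = 0.4, seed = 1L),
                    class = "corr_null")
  qt <- query_top(corr, "q", null, top_n = 3)
  expect_equal(qt$ranked$gene_id, c("a", "b", "z"))   # |r| ties: lexicographic
  expect_equal(qt$ranked$beyond_threshold, c(TRUE, TRUE, FALSE))
  expect_error(query_top(corr, "nope", null), class = "acylomics_lookup_error")
  expect_message(qt_all <- query_top(corr, "q", null, top_n = 10), "truncating")
  expect_equal(nrow(qt_all$ranked), 3)
})

test_that("planted module is recovered in the top correlates", {
  recall <- sapply(1:10, function(s) {
    sim <- gen_expression(sim_config(seed = s, n_genes = 300, n_samples = 200,
                                     frac_tumor = 0, planted_module_size = 20,
                                     planted_r = 0.8), "SIRT5")
    corr <- correlation_matrix(sim$expr)
    null <- resample_null(corr, B = 200, list_size = 20, seed = s)
    qt <- query_top(corr, "SIRT5", null, top_n = 20)
    mean(sim$truth$planted_gene_ids %in% qt$ranked$gene_id)
  })
  expect_gte(mean(recall), 0.9)
})

test_that("enrich matches the enumeration oracle and behaves at the extremes", {
  universe <- sprintf("g%04d", 1:1000)
  sets <- list(hitset = universe[1:50], other = universe[101:140])
  glist <- c(universe[1:5], universe[201:215])       # overlap 5 with hitset, 0 with other
  res <- enrich(glist, sets, universe)
  expect_equal(res$p[res$set_name == "hitset"],
               oracle_hyper(5, 50, 20, 1000), tolerance = 1e-10)
  expect_equal(res$p[res$set_name == "other"], 1)    # zero overlap, upper tail includes 0
  # a gene list identical to one set ranks it first with tiny p
  res2 <- enrich(universe[1:20], list(exact = universe[1:20], other = sets$other), universe)
  expect_equal(res2$set_name[1], "exact")
  expect_lt(res2$p[1], 1e-30)
  # BH q monotone non-decreasing in rank of p
  expect_true(all(diff(res2$q) >= -1e-15))
  expect_error(enrich(c("not_in_universe"), sets, universe),
               class = "acylomics_invalid_config")
  expect_error(enrich(glist, sets, character()), class = "acylomics_invalid_config")
})
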