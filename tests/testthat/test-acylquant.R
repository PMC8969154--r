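# Acyl-site quantification: normalization, imputation, statistics, masses.

test_that("protein_abundance aggregates unmodified peptides only", {
  tab <- tiny_acyl_table()
  one <- tab[tab$peptide_seq != "CCCCK", ]
  expect_equal(protein_abundance(one, "unmod", 1), 10)       # single peptide
  expect_equal(protein_abundance(tab, "unmod", 1), mean(c(10, 30)))
  expect_equal(protein_abundance(tab, "unmod", 1, aggregate = "sum"), 40)
  no_unmod <- tab[tab$mod_type != "none", ]
  expect_error(protein_abundance(no_unmod, "unmod", 1),
               class = "acylomics_normalization_impossible")
})

test_that("normalization is exactly invariant to per-sample scaling", {
  tab <- tiny_acyl_table()
  norm <- normalize_to_protein(tab)
  scaled <- tab
  sel <- scaled$condition == "glut" & scaled$replicate == 2
  scaled$intensity[sel] <- scaled$intensity[sel] * 7
  norm_scaled <- normalize_to_protein(scaled)
  expect_equal(norm$intensity, norm_scaled$intensity, tolerance = 1e-12)
  # uniform table: every normalized value equals 1
  unif <- tab; unif$intensity <- 5
  expect_true(all(normalize_to_protein(unif)$intensity == 1))
})

test_that("protein_abundance tracks the injected per-sample scale factor", {
  sim <- gen_acyl_table(5, 6, c("unmod", "glut"), 3, seed = 8,
                        rep_sd_log2 = 1e-6, scale_sd_log2 = 0.6)
  keys <- unique(sim$table[, c("condition", "replicate")])
  est <- log2(mapply(function(c, r) protein_abundance(sim$table, c, r),
                     keys$condition, keys$replicate))
  truth <- sim$truth$sample_scale_log2[paste(keys$condition, keys$replicate, sep = ".")]
  expect_gt(summary(lm(est ~ truth))$r.squared, 0.99)
})

test_that("impute_low fills from the sample's low tail, deterministically", {
  tab <- tiny_acyl_table()
  expect_identical(impute_low(tab, seed = 3), tab)           # no missing: identity
  sim <- gen_acyl_table(10, 8, c("unmod", "glut"), 3, missing_rate = 0.2, seed = 14)
  imp1 <- impute_low(sim$table, seed = 9)
  imp2 <- impute_low(sim$table, seed = 9)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1$intensity))
  # property: imputed values never exceed the sample's 5th-percentile ceiling
  for (s in 1:20) {
    sim <- gen_acyl_table(10, 8, c("unmod", "glut"), 3, missing_rate = 0.25, seed = s)
    was_na <- is.na(sim$table$intensity)
    imp <- impute_low(sim$table, quantile = 0.05, seed = s)
    k <- paste(sim$table$condition, sim$table$replicate, sep = ".")
    for (kk in unique(k)) {
      obs <- sim$table$intensity[k == kk & !was_na]
      ceiling_val <- quantile(obs, 0.05, names = FALSE)
      filled <- imp$intensity[k == kk & was_na]
      if (length(filled)) expect_lte(max(filled), ceiling_val)
    }
  }
  # a sample with nothing observed cannot be imputed
  broken <- gen_acyl_table(10, 8, c("unmod", "glut"), 3, missing_rate = 0.1,
                           seed = 2)$table
  broken$intensity[broken$condition == "glut" & broken$replicate == 1] <- NA
  expect_error(impute_low(broken, seed = 1), class = "acylomics_unimputable_sample")
})

test_that("site_differential matches the closed-form t oracle", {
  # identical replicate vectors in A and B: log2fc = 0
  tab <- tiny_acyl_table()
  same <- tab
  same$intensity[same$mod_type != "none"] <- rep(c(3, 4, 5), 4)
  same$intensity[same$mod_type == "none"] <- 1   # neutral normalization divisor
  res0 <- site_differential(same, c("unmod", "glut"))
  expect_equal(res0$log2fc, c(0, 0), tolerance = 1e-12)

  # hand case against the oracle: intensities so that log2 values are known
  a <- c(2, 2, 2); b <- c(16, 2^4.2, 2^3.9)
  hand <- tab
  hand$intensity[hand$site_residue %in% 100] <- c(a, b)
  hand$intensity[hand$mod_type == "none"] <- 1
  res <- site_differential(hand, c("unmod", "glut"))
  orc <- oracle_t_pooled(log2(a), log2(b))
  i <- which(res$site_residue == 100)
  expect_equal(res$p[i], orc$p, tolerance = 1e-9)
  expect_equal(res$t[i], orc$t, tolerance = 1e-9)
  expect_equal(res$log2fc[i], mean(log2(b)) - mean(log2(a)), tolerance = 1e-12)
  expect_true(res$significant[i])          # lfc ~ 3 > 1.8 and p <= 0.05

  # zero variance in both groups: not testable
  const <- tab
  const$intensity[const$mod_type == "none"] <- 1
  const$intensity[const$site_residue %in% 100] <- c(2, 2, 2, 8, 8, 8)
  resc <- site_differential(const, c("unmod", "glut"))
  expect_true(is.na(resc$p[resc$site_residue == 100]))
  expect_true(is.na(resc$significant[resc$site_residue == 100]))
})

test_that("deglutarylation calls use the p-gate only", {
  tab <- tiny_acyl_table()
  tab$intensity[tab$mod_type == "none"] <- 1
  # site 100: modest decrease, clearly significant p but |lfc| < 1.8
  tab$intensity[tab$site_residue %in% 100] <- c(4, 4.1, 3.9, 2, 2.05, 1.95)
  glu <- site_differential(tab, c("unmod", "glut"), ratio_kind = "glutarylation")
  deg <- site_differential(tab, c("unmod", "glut"), ratio_kind = "deglutarylation")
  i <- which(glu$site_residue == 100)
  expect_false(glu$significant[i])                 # fails the 1.8 gate
  expect_true(deg$significant[i])                  # p-only gate
  expect_lt(deg$log2fc[i], 0)
})

test_that("full-null tables rarely pass the joint significance gate", {
  hits <- sapply(1:30, function(s) {
    sim <- gen_acyl_table(10, 6, c("unmod", "glut"), 3, seed = 100 + s)
    res <- site_differential(normalize_to_protein(sim$table), c("unmod", "glut"))
    sum(res$significant, na.rm = TRUE)
  })
  expect_lt(mean(hits) / 10, 0.01)
})

test_that("map_residue is exact 1-based arithmetic with an inverse", {
  expect_equal(map_residue(209, 44), 253)
  expect_equal(map_residue(10, 0), 10)
  expect_error(map_residue(0, 0), class = "acylomics_coordinate_error")
  expect_error(map_residue(5, -1), class = "acylomics_invalid_config")
  set.seed(13)
  pos <- sample(1:2000, 1000, replace = TRUE)
  off <- sample(0:100, 1000, replace = TRUE)
  expect_identical(unmap_residue(map_residue(pos, off), off), pos)
})

test_that("mod_mass sums standard monoisotopic masses", {
  expect_identical(mod_mass(c()), 0)
  expect_equal(mod_mass(c(H = 2, O = 1)), 18.0105646, tolerance = 1e-5)
  expect_equal(mod_mass(c(C = 4, H = 4, O = 3)), 100.0160440, tolerance = 1e-5)  # succinyl
  expect_error(mod_mass(c(Xx = 1)), class = "acylomics_invalid_config")
})
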