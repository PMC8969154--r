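# Independent brute-force oracles, kept free of any package internals.

# Textbook product-moment correlation, explicit double loop.
oracle_cor <- function(m) {
  ng <- nrow(m)
  r <- diag(1, ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    x <- m[i, ] - mean(m[i, ]); y <- m[j, ] - mean(m[j, ])
    r[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

# Upper-tail hypergeometric P(X >= overlap) by exhaustive PMF summation.
oracle_hyper <- function(overlap, set_size, list_size, universe_size) {
  ks <- overlap:min(set_size, list_size)
  sum(exp(lchoose(set_size, ks) + lchoose(universe_size - set_size, list_size - ks) -
            lchoose(universe_size, list_size)))
}

# Textbook BH step-up: sort, p_(i) * m / i, cumulative min from the top.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1)) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Closed-form pooled-variance two-sample t, two-sided.
oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# A small acyl table written out by hand (2 unmodified peptides, 2 sites,
# 2 conditions x 3 replicates), used by several quant tests.
tiny_acyl_table <- function() {
  expand_rows <- function(pep, site, mod, ints) {
    data.frame(peptide_seq = pep, site_residue = site, mod_type = mod,
               condition = rep(c("unmod", "glut"), each = 3),
               replicate = rep(1:3, 2), intensity = ints,
               stringsAsFactors = FALSE)
  }
  rbind(
    expand_rows("AAAAK", NA_integer_, "none", c(10, 11, 9, 20, 22, 18)),
    expand_rows("CCCCK", NA_integer_, "none", c(30, 29, 31, 60, 58, 62)),
    expand_rows("DDDKR", 100L, "glutaryl", c(1, 1.1, 0.9, 16, 17, 15)),
    expand_rows("EEEKR", 200L, "glutaryl", c(5, 5.2, 4.8, 10, 10.4, 9.6)))
}
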