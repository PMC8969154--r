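# Label-free acyl-site quantification: protein-level normalization from
# unmodified peptides, low-abundance imputation, per-site differential
# statistics, residue-coordinate mapping, and modification-mass arithmetic.

check_acyl_table <- function(table) {
  need <- c("peptide_seq", "site_residue", "mod_type", "condition", "replicate", "intensity")
  assert_that(all(need %in% names(table)),
              paste("acyl table needs columns:", paste(need, collapse = ", ")))
  bad <- xor(is.na(table$site_residue), table$mod_type == "none")
  assert_that(!any(bad), "site_residue must be NA exactly for unmodified (mod_type == 'none') rows")
  assert_that(all(table$intensity > 0, na.rm = TRUE), "intensities must be positive where present")
  invisible(table)
}

sample_key <- function(table) paste(table$condition, table$replicate, sep = ".")

#' Protein abundance of one sample from its unmodified peptides
#'
#' The loading/ionization proxy used for normalization: an aggregate (mean by
#' default) of the unmodified-peptide intensities observed in a given
#' (condition, replicate) sample.
#'
#' @param table Long acyl-peptide table (see [gen_acyl_table()] for columns).
#' @param condition,replicate Identify the sample.
#' @param aggregate `"mean"` (default), `"median"`, or `"sum"`.
#' @return A positive scalar.
#' @export
protein_abundance <- function(table, condition, replicate,
                              aggregate = c("mean", "median", "sum")) {
  check_acyl_table(table)
  aggregate <- match.arg(aggregate)
  sel <- table$mod_type == "none" & table$condition == condition &
    table$replicate == replicate & !is.na(table$intensity)
  if (!any(sel))
    stop(errorCondition(sprintf("no unmodified peptide intensities in sample %s.%s",
                                condition, replicate),
                        class = c("acylomics_normalization_impossible", "error")))
  fn <- switch(aggregate, mean = mean, median = stats::median, sum = sum)
  fn(table$intensity[sel])
}

#' Normalize acyl-peptide intensities to per-sample protein abundance
#'
#' Divides every intensity by its sample's protein abundance (computed from
#' unmodified peptides only), cancelling per-sample loading and LC-MS
#' performance differences. The result is exactly invariant to multiplying
#' all of one sample's intensities by a constant.
#'
#' @inheritParams protein_abundance
#' @return The table with `intensity` replaced by its normalized value and a
#'   `protein_abundance` column recording the divisor used.
#' @export
normalize_to_protein <- function(table, aggregate = c("mean", "median", "sum")) {
  check_acyl_table(table)
  aggregate <- match.arg(aggregate)
  keys <- unique(table[, c("condition", "replicate")])
  ab <- mapply(function(cond, rep) protein_abundance(table, cond, rep, aggregate),
               keys$condition, keys$replicate)
  names(ab) <- paste(keys$condition, keys$replicate, sep = ".")
  k <- sample_key(table)
  out <- table
  out$protein_abundance <- unname(ab[k])
  out$intensity <- table$intensity / out$protein_abundance
  out
}

#' Impute missing intensities by low-abundance resampling
#'
#' Each missing cell is filled with a value drawn uniformly from the observed
#' intensities at or below the `quantile`-th quantile of its own sample's
#' intensity distribution, mimicking the assumption that missingness is
#' caused by low abundance.
#'
#' @param table Long acyl-peptide table, possibly with `NA` intensities.
#' @param quantile Low-tail quantile defining the donor pool (default 0.05).
#' @param seed Integer seed (imputation is seed-deterministic).
#' @return The table with all intensities present.
#' @export
impute_low <- function(table, quantile = 0.05, seed = 1L) {
  check_acyl_table(table)
  if (!anyNA(table$intensity)) return(table)
  assert_that(mean(is.na(table$intensity)) < 0.5, "more than half of intensities missing")
  out <- table
  with_seed(seed, {
    for (k in unique(sample_key(table))) {
      idx <- sample_key(table) == k
      obs <- table$intensity[idx & !is.na(table$intensity)]
      miss <- which(idx & is.na(table$intensity))
      if (!length(miss)) next
      if (!length(obs))
        stop(errorCondition(sprintf("sample %s has no observed intensities to resample", k),
                            class = c("acylomics_unimputable_sample", "error")))
      ceiling_val <- stats::quantile(obs, quantile, names = FALSE, type = 7)
      pool <- obs[obs <= ceiling_val]
      out$intensity[miss] <- pool[sample.int(length(pool), length(miss), replace = TRUE)]
    }
  })
  out
}

# Pooled-variance two-sample Student's t (df = nA + nB - 2), two-sided.
student_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(list(t = NA_real_, p = NA_real_, df = na + nb - 2))
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2), df = na + nb - 2)
}

#' Per-site differential statistics between two conditions
#'
#' For each acyl site: log2 fold change as the difference of mean log2
#' normalized intensities (condition B minus A) and a two-sided
#' pooled-variance Student's t test across replicates. When several peptides
#' cover one site, their normalized intensities are averaged per sample
#' before statistics. Significance for `ratio_kind = "glutarylation"` follows
#' the joint gate `log2fc > lfc_threshold & p <= alpha`; for
#' `"deglutarylation"` there is no fold-change gate and significance is
#' `p <= alpha` alone.
#'
#' @param normalized A table from [normalize_to_protein()] (complete; run
#'   [impute_low()] first if it has missing values).
#' @param pair Character pair `c(A, B)`: reference condition then treatment.
#' @param lfc_threshold Log2 fold-change gate (default 1.8).
#' @param alpha P-value gate (default 0.05).
#' @param ratio_kind `"glutarylation"` (modified / unmodified) or
#'   `"deglutarylation"` (modified + deacylase / modified).
#' @return data.frame: site_residue, mean_log2_A, mean_log2_B, log2fc, t, p,
#'   significant, ratio_kind; ordered by site. Sites with zero variance in
#'   both groups get `p = NA` and `significant = NA` (not testable).
#' @export
site_differential <- function(normalized, pair, lfc_threshold = 1.8,
                              alpha = 0.05,
                              ratio_kind = c("glutarylation", "deglutarylation")) {
  check_acyl_table(normalized)
  ratio_kind <- match.arg(ratio_kind)
  assert_that(length(pair) == 2 && all(pair %in% normalized$condition),
              "pair must name two conditions present in the table")
  assert_that(!anyNA(normalized$intensity), "normalized table has missing values; impute first")
  acyl <- normalized[normalized$mod_type != "none", , drop = FALSE]
  sites <- sort(unique(acyl$site_residue))
  rows <- lapply(sites, function(s) {
    sub <- acyl[acyl$site_residue == s, , drop = FALSE]
    # aggregate multiple covering peptides per sample, then log2
    per_sample <- tapply(sub$intensity, list(sample_key(sub)), mean)
    cond_of <- sub$condition[match(names(per_sample), sample_key(sub))]
    la <- log2(per_sample[cond_of == pair[1]])
    lb <- log2(per_sample[cond_of == pair[2]])
    assert_that(length(la) >= 2 && length(lb) >= 2,
                sprintf("site %s needs >= 2 replicates in each condition", s))
    tt <- student_t_pooled(la, lb)
    lfc <- mean(lb) - mean(la)
    sig <- if (is.na(tt$p)) NA else if (ratio_kind == "glutarylation") {
      lfc > lfc_threshold && tt$p <= alpha
    } else tt$p <= alpha
    data.frame(site_residue = s, mean_log2_A = mean(la), mean_log2_B = mean(lb),
               log2fc = lfc, t = tt$t, p = tt$p, significant = sig,
               ratio_kind = ratio_kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map a construct residue position to full-length protein coordinates
#'
#' Recombinant constructs often lack the mitochondrial targeting presequence;
#' reported residue numbers refer to the full-length protein. Pure 1-based
#' arithmetic: `full = construct + offset`.
#'
#' @param construct_pos 1-based position in the expressed construct.
#' @param offset Non-negative length of the missing N-terminal presequence.
#' @return 1-based full-length position.
#' @export
map_residue <- function(construct_pos, offset) {
  assert_that(all(offset >= 0), "offset must be non-negative")
  full <- construct_pos + offset
  if (any(full < 1))
    stop(errorCondition("mapped residue position is non-positive",
                        class = c("acylomics_coordinate_error", "error")))
  full
}

#' Inverse of [map_residue()]
#' @param full_pos 1-based full-length position.
#' @param offset Presequence length.
#' @return 1-based construct position.
#' @export
unmap_residue <- function(full_pos, offset) {
  assert_that(all(offset >= 0), "offset must be non-negative")
  pos <- full_pos - offset
  if (any(pos < 1))
    stop(errorCondition("unmapped residue position is non-positive",
                        class = c("acylomics_coordinate_error", "error")))
  pos
}

# CODATA/IUPAC standard monoisotopic atomic masses (Da).
MONOISOTOPIC_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                       O = 15.9949146221, S = 31.97207069)

#' Monoisotopic mass of a modification formula
#'
#' Sum of standard monoisotopic atomic masses. Glutarylation adds C5H6O3 to
#' lysine (114.0316941 Da); succinylation adds C4H4O3 (100.0160440 Da).
#'
#' @param formula Named integer vector, element -> atom count. Elements
#'   limited to C, H, N, O, S.
#' @return Mass in Da.
#' @examples
#' mod_mass(c(C = 5, H = 6, O = 3))  # glutaryl
#' @export
mod_mass <- function(formula) {
  if (length(formula) == 0) return(0)
  assert_that(!is.null(names(formula)) && all(nzchar(names(formula))),
              "formula must be a named element -> count vector")
  unknown <- setdiff(names(formula), names(MONOISOTOPIC_MASS))
  assert_that(length(unknown) == 0,
              paste("unknown element(s):", paste(unknown, collapse = ", ")))
  sum(MONOISOTOPIC_MASS[names(formula)] * formula)
}
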