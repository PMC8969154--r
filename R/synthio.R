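# Synthetic-data generators: every input the pipeline consumes, emitted with
# known ground truth so downstream stages can be scored without external data.

#' Simulation configuration for the synthetic expression matrix
#'
#' Bundles and validates the parameters of [gen_expression()]. Defaults state
#' the simulated world once: a liver-cohort-sized matrix (2000 genes x 200
#' arrays, a quarter of them tumor samples), one planted coexpression module
#' of 20 genes correlated at 0.8 with the query gene, and unit-variance
#' log-scale noise.
#'
#' @param seed Integer seed; fixes all outputs bit-for-bit.
#' @param n_genes Number of genes (rows).
#' @param n_samples Number of samples (columns).
#' @param frac_tumor Fraction of samples flagged as tumor, in `[0, 1]`.
#' @param planted_module_size Number of genes in the planted module
#'   (excluding the query gene itself).
#' @param planted_r Target population correlation between each planted gene
#'   and the query gene, in `(0, 1)`.
#' @param noise_sd Standard deviation of the independent per-gene noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L, n_samples = 200L,
                       frac_tumor = 0.25, planted_module_size = 20L,
                       planted_r = 0.8, noise_sd = 1) {
  assert_that(is_count(n_genes) && is_count(n_samples), "n_genes and n_samples must be positive integers")
  assert_that(is_count(planted_module_size), "planted_module_size must be a positive integer")
  assert_that(planted_module_size < n_genes, "planted_module_size must be smaller than n_genes")
  assert_that(is.numeric(frac_tumor) && frac_tumor >= 0 && frac_tumor <= 1, "frac_tumor must lie in [0, 1]")
  assert_that(is.numeric(planted_r) && planted_r >= 0 && planted_r < 1, "planted_r must lie in [0, 1)")
  assert_that(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be positive")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), frac_tumor = frac_tumor,
                 planted_module_size = as.integer(planted_module_size),
                 planted_r = planted_r, noise_sd = noise_sd),
            class = "sim_config")
}

#' Generate a synthetic expression matrix with a planted coexpression module
#'
#' Single-latent-factor construction: the query gene is the factor itself and
#' each planted-module gene loads on it with loading
#' `beta = noise_sd * r / sqrt(1 - r^2)`, so the population correlation of a
#' planted gene with the query is exactly `planted_r = beta / sqrt(beta^2 +
#' noise_sd^2)`. All remaining genes are independent noise. Tumor samples
#' receive a global mean shift of `+0.5 * noise_sd` on every gene, so the
#' non-tumor filter has an observable effect. Values are on an
#' already-normalized log2 microarray-like scale (per-gene baselines near 8).
#'
#' @param config A [sim_config()].
#' @param query_gene Identifier to give the query gene (e.g. `"SIRT5"`).
#' @return A list with elements `expr` (an [expression_matrix()]) and
#'   `truth` (list with `planted_gene_ids`, `query_gene`, `planted_r`).
#' @examples
#' sim <- gen_expression(sim_config(seed = 1, n_genes = 50, n_samples = 30,
#'                                  planted_module_size = 5), "SIRT5")
#' dim(sim$expr$values)
#' @export
gen_expression <- function(config, query_gene = "SIRT5") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes; ns <- config$n_samples
    gene_ids <- c(query_gene, sprintf("GENE%04d", seq_len(ng - 1L)))
    sample_ids <- sprintf("S%03d", seq_len(ns))
    n_tumor <- round(config$frac_tumor * ns)
    tumor <- sample(c(rep(TRUE, n_tumor), rep(FALSE, ns - n_tumor)))

    f <- rnorm(ns)                                   # latent factor, one value per sample
    sigma <- config$noise_sd
    beta <- sigma * config$planted_r / sqrt(1 - config$planted_r^2)

    vals <- matrix(rnorm(ng * ns, sd = sigma), nrow = ng,
                   dimnames = list(gene_ids, sample_ids))
    planted <- sample(gene_ids[-1L], config$planted_module_size)
    vals[query_gene, ] <- f * sigma                  # query carries the factor, matched variance
    vals[planted, ] <- beta * rep(f, each = length(planted)) +
      matrix(rnorm(length(planted) * ns, sd = sigma), nrow = length(planted))
    vals[, tumor] <- vals[, tumor] + 0.5 * sigma     # tumor global mean shift
    vals <- vals + rnorm(ng, mean = 8, sd = 1)       # per-gene baseline, recycled down columns

    meta <- data.frame(sample_id = sample_ids, tumor = tumor,
                       stringsAsFactors = FALSE)
    list(expr = expression_matrix(vals, meta),
         truth = list(planted_gene_ids = sort(planted), query_gene = query_gene,
                      planted_r = config$planted_r))
  })
}

# Random tryptic-looking peptide string (ends in K or R).
random_peptide <- function(len) {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P", "Q", "S", "T", "V", "W", "Y")
  paste0(paste(sample(aa, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a synthetic long-format acyl-peptide quantification table
#'
#' Emulates replicate label-free MS1 intensities for one acylated protein:
#' unmodified peptides carry only the per-sample loading scale factor (so
#' protein-level normalization is both possible and necessary), while each
#' acyl site's peptide additionally carries its condition effect. Intensities
#' are log-normal; missing values are placed preferentially in low-intensity
#' cells via a logistic weight in log2 intensity.
#'
#' @param n_sites Number of acylated lysine sites (one peptide each).
#' @param n_unmod_peptides Number of unmodified peptides.
#' @param conditions Character vector of condition labels; the first is the
#'   reference, all later conditions receive the site effects.
#' @param n_reps Replicates per condition (>= 2).
#' @param effect_log2fc Named numeric vector, site residue -> true log2 fold
#'   change versus the reference condition. Unnamed sites get effect 0.
#' @param missing_rate Overall expected fraction of missing intensities (< 0.5).
#' @param seed Integer seed.
#' @param mod_type Modification label for the acyl peptides.
#' @param rep_sd_log2 Replicate noise SD on the log2 scale (default 0.3,
#'   i.e. roughly a 20--25% CV, typical of label-free MS1 quantification).
#' @param scale_sd_log2 SD of the per-sample log2 loading factor.
#' @return List with `table` (long data.frame: peptide_seq, site_residue,
#'   mod_type, condition, replicate, intensity with `NA` for missing) and
#'   `truth` (named true log2 fold changes per site, per-sample scale factors).
#' @export
gen_acyl_table <- function(n_sites, n_unmod_peptides, conditions, n_reps,
                           effect_log2fc = numeric(), missing_rate = 0,
                           seed = 1L, mod_type = "glutaryl",
                           rep_sd_log2 = 0.3, scale_sd_log2 = 0.5) {
  assert_that(length(conditions) >= 1 && all(nzchar(conditions)), "conditions must be a non-empty label vector")
  assert_that(is_count(n_reps) && n_reps >= 2, "n_reps must be >= 2")
  assert_that(missing_rate >= 0 && missing_rate < 0.5, "missing_rate must lie in [0, 0.5)")
  with_seed(seed, {
    sites <- sort(sample(30:430, n_sites))
    fc <- setNames(rep(0, n_sites), as.character(sites))
    if (length(effect_log2fc)) {
      # effects keyed by position among sites if names absent
      if (is.null(names(effect_log2fc))) {
        fc[seq_along(effect_log2fc)] <- effect_log2fc
      } else {
        keep <- intersect(names(effect_log2fc), names(fc))
        fc[keep] <- effect_log2fc[keep]
      }
    }
    peps_unmod <- vapply(seq_len(n_unmod_peptides), function(i) random_peptide(sample(8:16, 1)), "")
    peps_site <- vapply(seq_len(n_sites), function(i) random_peptide(sample(8:16, 1)), "")

    samples <- expand.grid(replicate = seq_len(n_reps), condition = conditions,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
    scale_l2 <- setNames(rnorm(nrow(samples), sd = scale_sd_log2),
                         paste(samples$condition, samples$replicate, sep = "."))

    base_unmod <- rnorm(n_unmod_peptides, 20, 1.5)
    base_site <- rnorm(n_sites, 18, 1.5)

    rows <- vector("list", nrow(samples))
    for (k in seq_len(nrow(samples))) {
      cond <- samples$condition[k]; rep_i <- samples$replicate[k]
      eff <- if (cond == conditions[1L]) 0 else fc
      l2 <- c(base_unmod + scale_l2[k] + rnorm(n_unmod_peptides, sd = rep_sd_log2),
              base_site + eff + scale_l2[k] + rnorm(n_sites, sd = rep_sd_log2))
      rows[[k]] <- data.frame(
        peptide_seq = c(peps_unmod, peps_site),
        site_residue = c(rep(NA_integer_, n_unmod_peptides), sites),
        mod_type = c(rep("none", n_unmod_peptides), rep(mod_type, n_sites)),
        condition = cond, replicate = rep_i, intensity = 2^l2,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    if (missing_rate > 0) {
      l2 <- log2(tab$intensity)
      w <- plogis(-(l2 - median(l2)))                # heavier in the low tail
      p <- pmin(missing_rate * w / mean(w), 0.95)
      tab$intensity[runif(nrow(tab)) < p] <- NA_real_
    }
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(true_site_log2fc = fc, sample_scale_log2 = scale_l2,
                      conditions = conditions))
  })
}

#' Two-state van't Hoff melting-curve model
#'
#' Computes the observed signal of a two-state unfolding transition with
#' linear native and unfolded baselines:
#' `signal(T) = [(yN + mN*T) + (yU + mU*T) * K(T)] / (1 + K(T))` with
#' `K(T) = exp(-(dH/R) * (1/T_K - 1/Tm_K))`, temperatures in kelvin inside
#' the exponential and in degrees Celsius for the baselines.
#'
#' @param temp_c Temperatures in degrees Celsius.
#' @param tm_c Midpoint temperature (degrees Celsius).
#' @param dh_vh Van't Hoff enthalpy (kJ/mol), positive.
#' @param baselines Numeric vector `(yN, mN, yU, mU)`: intercepts and slopes
#'   of the native and unfolded baselines in signal units (vs. deg C).
#' @return Numeric signal values.
#' @export
two_state_signal <- function(temp_c, tm_c, dh_vh, baselines) {
  R <- 8.314                                         # J / mol / K
  tK <- temp_c + 273.15
  tmK <- tm_c + 273.15
  K <- exp(-(dh_vh * 1000 / R) * (1 / tK - 1 / tmK))
  yN <- baselines[1] + baselines[2] * temp_c
  yU <- baselines[3] + baselines[4] * temp_c
  (yN + yU * K) / (1 + K)
}

#' Generate a synthetic thermal-unfolding curve
#'
#' Two-state van't Hoff transition with linear baselines sampled on a linear
#' temperature ramp (default 20--85 deg C in 1 deg C steps, i.e. a 1 deg
#' C/min ramp read once per minute), plus i.i.d. Gaussian noise in raw signal
#' units (the instrument records raw ellipticity, not fraction unfolded).
#'
#' @inheritParams two_state_signal
#' @param noise_sd Gaussian noise SD in signal units.
#' @param t_range Temperature span `(low, high)` in deg C.
#' @param step Temperature step in deg C (> 0).
#' @param seed Integer seed.
#' @return A `melting_curve` data.frame with columns `temp_c`, `signal` and
#'   attribute `truth` carrying the generating parameters.
#' @examples
#' mc <- gen_melting_curve(55, 300, noise_sd = 0)
#' range(mc$signal)
#' @export
gen_melting_curve <- function(tm_c, dh_vh,
                              baselines = c(yN = -20, mN = 0.02, yU = -5, mU = 0.01),
                              noise_sd = 0.3, t_range = c(20, 85), step = 1,
                              seed = 1L) {
  assert_that(step > 0, "step must be positive")
  assert_that(dh_vh > 0, "dh_vh must be positive")
  assert_that(tm_c >= t_range[1] && tm_c <= t_range[2], "tm_c must lie within t_range")
  with_seed(seed, {
    temp_c <- seq(t_range[1], t_range[2], by = step)
    sig <- two_state_signal(temp_c, tm_c, dh_vh, baselines)
    if (noise_sd > 0) sig <- sig + rnorm(length(sig), sd = noise_sd)
    structure(data.frame(temp_c = temp_c, signal = sig),
              truth = list(tm_c = tm_c, dh_vh = dh_vh, baselines = baselines),
              class = c("melting_curve", "data.frame"))
  })
}

#' Generate a synthetic dye-reduction activity trace
#'
#' Linear initial-rate decay of absorbance at 600 nm as DCPIP is reduced:
#' `A600(t) = A0 - eps * l * (rate / volume) / 1000 * t_min + noise`, with
#' `A0 = eps * l * [DCPIP]_mM`. Units: rate in nmol/min, volume in mL, eps in
#' mM^-1 cm^-1, so `rate/volume` is in uM/min.
#'
#' @param rate_nmol_min True DCPIP reduction rate (nmol/min).
#' @param dcpip0_uM Initial DCPIP concentration (uM), default 30.
#' @param eps_mM_cm DCPIP extinction coefficient at 600 nm (mM^-1 cm^-1).
#' @param path_cm Optical path length (cm).
#' @param volume_ml Assay volume (mL).
#' @param duration_s Trace duration (s).
#' @param dt_s Sampling interval (s).
#' @param noise_sd Absorbance noise SD (AU).
#' @param seed Integer seed.
#' @param protein_mg Optional protein amount for specific activity per mg.
#' @return An `activity_trace` data.frame (`time_s`, `a600`) with assay
#'   constants stored as attributes.
#' @export
gen_activity_trace <- function(rate_nmol_min, dcpip0_uM = 30, eps_mM_cm = 21,
                               path_cm = 1, volume_ml = 1, duration_s = 300,
                               dt_s = 1, noise_sd = 0.002, seed = 1L,
                               protein_mg = NULL) {
  assert_that(rate_nmol_min >= 0, "rate must be non-negative")
  nmol_available <- dcpip0_uM * volume_ml            # uM * mL = nmol
  assert_that(rate_nmol_min * duration_s / 60 < nmol_available,
              "DCPIP would be exhausted within the trace; shorten duration or lower rate")
  with_seed(seed, {
    time_s <- seq(0, duration_s, by = dt_s)
    a0 <- eps_mM_cm * path_cm * dcpip0_uM / 1000
    slope_min <- eps_mM_cm * path_cm * (rate_nmol_min / volume_ml) / 1000
    a600 <- a0 - slope_min * time_s / 60
    if (noise_sd > 0) a600 <- a600 + rnorm(length(a600), sd = noise_sd)
    structure(data.frame(time_s = time_s, a600 = a600),
              eps_mM_cm = eps_mM_cm, path_cm = path_cm, volume_ml = volume_ml,
              protein_mg = protein_mg,
              truth = list(rate_nmol_min = rate_nmol_min),
              class = c("activity_trace", "data.frame"))
  })
}

#' Generate a synthetic metabolite peak-area table
#'
#' Log-normal peak areas with group mean shifts on the log2 scale: the first
#' group is the reference; later groups receive the per-metabolite effects.
#'
#' @param n_metabolites Number of metabolites.
#' @param groups Character vector of group labels (first = reference).
#' @param n_reps Replicates per group (>= 2).
#' @param effects Named numeric vector, metabolite id -> true log2 effect, or
#'   an unnamed vector applied to the first metabolites. Others get 0.
#' @param seed Integer seed.
#' @param rep_sd_log2 Replicate noise SD on the log2 scale (default 0.2,
#'   i.e. about a 15% CV, the typical technical-replicate precision of LC-MS
#'   peak areas from cultured-cell extracts).
#' @return List with `table` (long data.frame: metabolite, group, replicate,
#'   area) and `truth` (`true_group_effects`).
#' @export
gen_metabolite_table <- function(n_metabolites, groups = c("crWT", "crKO"),
                                 n_reps = 3, effects = numeric(), seed = 1L,
                                 rep_sd_log2 = 0.2) {
  assert_that(length(groups) >= 2, "need at least two groups")
  assert_that(is_count(n_reps) && n_reps >= 2, "n_reps must be >= 2")
  with_seed(seed, {
    ids <- sprintf("MET%04d", seq_len(n_metabolites))
    eff <- setNames(rep(0, n_metabolites), ids)
    if (length(effects)) {
      if (is.null(names(effects))) eff[seq_along(effects)] <- effects
      else eff[intersect(names(effects), ids)] <- effects[intersect(names(effects), ids)]
    }
    base <- rnorm(n_metabolites, 18, 2)
    rows <- list()
    for (g in groups) for (r in seq_len(n_reps)) {
      shift <- if (g == groups[1L]) 0 else eff
      rows[[paste(g, r)]] <- data.frame(
        metabolite = ids, group = g, replicate = r,
        area = 2^(base + shift + rnorm(n_metabolites, sd = rep_sd_log2)),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab, truth = list(true_group_effects = eff, groups = groups))
  })
}
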