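# Deterministic arithmetic of enzymatic, radiometric, and qPCR readouts.

#' Specific activity from a dye-reduction absorbance trace
#'
#' Initial-rate slope of A600 versus time by ordinary least squares over the
#' fit window, converted with Beer--Lambert:
#' `rate (nmol/min) = |slope per min| / (eps * l) * volume_mL * 1000`.
#' One unit of activity is one nmol of DCPIP reduced per minute; if
#' `protein_mg` is available the rate is also reported per mg.
#'
#' @param trace An `activity_trace` data.frame (`time_s`, `a600`) with
#'   attributes `eps_mM_cm`, `path_cm`, `volume_ml` and optionally
#'   `protein_mg` (as produced by [gen_activity_trace()] or
#'   [read_activity_trace()]). These can be overridden via arguments.
#' @param fit_window Time range `c(t0, t1)` in seconds; default the first 20%
#'   of the trace (the initial-rate region).
#' @param eps_mM_cm,path_cm,volume_ml,protein_mg Optional overrides of the
#'   trace attributes. DCPIP eps600 defaults to 21 mM^-1 cm^-1 (literature
#'   value) when the trace carries none.
#' @return List: `rate_nmol_min`, `rate_nmol_min_mg` (NA without protein),
#'   `slope_au_min`, `fit_window`.
#' @export
specific_activity <- function(trace, fit_window = NULL, eps_mM_cm = NULL,
                              path_cm = NULL, volume_ml = NULL, protein_mg = NULL) {
  assert_that(all(c("time_s", "a600") %in% names(trace)), "trace needs time_s and a600 columns")
  eps <- eps_mM_cm %||% attr(trace, "eps_mM_cm") %||% 21
  l <- path_cm %||% attr(trace, "path_cm") %||% 1
  vol <- volume_ml %||% attr(trace, "volume_ml") %||% 1
  prot <- protein_mg %||% attr(trace, "protein_mg")
  assert_that(eps > 0 && l > 0 && vol > 0, "eps, path and volume must be positive")
  if (is.null(fit_window)) {
    t0 <- min(trace$time_s)
    fit_window <- c(t0, t0 + 0.2 * (max(trace$time_s) - t0))
  }
  sel <- trace$time_s >= fit_window[1] & trace$time_s <= fit_window[2]
  assert_that(sum(sel) >= 3, "fit window must contain at least 3 points")
  fit <- stats::lm(a600 ~ time_s, data = trace[sel, ])
  slope_s <- unname(stats::coef(fit)[2])
  slope_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  if (slope_s > 0 && abs(slope_s) > 2 * slope_se)
    stop(errorCondition("A600 is increasing: DCPIP is not being reduced",
                        class = c("acylomics_assay_direction", "error")))
  slope_min <- abs(slope_s) * 60
  rate <- slope_min / (eps * l) * vol * 1000        # mM/min * mL -> nmol/min
  list(rate_nmol_min = rate,
       rate_nmol_min_mg = if (is.null(prot)) NA_real_ else rate / prot,
       slope_au_min = -slope_min, fit_window = fit_window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Activity as a percentage of an unmodified control
#'
#' @param value Measured activity.
#' @param control Control activity (> 0).
#' @return `100 * value / control`.
#' @export
percent_of_control <- function(value, control) {
  assert_that(all(control > 0), "control activity must be positive")
  100 * value / control
}

#' Released radiolabel as a percentage of total label added
#'
#' Background-subtracted disintegrations per minute over the total label in
#' the incubation, clamped at zero (a sample below background is reported as
#' 0% with a message).
#'
#' @param dpm_sample Sample counts (DPM).
#' @param dpm_background Background counts (DPM).
#' @param dpm_total_added Total label added (DPM, > 0).
#' @return Percentage of label released.
#' @export
oxidation_percent <- function(dpm_sample, dpm_background, dpm_total_added) {
  assert_that(all(dpm_total_added > 0), "dpm_total_added must be positive")
  net <- dpm_sample - dpm_background
  if (any(net < 0)) {
    message("sample counts below background; clamping released fraction at 0")
    net <- pmax(net, 0)
  }
  100 * net / dpm_total_added
}

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-ddCt` with `ddCt = (Ct_target - Ct_ref)_sample -
#' (Ct_target - Ct_ref)_calibrator`, using an endogenous control gene
#' (e.g. ATP synthase subunit B) as the reference.
#'
#' @param ct data.frame with columns `sample`, `ct_target`, `ct_ref`
#'   (positive Ct values).
#' @param calibrator Sample id serving as the calibrator (fold change 1).
#' @return data.frame: sample, dct, ddct, fold.
#' @export
relative_expression <- function(ct, calibrator) {
  assert_that(all(c("sample", "ct_target", "ct_ref") %in% names(ct)),
              "ct needs sample, ct_target and ct_ref columns")
  assert_that(all(ct$ct_target > 0) && all(ct$ct_ref > 0), "Ct values must be positive")
  if (!calibrator %in% ct$sample)
    stop(errorCondition(sprintf("calibrator sample '%s' not found", calibrator),
                        class = c("acylomics_lookup_error", "error")))
  dct <- ct$ct_target - ct$ct_ref
  dct_cal <- dct[match(calibrator, ct$sample)]
  ddct <- dct - dct_cal
  data.frame(sample = ct$sample, dct = dct, ddct = ddct, fold = 2^(-ddct),
             stringsAsFactors = FALSE)
}
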