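# Two-state thermal-unfolding fits: nonlinear least squares on the van't
# Hoff model with linear native/unfolded baselines, and Tm comparison.

check_melting_curve <- function(curve) {
  assert_that(all(c("temp_c", "signal") %in% names(curve)),
              "melting curve needs temp_c and signal columns")
  assert_that(all(diff(curve$temp_c) > 0), "temperatures must be strictly increasing")
  assert_that(nrow(curve) >= 15, "need >= 15 points spanning the transition")
  assert_that(all(is.finite(curve$signal)), "signal must be finite")
  invisible(curve)
}

# Heuristic starting values: Tm at the steepest (smoothed) signal change,
# baselines from linear fits to the first/last 20% of points, dH = 300 kJ/mol.
two_state_init <- function(curve) {
  n <- nrow(curve)
  k <- max(5L, ceiling(0.2 * n))
  head_fit <- stats::lm(signal ~ temp_c, data = curve[seq_len(k), ])
  tail_fit <- stats::lm(signal ~ temp_c, data = curve[seq(n - k + 1L, n), ])
  d <- diff(stats::filter(curve$signal, rep(1 / 5, 5), sides = 2))
  d[is.na(d)] <- 0
  tm0 <- curve$temp_c[which.max(abs(d))]
  tm0 <- min(max(tm0, curve$temp_c[2]), curve$temp_c[n - 1L])
  list(tm_c = tm0, dh_vh = 300,
       yN = unname(stats::coef(head_fit)[1]), mN = unname(stats::coef(head_fit)[2]),
       yU = unname(stats::coef(tail_fit)[1]), mU = unname(stats::coef(tail_fit)[2]))
}

#' Fit a two-state van't Hoff unfolding model to a melting curve
#'
#' Nonlinear least squares of the raw signal against
#' [two_state_signal()] (six parameters: Tm, van't Hoff dH, and two linear
#' baselines). Fitting uses `nls` (port algorithm, Tm bounded inside the
#' temperature range) with a BFGS fallback; a failed fit is reported with
#' `converged = FALSE`, never an exception. Fitting raw signal (rather than
#' normalized fraction unfolded) keeps the noise model homoscedastic in
#' instrument units.
#'
#' @param curve A melting curve data.frame (`temp_c`, `signal`), e.g. from
#'   [gen_melting_curve()] or [read_melting_curve()].
#' @param init Optional named list overriding the heuristic starting values
#'   (`tm_c`, `dh_vh`, `yN`, `mN`, `yU`, `mU`).
#' @return A `two_state_fit` list: `tm_c`, `dh_vh` (kJ/mol), `baselines`
#'   (yN, mN, yU, mU), `rss`, `converged`, `fitted`, `message`.
#' @export
fit_two_state <- function(curve, init = NULL) {
  check_melting_curve(curve)
  start <- two_state_init(curve)
  if (!is.null(init)) start[names(init)] <- init
  t_lo <- min(curve$temp_c); t_hi <- max(curve$temp_c)
  lower <- c(tm_c = t_lo + 0.5, dh_vh = 1, yN = -Inf, mN = -Inf, yU = -Inf, mU = -Inf)
  upper <- c(tm_c = t_hi - 0.5, dh_vh = 5000, yN = Inf, mN = Inf, yU = Inf, mU = Inf)
  model <- function(p) two_state_signal(curve$temp_c, p[["tm_c"]], p[["dh_vh"]],
                                        c(p[["yN"]], p[["mN"]], p[["yU"]], p[["mU"]]))
  rss_fn <- function(p) sum((curve$signal - model(p))^2)

  fit <- tryCatch(
    stats::nls(signal ~ two_state_signal(temp_c, tm_c, dh_vh, c(yN, mN, yU, mU)),
               data = curve, start = start, lower = lower, upper = upper,
               algorithm = "port", control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "nls")) {
    p <- stats::coef(fit)
  } else {
    # fall back to box-respecting quasi-Newton on the same objective
    opt <- tryCatch(
      stats::optim(unlist(start), rss_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 500)),
      error = function(e) e)
    if (inherits(opt, "error") || opt$convergence != 0) {
      msg <- if (inherits(opt, "error")) conditionMessage(opt) else
        paste("optim convergence code", opt$convergence)
      return(structure(list(tm_c = NA_real_, dh_vh = NA_real_,
                            baselines = c(yN = NA, mN = NA, yU = NA, mU = NA),
                            rss = NA_real_, converged = FALSE, fitted = NULL,
                            message = msg),
                       class = "two_state_fit"))
    }
    p <- opt$par
  }
  # a transition pinned to the range boundary, or one a straight line
  # explains just as well, is not an identified two-state fit
  lin_rss <- sum(stats::resid(stats::lm(signal ~ temp_c, data = curve))^2)
  identified <- p[["tm_c"]] > t_lo + 0.6 && p[["tm_c"]] < t_hi - 0.6 &&
    lin_rss > 0 && rss_fn(p) < 0.5 * lin_rss
  structure(list(tm_c = unname(p[["tm_c"]]), dh_vh = unname(p[["dh_vh"]]),
                 baselines = c(yN = unname(p[["yN"]]), mN = unname(p[["mN"]]),
                               yU = unname(p[["yU"]]), mU = unname(p[["mU"]])),
                 rss = rss_fn(p), converged = identified, fitted = model(p),
                 message = if (identified) "converged" else "degenerate fit (flat or boundary transition)"),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("two-state fit: Tm = %.2f degC, dHvH = %.0f kJ/mol, rss = %.4g\n",
                x$tm_c, x$dh_vh, x$rss))
  } else {
    cat("two-state fit: NOT converged -", x$message, "\n")
  }
  invisible(x)
}

#' Melting-temperature difference between two fits
#'
#' Signed difference `Tm(a) - Tm(b)`; call with the modified protein first
#' and the unmodified control second to report destabilization as a negative
#' delta (e.g. -3 deg C).
#'
#' @param fit_a,fit_b Converged [fit_two_state()] results.
#' @return Difference in deg C.
#' @export
delta_tm <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "two_state_fit"), inherits(fit_b, "two_state_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop(errorCondition("delta_tm requires two converged fits",
                        class = c("acylomics_unconverged_fit", "error")))
  fit_a$tm_c - fit_b$tm_c
}

#' Fraction unfolded implied by a two-state fit
#'
#' Output transform only (the fit itself is done on raw signal): baseline
#' subtraction and amplitude normalization,
#' `fU(T) = (signal - yN(T)) / (yU(T) - yN(T))`.
#'
#' @param curve The fitted melting curve.
#' @param fit A converged [fit_two_state()] result.
#' @return Numeric vector of fraction-unfolded values.
#' @export
fraction_unfolded <- function(curve, fit) {
  check_melting_curve(curve)
  stopifnot(inherits(fit, "two_state_fit"), isTRUE(fit$converged))
  b <- fit$baselines
  yN <- b[["yN"]] + b[["mN"]] * curve$temp_c
  yU <- b[["yU"]] + b[["mU"]] * curve$temp_c
  (curve$signal - yN) / (yU - yN)
}
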