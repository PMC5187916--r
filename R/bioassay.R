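# Fluorescence enzyme-assay analysis: two-point kinetic slopes in the
# linear range of the progress curve, relative inhibition versus the
# enzyme control, four-parameter logistic (4PL) dose-response fitting for
# IC50, and pIC50 conversion.

#' Four-parameter logistic dose-response model
#'
#' `y = bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(c)) * hill))`
#' in percent inhibition; at `c = ic50` the response is midway between the
#' asymptotes, and `hill > 0` means inhibition grows with concentration.
#'
#' @param conc Concentrations (molar, > 0).
#' @param bottom,top Lower/upper asymptotes (percent).
#' @param hill Hill slope.
#' @param ic50 Half-maximal concentration (molar).
#' @return Percent inhibition at each concentration.
#' @export
four_pl <- function(conc, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(conc)) * hill))
}

#' Kinetic slope over a time window
#'
#' `(RFU(t2) - RFU(t1)) / (t2 - t1)`, with linear interpolation when the
#' window endpoints fall between sampled time points. The default window
#' (25 to 30 min) sits in the linear range of the progress curve.
#'
#' @param times Strictly increasing sampling times (minutes).
#' @param rfu Relative fluorescence units, same length as `times`.
#' @param t1,t2 Window endpoints (minutes), `t1 < t2`, both within the
#'   sampled span.
#' @return Slope in RFU/min.
#' @export
kinetic_slope <- function(times, rfu, t1 = 25, t2 = 30) {
  if (length(times) < 2L || length(times) != length(rfu))
    .tf_error("trace needs >= 2 matching time/RFU points",
              "targetfish_validation_error")
  if (any(diff(times) <= 0))
    .tf_error("times must be strictly increasing",
              "targetfish_validation_error")
  if (!(t1 < t2))
    .tf_error("slope window needs t1 < t2", "targetfish_range_error")
  if (t1 < min(times) || t2 > max(times))
    .tf_error(sprintf("slope window [%g, %g] outside trace span [%g, %g]",
                      t1, t2, min(times), max(times)),
              "targetfish_range_error")
  y <- stats::approx(times, rfu, xout = c(t1, t2))$y
  (y[2L] - y[1L]) / (t2 - t1)
}

#' Relative inhibition of the enzyme-control slope
#'
#' `(slope_ec - slope_s) * 100 / slope_ec`. May be negative (activation) or
#' exceed 100.
#'
#' @param slope_ec Enzyme-control slope (RFU/min, must be > 0).
#' @param slope_s Sample slope (RFU/min).
#' @return Percent inhibition.
#' @export
relative_inhibition <- function(slope_ec, slope_s) {
  if (!is.finite(slope_ec) || slope_ec <= 0)
    .tf_error("enzyme-control slope must be positive (no enzyme signal)",
              "targetfish_validation_error")
  (slope_ec - slope_s) * 100 / slope_ec
}

#' Default 4PL fitting constraints
#'
#' Box constraints stabilizing sparse dose-response curves: bottom within
#' \[-10, 30\]%, top within \[70, 110\]%, Hill slope within \[0.2, 5\];
#' log10(IC50) is allowed 2 decades beyond the tested concentration range.
#'
#' @param bottom,top,hill Two-element `c(lower, upper)` bounds.
#' @return A `fourpl_constraints` list.
#' @export
fourpl_constraints <- function(bottom = c(-10, 30), top = c(70, 110),
                               hill = c(0.2, 5)) {
  structure(list(bottom = bottom, top = top, hill = hill),
            class = "fourpl_constraints")
}

#' Fit a 4PL dose-response curve
#'
#' Bounded least-squares fit (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of [four_pl()] in log10(IC50) parameterization,
#' with multi-start initialization over five log-spaced IC50 guesses across
#' the tested concentration range; the lowest-RSS fit wins. The `converged`
#' flag is FALSE when the optimizer failed or the fitted IC50 ended up
#' pinned at the search bounds (degenerate data).
#'
#' @param conc Concentrations (molar, > 0), length >= 4, spanning at least
#'   2 log10 units.
#' @param inhibition Percent inhibition, same length (noise may push values
#'   slightly outside \[0, 100\]).
#' @param constraints A [fourpl_constraints()].
#' @return A `fourpl_fit`: list with `bottom`, `top`, `hill`, `ic50`
#'   (molar), `rss`, `converged`, and the underlying `fit` object (NULL if
#'   every start failed).
#' @export
fit_4pl <- function(conc, inhibition, constraints = fourpl_constraints()) {
  if (length(conc) < 4L || length(conc) != length(inhibition))
    .tf_error("4PL fit needs >= 4 matching concentration/inhibition points",
              "targetfish_validation_error")
  if (any(conc <= 0))
    .tf_error("concentrations must be positive",
              "targetfish_validation_error")
  lc <- log10(conc)
  if (diff(range(lc)) < 2)
    .tf_error("concentrations must span >= 2 log10 units",
              "targetfish_validation_error")
  dat <- data.frame(lc = lc, y = inhibition)
  lower <- c(constraints$bottom[1L], constraints$top[1L],
             constraints$hill[1L], min(lc) - 2)
  upper <- c(constraints$bottom[2L], constraints$top[2L],
             constraints$hill[2L], max(lc) + 2)
  starts <- seq(min(lc), max(lc), length.out = 5L)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((lic50 - lc) * hill)),
        data = dat,
        start = list(bottom = max(lower[1L], min(0, upper[1L])),
                     top = min(upper[2L], max(100, lower[2L])),
                     hill = 1, lic50 = s),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          hill = NA_real_, ic50 = NA_real_, rss = NA_real_,
                          converged = FALSE, fit = NULL),
                     class = "fourpl_fit"))
  }
  cf <- stats::coef(best$fit)
  # a parameter pinned at a constraint bound marks an unsupported fit
  # (flat or saturated data): report it as not converged
  at_bound <- any(cf <= lower + 1e-6) || any(cf >= upper - 1e-6)
  structure(list(bottom = cf[["bottom"]], top = cf[["top"]],
                 hill = cf[["hill"]], ic50 = 10^cf[["lic50"]],
                 rss = best$rss,
                 converged = isTRUE(best$fit$convInfo$isConv) && !at_bound,
                 fit = best$fit),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<4PL fit: IC50 %.3g M (pIC50 %.3f), hill %.2f, bottom %.1f, top %.1f, %s>\n",
    x$ic50, if (is.finite(x$ic50) && x$ic50 > 0) -log10(x$ic50) else NA,
    x$hill, x$bottom, x$top,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Convert a molar IC50 to pIC50
#'
#' `-log10(ic50)`; e.g. 8.79e-6 M gives 5.056.
#'
#' @param ic50 Molar IC50 (> 0), vectorized.
#' @return pIC50 value(s).
#' @export
pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    .tf_error("IC50 must be positive and finite",
              "targetfish_validation_error")
  -log10(ic50)
}

#' Analyze an assay plate: slopes, inhibition, and the 4PL fit
#'
#' For every well the kinetic slope over `[t1, t2]` is computed; sample-well
#' slopes are converted to relative inhibition against the mean
#' enzyme-control slope, inhibition is averaged per concentration (with the
#' well count recorded), and a 4PL curve is fitted to the per-well data.
#'
#' @param plate data.frame as produced by [simulate_plate()] /
#'   [read_plate_csv()]: columns `well_id`, `role` (`EC`, `S`, `blank`),
#'   `concentration_M`, then `t<min>` RFU columns.
#' @param t1,t2 Slope window (minutes); defaults 25 and 30.
#' @param subtract_blank If TRUE, the mean blank-well slope is subtracted
#'   from every slope before computing inhibition (off by default).
#' @param constraints Passed to [fit_4pl()].
#' @return list with `well_slopes` (per-well slopes and inhibition),
#'   `dose_response` (per-concentration mean inhibition and n), `fit`
#'   (a `fourpl_fit`), `ic50_M`, `ic50_uM`, `pic50`.
#' @export
analyze_plate <- function(plate, t1 = 25, t2 = 30, subtract_blank = FALSE,
                          constraints = fourpl_constraints()) {
  tcols <- grep("^t[0-9.]+$", names(plate), value = TRUE)
  if (length(tcols) < 2L)
    .tf_error("plate needs >= 2 time columns t<min>",
              "targetfish_format_error")
  times <- as.numeric(sub("^t", "", tcols))
  o <- order(times)
  times <- times[o]; tcols <- tcols[o]

  slopes <- vapply(seq_len(nrow(plate)), function(i)
    kinetic_slope(times, as.numeric(plate[i, tcols]), t1, t2), numeric(1))
  if (subtract_blank && any(plate$role == "blank"))
    slopes <- slopes - mean(slopes[plate$role == "blank"])

  ec <- plate$role == "EC"
  if (!any(ec))
    .tf_error("plate has no enzyme-control (EC) wells",
              "targetfish_validation_error")
  slope_ec <- mean(slopes[ec])

  ws <- data.frame(well_id = plate$well_id, role = plate$role,
                   concentration_M = plate$concentration_M,
                   slope = slopes, inhibition = NA_real_,
                   stringsAsFactors = FALSE)
  smp <- ws$role == "S"
  ws$inhibition[smp] <- vapply(slopes[smp],
                               function(s) relative_inhibition(slope_ec, s),
                               numeric(1))

  sw <- ws[smp, , drop = FALSE]
  agg <- stats::aggregate(inhibition ~ concentration_M, data = sw, FUN = mean)
  agg$n <- as.integer(table(sw$concentration_M)[
    as.character(agg$concentration_M)])
  agg <- agg[order(agg$concentration_M), , drop = FALSE]
  rownames(agg) <- NULL

  fit <- fit_4pl(sw$concentration_M, sw$inhibition, constraints)
  list(well_slopes = ws, dose_response = agg, fit = fit,
       ic50_M = fit$ic50, ic50_uM = fit$ic50 * 1e6,
       pic50 = if (is.finite(fit$ic50) && fit$ic50 > 0)
         pic50(fit$ic50) else NA_real_)
}
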