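#' Four-parameter logistic curve
#'
#' `y(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill)`. With positive
#' `hill`, `top` is the low-concentration asymptote (viability of untreated
#' cells) and `bottom` the high-concentration asymptote.
#'
#' @param top,bottom asymptotes (percent viability).
#' @param ec50 inflection concentration (nM, > 0).
#' @param hill slope.
#' @param rss residual sum of squares of a fit (0 for a ground-truth curve).
#' @param converged logical fit flag.
#' @param ec50_identifiable logical; `FALSE` when the data are flat and the
#'   inflection is meaningless.
#' @return An object of class `Curve4PL`.
#' @export
curve_4pl <- function(top, bottom, ec50, hill, rss = 0, converged = TRUE,
                      ec50_identifiable = TRUE) {
  if (ec50 <= 0) stop("ec50 must be positive")
  structure(list(top = top, bottom = bottom, ec50 = ec50, hill = hill,
                 rss = rss, converged = converged,
                 ec50_identifiable = ec50_identifiable),
            class = "Curve4PL")
}

#' @export
print.Curve4PL <- function(x, ...) {
  cat(sprintf("Curve4PL: top=%.3g bottom=%.3g ec50=%.4g hill=%.3g (rss=%.3g%s)\n",
              x$top, x$bottom, x$ec50, x$hill, x$rss,
              if (!x$converged) ", not converged" else ""))
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' @param curve a [curve_4pl()] object.
#' @param concentrations positive concentrations.
#' @return Predicted responses.
#' @export
predict_4pl <- function(curve, concentrations) {
  curve$bottom + (curve$top - curve$bottom) /
    (1 + (concentrations / curve$ec50)^curve$hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL on a log10-concentration scale via
#' Levenberg-Marquardt, multi-started over a grid of ec50 decades spanning
#' the tested range and hill slopes in both directions to avoid local
#' minima. The result is canonicalized so `top > bottom` (swapping flips the
#' hill sign, leaving the curve unchanged).
#'
#' @param concentrations positive concentrations (replicated values allowed).
#' @param responses responses aligned with `concentrations`.
#' @return A `Curve4PL` with fit diagnostics. Flat data return
#'   `converged = FALSE` with `top ~ bottom` and the ec50 flagged
#'   unidentifiable.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(!is.finite(responses))) stop("responses must be finite")
  if (length(unique(concentrations)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  rng <- range(responses)
  mid <- mean(rng)
  if (diff(rng) < 1e-8 * max(1, abs(mid))) {
    return(curve_4pl(mid, mid, stats::median(concentrations), 1,
                     rss = sum((responses - mid)^2), converged = FALSE,
                     ec50_identifiable = FALSE))
  }
  resid_fn <- function(par) {
    responses - (par[2] + (par[1] - par[2]) /
                   (1 + 10^((log10(concentrations) - par[3]) * par[4])))
  }
  lc <- log10(range(concentrations))
  starts <- expand.grid(le = seq(floor(lc[1]), ceiling(lc[2])),
                        hill = c(0.5, 1, 2, -0.5, -1, -2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(max(responses), min(responses), starts$le[i], starts$hill[i]),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
  }
  if (is.null(best)) stop("4PL fit failed for all starts")
  par <- best$par
  top <- par[1]; bottom <- par[2]; ec50 <- 10^par[3]; hill <- par[4]
  if (top < bottom) {  # canonical orientation: top > bottom
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  flat <- abs(top - bottom) < 1e-6 * max(1, abs(top))
  curve_4pl(top, bottom, ec50, hill, rss = best$deviance,
            converged = !flat && best$info %in% 1:4,
            ec50_identifiable = !flat)
}

#' Absolute IC50 of a fitted curve
#'
#' Concentration at which fitted viability equals 50% of the untreated
#' control (y = 50 on the 0-100 scale) — distinct from the curve's
#' inflection ec50 unless `top = 100`, `bottom = 0`. Closed form:
#' `ec50 * ((top - 50) / (50 - bottom))^(1/hill)`.
#'
#' @param curve a converged `Curve4PL`.
#' @param target response level defining "absolute" (default 50).
#' @return Concentration, or `NA` when the curve never crosses the target
#'   (`bottom >= target` or `top <= target`).
#' @export
absolute_ic50 <- function(curve, target = 50) {
  if (!curve$converged) stop("curve did not converge")
  if (curve$bottom >= target || curve$top <= target) return(NA_real_)
  curve$ec50 * ((curve$top - target) / (target - curve$bottom))^(1 / curve$hill)
}

#' GI50 from growth data with a day-0 baseline
#'
#' Growth inhibition follows the NCI-60 convention:
#' `GI(c) = 100 (T(c) - T0) / (C - T0)` when `T(c) >= T0` (slowed growth),
#' `100 (T(c) - T0) / T0` otherwise (net cell kill). A 4PL is fitted to
#' GI versus concentration and the GI50 read off where the fitted curve
#' crosses 50.
#'
#' @param concentrations positive concentrations.
#' @param treated cell quantity at each concentration after treatment
#'   (vector aligned with `concentrations`).
#' @param control untreated cell quantity at assay end (scalar).
#' @param t0 cell quantity at day 0 (scalar, > 0).
#' @return List with `gi50` (concentration, `NA` if the fitted curve never
#'   crosses 50), `gi` (the per-concentration GI values) and `curve` (the
#'   fitted `Curve4PL`).
#' @export
gi50 <- function(concentrations, treated, control, t0) {
  if (t0 <= 0) stop("t0 must be positive")
  if (control <= t0) stop("control must exceed t0 (no net growth window)")
  gi <- ifelse(treated >= t0,
               100 * (treated - t0) / (control - t0),
               100 * (treated - t0) / t0)
  curve <- fit_4pl(concentrations, gi)
  list(gi50 = if (curve$converged) absolute_ic50(curve, 50) else NA_real_,
       gi = gi, curve = curve)
}

#' Collateral-sensitivity log2 fold-change matrix
#'
#' For each drug and cell line, `log2(IC50_line / IC50_reference)`: negative
#' values mean the line is *more* sensitive than its reference (collateral
#' sensitivity), positive values mean resistance. Reference entries are 0 by
#' construction; undefined IC50s propagate as `NA`.
#'
#' @param ic50 numeric matrix drug x cell line of absolute IC50s (`NA` where
#'   undefined).
#' @param reference named character vector mapping each cell line to its
#'   reference line (e.g. the parental or empty-vector control).
#' @return Matrix drug x cell line of log2 fold-changes.
#' @export
sensitivity_matrix <- function(ic50, reference) {
  ic50 <- as.matrix(ic50)
  if (is.null(colnames(ic50)) || is.null(rownames(ic50))) {
    stop("ic50 matrix needs drug rownames and cell-line colnames")
  }
  missing <- setdiff(colnames(ic50), names(reference))
  if (length(missing)) stop("missing reference for cell line: ", missing[1])
  bad_ref <- setdiff(unname(reference[colnames(ic50)]), colnames(ic50))
  if (length(bad_ref)) stop("reference line not in matrix: ", bad_ref[1])
  out <- ic50
  for (line in colnames(ic50)) {
    out[, line] <- log2(ic50[, line] / ic50[, reference[[line]]])
  }
  out
}
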