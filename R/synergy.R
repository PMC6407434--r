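#' Fit the median-effect model to a dose-response curve
#'
#' The median-effect model \eqn{fa/fu = (D/Dm)^m} (with \eqn{fu = 1 - fa})
#' linearizes to \eqn{\log_{10}(fa/(1-fa)) = m\,\log_{10} D - m\,\log_{10} Dm},
#' so the fit is an ordinary least-squares line on that scale: `m` is the
#' slope, `Dm = 10^(-intercept/m)` the median-effect dose, and `r` the
#' linear correlation of the plot. Points with fa outside (0, 1) carry no
#' information on this scale and are excluded (fa is clipped to
#' `[1e-6, 1 - 1e-6]` first, the standard treatment of exact 0/1 readouts);
#' replicate measurements at the same dose are averaged before fitting.
#'
#' @param dose vector of positive doses.
#' @param fa fraction affected at each dose, in [0, 1].
#' @param drug_id label carried through to reports.
#' @param clip_fa clip exact 0/1 readouts into (0,1) before filtering
#'   (default TRUE); with `FALSE` such points are dropped.
#' @return Object of class `median_effect_fit`: list with `drug_id`, `dm`,
#'   `m`, `r`, `n_points`, `data` (dose/fa used), `lm` (the underlying fit).
#' @export
fit_median_effect <- function(dose, fa, drug_id = "drug", clip_fa = TRUE) {
  if (any(dose <= 0)) stop("doses must be positive")
  if (length(dose) != length(fa)) stop("dose and fa lengths differ")
  if (clip_fa) fa <- pmin(pmax(fa, 1e-6), 1 - 1e-6)
  keep <- fa > 0 & fa < 1
  dose <- dose[keep]; fa <- fa[keep]
  if (length(unique(dose)) < length(dose)) {   # average replicates per dose
    fa <- as.numeric(tapply(fa, dose, mean))
    dose <- sort(unique(dose))
  }
  if (length(dose) < 2L)
    stop("median-effect fit needs at least 2 points with fa in (0, 1)")
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m == 0)
    stop("degenerate median-effect fit: zero slope (dm undefined)")
  dm <- 10^(-unname(stats::coef(fit)[1L]) / m)
  r <- if (length(dose) == 2L) 1 else stats::cor(x, y)
  structure(list(drug_id = drug_id, dm = dm, m = m, r = r,
                 n_points = length(dose),
                 data = data.frame(dose = dose, fa = fa), lm = fit),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit:", x$drug_id, "\n")
  cat(sprintf("  Dm = %.6g   m = %.4f   r = %.4f   (n = %d points)\n",
              x$dm, x$m, x$r, x$n_points))
  invisible(x)
}

#' @export
#' @method coef median_effect_fit
coef.median_effect_fit <- function(object, ...) {
  c(dm = object$dm, m = object$m)
}

#' Predicted fraction affected at given doses
#' @param object a `median_effect_fit`.
#' @param newdose vector of positive doses (default: the fitted doses).
#' @param ... unused.
#' @export
#' @method predict median_effect_fit
predict.median_effect_fit <- function(object, newdose = object$data$dose, ...) {
  if (any(newdose <= 0)) stop("doses must be positive")
  (newdose / object$dm)^object$m / (1 + (newdose / object$dm)^object$m)
}

#' @export
#' @method plot median_effect_fit
plot.median_effect_fit <- function(x, ...) {
  graphics::plot(log10(x$data$dose), log10(x$data$fa / (1 - x$data$fa)),
                 xlab = "log10 dose", ylab = "log10(fa / (1 - fa))",
                 main = paste("Median-effect plot:", x$drug_id), ...)
  graphics::abline(x$lm)
  invisible(x)
}

#' @export
#' @method residuals median_effect_fit
residuals.median_effect_fit <- function(object, ...) stats::residuals(object$lm)

#' Dose required for a given fraction affected
#'
#' Inverts the median-effect equation:
#' \eqn{D_x = Dm\,(fa/(1-fa))^{1/m}}.
#'
#' @param fit a `median_effect_fit`.
#' @param fa target fraction affected, strictly in (0, 1).
#' @return dose in the units of the fitted doses.
#' @export
dose_for_fa <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly in (0, 1)")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

ci_bands <- data.frame(
  upper = c(0.1, 0.3, 0.7, 0.85, 0.9, 1.1, 1.2, 1.45, Inf),
  classification = c("strong synergism", "strong synergism", "synergism",
                     "moderate synergism", "slight synergism", "additive",
                     "slight antagonism", "moderate antagonism", "antagonism"),
  stringsAsFactors = FALSE)

#' Verbal synergy classification of a combination index
#'
#' Bands: below 0.3 strong synergism; 0.3-0.7 synergism; 0.7-0.85 moderate
#' synergism; 0.85-0.9 slight synergism; 0.9-1.1 additive; 1.1-1.2 slight
#' antagonism; 1.2-1.45 moderate antagonism; 1.45 and above antagonism.
#' Intervals are half-open on the upper end, so e.g. CI = 0.85 reads as
#' slight synergism.
#'
#' @param ci positive combination index (vectorized).
#' @return character vector of classifications.
#' @export
classify_ci <- function(ci) {
  if (any(ci <= 0)) stop("combination index must be positive")
  ci_bands$classification[findInterval(ci, ci_bands$upper, left.open = FALSE) + 1L]
}

#' Combination index and dose-reduction index at chosen effect levels
#'
#' For a constant-ratio a:b combination fitted on the total-dose scale:
#' the total combination dose reaching each `fa` is split into its
#' components, and the combination index is the mutually-exclusive
#' Chou-Talalay form \eqn{CI = d_a/D_{x,a} + d_b/D_{x,b}}, where
#' \eqn{D_{x,i}} is the monotherapy dose reaching the same effect. The
#' dose-reduction index is \eqn{DRI_i = D_{x,i}/d_i}, so
#' \eqn{CI = 1/DRI_a + 1/DRI_b} by construction. With
#' `exclusive = FALSE` the non-exclusive third term
#' \eqn{(d_a d_b)/(D_{x,a} D_{x,b})} is added.
#'
#' @param fit_a,fit_b monotherapy `median_effect_fit`s.
#' @param fit_combo `median_effect_fit` of the combination on total dose.
#' @param ratio length-2 positive numeric, the fixed a:b dose ratio.
#' @param fa_levels fraction-affected levels to evaluate (default
#'   0.5, 0.75, 0.9).
#' @param exclusive use the mutually-exclusive two-term CI (default TRUE).
#' @return data.frame of class `combination_result`, one row per fa level:
#'   `fa`, `ci`, `dri_a`, `dri_b`, `classification`, plus the component and
#'   monotherapy doses (`d_a`, `d_b`, `dx_a`, `dx_b`).
#' @export
combination_index <- function(fit_a, fit_b, fit_combo, ratio = c(1, 1),
                              fa_levels = c(0.5, 0.75, 0.9),
                              exclusive = TRUE) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"),
            inherits(fit_combo, "median_effect_fit"),
            length(ratio) == 2L, all(ratio > 0))
  dx_combo <- dose_for_fa(fit_combo, fa_levels)
  d_a <- dx_combo * ratio[1L] / sum(ratio)
  d_b <- dx_combo * ratio[2L] / sum(ratio)
  dx_a <- dose_for_fa(fit_a, fa_levels)
  dx_b <- dose_for_fa(fit_b, fa_levels)
  ci <- d_a / dx_a + d_b / dx_b
  if (!exclusive) ci <- ci + (d_a * d_b) / (dx_a * dx_b)
  out <- data.frame(fa = fa_levels, ci = ci,
                    dri_a = dx_a / d_a, dri_b = dx_b / d_b,
                    classification = classify_ci(ci),
                    d_a = d_a, d_b = d_b, dx_a = dx_a, dx_b = dx_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("combination_result", "data.frame")
  out
}

#' Format a combination result in the "CI (DRI_a;DRI_b)" table style
#'
#' CI rounded to 2 decimals, DRIs to 1, matching the conventional reporting
#' of combination-index tables; the raw values stay in the input.
#'
#' @param result a `combination_result` from [combination_index].
#' @return character vector, one formatted cell per fa level.
#' @export
dri_report <- function(result) {
  sprintf("%.2f (%.1f;%.1f)", result$ci, result$dri_a, result$dri_b)
}

#' Read a dose-response TSV (columns drug, dose, fa)
#' @param path TSV path.
#' @return data.frame with columns `drug`, `dose`, `fa`.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose", "fa")
  if (!all(need %in% names(df)))
    stop("dose-response table needs columns: ", paste(need, collapse = ", "))
  df[need]
}
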