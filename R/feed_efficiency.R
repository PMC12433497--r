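#' Laying percentage
#'
#' Eggs laid as a percentage of eggs expected over the laying window.
#'
#' @param eggs_laid Egg count over the window.
#' @param expected_eggs Expected egg count; must be positive.
#' @return Percent (vectorised).
#' @export
laying_percentage <- function(eggs_laid, expected_eggs) {
  if (any(expected_eggs <= 0, na.rm = TRUE)) {
    stop("expected_eggs must be positive", call. = FALSE)
  }
  eggs_laid / expected_eggs * 100
}

#' Egg mass
#'
#' Daily egg output in grams: average egg weight scaled by the laying
#' percentage.
#'
#' @param mean_egg_weight Mean egg weight, g/egg.
#' @param lp Laying percentage.
#' @return g/day (vectorised).
#' @export
egg_mass <- function(mean_egg_weight, lp) {
  if (any(mean_egg_weight < 0, na.rm = TRUE) || any(lp < 0, na.rm = TRUE)) {
    stop("egg weight and laying percentage must be non-negative", call. = FALSE)
  }
  mean_egg_weight * lp / 100
}

#' Feed conversion ratio
#'
#' Feed consumed per unit egg mass produced: total feed over the recording
#' period divided by egg mass, divided by the period length. For a constant
#' daily feed consumption this reduces to `dfc / em`. Lower is more
#' efficient. Undefined (returned as `NA`) when egg mass is zero.
#'
#' @param dfc Daily feed consumed, g/day.
#' @param em Egg mass, g/day.
#' @param period_days Length of the feed-recording period, days (default 7).
#' @return Dimensionless ratio (vectorised); `NA` where `em` is 0.
#' @export
fcr <- function(dfc, em, period_days = 7) {
  if (any(dfc < 0, na.rm = TRUE) || any(em < 0, na.rm = TRUE)) {
    stop("dfc and em must be non-negative", call. = FALSE)
  }
  out <- (dfc * period_days / em) / period_days
  out[!is.na(em) & em == 0] <- NA_real_
  out
}

#' Residual-feed-consumption model coefficients
#'
#' The linear model predicting period feed consumption from daily body
#' weight, egg mass and body-weight gain. The coefficients are
#' population-specific and must be supplied by the user; the default null
#' model (all zero) makes residual feed consumption equal observed feed,
#' so the software runs out of the box while making clear that real
#' coefficients have not been provided.
#'
#' @param b0 Intercept, g.
#' @param b1 g feed per g daily body weight.
#' @param b2 g feed per g egg mass.
#' @param b3 g feed per g body-weight gain.
#' @return An object of class `rfc_coefficients`.
#' @export
rfc_coefficients <- function(b0 = 0, b1 = 0, b2 = 0, b3 = 0) {
  vals <- c(b0 = b0, b1 = b1, b2 = b2, b3 = b3)
  if (any(!is.finite(vals))) stop("coefficients must be finite", call. = FALSE)
  structure(as.list(vals), class = "rfc_coefficients")
}

#' Residual feed consumption
#'
#' Observed feed consumption minus that predicted from body weight, egg mass
#' and body-weight gain. Positive values mark birds eating more than their
#' production predicts (less efficient).
#'
#' @param dfc_total Observed feed over the recording period, g.
#' @param dbw Daily body weight, g.
#' @param em Egg mass, g/day.
#' @param bwg Body-weight gain, g; 0 by default (negligible over a one-week
#'   window in adult hens).
#' @param coeffs An [rfc_coefficients()] object.
#' @return g (vectorised).
#' @export
rfc <- function(dfc_total, dbw, em, bwg = 0, coeffs) {
  if (missing(coeffs) || !inherits(coeffs, "rfc_coefficients")) {
    stop("coeffs must be supplied as an rfc_coefficients object", call. = FALSE)
  }
  dfc_total - (coeffs$b0 + coeffs$b1 * dbw + coeffs$b2 * em + coeffs$b3 * bwg)
}

#' Feed-efficiency indicators for every bird in a trial
#'
#' Laying percentage, egg mass, feed conversion ratio and residual feed
#' consumption per bird. Birds that laid no eggs have zero egg mass, a
#' missing feed conversion ratio and a `no_eggs` flag (they remain available
#' to the outlier stage).
#'
#' @param dataset A [trial_dataset()], or a [bird_records()] table.
#' @param coeffs [rfc_coefficients()]; defaults to the null model.
#' @param bwg Body-weight gain in grams, recycled across birds; default 0.
#' @param rfc_basis `"total"` (default) uses feed summed over `period_days`
#'   for the residual-feed term; `"per_day"` uses the daily mean instead.
#' @return A tibble: `bird_id`, `line`, `lp`, `em`, `dbw`, `bwg`, `fcr`,
#'   `rfc`, `flags`.
#' @export
compute_efficiency <- function(dataset, coeffs = rfc_coefficients(), bwg = 0,
                               rfc_basis = c("total", "per_day")) {
  rfc_basis <- match.arg(rfc_basis)
  birds <- if (inherits(dataset, "trial_dataset")) dataset$birds
           else bird_records(dataset)
  lp <- laying_percentage(birds$eggs_laid, birds$expected_eggs)
  mew <- ifelse(birds$eggs_laid > 0, birds$mean_egg_weight, 0)
  em <- egg_mass(mew, lp)
  dfc_term <- if (rfc_basis == "total") birds$dfc * birds$period_days
              else birds$dfc
  out <- tibble::tibble(
    bird_id = birds$bird_id,
    line = birds$line,
    lp = lp,
    em = em,
    dbw = birds$dbw,
    bwg = rep_len(bwg, nrow(birds)),
    fcr = fcr(birds$dfc, em, birds$period_days),
    rfc = rfc(dfc_term, birds$dbw, em, rep_len(bwg, nrow(birds)), coeffs),
    flags = ifelse(birds$eggs_laid == 0, "no_eggs", NA_character_)
  )
  out
}
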