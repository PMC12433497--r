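#' Stoichiometric nitrogen fraction of uric acid
#'
#' Uric acid (C5H4N4O3, molar mass 168.11 g/mol) carries four nitrogen atoms
#' (4 x 14.007 g/mol), so nitrogen makes up about 33.3 % of its mass. Used to
#' subtract uric-acid-bound (urinary) nitrogen from total manure nitrogen.
#'
#' @return The mass fraction 4*14.007/168.11.
#' @export
ua_nitrogen_fraction <- function() 4 * 14.007 / 168.11

#' Convert assay values from air-dried to dry-matter basis
#'
#' Manure chemistry is assayed on the air-dried sample; digestibility
#' arithmetic needs contents per kg of dry matter. Each analyte is rescaled by
#' the dry-matter content of the air-dried sample, and organic matter is
#' defined as dry matter minus ash.
#'
#' @param assays A [manure_assays()] table (or anything it accepts).
#' @return A tibble with columns `bird_id`, `nitrogen_dm`, `fat_dm`,
#'   `ash_dm`, `org_dm`, `uric_acid_dm` (all g/kg DM).
#' @examples
#' airdry_to_dm_basis(data.frame(bird_id = "h1", adm = 260, dm_ad = 900,
#'   ash_ad = 220, nitrogen_ad = 25, fat_ad = 28, uric_acid_ad = 30))
#' @export
airdry_to_dm_basis <- function(assays) {
  assays <- manure_assays(assays)
  f <- 1000 / assays$dm_ad
  tibble::tibble(
    bird_id = assays$bird_id,
    nitrogen_dm = assays$nitrogen_ad * f,
    fat_dm = assays$fat_ad * f,
    ash_dm = assays$ash_ad * f,
    org_dm = 1000 - assays$ash_ad * f,
    uric_acid_dm = assays$uric_acid_ad * f
  )
}

#' Correct manure nitrogen for uric-acid-bound nitrogen
#'
#' Avian excreta mix faeces and urine; the urinary share of nitrogen is
#' largely bound in uric acid. Subtracting the stoichiometric uric-acid
#' nitrogen leaves the faecal nitrogen used in the nitrogen digestibility
#' coefficient. A negative result is floored at zero with a warning.
#'
#' @param nitrogen_dm Total manure nitrogen, g/kg DM.
#' @param uric_acid_dm Uric acid, g/kg DM.
#' @param f_ua Mass fraction of nitrogen in uric acid; default
#'   [ua_nitrogen_fraction()].
#' @return Corrected nitrogen, g/kg DM (vectorised).
#' @export
correct_nitrogen_for_uric_acid <- function(nitrogen_dm, uric_acid_dm,
                                           f_ua = ua_nitrogen_fraction()) {
  if (any(nitrogen_dm < 0, na.rm = TRUE) || any(uric_acid_dm < 0, na.rm = TRUE)) {
    stop("nitrogen and uric acid contents must be non-negative", call. = FALSE)
  }
  out <- nitrogen_dm - f_ua * uric_acid_dm
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(sum(neg), " corrected nitrogen value(s) below zero floored at 0 ",
            "(uric acid exceeds what total nitrogen can carry)", call. = FALSE)
    out[neg] <- 0
  }
  out
}

#' Daily manure dry-matter amount
#'
#' Grams of manure dry matter excreted per day, from the air-dry recovery
#' (g/kg fresh manure) and the fresh daily manure weight (g/day).
#'
#' @param adm Air-dry recovery, g per kg fresh manure.
#' @param dmw Daily fresh manure weight, g/day.
#' @return g DM/day (vectorised).
#' @examples
#' manure_dm_amount(adm = 260.2, dmw = 146.6)  # 38.1 g/day
#' @export
manure_dm_amount <- function(adm, dmw) {
  if (any(adm < 0, na.rm = TRUE) || any(dmw < 0, na.rm = TRUE)) {
    stop("adm and dmw must be non-negative", call. = FALSE)
  }
  adm / 1000 * dmw
}

#' Daily feed dry-matter intake
#'
#' @param dfc Daily feed consumed, g/day as-fed.
#' @param feed_dm Feed dry-matter content, g/kg as-fed.
#' @return g DM/day (vectorised).
#' @export
feed_dm_amount <- function(dfc, feed_dm) {
  if (any(dfc < 0, na.rm = TRUE) || any(feed_dm < 0, na.rm = TRUE)) {
    stop("dfc and feed_dm must be non-negative", call. = FALSE)
  }
  dfc * feed_dm / 1000
}

#' Dry-matter digestibility coefficient
#'
#' Percent of ingested dry matter not recovered in the manure:
#' `100 - manure_dm / feed_dm_in * 100`.
#'
#' @param manure_dm Manure dry matter, g/day.
#' @param feed_dm_in Feed dry-matter intake, g/day; must be positive.
#' @return Percent (vectorised). May be negative when excretion exceeds
#'   intake; values are never clamped.
#' @export
dc_dry_matter <- function(manure_dm, feed_dm_in) {
  if (any(feed_dm_in <= 0, na.rm = TRUE)) {
    stop("feed_dm_in must be positive", call. = FALSE)
  }
  100 - manure_dm / feed_dm_in * 100
}

#' Nutrient digestibility coefficient
#'
#' Percent of an ingested nutrient not recovered in the manure, with both
#' contents expressed in g/kg DM:
#' `100 - (manure_dm * content_manure) / (feed_dm_in * content_feed) * 100`.
#' For nitrogen, `content_manure` should be the uric-acid-corrected value.
#'
#' @param manure_dm Manure dry matter, g/day.
#' @param content_manure Nutrient content of manure, g/kg DM.
#' @param feed_dm_in Feed dry-matter intake, g/day.
#' @param content_feed Nutrient content of feed, g/kg DM; must be positive
#'   (the coefficient is undefined for a nutrient absent from the diet).
#' @return Percent (vectorised), unclamped.
#' @export
dc_nutrient <- function(manure_dm, content_manure, feed_dm_in, content_feed) {
  if (any(feed_dm_in <= 0, na.rm = TRUE)) {
    stop("feed_dm_in must be positive", call. = FALSE)
  }
  if (any(content_feed <= 0, na.rm = TRUE)) {
    stop("content_feed must be positive: digestibility is undefined for a ",
         "nutrient absent from the feed", call. = FALSE)
  }
  100 - (manure_dm * content_manure) / (feed_dm_in * content_feed) * 100
}

#' Digestibility coefficients for every bird in a trial
#'
#' Chains the basis conversion, uric-acid nitrogen correction and the
#' dry-matter/nutrient coefficient formulas for each bird with a manure
#' assay. Feed contents (as-fed) are converted to g/kg DM internally; feed
#' organic matter is dry matter minus ash on the DM basis.
#'
#' Birds with zero manure weight get all coefficients equal to 100 and a
#' `zero_manure` flag; negative coefficients (excretion exceeding intake) are
#' reported as-is with a `mass_balance` flag.
#'
#' @param dataset A [trial_dataset()].
#' @param f_ua Nitrogen mass fraction of uric acid, see
#'   [correct_nitrogen_for_uric_acid()].
#' @param feed_as_fed Set to `FALSE` if the feed composition is already on a
#'   dry-matter basis (no as-fed-to-DM conversion is then applied).
#' @return A tibble with columns `bird_id`, `line`, `dc_dm`, `dc_fat`,
#'   `dc_n`, `dc_org` (percent) and `flags` (`NA` or `;`-separated labels).
#'   Birds without an assay get `NA` coefficients and a `no_assay` flag.
#' @export
compute_all_dcs <- function(dataset, f_ua = ua_nitrogen_fraction(),
                            feed_as_fed = TRUE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  birds <- dataset$birds
  feed <- dataset$feed
  conv <- if (feed_as_fed) 1000 / feed$dm else 1
  n_feed_dm <- feed$nitrogen * conv
  fat_feed_dm <- feed$fat * conv
  ash_feed_dm <- feed$ash * conv
  org_feed_dm <- 1000 - ash_feed_dm

  dm_basis <- airdry_to_dm_basis(dataset$assays)
  idx <- match(birds$bird_id, dataset$assays$bird_id)
  adm <- dataset$assays$adm[idx]
  nb <- dm_basis[idx, ]

  n_corr <- correct_nitrogen_for_uric_acid(nb$nitrogen_dm, nb$uric_acid_dm,
                                           f_ua = f_ua)
  manure_dm <- manure_dm_amount(adm, birds$dmw)
  feed_dm_in <- feed_dm_amount(birds$dfc, feed$dm)

  out <- tibble::tibble(
    bird_id = birds$bird_id,
    line = birds$line,
    dc_dm = dc_dry_matter(manure_dm, feed_dm_in),
    dc_fat = dc_nutrient(manure_dm, nb$fat_dm, feed_dm_in, fat_feed_dm),
    dc_n = dc_nutrient(manure_dm, n_corr, feed_dm_in, n_feed_dm),
    dc_org = dc_nutrient(manure_dm, nb$org_dm, feed_dm_in, org_feed_dm),
    flags = NA_character_
  )

  add_flag <- function(flags, which, label) {
    ifelse(which, ifelse(is.na(flags), label, paste(flags, label, sep = ";")),
           flags)
  }
  no_assay <- is.na(idx)
  zero_manure <- !no_assay & birds$dmw == 0
  if (any(zero_manure)) {
    warning(sum(zero_manure), " bird(s) with zero manure weight: ",
            "coefficients set to 100, check data quality", call. = FALSE)
  }
  dc_cols <- c("dc_dm", "dc_fat", "dc_n", "dc_org")
  for (cl in dc_cols) out[[cl]][zero_manure] <- 100
  neg <- !no_assay & Reduce(`|`, lapply(dc_cols, function(cl) {
    !is.na(out[[cl]]) & out[[cl]] < 0
  }))
  out$flags <- add_flag(out$flags, no_assay, "no_assay")
  out$flags <- add_flag(out$flags, zero_manure, "zero_manure")
  out$flags <- add_flag(out$flags, neg, "mass_balance")
  out
}
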