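#' Feed composition on an as-fed basis
#'
#' Nutrient contents of the (single) trial diet, all in g/kg as-fed. Sugar is
#' carried for completeness but not used in any digestibility coefficient.
#'
#' @param dm Dry matter, g/kg as-fed.
#' @param nitrogen Nitrogen, g/kg as-fed.
#' @param fat Fat (hydrochloric-acid fat), g/kg as-fed.
#' @param ash Crude ash, g/kg as-fed.
#' @param sugar Sugar, g/kg as-fed; optional (`NA` when not assayed).
#'
#' @return An object of class `feed_composition`.
#' @examples
#' feed_composition(dm = 900, nitrogen = 25, fat = 50, ash = 131, sugar = 38)
#' @export
feed_composition <- function(dm, nitrogen, fat, ash, sugar = NA_real_) {
  vals <- c(dm = dm, nitrogen = nitrogen, fat = fat, ash = ash)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("feed composition values must be finite and non-negative", call. = FALSE)
  }
  if (dm > 1000) stop("feed dm cannot exceed 1000 g/kg", call. = FALSE)
  if (nitrogen + fat + ash > dm) {
    stop("nitrogen + fat + ash exceeds dry matter (", nitrogen + fat + ash,
         " > ", dm, " g/kg)", call. = FALSE)
  }
  if (!is.na(sugar) && sugar < 0) stop("sugar must be non-negative", call. = FALSE)
  structure(list(dm = dm, nitrogen = nitrogen, fat = fat, ash = ash,
                 sugar = as.numeric(sugar)),
            class = "feed_composition")
}

#' @export
print.feed_composition <- function(x, ...) {
  cat("Feed composition (g/kg as-fed):\n")
  cat(sprintf("  DM %.0f | N %.1f | fat %.1f | ash %.1f | sugar %s\n",
              x$dm, x$nitrogen, x$fat, x$ash,
              if (is.na(x$sugar)) "-" else sprintf("%.1f", x$sugar)))
  invisible(x)
}

bird_columns <- c("bird_id", "line", "dfc", "dmw", "dbw", "eggs_laid",
                  "mean_egg_weight", "expected_eggs", "period_days")
assay_columns <- c("bird_id", "adm", "dm_ad", "ash_ad", "nitrogen_ad",
                   "fat_ad", "uric_acid_ad")

#' Build and validate a per-bird record table
#'
#' One row per hen: period-aggregated performance. Masses are grams, rates
#' g/day. `eggs_laid` counts eggs over the laying window (default 8 expected
#' eggs); `period_days` is the feed-recording window used by the feed
#' conversion ratio (default 7).
#'
#' @param df A data frame with columns `bird_id`, `line`, `dfc` (g/day feed
#'   consumed), `dmw` (g/day fresh manure), `dbw` (g body weight),
#'   `eggs_laid`, `mean_egg_weight` (g/egg; `NA` allowed when no eggs), and
#'   optionally `expected_eggs` (default 8) and `period_days` (default 7).
#' @return A validated [tibble::tibble] of bird records.
#' @export
bird_records <- function(df) {
  df <- tibble::as_tibble(df)
  if (!("expected_eggs" %in% names(df))) df$expected_eggs <- 8L
  if (!("period_days" %in% names(df))) df$period_days <- 7L
  missing_cols <- setdiff(bird_columns, names(df))
  if (length(missing_cols)) {
    stop("bird records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), bird_columns)
  if (length(extra)) {
    stop("unknown bird record column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  df <- df[bird_columns]
  df$bird_id <- as.character(df$bird_id)
  df$line <- as.character(df$line)
  df$eggs_laid <- as.integer(df$eggs_laid)
  df$expected_eggs <- as.integer(df$expected_eggs)
  df$period_days <- as.integer(df$period_days)
  if (anyDuplicated(df$bird_id)) {
    stop("duplicate bird_id: ",
         paste(unique(df$bird_id[duplicated(df$bird_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(
    is.na(df$bird_id) | is.na(df$line) |
      !is.finite(df$dfc) | df$dfc <= 0 |
      !is.finite(df$dmw) | df$dmw < 0 |
      !is.finite(df$dbw) | df$dbw <= 0 |
      is.na(df$eggs_laid) | df$eggs_laid < 0 |
      df$expected_eggs <= 0 | df$period_days <= 0 |
      df$eggs_laid > df$expected_eggs |
      (df$eggs_laid > 0 & !(is.finite(df$mean_egg_weight) & df$mean_egg_weight > 0))
  )
  if (length(bad)) {
    stop("invalid bird record row(s) ", paste(bad, collapse = ", "),
         ": require dfc > 0, dmw >= 0, dbw > 0, 0 <= eggs_laid <= expected_eggs, ",
         "mean_egg_weight > 0 when eggs were laid", call. = FALSE)
  }
  df
}

#' Build and validate a manure assay table
#'
#' One row per hen: the air-dry recovery `adm` (g air-dried manure per kg
#' fresh manure) and the chemistry of the air-dried sample, all in g/kg of
#' air-dried material (`_ad` suffix): dry matter, ash, nitrogen, fat
#' (hydrochloric), uric acid.
#'
#' @param df Data frame with columns `bird_id`, `adm`, `dm_ad`, `ash_ad`,
#'   `nitrogen_ad`, `fat_ad`, `uric_acid_ad`.
#' @return A validated [tibble::tibble] of assays.
#' @export
manure_assays <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(assay_columns, names(df))
  if (length(missing_cols)) {
    stop("assay table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[assay_columns]
  df$bird_id <- as.character(df$bird_id)
  if (anyDuplicated(df$bird_id)) {
    stop("duplicate bird_id in assays: ",
         paste(unique(df$bird_id[duplicated(df$bird_id)]), collapse = ", "),
         call. = FALSE)
  }
  contents <- c("ash_ad", "nitrogen_ad", "fat_ad", "uric_acid_ad")
  bad <- which(
    !is.finite(df$adm) | df$adm < 0 | df$adm > 1000 |
      !is.finite(df$dm_ad) | df$dm_ad <= 0 | df$dm_ad > 1000 |
      Reduce(`|`, lapply(contents, function(cl) {
        !is.finite(df[[cl]]) | df[[cl]] < 0 | df[[cl]] > df$dm_ad
      }))
  )
  if (length(bad)) {
    stop("invalid assay row(s) ", paste(bad, collapse = ", "),
         ": require 0 <= adm <= 1000, 0 < dm_ad <= 1000, and each content in ",
         "[0, dm_ad] g/kg", call. = FALSE)
  }
  df
}

#' Assemble a trial dataset
#'
#' Bundles bird records, matching manure assays and the feed composition.
#' Every assay must belong to a known bird; birds without an assay are allowed
#' (their digestibility coefficients will be `NA`).
#'
#' @param birds A table accepted by [bird_records()].
#' @param assays A table accepted by [manure_assays()].
#' @param feed A [feed_composition()].
#' @return An object of class `trial_dataset` (list with `birds`, `assays`,
#'   `feed`).
#' @export
trial_dataset <- function(birds, assays, feed) {
  birds <- bird_records(birds)
  assays <- manure_assays(assays)
  if (!inherits(feed, "feed_composition")) {
    stop("feed must be a feed_composition object", call. = FALSE)
  }
  orphan <- setdiff(assays$bird_id, birds$bird_id)
  if (length(orphan)) {
    stop("assay bird_id(s) not present among bird records: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(birds = birds, assays = assays, feed = feed),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  lines <- table(x$birds$line)
  cat(sprintf("Trial dataset: %d birds (%s), %d manure assays\n",
              nrow(x$birds),
              paste(sprintf("%s: %d", names(lines), lines), collapse = ", "),
              nrow(x$assays)))
  print(x$feed)
  invisible(x)
}

#' Read a trial dataset from delimited files
#'
#' Expects three UTF-8 comma-delimited files with one header row:
#' `birds.csv` (columns of [bird_records()]), `assays.csv` (columns of
#' [manure_assays()]) and `feed.csv` (one row with columns `dm`, `nitrogen`,
#' `fat`, `ash`, `sugar`; `sugar` may be empty). All masses in grams,
#' contents in g/kg; no row-index column.
#'
#' @param path_records,path_assays,path_feed File paths.
#' @return A validated `trial_dataset`.
#' @seealso [write_trial()]
#' @export
read_trial <- function(path_records, path_assays, path_feed) {
  for (p in c(path_records, path_assays, path_feed)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  birds <- utils::read.csv(path_records, stringsAsFactors = FALSE)
  assays <- utils::read.csv(path_assays, stringsAsFactors = FALSE)
  feed_df <- utils::read.csv(path_feed, stringsAsFactors = FALSE)
  if (nrow(feed_df) != 1) {
    stop("feed file must contain exactly one composition row", call. = FALSE)
  }
  feed_cols <- c("dm", "nitrogen", "fat", "ash")
  miss <- setdiff(feed_cols, names(feed_df))
  if (length(miss)) {
    stop("feed file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sugar <- if ("sugar" %in% names(feed_df)) feed_df$sugar[1] else NA_real_
  feed <- feed_composition(dm = feed_df$dm[1], nitrogen = feed_df$nitrogen[1],
                           fat = feed_df$fat[1], ash = feed_df$ash[1],
                           sugar = if (is.na(sugar)) NA_real_ else as.numeric(sugar))
  trial_dataset(birds, assays, feed)
}

#' Write a trial dataset to delimited files
#'
#' Inverse of [read_trial()]: writes `birds.csv`, `assays.csv` and `feed.csv`
#' into `out_dir` so that reading them back reproduces the dataset
#' field-for-field.
#'
#' @param dataset A `trial_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_trial <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (nrow(dataset$birds) == 0) stop("dataset has no birds to write", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- c(birds = file.path(out_dir, "birds.csv"),
             assays = file.path(out_dir, "assays.csv"),
             feed = file.path(out_dir, "feed.csv"))
  utils::write.csv(dataset$birds, paths["birds"], row.names = FALSE, na = "")
  utils::write.csv(dataset$assays, paths["assays"], row.names = FALSE, na = "")
  fd <- dataset$feed
  utils::write.csv(data.frame(dm = fd$dm, nitrogen = fd$nitrogen, fat = fd$fat,
                              ash = fd$ash, sugar = fd$sugar),
                   paths["feed"], row.names = FALSE, na = "")
  invisible(paths)
}

#' Aggregate raw daily rows into one bird record
#'
#' Collapses a bird's daily measurements into the period summary used by the
#' digestibility and efficiency computations. Feed consumption is averaged
#' over the days it was recorded; fresh manure is totalled and divided by the
#' length of the manure-collection window (3.5 days by default: two pickups a
#' day over days 5-8 with a single morning pickup on the last day); body
#' weight is the mean of the weighings; eggs are counted over the whole
#' laying window.
#'
#' @param daily Data frame with one row per bird-day and columns `bird_id`,
#'   `line`, `day`, and any of `feed` (g consumed that day), `manure`
#'   (g fresh manure collected), `body_weight` (g), `egg_weight` (g, `NA` on
#'   days with no egg). `NA` marks "not measured that day".
#' @param manure_span_days Length of the manure-collection window in days
#'   used as the daily-manure-weight divisor. Default 3.5.
#' @param feed_days Optional integer vector of `day` values over which to
#'   average feed consumption; default uses every day with a feed weight.
#' @param expected_eggs,period_days Passed through to the bird record.
#' @return A [bird_records()] tibble with one row per bird.
#' @export
aggregate_daily <- function(daily, manure_span_days = 3.5, feed_days = NULL,
                            expected_eggs = 8L, period_days = 7L) {
  daily <- as.data.frame(daily)
  needed <- c("bird_id", "line", "day")
  miss <- setdiff(needed, names(daily))
  if (length(miss)) stop("daily rows missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (cl in c("feed", "manure", "body_weight", "egg_weight")) {
    if (!(cl %in% names(daily))) daily[[cl]] <- NA_real_
    if (any(daily[[cl]] < 0, na.rm = TRUE)) {
      stop("negative daily ", cl, " value", call. = FALSE)
    }
  }
  per_bird <- lapply(split(daily, daily$bird_id), function(d) {
    feed <- if (is.null(feed_days)) d$feed else d$feed[d$day %in% feed_days]
    feed <- feed[!is.na(feed)]
    if (!length(feed)) stop("bird ", d$bird_id[1], ": no feed-weighing rows",
                            call. = FALSE)
    eggs <- d$egg_weight[!is.na(d$egg_weight) & d$egg_weight > 0]
    data.frame(
      bird_id = d$bird_id[1],
      line = d$line[1],
      dfc = mean(feed),
      dmw = sum(d$manure, na.rm = TRUE) / manure_span_days,
      dbw = mean(d$body_weight, na.rm = TRUE),
      eggs_laid = length(eggs),
      mean_egg_weight = if (length(eggs)) mean(eggs) else NA_real_,
      expected_eggs = as.integer(expected_eggs),
      period_days = as.integer(period_days)
    )
  })
  bird_records(do.call(rbind, per_bird))
}
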