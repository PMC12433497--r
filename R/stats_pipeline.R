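#' Interquartile-range outlier screening
#'
#' Boxplot-style screening: within each group, a record is removed when any
#' screened trait lies outside `[Q1 - k*IQR, Q3 + k*IQR]`. Quartiles use the
#' linear-interpolation convention (type 7). Fences are computed once on the
#' incoming data, never re-iterated after removals. Missing trait values do
#' not flag a record.
#'
#' @param data Data frame with one row per bird, a `line` column (unless
#'   `group = NULL`) and the trait columns.
#' @param traits Character vector of trait columns to screen.
#' @param k Fence multiplier (default 1.5).
#' @param group Grouping column for per-line fences; `NULL` pools all rows.
#' @return A list with `retained` (tibble), `removed` (tibble with
#'   `bird_id`, `line`, `trait`, `value` for every flagged trait) and
#'   `n_removed`.
#' @export
iqr_filter <- function(data, traits, k = 1.5, group = "line") {
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(traits, group), names(data))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  grp <- if (is.null(group)) rep("all", nrow(data)) else data[[group]]
  if (any(table(grp) < 4)) {
    stop("need at least 4 records per group to place fences", call. = FALSE)
  }
  drop <- rep(FALSE, nrow(data))
  removed <- list()
  for (g in unique(grp)) {
    rows <- which(grp == g)
    for (tr in traits) {
      x <- data[[tr]][rows]
      q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                           type = 7)
      fence <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
      out <- !is.na(x) & (x < fence[1] | x > fence[2])
      if (any(out)) {
        drop[rows[out]] <- TRUE
        removed[[length(removed) + 1L]] <- tibble::tibble(
          bird_id = if ("bird_id" %in% names(data)) data$bird_id[rows[out]]
                    else as.character(rows[out]),
          line = g, trait = tr, value = x[out])
      }
    }
  }
  if (all(drop)) stop("outlier screening removed every record; ",
                      "check traits and fence multiplier", call. = FALSE)
  removed <- if (length(removed)) do.call(rbind, removed)
             else tibble::tibble(bird_id = character(), line = character(),
                                 trait = character(), value = numeric())
  list(retained = data[!drop, , drop = FALSE], removed = removed,
       n_removed = sum(drop))
}

#' Between-line comparison of one trait
#'
#' Two-sided two-sample t-test (Welch unequal-variance by default) with
#' per-line means and standard errors. When both groups are constant the
#' test statistic is undefined; equal constants give p = 1 by convention and
#' distinct constants give p = 0.
#'
#' @param data Data frame with the trait and a grouping column.
#' @param trait Trait column name.
#' @param group Grouping column (default `"line"`); must have exactly two
#'   levels.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return One-row tibble: `trait`, `mean_1`, `se_1`, `n_1`, `mean_2`,
#'   `se_2`, `n_2`, `t`, `p_value` (groups in sorted label order, labels in
#'   attributes `groups`).
#' @export
line_ttest <- function(data, trait, group = "line", var_equal = FALSE) {
  if (!(trait %in% names(data))) stop("unknown trait: ", trait, call. = FALSE)
  g <- sort(unique(as.character(data[[group]])))
  if (length(g) != 2) stop("line_ttest needs exactly two groups", call. = FALSE)
  x <- data[[trait]][data[[group]] == g[1]]
  y <- data[[trait]][data[[group]] == g[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) {  # essentially constant data
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    tstat <- if (p == 1) 0 else Inf
  } else {
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  out <- tibble::tibble(
    trait = trait,
    mean_1 = mean(x), se_1 = stats::sd(x) / sqrt(length(x)), n_1 = length(x),
    mean_2 = mean(y), se_2 = stats::sd(y) / sqrt(length(y)), n_2 = length(y),
    t = tstat, p_value = p)
  attr(out, "groups") <- g
  out
}

#' Between-line comparison table for many traits
#'
#' @param data Data frame with trait columns and a grouping column.
#' @param traits Trait column names.
#' @inheritParams line_ttest
#' @return Tibble with one row per trait (see [line_ttest()]).
#' @export
line_comparison <- function(data, traits, group = "line", var_equal = FALSE) {
  rows <- lapply(traits, function(tr) line_ttest(data, tr, group, var_equal))
  out <- do.call(rbind, rows)
  attr(out, "groups") <- attr(rows[[1]], "groups")
  out
}

#' Significance-masked Pearson correlation matrix
#'
#' Pairwise Pearson correlations with t-distribution p-values and a mask of
#' the pairs that do not reach the significance level. Missing values are
#' handled pairwise-complete (a bird with a missing feed conversion ratio
#' still contributes to other pairs). Constant traits yield an undefined
#' correlation, reported as `NA` and masked.
#'
#' @param data Data frame with the trait columns.
#' @param traits Trait column names; default all numeric columns.
#' @param alpha Significance level for the mask (default 0.05).
#' @return Object of class `correlation_matrix`: list with matrices `r`,
#'   `p`, `n` and logical `mask` (`TRUE` = not significant at `alpha`), plus
#'   `alpha`.
#' @export
correlation_matrix <- function(data, traits = NULL, alpha = 0.05) {
  data <- as.data.frame(data)
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  m <- as.matrix(data[traits])
  if (sum(stats::complete.cases(m)) < 3) {
    stop("need at least 3 complete records", call. = FALSE)
  }
  p <- length(traits)
  r <- diag(1, p); pv <- matrix(0, p, p); n <- matrix(0L, p, p)
  dimnames(r) <- dimnames(pv) <- dimnames(n) <- list(traits, traits)
  diag(n) <- colSums(!is.na(m))
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
    ok <- stats::complete.cases(m[, c(i, j)])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    rij <- if (nij >= 3) suppressWarnings(stats::cor(m[ok, i], m[ok, j]))
           else NA_real_
    r[i, j] <- r[j, i] <- rij
    pv[i, j] <- pv[j, i] <- if (is.na(rij) || abs(rij) >= 1) {
      if (is.na(rij)) NA_real_ else 0
    } else {
      tt <- rij * sqrt((nij - 2) / (1 - rij^2))
      2 * stats::pt(-abs(tt), df = nij - 2)
    }
  }
  mask <- is.na(pv) | pv >= alpha
  diag(mask) <- FALSE
  structure(list(r = r, p = pv, n = n, mask = mask, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations (pairs masked at alpha = %g shown as '.')\n",
              x$alpha))
  disp <- formatC(x$r, digits = digits, format = "f")
  disp[x$mask] <- "."
  print(noquote(disp))
  invisible(x)
}

#' Principal component summary of a trait table
#'
#' Centred (and by default unit-scaled, since the traits mix grams, percent
#' and ratios) principal components via [stats::prcomp()], summarised as
#' explained-variance percentages, loadings, and per-trait contribution
#' percentages (squared loading scaled to sum to 100 within a dimension).
#' Incomplete records are dropped. Constant columns cannot be scaled and
#' raise an error when `standardize` is on; rank deficiency is reported via
#' the `rank` element.
#'
#' @param data Data frame with the trait columns.
#' @param traits Trait column names; default all numeric columns.
#' @param standardize Scale traits to unit variance (default `TRUE`).
#' @return Object of class `pca_summary`: `explained_variance` (percent per
#'   dimension), `loadings` (orthonormal columns), `contributions` (percent,
#'   traits x dimensions), `n`, `rank`, `prcomp` (the underlying fit).
#' @export
pca_summary <- function(data, traits = NULL, standardize = TRUE) {
  data <- as.data.frame(data)
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  m <- as.matrix(data[traits])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) <= length(traits)) {
    stop("need more complete records than traits", call. = FALSE)
  }
  if (standardize && any(apply(m, 2, stats::sd) == 0)) {
    stop("constant trait cannot be standardized: ",
         paste(traits[apply(m, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  var_ <- fit$sdev^2
  explained <- var_ / sum(var_) * 100
  contrib <- fit$rotation^2 * 100
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-9)
  if (rank < length(traits)) {
    message("input is rank-deficient: effective dimensionality ", rank,
            " of ", length(traits))
  }
  structure(list(explained_variance = explained, loadings = fit$rotation,
                 contributions = contrib, n = nrow(m), rank = rank,
                 prcomp = fit),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("PCA on %d records, rank %d\n", x$n, x$rank))
  cat("Explained variance (%):",
      paste(sprintf("%s %.1f", colnames(x$loadings), x$explained_variance),
            collapse = ", "), "\n")
  invisible(x)
}

tidy_lm <- function(fit, response, model_label) {
  s <- summary(fit)
  cf <- s$coefficients
  structure(list(
    response = response,
    model = model_label,
    coefficients = tibble::tibble(
      term = rownames(cf), estimate = unname(cf[, 1]), se = unname(cf[, 2]),
      t = unname(cf[, 3]), p_value = unname(cf[, 4])),
    r_squared = s$r.squared,
    n = length(s$residuals),
    df_residual = fit$df.residual,
    fit = fit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s  (n = %d, R^2 = %.2f)\n", x$response, x$model, x$n,
              x$r_squared))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict feed efficiency from performance traits
#'
#' Ordinary least squares of a feed-efficiency indicator on egg mass and
#' daily body weight (intercept included). Records with missing values are
#' dropped.
#'
#' @param data Data frame with the response and `em`, `dbw` columns.
#' @param response `"fcr"` or `"rfc"` (or any numeric column name).
#' @return A `model_fit`: coefficient table (estimate, SE, t, p), R-squared,
#'   n, residual degrees of freedom.
#' @export
fit_performance_model <- function(data, response = c("fcr", "rfc")) {
  response <- if (is.character(response)) response[1] else response
  d <- as.data.frame(data)[, c(response, "em", "dbw")]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 4) stop("need at least 4 complete records", call. = FALSE)
  if (stats::sd(d$em) == 0 || stats::sd(d$dbw) == 0) {
    stop("constant predictor", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(c("em", "dbw"), response), data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear predictors: model is not estimable", call. = FALSE)
  }
  tidy_lm(fit, response, "performance (em + dbw)")
}

#' Predict feed efficiency from one digestibility coefficient
#'
#' Ordinary least squares of a feed-efficiency indicator on a single
#' digestibility coefficient. The coefficients are strongly correlated with
#' one another, so only one enters at a time.
#'
#' @param data Data frame with the response and the coefficient column.
#' @param response `"fcr"` or `"rfc"`.
#' @param dc `"dc_dm"`, `"dc_n"` or `"dc_org"` (any numeric column accepted).
#' @return A `model_fit`.
#' @export
fit_dc_model <- function(data, response = c("fcr", "rfc"),
                         dc = c("dc_dm", "dc_n", "dc_org")) {
  response <- if (is.character(response)) response[1] else response
  dc <- if (is.character(dc)) dc[1] else dc
  d <- as.data.frame(data)[, c(response, dc)]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("need at least 3 complete records", call. = FALSE)
  if (stats::sd(d[[dc]]) == 0) stop("constant digestibility coefficient",
                                    call. = FALSE)
  fit <- stats::lm(stats::reformulate(dc, response), data = d)
  tidy_lm(fit, response, dc)
}
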