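#' Pipeline configuration
#'
#' Bundles everything one analysis run needs. Exactly one of `input` (paths
#' to the three delimited files) or `simulate` (a [sim_config()]) must be
#' given.
#'
#' @param input Named list/vector with `records`, `assays`, `feed` paths.
#' @param simulate A [sim_config()] for a simulated trial.
#' @param rfc_coeffs [rfc_coefficients()]; defaults to the null model.
#' @param k Fence multiplier for the outlier screen (default 1.5).
#' @param alpha Significance level used for masking (default 0.05).
#' @param pca_standardize Unit-scale traits before the principal component
#'   summary (default `TRUE`).
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @param screen_traits Traits screened by the outlier stage.
#' @param out_dir Optional directory; when given, every stage writes a CSV.
#' @param seed Integer seed recorded in the run log (the simulation seed
#'   lives in `simulate`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            rfc_coeffs = rfc_coefficients(),
                            k = 1.5, alpha = 0.05, pca_standardize = TRUE,
                            var_equal = FALSE,
                            screen_traits = c("dfc", "em", "dmw", "dbw", "fcr",
                                              "dc_dm", "dc_fat", "dc_n",
                                              "dc_org"),
                            out_dir = NULL, seed = 1L) {
  if (is.null(input) == is.null(simulate)) {
    stop("give exactly one of `input` file paths or a `simulate` config",
         call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(input)) {
    miss <- setdiff(c("records", "assays", "feed"), names(input))
    if (length(miss)) stop("input needs paths named records, assays, feed",
                           call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, k > 0,
            inherits(rfc_coeffs, "rfc_coefficients"))
  structure(list(input = input, simulate = simulate, rfc_coeffs = rfc_coeffs,
                 k = k, alpha = alpha, pca_standardize = pca_standardize,
                 var_equal = var_equal, screen_traits = screen_traits,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

pca_trait_set <- c("dfc", "em", "dmw", "dbw", "lp",
                   "dc_dm", "dc_fat", "dc_n", "dc_org")
corr_trait_set <- c("fcr", "rfc", "dc_dm", "dc_fat", "dc_n", "dc_org")

#' Run the full digestibility and feed-efficiency analysis
#'
#' Reads (or simulates) a trial, computes digestibility coefficients and
#' feed-efficiency indicators, screens outliers per line by interquartile
#' fences, then runs between-line t-tests, per-line significance-masked
#' correlations among the efficiency indicators and digestibility
#' coefficients, per-line principal component summaries of performance
#' traits plus coefficients, and per-line linear prediction models of the
#' feed conversion ratio and residual feed consumption (performance model
#' plus one model per digestibility coefficient).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_bundle`: `dataset`, `ground_truth`
#'   (simulation only), `traits` (per-bird trait table before screening),
#'   `screen` (the [iqr_filter()] result), `retained`, `comparisons`,
#'   `correlations` (per line), `pca` (per line), `models` (per line), and
#'   `log` (seed, counts per stage, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  ground_truth <- NULL
  tryCatch({
    if (!is.null(config$simulate)) {
      sim <- simulate_trial(config$simulate)
      dataset <- sim$dataset
      ground_truth <- sim$ground_truth
    } else {
      dataset <- read_trial(config$input[["records"]], config$input[["assays"]],
                            config$input[["feed"]])
    }

    stage <- "digestibility"
    dcs <- compute_all_dcs(dataset)
    stage <- "efficiency"
    eff <- compute_efficiency(dataset, coeffs = config$rfc_coeffs)
    traits <- tibble::as_tibble(cbind(
      dataset$birds[c("bird_id", "line", "dfc", "dmw")],
      eff[c("lp", "em", "dbw", "fcr", "rfc")],
      dcs[c("dc_dm", "dc_fat", "dc_n", "dc_org")]))

    stage <- "outlier screening"
    screen <- iqr_filter(traits, traits = config$screen_traits, k = config$k)
    retained <- screen$retained

    two_lines <- length(unique(retained$line)) == 2
    stage <- "line comparisons"
    comp_traits <- c("dfc", "em", "dmw", "dbw", "lp", "fcr", "rfc",
                     "dc_dm", "dc_fat", "dc_n", "dc_org")
    comparisons <- if (two_lines) {
      line_comparison(retained, comp_traits, var_equal = config$var_equal)
    } else NULL
    under_powered <- any(table(retained$line) < 10)

    per_line <- split(retained, retained$line)
    stage <- "correlations"
    correlations <- lapply(per_line, function(d) {
      correlation_matrix(d, corr_trait_set, alpha = config$alpha)
    })
    stage <- "principal components"
    pca <- lapply(per_line, function(d) {
      pca_summary(d, pca_trait_set, standardize = config$pca_standardize)
    })
    stage <- "prediction models"
    models <- lapply(per_line, function(d) {
      fits <- list(fit_performance_model(d, "fcr"),
                   fit_performance_model(d, "rfc"))
      for (resp in c("fcr", "rfc")) {
        for (dc in c("dc_dm", "dc_n", "dc_org")) {
          fits[[length(fits) + 1L]] <- fit_dc_model(d, resp, dc)
        }
      }
      names(fits) <- vapply(fits, function(f) paste(f$response, f$model),
                            character(1))
      fits
    })

    log <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("layerdig")),
      n_birds = nrow(dataset$birds),
      n_per_line = as.list(table(dataset$birds$line)),
      n_removed = screen$n_removed,
      removed_ids = unique(screen$removed$bird_id),
      n_retained_per_line = as.list(table(retained$line)),
      under_powered = under_powered
    )
    bundle <- structure(list(dataset = dataset, ground_truth = ground_truth,
                             traits = traits, screen = screen,
                             retained = retained, comparisons = comparisons,
                             correlations = correlations, pca = pca,
                             models = models, log = log, config = config),
                        class = "pipeline_bundle")
    if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
    bundle
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  write_trial(bundle$dataset, out_dir)
  if (!is.null(bundle$ground_truth)) w(bundle$ground_truth, "ground_truth.csv")
  w(bundle$traits[c("bird_id", "line", "dc_dm", "dc_fat", "dc_n", "dc_org")],
    "dcs.csv")
  w(bundle$traits[c("bird_id", "line", "lp", "em", "dbw", "fcr", "rfc")],
    "efficiency.csv")
  w(bundle$screen$removed, "removed.csv")
  if (!is.null(bundle$comparisons)) w(bundle$comparisons, "line_comparison.csv")
  corr_long <- do.call(rbind, lapply(names(bundle$correlations), function(ln) {
    cm <- bundle$correlations[[ln]]
    idx <- which(upper.tri(cm$r), arr.ind = TRUE)
    data.frame(line = ln, trait_1 = rownames(cm$r)[idx[, 1]],
               trait_2 = colnames(cm$r)[idx[, 2]], r = cm$r[idx],
               p_value = cm$p[idx], significant = !cm$mask[idx])
  }))
  w(corr_long, "correlations.csv")
  pca_long <- do.call(rbind, lapply(names(bundle$pca), function(ln) {
    pc <- bundle$pca[[ln]]
    data.frame(line = ln, dimension = colnames(pc$loadings),
               explained_variance = pc$explained_variance)
  }))
  w(pca_long, "pca.csv")
  model_long <- do.call(rbind, lapply(names(bundle$models), function(ln) {
    do.call(rbind, lapply(bundle$models[[ln]], function(f) {
      cbind(data.frame(line = ln, trait = f$response, model = f$model),
            as.data.frame(f$coefficients))
    }))
  }))
  w(model_long, "models.csv")
  r2 <- do.call(rbind, lapply(names(bundle$models), function(ln) {
    do.call(rbind, lapply(bundle$models[[ln]], function(f) {
      data.frame(line = ln, trait = f$response, model = f$model,
                 r_squared = f$r_squared)
    }))
  }))
  w(r2, "r_squared.csv")
  writeLines(c(
    sprintf("seed: %d", bundle$log$seed),
    sprintf("layerdig version: %s", bundle$log$package_version),
    sprintf("birds simulated/read: %d (%s)", bundle$log$n_birds,
            paste(sprintf("%s=%s", names(bundle$log$n_per_line),
                          unlist(bundle$log$n_per_line)), collapse = ", ")),
    sprintf("removed by fence screen: %d (%s)", bundle$log$n_removed,
            paste(bundle$log$removed_ids, collapse = ", ")),
    sprintf("retained per line: %s",
            paste(sprintf("%s=%s", names(bundle$log$n_retained_per_line),
                          unlist(bundle$log$n_retained_per_line)),
                  collapse = ", "))
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

p_band <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", ifelse(p < 0.01, "<0.01",
         ifelse(p < 0.05, "<0.05", ifelse(p < 0.1, "<0.1",
         sprintf("%.2f", p))))))
}

#' Render a pipeline bundle as a plain-text report
#'
#' Fixed-width tables with one-decimal means and standard errors in
#' parentheses, p-values reported in the conventional bands (<0.1, <0.05,
#' <0.01, <0.001), masked correlations shown as dots.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param file Optional path; default prints to the console.
#' @return Invisibly, the report lines.
#' @export
render_report <- function(bundle, file = "") {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))
  add("Digestibility and feed-efficiency report")
  add("=========================================")
  add("Birds: %d; removed by fence screen: %d; retained: %s",
      bundle$log$n_birds, bundle$log$n_removed,
      paste(sprintf("%s=%s", names(bundle$log$n_retained_per_line),
                    unlist(bundle$log$n_retained_per_line)), collapse = ", "))
  if (isTRUE(bundle$log$under_powered)) {
    add("NOTE: fewer than 10 birds in a line; between-line tests are under-powered.")
  }
  if (!is.null(bundle$comparisons)) {
    g <- attr(bundle$comparisons, "groups")
    add("")
    add("Between-line comparison (mean (SE)):")
    add("%-8s %18s %18s %10s", "trait", paste("line", g[1]),
        paste("line", g[2]), "p")
    for (i in seq_len(nrow(bundle$comparisons))) {
      r <- bundle$comparisons[i, ]
      add("%-8s %18s %18s %10s", r$trait,
          sprintf("%.1f (%.1f)", r$mean_1, r$se_1),
          sprintf("%.1f (%.1f)", r$mean_2, r$se_2), p_band(r$p_value))
    }
  }
  for (ln in names(bundle$correlations)) {
    add("")
    add("Correlations, line %s (non-significant masked as '.'):", ln)
    cm <- bundle$correlations[[ln]]
    disp <- formatC(cm$r, digits = 2, format = "f")
    disp[cm$mask] <- "  .  "
    hdr <- paste(sprintf("%7s", colnames(cm$r)), collapse = "")
    add("%8s%s", "", hdr)
    for (i in seq_len(nrow(cm$r))) {
      add("%8s%s", rownames(cm$r)[i],
          paste(sprintf("%7s", disp[i, ]), collapse = ""))
    }
  }
  for (ln in names(bundle$pca)) {
    pc <- bundle$pca[[ln]]
    add("")
    add("Principal components, line %s (n = %d): %s", ln, pc$n,
        paste(sprintf("%s %.1f%%", colnames(pc$loadings),
                      pc$explained_variance), collapse = ", "))
  }
  add("")
  add("Prediction models:")
  if (!length(bundle$models) || !length(bundle$models[[1]])) {
    add("  (no models could be fitted)")
  } else {
    add("%-4s %-5s %-22s %-10s %9s %8s %7s %8s", "line", "trait", "model",
        "term", "estimate", "SE", "t", "p")
    for (ln in names(bundle$models)) {
      for (f in bundle$models[[ln]]) {
        for (i in seq_len(nrow(f$coefficients))) {
          cf <- f$coefficients[i, ]
          add("%-4s %-5s %-22s %-10s %9.2f %8.2f %7.2f %8s", ln, f$response,
              f$model, cf$term, cf$estimate, cf$se, cf$t, p_band(cf$p_value))
        }
        add("%-4s %-5s %-22s   R^2 = %.2f (n = %d)", ln, f$response, f$model,
            f$r_squared, f$n)
      }
    }
  }
  writeLines(out, con = if (nzchar(file)) file else stdout())
  invisible(out)
}
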