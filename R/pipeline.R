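#' Configuration for one two-group comparison
#'
#' Defaults mirror the analysis constants: alpha 0.05, 10,000 permutations,
#' 80% correlation screen, 20% DE dominance threshold, 1% forward DE gain,
#' both the raw and the pair-smoothed basis. The default test statistic is
#' the mean difference (the focal statistic; `median_diff` and `var_ratio`
#' can be added and classification then counts significance under any of
#' them).
#'
#' @param name comparison label.
#' @param alpha significance level.
#' @param n_perm permutations per test.
#' @param statistics statistics passed to [perm_config()].
#' @param bases basis sizes to run; `NULL` means raw (K) and smoothed (K/2).
#' @param screen_threshold correlation threshold for [screen_features()].
#' @param de_threshold single-fit DE dominance threshold.
#' @param min_de_gain forward-step DE threshold.
#' @param combining NPC combining function.
#' @param seed base seed; every stage derives its own stream from it.
#' @return list of class `comparison_config`.
#' @export
comparison_config <- function(name = "comparison", alpha = 0.05,
                              n_perm = 10000, statistics = "mean_diff",
                              bases = NULL, screen_threshold = 0.8,
                              de_threshold = 0.20, min_de_gain = 0.01,
                              combining = "fisher", seed = 1L) {
  structure(list(name = name, alpha = alpha, n_perm = as.integer(n_perm),
                 statistics = statistics, bases = bases,
                 screen_threshold = screen_threshold,
                 de_threshold = de_threshold, min_de_gain = min_de_gain,
                 combining = combining, seed = as.integer(seed)),
            class = "comparison_config")
}

# Combine per-basis, per-statistic classifications: a feature is IDL if any
# run calls it IDL, else LDL if any run calls it LDL, else NS.
.combine_classes <- function(classes) {
  if ("IDL" %in% classes) "IDL" else if ("LDL" %in% classes) "LDL" else "NS"
}

#' Run one full two-group comparison
#'
#' Orchestrates screen -> ITP (per basis) -> univariate scalar tests ->
#' predictor construction -> single FLR -> dominance screen -> LASSO subset
#' -> stepwise multiple FLR, and optionally writes all stage tables under
#' `out_dir`. Fully deterministic given the config seed.
#'
#' @param curves named list of [curve_matrix] objects (rows = regions of
#'   both groups).
#' @param labels two-level factor over regions (first level = events).
#' @param scalars optional `scalar_table` of low-resolution features.
#' @param cfg a [comparison_config()].
#' @param out_dir optional output directory for the report tables.
#' @return list of class `comparison_report`: `screen`, `itp` (nested by
#'   feature/basis), `classification` (data.frame), `scalar_tests`,
#'   `single_fits` (DE table), `dominant`, `lasso`, `final_model`,
#'   `manifest`.
#' @export
run_comparison <- function(curves, labels, scalars = NULL,
                           cfg = comparison_config(), out_dir = NULL) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2)
  y <- as.integer(labels == levels(labels)[1])
  K <- ncol(curves[[1]]$values)
  bases <- cfg$bases %||% unique(c(K, K / 2))
  bases <- bases[K %% bases == 0]

  # 1. multicollinearity screen
  scr <- if (length(curves) >= 2)
    screen_features(curves, threshold_corr = cfg$screen_threshold)
  else list(retained = names(curves), clusters = NULL)

  # 2. ITP per retained feature and basis
  itp <- list()
  cls_rows <- list()
  for (nm in scr$retained) {
    per_basis <- list()
    classes <- character(0)
    for (b in bases) {
      pc <- perm_config(n_perm = cfg$n_perm, statistics = cfg$statistics,
                        seed = derive_seed(cfg$seed,
                                           paste0("itp::", nm, "::", b)))
      res <- itp_curves(curves[[nm]], labels, n_coef = b, cfg = pc,
                        combining = cfg$combining)
      per_basis[[as.character(b)]] <- res
      classes <- c(classes, vapply(cfg$statistics, function(st)
        classify_feature(res, st, cfg$alpha)$class, character(1)))
    }
    itp[[nm]] <- per_basis
    raw <- per_basis[[as.character(bases[1])]]
    cl_raw <- classify_feature(raw, cfg$statistics[1], cfg$alpha)
    cls_rows[[nm]] <- data.frame(
      feature = nm, class = .combine_classes(classes),
      L_star = cl_raw$L_star,
      n_significant = sum(cl_raw$significant),
      sign = if (any(cl_raw$significant))
        sign(sum(cl_raw$signs[cl_raw$significant])) else 0,
      stringsAsFactors = FALSE)
  }
  classification <- do.call(rbind, cls_rows)

  # 3. univariate tests on low-resolution scalars
  scalar_tests <- NULL
  scalar_p <- NULL
  if (!is.null(scalars)) {
    cols <- setdiff(names(scalars), "region_id")
    rows <- lapply(cols, function(nm) {
      pc <- perm_config(n_perm = cfg$n_perm,
                        statistics = cfg$statistics,
                        seed = derive_seed(cfg$seed,
                                           paste0("scalar::", nm)))
      tt <- univariate_perm_test(scalars[[nm]][y == 1],
                                 scalars[[nm]][y == 0], pc)
      data.frame(feature = nm, statistic = names(tt$p), p = unname(tt$p),
                 observed = unname(tt$observed), stringsAsFactors = FALSE)
    })
    scalar_tests <- do.call(rbind, rows)
    scalar_p <- vapply(split(scalar_tests$p, scalar_tests$feature),
                       min, numeric(1), na.rm = TRUE)
  }

  # 4. predictors from ITP results: per feature, the first basis whose own
  # classification is not NS (usually the raw basis)
  raw_itp <- lapply(itp, function(per_basis) {
    for (res in per_basis)
      if (classify_feature(res, cfg$statistics[1],
                           cfg$alpha)$class != "NS") return(res)
    per_basis[[1]]
  })
  # use the combined classification: re-map class for predictor building
  preds <- build_predictors(raw_itp, curves, scalars = scalars,
                            scalar_p = scalar_p, alpha = cfg$alpha,
                            statistic = cfg$statistics[1])
  # drop predictors for features the combined call says are NS
  keep <- vapply(names(preds), function(nm) {
    row <- classification$class[classification$feature == nm]
    !length(row) || row != "NS"
  }, logical(1))
  preds <- preds[keep]

  # 5. shifted-log regularization, column-wise, then single fits
  for (nm in names(preds)) {
    X <- preds[[nm]]$X
    for (j in seq_len(ncol(X))) {
      tr <- shifted_log(X[, j], labels)
      X[, j] <- tr$values
    }
    preds[[nm]]$X <- X
  }
  single <- lapply(preds, fit_single, y = y)
  single_tab <- if (length(single)) data.frame(
    feature = names(single),
    kind = vapply(single, `[[`, character(1), "kind"),
    DE = vapply(single, `[[`, numeric(1), "DE"),
    separation = vapply(single, `[[`, logical(1), "separation"),
    stringsAsFactors = FALSE) else NULL

  # 6. dominance screen, LASSO on scalars, stepwise multiple model
  dom <- screen_dominant(single, threshold = cfg$de_threshold)
  retained_preds <- preds[dom$retained]
  is_scalar <- vapply(retained_preds, function(p) p$kind == "scalar",
                      logical(1))
  scalar_sel <- character(0)
  lasso <- NULL
  if (any(is_scalar)) {
    Z <- do.call(cbind, lapply(retained_preds[is_scalar], `[[`, "X"))
    if (ncol(Z) >= 1) {
      lasso <- select_scalars_lasso(Z, y, seed = derive_seed(cfg$seed,
                                                             "lasso"))
      scalar_sel <- lasso$selected
    }
  }
  final <- stepwise_multiple_flr(retained_preds[scalar_sel],
                                 retained_preds[!is_scalar], y,
                                 min_de_gain = cfg$min_de_gain)

  manifest <- data.frame(
    key = c("name", "alpha", "n_perm", "statistics", "bases",
            "screen_threshold", "de_threshold", "min_de_gain", "combining",
            "seed", "n_group1", "n_group2", "features"),
    value = c(cfg$name, cfg$alpha, cfg$n_perm,
              paste(cfg$statistics, collapse = ","),
              paste(bases, collapse = ","), cfg$screen_threshold,
              cfg$de_threshold, cfg$min_de_gain, cfg$combining, cfg$seed,
              sum(y == 1), sum(y == 0),
              paste(names(curves), collapse = ",")),
    stringsAsFactors = FALSE)

  report <- structure(list(screen = scr, itp = itp,
                           classification = classification,
                           scalar_tests = scalar_tests,
                           single_fits = single_tab, dominant = dom$dominant,
                           lasso = lasso, final_model = final,
                           manifest = manifest),
                      class = "comparison_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a comparison report's stage tables as TSV
#'
#' Emits `classification.tsv`, `screen_clusters.tsv`,
#' `scalar_tests.tsv`, `single_flr.tsv`, `final_model.tsv`,
#' `manifest.tsv`, and one `itp_<feature>_K<basis>.tsv` heatmap table per
#' ITP run. Output is deterministic (no timestamps), so identical
#' config + seed gives byte-identical files.
#'
#' @param report a `comparison_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) if (!is.null(df))
    write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  w(report$classification, "classification.tsv")
  w(report$screen$clusters, "screen_clusters.tsv")
  w(report$scalar_tests, "scalar_tests.tsv")
  w(report$single_fits, "single_flr.tsv")
  w(report$final_model$table, "final_model.tsv")
  w(report$manifest, "manifest.tsv")
  for (nm in names(report$itp))
    for (b in names(report$itp[[nm]]))
      export_heatmap(report$itp[[nm]][[b]],
                     file.path(out_dir,
                               sprintf("itp_%s_K%s.tsv", nm, b)))
  invisible(out_dir)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report:", x$manifest$value[1], "\n")
  print(x$classification, row.names = FALSE)
  cat("dominant (DE > threshold):",
      if (length(x$dominant)) paste(x$dominant, collapse = ", ") else "none",
      "\n")
  cat("final model:", if (length(x$final_model$predictors))
    paste(x$final_model$predictors, collapse = ", ") else "(intercept only)",
    sprintf(" DE = %.3f\n", x$final_model$DE))
  invisible(x)
}
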