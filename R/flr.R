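#' Build scalar and functional predictor specifications from ITP results
#'
#' Features classified IDL enter the logistic model as scalar predictors
#' (their mean over the windows); LDL features enter as functional
#' predictors: the flank is partitioned into contiguous sub-intervals of
#' width at most the feature's significant scale `L*`, and the predictor
#' contributes one term per sub-interval equal to the curve's mean over it
#' (the discretized `1/|I| integral`, so each coefficient is the model
#' weight on that sub-interval). Low-resolution scalars with a significant
#' univariate test are added as scalar predictors. NS features are skipped.
#'
#' @param itp_results named list of `itp_result` objects.
#' @param curves named list of matching [curve_matrix] objects.
#' @param scalars optional `scalar_table` of low-resolution features.
#' @param scalar_p optional named vector of univariate p-values for the
#'   scalar columns; only those `< alpha` are kept (all kept when NULL).
#' @param alpha significance level for classification (default 0.05).
#' @param statistic ITP statistic used for classification.
#' @param layouts optional named list of explicit sub-interval layouts
#'   (each a list of `c(first, last)` window indices), overriding the
#'   default partition.
#' @return named list of `predictor_spec` objects: `name`, `kind`
#'   (`scalar`/`functional`), design matrix `X` (one column per term),
#'   `intervals` (window-index ranges, functional only), `class`.
#' @export
build_predictors <- function(itp_results, curves, scalars = NULL,
                             scalar_p = NULL, alpha = 0.05,
                             statistic = "mean_diff", layouts = NULL) {
  preds <- list()
  for (nm in names(itp_results)) {
    cl <- classify_feature(itp_results[[nm]], statistic = statistic,
                           alpha = alpha)
    if (cl$class == "NS") next
    vals <- curves[[nm]]$values
    if (cl$class == "IDL") {
      X <- matrix(rowMeans(vals), ncol = 1, dimnames = list(NULL, nm))
      preds[[nm]] <- structure(list(name = nm, kind = "scalar", X = X,
                                    intervals = NULL, class = "IDL"),
                               class = "predictor_spec")
    } else {
      K <- ncol(vals)
      # layout granularity follows the scale that emerged as significant:
      # the support scale (width of the localized run) when one was
      # detected, else the maximum significant scale. Scales are in
      # basis-component units; rescale to windows for smoothed bases.
      block <- K / itp_results[[nm]]$K
      Ls <- if (cl$L_support > 0) cl$L_support else max(cl$L_star, 1)
      lay <- layouts[[nm]] %||% default_layout(K, Ls * block)
      X <- vapply(lay, function(r) rowMeans(vals[, r[1]:r[2], drop = FALSE]),
                  numeric(nrow(vals)))
      wl <- curves[[nm]]$window_labels
      colnames(X) <- vapply(lay, function(r)
        sprintf("%s[%d..%d]", nm, wl[r[1]], wl[r[2]]), character(1))
      preds[[nm]] <- structure(list(name = nm, kind = "functional", X = X,
                                    intervals = lay, class = "LDL"),
                               class = "predictor_spec")
    }
  }
  if (!is.null(scalars)) {
    cols <- setdiff(names(scalars), "region_id")
    for (nm in cols) {
      if (!is.null(scalar_p) && !is.na(scalar_p[nm]) && scalar_p[nm] >= alpha)
        next
      X <- matrix(scalars[[nm]], ncol = 1, dimnames = list(NULL, nm))
      preds[[nm]] <- structure(list(name = nm, kind = "scalar", X = X,
                                    intervals = NULL, class = "low_res"),
                               class = "predictor_spec")
    }
  }
  preds
}

#' Default sub-interval layout for a functional predictor
#'
#' Partitions K windows into `ceiling(K / L_star)` contiguous sub-intervals
#' of near-equal width (each at most `L_star` windows), covering the whole
#' flank — e.g. K = 64 with a significant scale of 20 yields a layout of 4
#' sub-intervals of 16 windows.
#'
#' @param K number of windows.
#' @param L_star significant scale (maximum sub-interval width).
#' @return list of `c(first, last)` window-index pairs.
#' @export
default_layout <- function(K, L_star) {
  L_star <- max(1L, min(K, L_star))
  m <- ceiling(K / L_star)
  cuts <- round(seq(0, K, length.out = m + 1))
  lapply(seq_len(m), function(j) c(cuts[j] + 1L, cuts[j + 1]))
}

#' Shifted-log regularization of a skewed predictor
#'
#' When the sample skewness exceeds `trigger` in absolute value in either
#' group, the predictor is transformed to `log(x + s)` with the shift `s`
#' chosen on a logarithmic grid to maximize the smaller of the two groups'
#' Shapiro-Wilk normality p-values. The grid spans
#' `[1e-6 * range, 10 * range]` (200 points), offset so that `x + s > 0`
#' everywhere. Degenerate (constant) predictors are returned untouched with
#' a warning.
#'
#' @param values numeric predictor.
#' @param groups two-level factor aligned with `values`.
#' @param trigger absolute-skewness threshold (default 1).
#' @param grid_n grid resolution.
#' @return list: `values` (possibly transformed), `s` (chosen shift or NA),
#'   `applied` (logical).
#' @export
shifted_log <- function(values, groups, trigger = 1, grid_n = 200) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(values) == length(groups))
  if (stats::sd(values) == 0) {
    warning("constant predictor: shifted-log skipped")
    return(list(values = values, s = NA_real_, applied = FALSE))
  }
  sk <- tapply(values, groups, sample_skewness)
  if (max(abs(sk)) <= trigger)
    return(list(values = values, s = NA_real_, applied = FALSE))
  rng <- diff(range(values))
  base <- if (min(values) <= 0) -min(values) + 1e-12 * max(rng, 1) else 0
  grid <- base + exp(seq(log(1e-6 * rng), log(10 * rng), length.out = grid_n))
  sw_p <- function(x) {
    if (length(x) > 5000) x <- x[round(seq(1, length(x), length.out = 5000))]
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  score <- vapply(grid, function(s) {
    tx <- log(values + s)
    if (!all(is.finite(tx))) return(-Inf)
    min(tapply(tx, groups, sw_p))
  }, numeric(1))
  s <- grid[which.max(score)]
  tx <- log(values + s)
  if (!all(is.finite(tx))) stop("shifted-log produced non-finite values")
  list(values = tx, s = s, applied = TRUE)
}

# Maximum-likelihood logistic fit on a design matrix; the workhorse shared
# by single fits, the stepwise loop and RCDE refits.
.fit_logistic <- function(X, y) {
  df <- if (is.null(X) || ncol(X) == 0) data.frame(.y = y)
  else data.frame(.y = y, X, check.names = FALSE)
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  de <- (fit$null.deviance - fit$deviance) / fit$null.deviance
  sep <- warned && any(fit$fitted.values > 1 - 1e-8 |
                         fit$fitted.values < 1e-8)
  list(fit = fit, coef = sm, D_null = fit$null.deviance,
       D_model = fit$deviance, DE = de, AIC = fit$aic,
       converged = fit$converged, separation = sep)
}

#' Fit a single-predictor (functional) logistic regression
#'
#' Scalar predictors contribute one term; functional predictors contribute
#' one term per sub-interval. Reports the proportion of deviance explained
#' `DE = (D_null - D_model) / D_null` (pseudo R-squared). Perfect
#' separation is flagged (`separation = TRUE`); the maximum-likelihood fit
#' is still returned and its DE is close to 1 by construction.
#'
#' @param pred a `predictor_spec` from [build_predictors()], or a numeric
#'   vector/matrix.
#' @param y binary response (1 = event, 0 = control).
#' @return object of class `flr_fit`.
#' @export
fit_single <- function(pred, y) {
  X <- if (inherits(pred, "predictor_spec")) pred$X else as.matrix(pred)
  nm <- if (inherits(pred, "predictor_spec")) pred$name else "predictor"
  f <- .fit_logistic(X, y)
  structure(c(f, list(predictor = nm,
                      kind = if (inherits(pred, "predictor_spec"))
                        pred$kind else "scalar")),
            class = "flr_fit")
}

#' Partition single-fit results by dominance
#'
#' Predictors whose single-model DE exceeds `threshold` (strictly) are set
#' aside as dominant — noted and interpreted but excluded from the multiple
#' model, where they would obscure weaker contributions.
#'
#' @param fits named list of `flr_fit` (or named numeric DE vector).
#' @param threshold DE threshold (default 0.20).
#' @return list with character vectors `dominant` and `retained`.
#' @export
screen_dominant <- function(fits, threshold = 0.20) {
  de <- if (is.numeric(fits)) fits
  else vapply(fits, function(f) f$DE, numeric(1))
  list(dominant = names(de)[de > threshold],
       retained = names(de)[de <= threshold])
}

#' Select a subset of scalar predictors by cross-validated LASSO
#'
#' Standardizes the predictors, fits an L1-penalized logistic path, picks
#' the penalty minimizing the 10-fold cross-validation misclassification
#' rate, and returns the predictors with nonzero coefficients there,
#' together with an unpenalized logistic refit on that subset. Columns that
#' are linearly aliased with earlier selections (e.g. exact duplicates) are
#' dropped before the refit, which requires a full-rank design.
#'
#' @param Z numeric matrix of scalar predictors (columns named).
#' @param y binary response.
#' @param cv_folds folds (default 10).
#' @param seed seed for the fold assignment.
#' @return list: `selected` (character, possibly empty), `refit`
#'   (`flr_fit` on the subset, or NULL when empty), `lambda`.
#' @export
select_scalars_lasso <- function(Z, y, cv_folds = 10, seed = 1L) {
  Z <- as.matrix(Z)
  stopifnot(!is.null(colnames(Z)))
  single <- ncol(Z) == 1
  Zi <- if (single) cbind(Z, .null.. = 0) else Z
  Zs <- scale(Zi)
  Zs[, attr(Zs, "scaled:scale") == 0] <- 0
  cvfit <- with_seed(derive_seed(seed, "lasso_cv"), {
    foldid <- sample(rep_len(seq_len(cv_folds), length(y)))
    glmnet::cv.glmnet(Zs, y, family = "binomial", type.measure = "class",
                      foldid = foldid, standardize = FALSE)
  })
  b <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, 1]
  selected <- setdiff(names(b)[b != 0], ".null..")
  if (length(selected) > 1) {
    # the unpenalized refit needs a full-rank design: drop columns aliased
    # with earlier selections (exact duplicates enter the LASSO jointly
    # with split coefficients at small lambda)
    qx <- qr(Z[, selected, drop = FALSE])
    selected <- selected[sort(qx$pivot[seq_len(qx$rank)])]
  }
  refit <- if (length(selected))
    .fit_logistic(Z[, selected, drop = FALSE], y) else NULL
  if (!length(selected))
    message("LASSO selected no scalar predictor; proceeding from ",
            "intercept-only")
  list(selected = selected, refit = refit, lambda = cvfit$lambda.min)
}

#' Forward-then-backward construction of the multiple FLR model
#'
#' Starting from the LASSO-selected scalar model, functional predictors are
#' added greedily (largest DE gain first) as long as the gain exceeds
#' `min_de_gain` (default 1%) and the AIC decreases. Scalar predictors
#' rendered non-significant (coefficient p >= `p_drop`) are then removed
#' backward, worst first, refitting after each removal. The final model
#' reports, per predictor, its coefficients with p-values and its relative
#' contribution to the deviance explained
#' `RCDE = ((D_null - D_model) - (D_null - D_red)) / (D_null - D_model)`,
#' where `D_red` is the deviance of the model refitted without the
#' predictor (functional predictors are removed as a block).
#'
#' @param scalar_preds named list of scalar `predictor_spec`s (the selected
#'   subset; may be empty).
#' @param functional_preds named list of functional `predictor_spec`s
#'   (candidates).
#' @param y binary response.
#' @param min_de_gain forward-step DE threshold (default 0.01).
#' @param p_drop backward-elimination p threshold (default 0.05).
#' @return object of class `flr_model`: final `flr_fit` fields plus
#'   `predictors` (those in the final model), `rcde` (named), `table`
#'   (tidy per-term summary) and `log` (step log).
#' @export
stepwise_multiple_flr <- function(scalar_preds, functional_preds, y,
                                  min_de_gain = 0.01, p_drop = 0.05) {
  design_of <- function(preds) {
    if (!length(preds)) return(NULL)
    do.call(cbind, lapply(preds, `[[`, "X"))
  }
  active <- scalar_preds
  cur <- .fit_logistic(design_of(active), y)
  log <- character(0)
  remaining <- functional_preds
  repeat {
    if (!length(remaining)) break
    gains <- vapply(names(remaining), function(nm) {
      f <- tryCatch(.fit_logistic(design_of(c(active, remaining[nm])), y),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) return(c(NA_real_, NA_real_))
      c(f$DE - cur$DE, f$AIC)
    }, numeric(2))
    ok <- which(is.finite(gains[1, ]))
    if (!length(ok)) break
    best <- ok[which.max(gains[1, ok])]
    if (gains[1, best] > min_de_gain && gains[2, best] < cur$AIC) {
      nm <- names(remaining)[best]
      active <- c(active, remaining[nm])
      remaining <- remaining[-best]
      cur <- .fit_logistic(design_of(active), y)
      log <- c(log, sprintf("forward: + %s (dDE = %.4f)", nm,
                            gains[1, best]))
    } else break
  }
  # backward removal of non-significant scalars, worst first
  repeat {
    sc <- names(active)[vapply(active, function(p) p$kind == "scalar",
                               logical(1))]
    if (!length(sc)) break
    cf <- cur$coef
    pv <- vapply(sc, function(nm) {
      row <- which(rownames(cf) %in% c(nm, paste0("`", nm, "`")))
      if (!length(row)) NA_real_ else cf[row[1], 4]
    }, numeric(1))
    worst <- which.max(pv)
    if (is.na(pv[worst]) || pv[worst] < p_drop) break
    log <- c(log, sprintf("backward: - %s (p = %.3f)", sc[worst],
                          pv[worst]))
    active <- active[names(active) != sc[worst]]
    cur <- .fit_logistic(design_of(active), y)
  }
  # RCDE by explicit refit without each remaining predictor
  rcde <- setNames(numeric(length(active)), names(active))
  expl <- cur$D_null - cur$D_model
  for (nm in names(active)) {
    red <- .fit_logistic(design_of(active[names(active) != nm]), y)
    rcde[nm] <- if (expl > 0) (red$D_model - cur$D_model) / expl else 0
  }
  table <- do.call(rbind, lapply(names(active), function(nm) {
    p <- active[[nm]]
    terms <- colnames(p$X)
    rows <- match(terms, rownames(cur$coef))
    rows[is.na(rows)] <- match(paste0("`", terms, "`"),
                               rownames(cur$coef))[is.na(rows)]
    data.frame(predictor = nm, kind = p$kind, term = terms,
               estimate = cur$coef[rows, 1], p_value = cur$coef[rows, 4],
               RCDE = rcde[nm], stringsAsFactors = FALSE)
  }))
  structure(c(cur, list(predictors = names(active), rcde = rcde,
                        table = table, log = log)),
            class = "flr_model")
}

#' @export
print.flr_fit <- function(x, ...) {
  cat(sprintf("flr_fit '%s' (%s): DE = %.4f, AIC = %.1f%s\n", x$predictor,
              x$kind, x$DE, x$AIC,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' @export
print.flr_model <- function(x, ...) {
  cat(sprintf("flr_model: %d predictors, DE = %.4f, AIC = %.1f\n",
              length(x$predictors), x$DE, x$AIC))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
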