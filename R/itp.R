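#' Expand curves on a piecewise-constant basis
#'
#' Curves observed at K windows are represented on an order-1 B-spline
#' (piecewise constant) basis. With `n_coef = K` (65 nodes for K = 64) the
#' coefficients are the raw window values; with `n_coef = K/2` (33 nodes)
#' they are means of adjacent non-overlapping window pairs — a piecewise
#' constant smoothed version of the raw data. More generally any `n_coef`
#' dividing K yields block means.
#'
#' @param values numeric matrix (regions x windows) or a [curve_matrix].
#' @param n_coef number of basis coefficients; must divide the window count.
#' @return list with `coef` (regions x n_coef matrix) and
#'   `component_labels` (character, genomic label range per coefficient).
#' @export
expand_basis <- function(values, n_coef) {
  labs <- NULL
  if (inherits(values, "curve_matrix")) {
    labs <- values$window_labels
    values <- values$values
  }
  K <- ncol(values)
  if (is.null(labs)) labs <- window_labels(K)
  if (K %% n_coef != 0)
    stop("n_coef = ", n_coef, " does not divide window count ", K)
  b <- K / n_coef
  if (b == 1) {
    coef <- values
    cl <- as.character(labs)
  } else {
    grp <- rep(seq_len(n_coef), each = b)
    coef <- t(apply(values, 1, function(r) tapply(r, grp, mean)))
    cl <- vapply(seq_len(n_coef), function(j) {
      rng <- labs[grp == j]
      paste0(rng[1], "..", rng[length(rng)])
    }, character(1))
  }
  dimnames(coef) <- list(rownames(values), cl)
  list(coef = coef, component_labels = cl)
}

# Per-assignment p-value matrix from a statistic matrix: the significance
# level function of each component, evaluated at every synchronized
# assignment.  p[r,k] = fraction of assignments with statistic >= the one of
# assignment r (ties extreme).
.plan_pvalue_matrix <- function(Tm, statistic) {
  A <- if (statistic %in% c("mean_diff", "median_diff")) abs(Tm) else Tm
  R <- nrow(A)
  P <- matrix(1, R, ncol(A))
  flags <- character(0)
  for (k in seq_len(ncol(A))) {
    v <- A[, k]
    if (anyNA(v)) {
      # degenerate component (e.g. variance ratio with both groups
      # constant): contributes p = 1 everywhere
      flags <- c(flags, paste0("component ", k, ": degenerate"))
      next
    }
    # quantize at 1e-9 relative resolution so exact-math ties (e.g.
    # complementary assignments) rank as ties despite FP noise
    u <- max(abs(v))
    if (u > 0 && is.finite(u)) v <- round(v / u * 1e9)
    v[!is.finite(v)] <- max(v[is.finite(v)], 0) + 1
    P[, k] <- (R - rank(v, ties.method = "min") + 1) / R
  }
  list(P = P, flags = flags)
}

# Interval evidence by nonparametric combination of the synchronized
# component p-values, for every contiguous interval [a, b]. The evidence is
# oriented so that larger = more extreme: the Fisher statistic
# -2 * sum(log p), or -min(p) for Tippett. Returns, per interval length:
# the interval p-values, the observed evidence per start, the scan-test
# p-value (permutation p-value of the maximum evidence over starts — an
# exact test of the global null at each scale), and quantiles of the
# permutation scan-max distribution for single-step maxT detection.
.npc_interval_pvalues <- function(P, combining) {
  R <- nrow(P); K <- ncol(P)
  E_of <- switch(combining,
    fisher = {
      L <- -2 * log(pmax(P, .Machine$double.xmin))
      CS <- cbind(0, t(apply(L, 1, cumsum)))
      function(a, len) CS[, a + len] - CS[, a]
    },
    tippett = function(a, len)
      -Reduce(pmin, lapply(a:(a + len - 1), function(j) P[, j])),
    stop("unknown combining function: ", combining))
  probs <- seq(0.5, 1, by = 0.001)
  pint <- stat_obs <- vector("list", K)
  scale_p <- numeric(K)
  scan_q <- matrix(NA_real_, K, length(probs),
                   dimnames = list(NULL, probs))
  for (len in seq_len(K)) {
    starts <- seq_len(K - len + 1)
    pv <- so <- numeric(length(starts))
    smax <- rep(-Inf, R)
    for (a in starts) {
      e <- E_of(a, len)
      pv[a] <- mean(e >= e[1] - 1e-10)   # exact-math ties are extreme
      so[a] <- e[1]
      smax <- pmax(smax, e)
    }
    pint[[len]] <- pv
    stat_obs[[len]] <- so
    scale_p[len] <- mean(smax >= smax[1] - 1e-10)
    scan_q[len, ] <- quantile(smax, probs, type = 1, names = FALSE)
  }
  list(pint = pint, stat_obs = stat_obs, scale_p = scale_p, scan_q = scan_q)
}

# Adjusted p-value matrix A(L, k): maximum interval p-value over all
# intervals of length <= L containing component k.  Row L = 1 is the raw
# component p-values; row K reproduces the original single-scale adjustment.
.adjust_matrix <- function(pint, K) {
  Mlen <- matrix(0, K, K)
  for (len in seq_len(K)) {
    for (a in seq_len(K - len + 1)) {
      idx <- a:(a + len - 1)
      Mlen[len, idx] <- pmax(Mlen[len, idx], pint[[len]][a])
    }
  }
  A <- Mlen
  if (K >= 2)
    for (L in 2:K) A[L, ] <- pmax(A[L - 1, ], Mlen[L, ])
  dimnames(A) <- list(L = seq_len(K), k = seq_len(K))
  A
}

#' Extended Interval Testing Procedure for two samples of curves
#'
#' Runs synchronized two-sample permutation tests on every basis component,
#' combines them with the Nonparametric Combination over every contiguous
#' component interval (no wrap-around: flanking regions are linear), and
#' adjusts for family-wise error at every maximum interval length L: the
#' adjusted p-value `A(L, k)` is the maximum interval p-value over all
#' intervals of length at most L that contain component k. `A(1, k)` is the
#' raw component p-value and `A(K, k)` reproduces the original
#' all-intervals adjustment.
#'
#' @param x1,x2 coefficient matrices (group x components), same column
#'   count.
#' @param cfg a [perm_config()]; the same permutation plan is applied to all
#'   components and statistics (synchronized).
#' @param combining NPC combining function: `"fisher"` (default,
#'   `-2 * sum(log p)`) or `"tippett"` (min-p).
#' @param component_labels optional labels for components.
#' @param feature_name recorded in the result.
#' @param plan optional pre-built [make_plan()].
#' @return object of class `itp_result`: per statistic, the component
#'   p-values, interval p-values by length, the `A(L, k)` matrix, observed
#'   signs, and degeneracy flags.
#' @export
itp_test <- function(x1, x2, cfg = perm_config(), combining = "fisher",
                     component_labels = NULL, feature_name = "feature",
                     plan = NULL) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  stopifnot(ncol(x1) == ncol(x2), nrow(x1) >= 2, nrow(x2) >= 2)
  K <- ncol(x1)
  X <- rbind(x1, x2)
  if (is.null(plan)) plan <- make_plan(nrow(x1), nrow(x2), cfg)
  if (is.null(component_labels)) component_labels <- as.character(seq_len(K))
  stats_out <- list()
  for (st in cfg$statistics) {
    Tm <- perm_stat_matrix(X, plan, st)
    pp <- .plan_pvalue_matrix(Tm, st)
    npc <- .npc_interval_pvalues(pp$P, combining)
    pint <- npc$pint
    A <- .adjust_matrix(pint, K)
    signs <- if (st == "var_ratio") {
      v1 <- apply(x1, 2, var); v2 <- apply(x2, 2, var)
      sign(v1 - v2)
    } else sign(Tm[1, ])
    stats_out[[st]] <- list(component_p = pint[[1]], interval_p = pint,
                            interval_stat = npc$stat_obs,
                            scale_p = npc$scale_p, scan_q = npc$scan_q,
                            adj = A, signs = signs, flags = pp$flags)
  }
  structure(list(feature_name = feature_name, K = K,
                 component_labels = component_labels,
                 statistics = stats_out, combining = combining,
                 n1 = nrow(x1), n2 = nrow(x2),
                 n_perm = nrow(plan$membership),
                 exhaustive = plan$exhaustive, seed = cfg$seed),
            class = "itp_result")
}

#' Run the ITP on a curve matrix with group labels
#'
#' Convenience wrapper: expands the basis, splits rows by label (first level
#' = group 1) and calls [itp_test()].
#'
#' @param cm a [curve_matrix].
#' @param labels two-level factor aligned with curve rows.
#' @param n_coef basis size (`ncol` for raw, `ncol/2` for the paired
#'   smoothing).
#' @inheritParams itp_test
#' @return an `itp_result`.
#' @export
itp_curves <- function(cm, labels, n_coef = NULL, cfg = perm_config(),
                       combining = "fisher") {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, length(labels) == nrow(cm$values))
  if (is.null(n_coef)) n_coef <- ncol(cm$values)
  eb <- expand_basis(cm, n_coef)
  g1 <- labels == levels(labels)[1]
  itp_test(eb$coef[g1, , drop = FALSE], eb$coef[!g1, , drop = FALSE],
           cfg = cfg, combining = combining,
           component_labels = eb$component_labels,
           feature_name = cm$feature_name)
}

#' Classify a feature from its adjusted p-value matrix
#'
#' The feature-level call combines exact scan tests across a dyadic ladder
#' of scales: at each maximum interval length L, the scan statistic (the
#' maximum NPC statistic over all length-L interval starts) gives an exact
#' permutation p-value for the whole-curve null, and the feature is
#' significant when any ladder scale (1, 2, 4, ..., K) rejects at the
#' Bonferroni-corrected level `alpha / |ladder|`. Null features are thus
#' called NS at (at most) the nominal rate, while sharply localized effects
#' are caught by the fine scales and distributed shifts by the coarse ones.
#' A significant feature is an invariant differential landscape (IDL) signal
#' when every component also survives the full adjustment
#' (`A(K, k) < alpha` for all k), and a localized differential landscape
#' (LDL) signal otherwise. For LDL features the reported component support
#' is FWER-controlled at a data-proposed scale: the raw component scan
#' (`A(1, k) < alpha`) proposes `L_hat`, the length of its longest
#' contiguous significant run, and a component belongs to the support when
#' it is raw-significant and covered by a length-`L_hat` interval whose NPC
#' evidence exceeds the `1 - alpha` quantile of the permutation scan-max
#' distribution (single-step maxT detection, so under the null the support
#' is empty with probability at least `1 - alpha`). The feature's scale
#' `L*` — the largest maximum interval length at which any component
#' remains significant in `A` — is reported alongside. Passing `L_star`
#' overrides the support scale with a user choice.
#'
#' @param res an `itp_result`.
#' @param statistic which test statistic to classify on.
#' @param alpha significance level (default 0.05).
#' @param L_star optional user-chosen support scale; default as described.
#' @return list with `class` (`"IDL"`, `"LDL"` or `"NS"`), `global_p`,
#'   `L_star` (max significant scale), `L_support` (scale of the reported
#'   support), `significant` (logical per component), and `signs`.
#' @export
classify_feature <- function(res, statistic = "mean_diff", alpha = 0.05,
                             L_star = NULL) {
  stopifnot(inherits(res, "itp_result"), statistic %in% names(res$statistics))
  st <- res$statistics[[statistic]]
  A <- st$adj
  K <- res$K
  sig <- A < alpha
  ladder <- unique(c(2^(0:floor(log2(K))), K))
  global_p <- min(st$scale_p[ladder]) * length(ladder)
  any_by_L <- apply(sig, 1, any)
  L_max <- if (any(any_by_L)) max(which(any_by_L)) else 0L
  if (global_p >= alpha) {
    return(list(class = "NS", global_p = global_p, L_star = 0L,
                L_support = 0L, significant = rep(FALSE, K),
                signs = st$signs))
  }
  if (all(sig[K, ])) {
    return(list(class = "IDL", global_p = global_p, L_star = as.integer(K),
                L_support = as.integer(K), significant = rep(TRUE, K),
                signs = st$signs))
  }
  raw <- sig[1, ]
  if (is.null(L_star)) {
    runs <- rle(raw)
    L_hat <- if (any(raw)) max(runs$lengths[runs$values]) else 0L
  } else L_hat <- L_star
  s <- rep(FALSE, K)
  if (L_hat >= 1) {
    qs <- st$scan_q[L_hat, ]
    pgrid <- as.numeric(colnames(st$scan_q))
    crit <- qs[which.min(abs(pgrid - (1 - alpha)))]
    hit <- which(st$interval_stat[[L_hat]] >= crit)
    covered <- rep(FALSE, K)
    for (a in hit) covered[a:(a + L_hat - 1)] <- TRUE
    s <- raw & covered
  }
  list(class = "LDL", global_p = global_p, L_star = as.integer(L_max),
       L_support = as.integer(L_hat), significant = s, signs = st$signs)
}

#' Export an ITP result as a plot-ready long table
#'
#' One row per (statistic, maximum length L, component k): the adjusted
#' p-value and the sign of the observed component statistic. This is the
#' machine-readable analogue of the significance heatmaps.
#'
#' @param res an `itp_result`.
#' @param path optional TSV output path.
#' @return data.frame (invisibly written to `path` when given).
#' @export
export_heatmap <- function(res, path = NULL) {
  stopifnot(inherits(res, "itp_result"))
  out <- do.call(rbind, lapply(names(res$statistics), function(st) {
    A <- res$statistics[[st]]$adj
    data.frame(feature = res$feature_name, statistic = st,
               L = rep(seq_len(res$K), res$K),
               k = rep(seq_len(res$K), each = res$K),
               window = rep(res$component_labels, each = res$K),
               adj_p = as.vector(A),
               sign = rep(res$statistics[[st]]$signs, each = res$K),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' @export
print.itp_result <- function(x, ...) {
  cat(sprintf("itp_result '%s': K = %d, n = %d + %d, %s plan (%d), NPC = %s\n",
              x$feature_name, x$K, x$n1, x$n2,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm,
              x$combining))
  for (st in names(x$statistics)) {
    cl <- classify_feature(x, st)
    cat(sprintf("  %-12s min A(K,k) = %.4g  class = %s (L* = %d)\n", st,
                min(x$statistics[[st]]$adj[x$K, ]), cl$class, cl$L_star))
  }
  invisible(x)
}
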