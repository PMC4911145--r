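#' Permutation-test configuration
#'
#' @param n_perm number of permutations (default 10000; at least 100 for
#'   reported p-values).
#' @param statistics subset of `mean_diff`, `median_diff`, `var_ratio`. All
#'   tests are two-sided: absolute difference for mean/median, and the
#'   variance ratio is oriented larger/smaller before comparison.
#' @param seed RNG seed for the sampled permutation plan.
#' @param include_observed keep the identity assignment in the reference set
#'   (guarantees valid p-values, p >= 1/n_perm).
#' @param exhaustive_limit use the exhaustive plan (all distinct group
#'   assignments) when `n1 + n2` is at most this (default 10).
#' @return object of class `perm_config`.
#' @export
perm_config <- function(n_perm = 10000,
                        statistics = c("mean_diff", "median_diff",
                                       "var_ratio"),
                        seed = 1L, include_observed = TRUE,
                        exhaustive_limit = 10) {
  statistics <- match.arg(statistics, c("mean_diff", "median_diff",
                                        "var_ratio"), several.ok = TRUE)
  if (n_perm < 100) warning("n_perm < 100: p-values too coarse to report")
  structure(list(n_perm = as.integer(n_perm), statistics = statistics,
                 alternative = "two_sided", seed = as.integer(seed),
                 include_observed = isTRUE(include_observed),
                 exhaustive_limit = as.integer(exhaustive_limit)),
            class = "perm_config")
}

#' Build a (possibly exhaustive) permutation plan
#'
#' A plan is the set of group-1 assignments reused across all components of a
#' curve ("synchronized" permutations) and across test statistics. Row 1 is
#' always the observed (identity) assignment. For `n1 + n2` up to
#' `cfg$exhaustive_limit` all `choose(n1+n2, n1)` distinct assignments are
#' enumerated; otherwise `n_perm` assignments are sampled (the identity
#' replacing the first draw when `include_observed`).
#'
#' @param n1,n2 group sizes.
#' @param cfg a [perm_config()].
#' @return object of class `perm_plan`: logical membership matrix
#'   (rows = assignments, columns = samples; TRUE = group 1) plus metadata.
#' @export
make_plan <- function(n1, n2, cfg = perm_config()) {
  stopifnot(n1 >= 2, n2 >= 2)
  n <- n1 + n2
  if (n <= cfg$exhaustive_limit) {
    sets <- combn(n, n1)
    M <- matrix(FALSE, ncol(sets), n)
    M[cbind(rep(seq_len(ncol(sets)), each = n1), as.vector(sets))] <- TRUE
    obs <- which(apply(M[, seq_len(n1), drop = FALSE], 1, all))[1]
    M <- M[c(obs, setdiff(seq_len(nrow(M)), obs)), , drop = FALSE]
    exhaustive <- TRUE
  } else {
    M <- with_seed(cfg$seed, {
      m <- matrix(FALSE, cfg$n_perm, n)
      for (r in seq_len(cfg$n_perm)) m[r, sample.int(n, n1)] <- TRUE
      m
    })
    if (cfg$include_observed) M[1, ] <- rep(c(TRUE, FALSE), c(n1, n2))
    exhaustive <- FALSE
  }
  structure(list(membership = M, n1 = n1, n2 = n2, exhaustive = exhaustive,
                 seed = cfg$seed),
            class = "perm_plan")
}

# Test-statistic matrices over a plan: one row per assignment, one column per
# component of X (n x K). mean and variance statistics are fully vectorized
# through cross-products; the median requires a per-assignment pass.
perm_stat_matrix <- function(X, plan, statistic) {
  X <- as.matrix(X)
  M <- plan$membership * 1
  n1 <- plan$n1; n2 <- plan$n2
  if (statistic == "mean_diff") {
    S1 <- M %*% X
    tot <- matrix(colSums(X), nrow(M), ncol(X), byrow = TRUE)
    return(S1 / n1 - (tot - S1) / n2)
  }
  if (statistic == "var_ratio") {
    S1 <- M %*% X
    Q1 <- M %*% X^2
    tot <- matrix(colSums(X), nrow(M), ncol(X), byrow = TRUE)
    qtot <- matrix(colSums(X^2), nrow(M), ncol(X), byrow = TRUE)
    v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
    v2 <- ((qtot - Q1) - (tot - S1)^2 / n2) / (n2 - 1)
    v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)     # guard tiny negatives
    r <- ifelse(v1 == 0 & v2 == 0, NaN, pmax(v1, v2) / pmin(v1, v2))
    return(r)
  }
  if (statistic == "median_diff") {
    out <- matrix(NA_real_, nrow(M), ncol(X))
    for (r in seq_len(nrow(M))) {
      g1 <- plan$membership[r, ]
      out[r, ] <- apply(X[g1, , drop = FALSE], 2, median) -
        apply(X[!g1, , drop = FALSE], 2, median)
    }
    return(out)
  }
  stop("unknown statistic: ", statistic)
}

# p-value column-wise from a statistic matrix whose first row is the observed
# assignment: p_k = fraction of assignments with a statistic at least as
# extreme (ties count as extreme). Degenerate columns (all NaN, from a
# variance ratio with both groups constant) return NA.
.perm_pvalues_from_stats <- function(Tm, statistic) {
  A <- if (statistic %in% c("mean_diff", "median_diff")) abs(Tm) else Tm
  vapply(seq_len(ncol(A)), function(k) {
    v <- A[, k]
    if (is.na(v[1])) return(NA_real_)   # observed statistic undefined
    # ties within FP noise count as extreme: complementary assignments are
    # exact-math ties whose dot products can differ in the last ulp
    eps <- 1e-9 * max(abs(v[is.finite(v)]), 1)
    mean(v >= v[1] - eps, na.rm = TRUE)
  }, numeric(1))
}

#' Two-sample univariate permutation test
#'
#' Tests equality of the two distributions with the configured statistics.
#' "More extreme" is implemented as `>=` on the absolute (mean/median
#' difference) or the larger/smaller-oriented (variance ratio) statistic,
#' with the observed assignment in the reference set, so p-values are valid
#' and bounded below by 1/n_perm. When both groups have zero variance the
#' variance-ratio p-value is undefined and returned as NA with a flag.
#'
#' @param x1,x2 numeric samples (each at least 2 values).
#' @param cfg a [perm_config()].
#' @param plan optional pre-built [make_plan()] (for synchronized reuse).
#' @return list with `p` (named p-values per statistic), `observed` (named
#'   observed statistics), `flags` (character vector of degeneracies), and
#'   `plan`.
#' @export
univariate_perm_test <- function(x1, x2, cfg = perm_config(), plan = NULL) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (is.null(plan)) plan <- make_plan(length(x1), length(x2), cfg)
  X <- matrix(c(x1, x2), ncol = 1)
  p <- obs <- setNames(numeric(length(cfg$statistics)), cfg$statistics)
  flags <- character(0)
  for (st in cfg$statistics) {
    Tm <- perm_stat_matrix(X, plan, st)
    pv <- .perm_pvalues_from_stats(Tm, st)
    if (is.na(pv)) flags <- c(flags, paste0(st, ":degenerate"))
    p[st] <- pv
    obs[st] <- Tm[1, 1]
  }
  list(p = p, observed = obs, flags = flags, plan = plan)
}
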