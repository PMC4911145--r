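# Independent brute-force oracles. These deliberately share no code with the
# package internals: per-base boolean arrays for quantification, full
# enumeration of label assignments for permutation tests and the interval
# testing procedure.

# --- quantification oracles (single chromosome, 0-based half-open) --------

oracle_content <- function(track, wstart, wend) {
  if (nrow(track) == 0) return(0)
  covered <- rep(FALSE, wend - wstart)
  for (i in seq_len(nrow(track))) {
    a <- max(track$start[i], wstart); b <- min(track$end[i], wend)
    if (a < b) covered[(a - wstart + 1):(b - wstart)] <- TRUE
  }
  mean(covered)
}

oracle_count <- function(track, wstart, wend) {
  if (nrow(track) == 0) return(0)
  sum(track$start >= wstart & track$start < wend)
}

oracle_wa <- function(track, wstart, wend) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(track))) {
    a <- max(track$start[i], wstart); b <- min(track$end[i], wend)
    if (a < b) { num <- num + track$value[i] * (b - a); den <- den + (b - a) }
  }
  if (den == 0) NA_real_ else num / den
}

# --- exhaustive permutation-test oracle -----------------------------------

oracle_stat <- function(a, b, statistic) {
  switch(statistic,
         mean_diff = mean(a) - mean(b),
         median_diff = median(a) - median(b),
         var_ratio = {
           va <- var(a); vb <- var(b)
           if (va == 0 && vb == 0) NA_real_
           else max(va, vb) / min(va, vb)
         })
}

oracle_perm_p <- function(x1, x2, statistic) {
  n1 <- length(x1); n <- n1 + length(x2)
  pool <- c(x1, x2)
  sets <- combn(n, n1)
  tt <- apply(sets, 2, function(idx)
    oracle_stat(pool[idx], pool[-idx], statistic))
  obs <- oracle_stat(x1, x2, statistic)
  if (statistic != "var_ratio") { tt <- abs(tt); obs <- abs(obs) }
  mean(tt >= obs)
}

# --- exhaustive extended-ITP oracle ---------------------------------------
# Enumerates all choose(n, n1) assignments, computes the per-assignment
# p-value of every component, Fisher-combines every contiguous interval, and
# assembles A(L, k) and the per-scale scan p-values by direct loops.

oracle_itp <- function(x1, x2, statistic = "mean_diff") {
  n1 <- nrow(x1)
  X <- rbind(x1, x2)
  n <- nrow(X); K <- ncol(X)
  sets <- combn(n, n1)
  R <- ncol(sets)
  obs_col <- which(apply(sets, 2, function(s) all(s == seq_len(n1))))
  Tm <- matrix(NA_real_, R, K)
  for (r in seq_len(R))
    for (k in seq_len(K))
      Tm[r, k] <- oracle_stat(X[sets[, r], k], X[-sets[, r], k], statistic)
  if (statistic != "var_ratio") Tm <- abs(Tm)
  P <- matrix(NA_real_, R, K)
  for (r in seq_len(R))
    for (k in seq_len(K))
      P[r, k] <- mean(Tm[, k] >= Tm[r, k])
  pint <- vector("list", K)
  scale_p <- numeric(K)
  for (len in seq_len(K)) {
    starts <- seq_len(K - len + 1)
    pv <- numeric(length(starts))
    emax <- rep(-Inf, R)
    for (a in starts) {
      e <- vapply(seq_len(R), function(r)
        -2 * sum(log(P[r, a:(a + len - 1)])), numeric(1))
      pv[a] <- mean(e >= e[obs_col])
      emax <- pmax(emax, e)
    }
    pint[[len]] <- pv
    scale_p[len] <- mean(emax >= emax[obs_col])
  }
  A <- matrix(NA_real_, K, K)
  for (L in seq_len(K))
    for (k in seq_len(K)) {
      worst <- 0
      for (len in seq_len(L))
        for (a in seq_len(K - len + 1))
          if (a <= k && k <= a + len - 1)
            worst <- max(worst, pint[[len]][a])
      A[L, k] <- worst
    }
  list(A = A, component_p = P[obs_col, ], interval_p = pint,
       scale_p = scale_p)
}

# small deterministic curve-matrix fixture
toy_curves <- function(n = 10, K = 8, seed = 1, shift = 0, windows = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(2 * n * K), 2 * n, K)
  if (shift != 0) {
    w <- windows %||% seq_len(K)
    v[seq_len(n), w] <- v[seq_len(n), w] + shift
  }
  labels <- factor(rep(c("g1", "g2"), each = n))
  list(cm = curve_matrix("toy", "weighted_average", v), labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
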