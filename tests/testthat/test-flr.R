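# deterministic logistic-data generator for recovery tests
gen_logit <- function(n, beta, seed, x = NULL) {
  set.seed(seed)
  if (is.null(x)) x <- rnorm(n)
  p <- plogis(beta * x)
  list(x = x, y = rbinom(n, 1, p))
}

test_that("shifted-log: trigger, improvement on lognormal, degenerate", {
  set.seed(1)
  g <- factor(rep(c("a", "b"), each = 250))
  # already-gaussian data: trigger not met, returned untouched
  x <- rnorm(500)
  tr <- shifted_log(x, g)
  expect_false(tr$applied)
  expect_identical(tr$values, x)
  # lognormal: transform applied and Shapiro-Wilk p improves in both groups
  xl <- exp(rnorm(500))
  tr2 <- shifted_log(xl, g)
  expect_true(tr2$applied)
  swp <- function(v, gg) tapply(v, gg, function(z) shapiro.test(z)$p.value)
  expect_true(all(swp(tr2$values, g) > swp(xl, g)))
  # constant: degenerate, skipped with warning
  expect_warning(tr3 <- shifted_log(rep(2, 500), g), "constant")
  expect_false(tr3$applied)
})

test_that("single fit: null DE ~ 0, intercept-only DE = 0, recovery of beta", {
  d0 <- gen_logit(2000, 0, seed = 2)
  f0 <- fit_single(matrix(d0$x, ncol = 1,
                          dimnames = list(NULL, "z")), d0$y)
  expect_lt(f0$DE, 0.005)
  # intercept-only: DE exactly 0 by definition of the null deviance
  fi <- flankfda:::.fit_logistic(NULL, d0$y)
  expect_identical(fi$DE, 0)
  d <- gen_logit(5000, 1.5, seed = 3)
  f <- fit_single(matrix(d$x, ncol = 1, dimnames = list(NULL, "z")), d$y)
  expect_lt(abs(f$coef["z", 1] - 1.5), 0.15)
})

test_that("perfect separation is flagged", {
  x <- c(rnorm(50, -3), rnorm(50, 3))
  y <- rep(c(0, 1), each = 50)
  f <- fit_single(matrix(x, ncol = 1, dimnames = list(NULL, "z")), y)
  expect_true(f$separation)
})

test_that("dominance screen uses a strict threshold", {
  de <- c(a = 0.25, b = 0.20, c = 0.05)
  out <- screen_dominant(de, threshold = 0.20)
  expect_equal(out$dominant, "a")
  expect_setequal(out$retained, c("b", "c"))
})

test_that("LASSO: selection accuracy with informative + noise scalars", {
  set.seed(4)
  res <- t(sapply(1:8, function(s) {
    set.seed(100 + s)
    n <- 2000
    Z <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0(rep(c("inf", "noi"),
                                                 c(5, 15)),
                                             c(1:5, 1:15))))
    eta <- Z[, 1:5] %*% rep(0.6, 5)
    y <- rbinom(n, 1, plogis(eta))
    sel <- select_scalars_lasso(Z, y, seed = s)$selected
    c(inf = sum(grepl("^inf", sel)), noi = sum(grepl("^noi", sel)))
  }))
  expect_gte(median(res[, "inf"]), 4)
  expect_lte(median(res[, "noi"]), 3)
})

test_that("LASSO degenerate cases: single predictor, duplicated pair", {
  set.seed(5)
  n <- 1500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x))
  out1 <- select_scalars_lasso(matrix(x, ncol = 1,
                                      dimnames = list(NULL, "z")), y,
                               seed = 1)
  expect_equal(out1$selected, "z")
  # pure-noise single predictor is typically dropped
  y0 <- rbinom(n, 1, 0.5)
  out0 <- select_scalars_lasso(matrix(x, ncol = 1,
                                      dimnames = list(NULL, "z")), y0,
                               seed = 1)
  expect_length(out0$selected, 0)
  # duplicated predictor: at most one survives in most seeds
  dup <- sapply(1:10, function(s) {
    Z <- cbind(a = x, b = x, c = rnorm(n))
    length(intersect(select_scalars_lasso(Z, y, seed = s)$selected,
                     c("a", "b")))
  })
  expect_gte(mean(dup <= 1), 0.9)
})

test_that("predictor construction maps ITP classes to specs", {
  spec <- sim_spec(60, 60, n_windows = 16, seed = 41, features = list(
    feature_spec("idl", effect_kind = "idl", effect_size = 1.5,
                 noise_sd = 0.5),
    feature_spec("ldl", effect_kind = "ldl", effect_size = 2,
                 effect_window_range = c(7, 9), noise_sd = 0.5),
    feature_spec("nul", noise_sd = 0.5)))
  sim <- simulate_curves(spec)
  cfg <- perm_config(n_perm = 500, statistics = "mean_diff", seed = 2)
  itp <- lapply(sim$curves, itp_curves, labels = sim$labels, cfg = cfg)
  preds <- build_predictors(itp, sim$curves)
  expect_equal(preds$idl$kind, "scalar")
  expect_equal(unname(preds$idl$X[, 1]),
               unname(rowMeans(sim$curves$idl$values)))
  expect_equal(preds$ldl$kind, "functional")
  expect_false("nul" %in% names(preds))
  # sub-intervals partition the flank with width <= L*
  lay <- preds$ldl$intervals
  expect_equal(lay[[1]][1], 1)
  expect_equal(lay[[length(lay)]][2], 16)
  widths <- vapply(lay, function(r) r[2] - r[1] + 1, numeric(1))
  cl <- classify_feature(itp$ldl)
  expect_true(all(widths <= max(cl$L_support, 1)))
  # explicit layout override
  preds2 <- build_predictors(itp, sim$curves,
                             layouts = list(ldl = list(c(1, 8), c(9, 16))))
  expect_equal(ncol(preds2$ldl$X), 2)
  expect_equal(unname(preds2$ldl$X[, 1]),
               unname(rowMeans(sim$curves$ldl$values[, 1:8])))
})

test_that("default_layout covers the flank with widths <= L*", {
  lay <- default_layout(64, 20)
  expect_equal(lay[[1]][1], 1)
  expect_equal(lay[[length(lay)]][2], 64)
  expect_equal(length(lay), 4)
  w <- vapply(lay, function(r) r[2] - r[1] + 1, numeric(1))
  expect_true(all(w <= 20))
  expect_equal(sum(w), 64)
})

test_that("stepwise: empty forward step keeps the scalar model; RCDE checks", {
  set.seed(6)
  n <- 800
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(z))
  sp <- structure(list(name = "z", kind = "scalar",
                       X = matrix(z, ncol = 1,
                                  dimnames = list(NULL, "z")),
                       intervals = NULL, class = "low_res"),
                  class = "predictor_spec")
  noisef <- structure(list(name = "f", kind = "functional",
                           X = matrix(rnorm(2 * n), n, 2,
                                      dimnames = list(NULL,
                                                      c("f[1..4]",
                                                        "f[5..8]"))),
                           intervals = list(c(1, 4), c(5, 8)),
                           class = "LDL"),
                      class = "predictor_spec")
  m <- stepwise_multiple_flr(list(z = sp), list(f = noisef), y)
  expect_equal(m$predictors, "z")
  # RCDE recomputation by explicit refit matches to 1e-10
  red <- flankfda:::.fit_logistic(NULL, y)
  rcde_manual <- (red$D_model - m$D_model) / (m$D_null - m$D_model)
  expect_equal(unname(m$rcde["z"]), rcde_manual, tolerance = 1e-10)
})

test_that("stepwise recovers a localized functional effect", {
  hits <- sapply(1:10, function(s) {
    set.seed(200 + s)
    n <- 600
    K <- 16
    curves <- matrix(rnorm(n * K), n, K)
    # true effect: mean over windows 7..9 drives the response
    eta <- 1.8 * rowMeans(curves[, 7:9])
    y <- rbinom(n, 1, plogis(eta))
    mkf <- function(nm, win) {
      X <- vapply(win, function(r) rowMeans(curves[, r[1]:r[2]]),
                  numeric(n))
      colnames(X) <- sprintf("%s[%d..%d]", nm,
                             vapply(win, `[`, numeric(1), 1),
                             vapply(win, `[`, numeric(1), 2))
      structure(list(name = nm, kind = "functional", X = X,
                     intervals = win, class = "LDL"),
                class = "predictor_spec")
    }
    win <- list(c(1, 4), c(5, 8), c(9, 12), c(13, 16))
    true_f <- mkf("true", list(c(7, 9)))
    noise1 <- mkf("n1", win)
    set.seed(300 + s)
    noise2 <- mkf("n2", list(c(1, 8), c(9, 16)))
    noise2$X[] <- rnorm(length(noise2$X))
    m <- stepwise_multiple_flr(list(), list(true = true_f, n1 = noise1,
                                            n2 = noise2), y)
    added_first <- length(m$log) > 0 && grepl("\\+ true", m$log[1])
    sig <- "true" %in% m$predictors &&
      m$table$p_value[m$table$predictor == "true"][1] < 0.05
    added_first && sig
  })
  expect_gte(mean(hits), 0.9)
})

test_that("DE nesting: adding a predictor never decreases DE", {
  set.seed(7)
  n <- 400
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * z1))
  f1 <- flankfda:::.fit_logistic(matrix(z1, ncol = 1,
                                        dimnames = list(NULL, "z1")), y)
  f12 <- flankfda:::.fit_logistic(cbind(z1 = z1, z2 = z2), y)
  expect_gte(f12$DE, f1$DE - 1e-12)
})

test_that("collinear positive predictors can flip sign in the joint fit", {
  set.seed(8)
  n <- 4000
  u <- rnorm(n)
  a <- u + rnorm(n, sd = 0.15)
  b <- u + rnorm(n, sd = 0.15)
  # response driven by a - 0.5 b, yet both correlate positively with y
  y <- rbinom(n, 1, plogis(1.5 * a - 0.75 * b))
  expect_gt(cor(a, y), 0)
  expect_gt(cor(b, y), 0)
  f <- flankfda:::.fit_logistic(cbind(a = a, b = b), y)
  expect_gt(f$coef["a", 1], 0)
  expect_lt(f$coef["b", 1], 0)
})
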