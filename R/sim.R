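#' Specify one simulated feature
#'
#' A feature is a latent Gaussian AR(1) process along the windows, to which a
#' group-1 mean shift is added (everywhere for `idl`, only inside
#' `effect_window_range` for `ldl`, nowhere for `null`), and which is then
#' pushed through a marginal transform respecting the measure:
#' \itemize{
#'   \item `gaussian`: identity. For `content` the baseline and shifted means
#'     must stay in `[0,1]`; draws are clipped to the bounds.
#'   \item `lognormal`: `exp(latent)`, right-skewed; the shift acts on the
#'     log scale.
#'   \item `beta_like`: inverse-logit of the latent, bounded in `(0,1)`; the
#'     shift acts on the logit scale.
#' }
#' `count` features are rounded to non-negative integers after the transform.
#' The stated mean shift is therefore exact on the latent (Gaussian) scale
#' and monotone-preserved through the transforms.
#'
#' @param name feature identifier (also seeds the feature's RNG stream).
#' @param measure `content`, `count` or `weighted_average`.
#' @param effect_kind `null`, `idl` (invariant shift at every window) or
#'   `ldl` (localized bump).
#' @param effect_size latent mean shift delta of group 1 vs group 2.
#' @param effect_window_range integer pair of window positions (1..K),
#'   required iff `effect_kind = "ldl"`.
#' @param marginal `gaussian`, `lognormal` or `beta_like`.
#' @param baseline latent baseline mean (default 0; 0.5 for gaussian
#'   content).
#' @param noise_sd latent stationary standard deviation (> 0).
#' @param autocorrelation AR(1) coefficient along windows, in `[0, 1)`;
#'   default 0.3 (genomic signals are locally correlated).
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(name, measure = "weighted_average",
                         effect_kind = "null", effect_size = 0,
                         effect_window_range = NULL, marginal = "gaussian",
                         baseline = NULL, noise_sd = 1,
                         autocorrelation = 0.3) {
  measure <- match.arg(measure, c("content", "count", "weighted_average"))
  effect_kind <- match.arg(effect_kind, c("null", "idl", "ldl"))
  marginal <- match.arg(marginal, c("gaussian", "lognormal", "beta_like"))
  if (noise_sd <= 0) stop("noise_sd must be > 0 for feature ", name)
  if (autocorrelation < 0 || autocorrelation >= 1)
    stop("autocorrelation must be in [0,1) for feature ", name)
  if (effect_kind == "ldl") {
    if (is.null(effect_window_range) || length(effect_window_range) != 2)
      stop("effect_window_range required for ldl feature ", name)
  } else if (!is.null(effect_window_range)) {
    stop("effect_window_range only valid for ldl feature ", name)
  }
  if (is.null(baseline))
    baseline <- if (measure == "content" && marginal == "gaussian") 0.5 else 0
  structure(list(name = name, measure = measure, effect_kind = effect_kind,
                 effect_size = effect_size,
                 effect_window_range = effect_window_range,
                 marginal = marginal, baseline = baseline,
                 noise_sd = noise_sd, autocorrelation = autocorrelation),
            class = "feature_spec")
}

#' Specify a two-group simulation
#'
#' @param n_group1,n_group2 group sizes (each at least 2).
#' @param n_windows number of windows K (even, default 64).
#' @param features list of [feature_spec()] objects.
#' @param seed base seed; each feature draws from its own stream derived
#'   from `(seed, feature name)`, so adding a feature never perturbs the
#'   draws of the others.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_group1, n_group2, n_windows = 64, features, seed = 1L) {
  if (n_group1 < 2 || n_group2 < 2) stop("group sizes must be >= 2")
  if (n_windows < 2 || n_windows %% 2 != 0)
    stop("n_windows must be even and >= 2")
  stopifnot(length(features) >= 1,
            all(vapply(features, inherits, logical(1), "feature_spec")))
  nms <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate feature names")
  for (f in features) .validate_feature(f, n_windows)
  structure(list(n_group1 = n_group1, n_group2 = n_group2,
                 n_windows = n_windows, features = setNames(features, nms),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.validate_feature <- function(f, K) {
  if (f$effect_kind == "ldl") {
    r <- f$effect_window_range
    if (r[1] < 1 || r[2] > K || r[1] > r[2])
      stop("effect_window_range outside [1, ", K, "] for feature ", f$name)
  }
  if (f$measure == "content" && f$marginal == "gaussian") {
    hi <- f$baseline + max(0, f$effect_size)
    lo <- f$baseline + min(0, f$effect_size)
    if (lo < 0 || hi > 1)
      stop("content mean shift leaves [0,1] for feature ", f$name)
  }
}

# Latent AR(1) Gaussian matrix, stationary with marginal sd `sdev`.
.ar1_matrix <- function(n, K, rho, sdev) {
  z <- matrix(rnorm(n * K), n, K)
  if (rho > 0 && K > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (k in 2:K) z[, k] <- rho * z[, k - 1] + innov_sd * z[, k]
  }
  z * sdev
}

.apply_marginal <- function(latent, f) {
  x <- switch(f$marginal,
              gaussian = latent,
              lognormal = exp(latent),
              beta_like = stats::plogis(latent))
  if (f$measure == "content") x <- pmin(pmax(x, 0), 1)
  if (f$measure == "count") x <- pmax(round(x), 0)
  x
}

#' Simulate labeled groups of curve matrices
#'
#' @param spec a [sim_spec()].
#' @return list with `curves` (named list of [curve_matrix]) and `labels`
#'   (factor of `"group1"`/`"group2"`, aligned with curve rows; group 1 rows
#'   first).
#' @export
simulate_curves <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n1 <- spec$n_group1; n2 <- spec$n_group2; K <- spec$n_windows
  labels <- factor(rep(c("group1", "group2"), c(n1, n2)),
                   levels = c("group1", "group2"))
  ids <- sprintf("r%04d", seq_len(n1 + n2))
  curves <- lapply(spec$features, function(f) {
    latent <- with_seed(derive_seed(spec$seed, paste0("curves::", f$name)),
                        .ar1_matrix(n1 + n2, K, f$autocorrelation, f$noise_sd))
    shift <- numeric(K)
    if (f$effect_kind == "idl") shift[] <- f$effect_size
    if (f$effect_kind == "ldl") {
      r <- f$effect_window_range
      shift[r[1]:r[2]] <- f$effect_size
    }
    latent <- latent + f$baseline +
      outer(as.numeric(labels == "group1"), shift)
    curve_matrix(f$name, f$measure, .apply_marginal(latent, f),
                 region_ids = ids, window_labels = window_labels(K))
  })
  list(curves = curves, labels = labels)
}

#' Simulate a low-resolution scalar feature for two groups
#'
#' Group means differ by `delta` in expectation; with `skew = "lognormal"`
#' the base draws are `exp(N(0,1))` (right-skewed), with the shift added on
#' the observation scale so the mean difference stays exactly `delta`.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param delta expected group-1 minus group-2 mean difference.
#' @param skew `"none"` (Gaussian) or `"lognormal"`.
#' @param seed RNG seed.
#' @param feature_name column name in the result.
#' @return list with `scalars` (a `scalar_table` of `n1 + n2` rows) and
#'   `labels`.
#' @export
simulate_scalars <- function(n1, n2, delta = 0, skew = c("none", "lognormal"),
                             seed = 1L, feature_name = "scalar") {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  skew <- match.arg(skew)
  n <- n1 + n2
  x <- with_seed(derive_seed(seed, paste0("scalars::", feature_name)), {
    base <- if (skew == "lognormal") exp(rnorm(n)) else rnorm(n)
    base + delta * rep(c(1, 0), c(n1, n2))
  })
  labels <- factor(rep(c("group1", "group2"), c(n1, n2)),
                   levels = c("group1", "group2"))
  out <- data.frame(region_id = sprintf("r%04d", seq_len(n)), x,
                    stringsAsFactors = FALSE)
  names(out)[2] <- feature_name
  class(out) <- c("scalar_table", "data.frame")
  list(scalars = out, labels = labels)
}

#' Write toy annotation tracks realizing a simulation on a toy genome
#'
#' Places the simulated regions on one toy chromosome and writes, per
#' feature, a plain-text track whose per-window quantification by
#' [quantify_content()], [quantify_count()] or [quantify_wa()] reproduces the
#' simulated curve values exactly: content features become one interval per
#' window covering the stated fraction from the window start, counts become
#' that many 1-bp records, weighted averages become one valued interval
#' spanning the window. Elements are 1-kb plus-strand records spaced so that
#' flanks never overlap.
#'
#' @param spec a [sim_spec()]; feature values are drawn via
#'   [simulate_curves()].
#' @param dir output directory.
#' @param chrom_length toy chromosome length in bp; must fit all regions.
#' @param chrom toy chromosome name.
#' @return list with `elements_bed`, `chrom_sizes`, per-feature `tracks`
#'   (paths), the realized `sim` object, and the element table.
#' @export
simulate_tracks <- function(spec, dir, chrom_length = NULL, chrom = "chrT") {
  stopifnot(inherits(spec, "sim_spec"))
  sim <- simulate_curves(spec)
  n <- spec$n_group1 + spec$n_group2
  K <- spec$n_windows
  w <- 1000
  fl <- K / 2 * w
  el_len <- 1000
  pitch <- 2 * fl + el_len + w          # spacing: flanks never overlap
  need <- n * pitch + fl + w
  if (is.null(chrom_length)) chrom_length <- need
  if (chrom_length < need)
    stop("chrom_length ", chrom_length, " too small; need >= ", need)
  start <- fl + w + (seq_len(n) - 1) * pitch
  els <- elements(chrom = chrom, start = start, end = start + el_len,
                  strand = "+", class_label = "fixed",
                  id = sprintf("r%04d", seq_len(n)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(data.frame(chrom = els$chrom, start = els$start, end = els$end,
                       name = els$id, score = 0L, strand = els$strand),
            file.path(dir, "elements.bed"))
  sizes_path <- file.path(dir, "chrom.sizes")
  write.table(data.frame(chrom, chrom_length), sizes_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  fw <- build_flanks(els, setNames(chrom_length, chrom), flank_kb = K / 2,
                     window_kb = 1)
  tracks <- list()
  for (nm in names(sim$curves)) {
    cm <- sim$curves[[nm]]
    if (cm$measure == "content") {
      # snap to 1-bp resolution so the written track realizes the curve
      # exactly and quantification round-trips bit-identically
      cm$values <- round(cm$values * w) / w
      sim$curves[[nm]]$values <- cm$values
    }
    rows <- list()
    for (i in seq_len(nrow(fw))) {
      v <- cm$values[fw$element_id[i], as.character(fw$label[i])]
      if (cm$measure == "content") {
        if (v > 0)
          rows[[length(rows) + 1]] <-
            data.frame(chrom = chrom, start = fw$start[i],
                       end = fw$start[i] + round(v * w))
      } else if (cm$measure == "count") {
        if (v > 0) {
          p <- fw$start[i] + seq_len(v) - 1
          rows[[length(rows) + 1]] <-
            data.frame(chrom = chrom, start = p, end = p + 1)
        }
      } else {
        rows[[length(rows) + 1]] <-
          data.frame(chrom = chrom, start = fw$start[i], end = fw$end[i],
                     value = v)
      }
    }
    df <- do.call(rbind, rows)
    path <- file.path(dir, paste0(
      nm, if (cm$measure == "weighted_average") ".bedgraph" else ".bed"))
    if (cm$measure == "weighted_average") write_bedgraph(df, path)
    else write_bed(df, path)
    tracks[[nm]] <- path
  }
  list(elements_bed = file.path(dir, "elements.bed"),
       chrom_sizes = sizes_path, tracks = tracks, sim = sim, elements = els)
}
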