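#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif median var cor hclust cutree as.dist glm
#'   binomial coef predict quantile shapiro.test sd setNames
#' @importFrom utils combn read.table write.table head
NULL

# Deterministic 31-bit hash of a string, used to derive independent RNG
# streams per feature so that adding a feature never perturbs the draws of
# another.  Plain polynomial rolling hash over UTF-8 bytes; stable across
# platforms (no reliance on R internals).
str_hash31 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Combine a user seed with a stream label into a 31-bit seed.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + str_hash31(label)) %%
               2147483647)
}

# Run `expr` with a local RNG state seeded by `seed`; restores the caller's
# RNG afterwards so library calls stay referentially transparent.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample skewness (g1, biased version; only used as a qualitative trigger).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(0)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

# Window labels -K/2..-1, +1..+K/2 (no zero), the convention for curves
# indexed relative to the integration site.
window_labels <- function(K) {
  stopifnot(K %% 2 == 0, K >= 2)
  c(seq.int(-K / 2, -1L), seq.int(1L, K / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
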