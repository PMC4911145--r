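#' Screen features for multicollinearity by hierarchical clustering
#'
#' Each feature is summarised to one value per region (the mean over its
#' windows), pairwise Spearman rank correlations are computed, and the
#' features are clustered with complete linkage on the distance
#' `1 - |correlation|`. The dendrogram is cut at `1 - threshold_corr`
#' (default 0.2, i.e. an 80% correlation threshold) and one representative
#' per cluster is retained — the lexicographically first by default, or the
#' member named in `prefer` when a cluster contains one. Constant features
#' (undefined correlation) form their own cluster with a warning. Features
#' are processed in name order, so the result does not depend on input
#' order.
#'
#' @param curves named list of [curve_matrix] objects sharing region ids.
#' @param threshold_corr absolute-correlation threshold above which features
#'   are considered redundant (default 0.8).
#' @param prefer optional character vector of feature names to favour as
#'   cluster representatives (domain overrides).
#' @return list with `retained` (character), `clusters` (data.frame:
#'   feature, cluster, representative, retained) and `cor` (the Spearman
#'   matrix).
#' @export
screen_features <- function(curves, threshold_corr = 0.8, prefer = NULL) {
  stopifnot(length(curves) >= 2)
  nms <- sort(names(curves))
  ids <- curves[[1]]$region_ids
  for (cm in curves) stopifnot(identical(cm$region_ids, ids))
  S <- vapply(nms, function(nm) rowMeans(curves[[nm]]$values), numeric(length(ids)))
  const <- apply(S, 2, function(v) stats::sd(v) == 0 || !all(is.finite(v)))
  if (any(const))
    warning("constant feature(s) kept as singleton clusters: ",
            paste(nms[const], collapse = ", "))
  rho <- suppressWarnings(cor(S, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  d <- as.dist(1 - abs(rho))
  if (length(nms) > 2) {
    hc <- hclust(d, method = "complete")
    cl <- cutree(hc, h = 1 - threshold_corr)
  } else {
    cl <- if (d[1] <= 1 - threshold_corr) c(1L, 1L) else c(1L, 2L)
    names(cl) <- nms
  }
  # constant features always stand alone
  if (any(const)) {
    mx <- max(cl)
    for (i in which(const)) { mx <- mx + 1L; cl[i] <- mx }
  }
  rep_of <- vapply(sort(unique(cl)), function(g) {
    members <- sort(nms[cl == g])
    hit <- intersect(prefer, members)
    if (length(hit)) hit[1] else members[1]
  }, character(1))
  names(rep_of) <- as.character(sort(unique(cl)))
  report <- data.frame(feature = nms, cluster = as.integer(cl),
                       representative = rep_of[as.character(cl)],
                       stringsAsFactors = FALSE)
  report$retained <- report$feature == report$representative
  list(retained = sort(unname(rep_of)), clusters = report, cor = rho)
}
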