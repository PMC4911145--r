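#' Construct a table of elements (integration events or controls)
#'
#' An element is an ERV (or other transposable element) insertion, or the
#' anchor point of a control region. Coordinates are 0-based half-open.
#' Control-class records may be zero-width: they anchor a 64-kb control
#' region at a point, so flank construction yields exactly the region.
#'
#' @param chrom,start,end,strand,class_label,id vectors of equal length;
#'   `class_label` one of `fixed`, `polymorphic`, `in_vitro`, `control`.
#' @param min_len,max_len retained element length range in bp for
#'   non-control classes (default 60 bp to 11 kb).
#' @return data.frame of class `element_table`.
#' @export
elements <- function(chrom, start, end, strand = "+", class_label = "fixed",
                     id = NULL, min_len = 60, max_len = 11000) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   class_label = rep_len(as.character(class_label), n),
                   id = if (is.null(id)) sprintf("el%04d", seq_len(n))
                        else as.character(id),
                   stringsAsFactors = FALSE)
  validate_elements(df, min_len = min_len, max_len = max_len)
  class(df) <- c("element_table", "data.frame")
  df
}

validate_elements <- function(df, min_len = 60, max_len = 11000) {
  if (anyDuplicated(df$id)) stop("duplicate element ids")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ok_class <- c("fixed", "polymorphic", "in_vitro", "control")
  if (!all(df$class_label %in% ok_class))
    stop("class_label must be one of ", paste(ok_class, collapse = ", "))
  ctrl <- df$class_label == "control"
  if (any(df$start[!ctrl] >= df$end[!ctrl]))
    stop("elements must have start < end")
  if (any(df$start[ctrl] > df$end[ctrl]))
    stop("control anchors must have start <= end")
  len <- df$end[!ctrl] - df$start[!ctrl]
  bad <- which(len < min_len | len > max_len)
  if (length(bad))
    stop("element length outside [", min_len, ", ", max_len, "] bp: ",
         paste(df$id[!ctrl][bad], collapse = ", "))
  invisible(df)
}

#' A matrix of per-window feature values for a set of regions
#'
#' The central container of the pipeline: one row per region, one column per
#' 1-kb window, columns ordered by signed window label (upstream -K/2..-1,
#' downstream +1..+K/2 relative to the integration site).
#'
#' @param feature_name feature identifier.
#' @param measure one of `content` (fraction of window covered, in `[0,1]`),
#'   `count` (non-negative integer), `weighted_average` (bp-weighted mean of
#'   a valued track; may carry NAs for windows without data).
#' @param values numeric matrix, regions x windows.
#' @param region_ids,window_labels row/column identifiers.
#' @return object of class `curve_matrix`.
#' @export
curve_matrix <- function(feature_name, measure, values,
                         region_ids = rownames(values),
                         window_labels = NULL) {
  measure <- match.arg(measure, c("content", "count", "weighted_average"))
  values <- as.matrix(values)
  if (is.null(region_ids)) region_ids <- sprintf("r%04d", seq_len(nrow(values)))
  if (is.null(window_labels)) window_labels <- window_labels(ncol(values))
  stopifnot(length(region_ids) == nrow(values),
            length(window_labels) == ncol(values))
  v <- values[is.finite(values)]
  if (measure == "content" && length(v) &&
      (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("content values must lie in [0,1] for feature ", feature_name)
  if (measure == "count" && length(v) && min(v) < 0)
    stop("count values must be non-negative for feature ", feature_name)
  rownames(values) <- region_ids
  colnames(values) <- as.character(window_labels)
  structure(list(feature_name = feature_name, measure = measure,
                 values = values, region_ids = region_ids,
                 window_labels = as.integer(window_labels)),
            class = "curve_matrix")
}

#' @export
print.curve_matrix <- function(x, ...) {
  cat(sprintf("curve_matrix '%s' (%s): %d regions x %d windows [%d..%d]\n",
              x$feature_name, x$measure, nrow(x$values), ncol(x$values),
              min(x$window_labels), max(x$window_labels)))
  invisible(x)
}

#' @export
dim.curve_matrix <- function(x) dim(x$values)
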