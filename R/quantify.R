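# Per-window quantification of feature tracks over flank windows.
# All three measures share the same assembly step: compute one value per
# (element, window label) pair, then pivot to a regions x windows matrix with
# columns ordered by signed label.

.assemble_curve <- function(fw, vals, feature_name, measure) {
  ids <- unique(fw$element_id)
  labs <- sort(unique(fw$label))
  labs <- labs[order(labs)]                       # -K/2..-1, 1..K/2
  m <- matrix(NA_real_, length(ids), length(labs),
              dimnames = list(ids, as.character(labs)))
  m[cbind(match(fw$element_id, ids), match(fw$label, labs))] <- vals
  curve_matrix(feature_name, measure, m, region_ids = ids,
               window_labels = labs)
}

#' Quantify an interval track as per-window content
#'
#' Content is the fraction of each window covered by the track, with
#' overlapping track intervals merged before computing coverage.
#'
#' @param track data.frame of intervals (`chrom`, `start`, `end`), 0-based
#'   half-open, e.g. from [read_bed()].
#' @param fw flank windows from [build_flanks()].
#' @param feature_name name recorded in the result.
#' @return a [curve_matrix] with `measure = "content"`.
#' @export
quantify_content <- function(track, fw, feature_name = "content") {
  w <- attr(fw, "window_bp")
  ov <- track_overlap_bp(fw$chrom, fw$start, fw$end, track)
  .assemble_curve(fw, ov / w, feature_name, "content")
}

#' Quantify a point/motif track as per-window counts
#'
#' A record is counted in the window containing its start coordinate, so a
#' motif straddling a window boundary is counted exactly once and window
#' totals are conserved.
#'
#' @inheritParams quantify_content
#' @return a [curve_matrix] with `measure = "count"`.
#' @export
quantify_count <- function(track, fw, feature_name = "count") {
  cnt <- numeric(nrow(fw))
  if (!is.null(track) && nrow(track)) {
    for (ch in unique(fw$chrom)) {
      qi <- which(fw$chrom == ch)
      ti <- which(track$chrom == ch)
      if (!length(ti)) { cnt[qi] <- 0; next }
      pos <- track$start[ti]
      for (k in qi)
        cnt[k] <- sum(pos >= fw$start[k] & pos < fw$end[k])
    }
  }
  .assemble_curve(fw, cnt, feature_name, "count")
}

#' Quantify a valued track as per-window weighted averages
#'
#' The weighted average of a bedGraph-style track over a window is
#' `sum(value_i * overlap_bp_i) / sum(overlap_bp_i)`. Windows with no
#' overlapping data are returned as `NA` (flagged missing); see
#' [impute_wa_curves()].
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`, e.g. from
#'   [read_bedgraph()].
#' @inheritParams quantify_content
#' @return a [curve_matrix] with `measure = "weighted_average"`.
#' @export
quantify_wa <- function(track, fw, feature_name = "wa") {
  stopifnot(all(is.finite(track$value)))
  num <- numeric(nrow(fw))
  den <- numeric(nrow(fw))
  for (ch in unique(fw$chrom)) {
    qi <- which(fw$chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    q <- .ir(fw$start[qi], fw$end[qi])
    tr <- .ir(track$start[ti], track$end[ti])
    hits <- IRanges::findOverlaps(q, tr)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ow <- IRanges::width(IRanges::pintersect(q[qh], tr[sh]))
    f <- factor(qh, levels = seq_along(q))
    num[qi] <- num[qi] + as.numeric(
      tapply(ow * track$value[ti][sh], f, sum, default = 0))
    den[qi] <- den[qi] + as.numeric(tapply(ow, f, sum, default = 0))
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  .assemble_curve(fw, vals, feature_name, "weighted_average")
}

#' Mean-impute missing weighted-average windows
#'
#' Downstream functional testing needs complete curves; windows flagged
#' missing by [quantify_wa()] are filled with the mean of the same region's
#' non-missing windows. A region with no data at all stays missing and is
#' reported in the `imputed` attribute.
#'
#' @param cm a [curve_matrix].
#' @return the curve matrix with NAs imputed; attribute `imputed` counts
#'   filled cells per region.
#' @export
impute_wa_curves <- function(cm) {
  v <- cm$values
  n_imp <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    miss <- is.na(v[i, ])
    if (any(miss) && !all(miss)) {
      v[i, miss] <- mean(v[i, !miss])
      n_imp[i] <- sum(miss)
    }
  }
  out <- curve_matrix(cm$feature_name, cm$measure, v, cm$region_ids,
                      cm$window_labels)
  attr(out, "imputed") <- setNames(n_imp, cm$region_ids)
  out
}

#' Quantify low-resolution features as one scalar per region
#'
#' Rate-like tracks (recombination rate, replication timing) are summarised
#' as the bp-weighted average over the whole flanking region; distances are
#' measured from the element midpoint (or control-region center) to the
#' nearest annotated landmark of each type on the same chromosome.
#'
#' @param els an [elements()] table.
#' @param flank_kb flank span per side, kb.
#' @param rate_tracks named list of valued-interval data.frames
#'   (`chrom`,`start`,`end`,`value`).
#' @param landmarks data.frame with `chrom`, `pos`, `type` (e.g.
#'   `"centromere"`, `"telomere"`), or NULL.
#' @return data.frame of class `scalar_table`: `region_id` plus one column
#'   per scalar feature (`dist_to_<type>` for landmarks).
#' @export
quantify_scalars <- function(els, flank_kb = 32, rate_tracks = list(),
                             landmarks = NULL) {
  fl <- flank_kb * 1000
  out <- data.frame(region_id = els$id, stringsAsFactors = FALSE)
  for (nm in names(rate_tracks)) {
    tr <- rate_tracks[[nm]]
    up <- .scalar_wa_parts(tr, els$chrom, els$start - fl, els$start)
    dn <- .scalar_wa_parts(tr, els$chrom, els$end, els$end + fl)
    num <- up$num + dn$num
    den <- up$den + dn$den
    out[[nm]] <- ifelse(den > 0, num / den, NA_real_)
  }
  if (!is.null(landmarks)) {
    mid <- (els$start + els$end) / 2
    for (ty in unique(landmarks$type)) {
      lm <- landmarks[landmarks$type == ty, , drop = FALSE]
      d <- vapply(seq_len(nrow(els)), function(i) {
        p <- lm$pos[lm$chrom == els$chrom[i]]
        if (!length(p)) return(NA_real_)
        min(abs(p - mid[i]))
      }, numeric(1))
      out[[paste0("dist_to_", ty)]] <- d
    }
  }
  class(out) <- c("scalar_table", "data.frame")
  out
}

.scalar_wa_parts <- function(track, chrom, start, end) {
  num <- numeric(length(chrom)); den <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    q <- .ir(start[qi], end[qi])
    tr <- .ir(track$start[ti], track$end[ti])
    hits <- IRanges::findOverlaps(q, tr)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ow <- IRanges::width(IRanges::pintersect(q[qh], tr[sh]))
    f <- factor(qh, levels = seq_along(q))
    num[qi] <- num[qi] + as.numeric(
      tapply(ow * track$value[ti][sh], f, sum, default = 0))
    den[qi] <- den[qi] + as.numeric(tapply(ow, f, sum, default = 0))
  }
  list(num = num, den = den)
}
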