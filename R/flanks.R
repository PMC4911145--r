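# Interval helpers over 0-based half-open coordinates, backed by IRanges.
# Internally shifted to 1-based closed; widths are unchanged by the shift.

.ir <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

# Total bp of a query interval covered by a (possibly overlapping) track,
# per chromosome, merging the track first.
track_overlap_bp <- function(chrom, start, end, track) {
  out <- numeric(length(chrom))
  if (is.null(track) || nrow(track) == 0) return(out)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    tr <- IRanges::reduce(.ir(track$start[ti], track$end[ti]))
    q <- .ir(start[qi], end[qi])
    hits <- IRanges::findOverlaps(q, tr)
    if (length(hits)) {
      w <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(hits)], tr[S4Vectors::subjectHits(hits)]))
      out[qi] <- out[qi] +
        as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                    levels = seq_along(q)), sum,
                          default = 0))
    }
  }
  out
}

#' Build flanking windows around each element
#'
#' Each element gets `K = 2 * flank_kb / window_kb` windows of `window_kb` kb:
#' the upstream flank abuts the element start (labels `-K/2..-1`), the
#' downstream flank abuts the element end (labels `+1..+K/2`). For
#' minus-strand elements with `oriented = TRUE` the labelling is inverted in
#' chromosome coordinates, so that labels are always relative to the element's
#' own orientation. Elements whose flanks would run off a chromosome end are
#' dropped and reported.
#'
#' @param els an [elements()] table.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param flank_kb flank span on each side, kb (default 32).
#' @param window_kb window width, kb (default 1).
#' @param oriented invert window order for minus-strand elements.
#' @return long data.frame of class `flank_windows` with columns
#'   `element_id`, `label`, `chrom`, `start`, `end`; attribute `dropped` is a
#'   data.frame of elements removed with the reason.
#' @export
build_flanks <- function(els, chrom_sizes, flank_kb = 32, window_kb = 1,
                         oriented = TRUE) {
  stopifnot(flank_kb %% window_kb == 0)
  fl <- flank_kb * 1000
  w <- window_kb * 1000
  half <- flank_kb / window_kb                       # windows per flank
  dropped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(els))
  for (i in seq_len(nrow(els))) {
    e <- els[i, ]
    lim <- chrom_sizes[[e$chrom]]
    if (is.null(lim) || is.na(lim)) {
      dropped <- rbind(dropped, data.frame(id = e$id,
                                           reason = "unknown_chromosome"))
      next
    }
    if (e$start - fl < 0 || e$end + fl > lim) {
      dropped <- rbind(dropped, data.frame(id = e$id,
                                           reason = "flank_out_of_bounds"))
      next
    }
    j <- seq_len(half)
    up_start <- e$start - j * w            # interval for offset j upstream
    dn_start <- e$end + (j - 1) * w        # offset j downstream
    if (e$strand == "-" && oriented) {
      lab <- c(rev(-j), j)                 # labels -half..-1, 1..half
      st <- c(rev(dn_start), up_start)     # +j maps to chromosome-upstream
    } else {
      lab <- c(rev(-j), j)
      st <- c(rev(up_start), dn_start)
    }
    rows[[i]] <- data.frame(element_id = e$id, label = lab,
                            chrom = e$chrom, start = st, end = st + w,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(element_id = character(0), label = integer(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0))
  attr(out, "dropped") <- dropped
  attr(out, "window_bp") <- w
  attr(out, "K") <- 2L * half
  class(out) <- c("flank_windows", "data.frame")
  out
}

#' Filter elements on genome gaps and mutual flank overlap
#'
#' Applies the two exclusion rules used before quantification: an element is
#' dropped if either of its flanks overlaps assembly gaps by more than
#' `max_gap_bp` (default 320 bp, i.e. 1% of a 32-kb flank), or if its flanks
#' overlap any other element's flanks by more than `max_flank_overlap` bp
#' (default 1 bp). The flank-overlap rule is symmetric: both members of an
#' overlapping pair are excluded. Optionally drops whole chromosomes
#' (default chrY, where most functional tracks lack data).
#'
#' @param els an [elements()] table.
#' @param gap_track data.frame (`chrom`,`start`,`end`) of assembly gaps, or
#'   NULL.
#' @param flank_kb flank span per side, kb.
#' @param max_gap_bp max tolerated gap overlap per flank, bp.
#' @param max_flank_overlap max tolerated overlap with another element's
#'   flanks, bp.
#' @param exclude_chroms chromosomes removed outright.
#' @return list with `retained` (element_table) and `excluded`
#'   (data.frame id, rule).
#' @export
filter_elements <- function(els, gap_track = NULL, flank_kb = 32,
                            max_gap_bp = 320, max_flank_overlap = 1,
                            exclude_chroms = "chrY") {
  fl <- flank_kb * 1000
  excl <- data.frame(id = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(els))

  chr_bad <- els$chrom %in% exclude_chroms
  if (any(chr_bad)) {
    excl <- rbind(excl, data.frame(id = els$id[chr_bad],
                                   rule = "excluded_chromosome"))
    drop <- drop | chr_bad
  }

  # gap rule, per flank
  up_gap <- track_overlap_bp(els$chrom, els$start - fl, els$start, gap_track)
  dn_gap <- track_overlap_bp(els$chrom, els$end, els$end + fl, gap_track)
  gap_bad <- (up_gap > max_gap_bp | dn_gap > max_gap_bp) & !drop
  if (any(gap_bad)) {
    excl <- rbind(excl, data.frame(id = els$id[gap_bad], rule = "gap_overlap"))
    drop <- drop | gap_bad
  }

  # mutual flank overlap (both members of a pair go)
  n <- nrow(els)
  fdf <- data.frame(
    owner = rep(seq_len(n), 2), chrom = rep(els$chrom, 2),
    start = c(els$start - fl, els$end), end = c(els$start, els$end + fl))
  ov_bad <- rep(FALSE, n)
  for (ch in unique(fdf$chrom)) {
    idx <- which(fdf$chrom == ch)
    ir <- .ir(fdf$start[idx], fdf$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- fdf$owner[idx[qh]] != fdf$owner[idx[sh]]
    if (!any(keep)) next
    w <- IRanges::width(IRanges::pintersect(ir[qh[keep]], ir[sh[keep]]))
    ow <- fdf$owner[idx[qh[keep]]]
    tot <- tapply(w, ow, sum)
    ov_bad[as.integer(names(tot))[tot > max_flank_overlap]] <- TRUE
  }
  ov_new <- ov_bad & !drop
  if (any(ov_new)) {
    excl <- rbind(excl, data.frame(id = els$id[ov_new],
                                   rule = "flank_overlap"))
    drop <- drop | ov_new
  }

  retained <- els[!drop, , drop = FALSE]
  class(retained) <- c("element_table", "data.frame")
  list(retained = retained, excluded = excl)
}

#' Place control regions by rejection sampling
#'
#' Draws contiguous regions of `region_kb` kb uniformly over the genome,
#' accepting a candidate when its overlap with the LTR annotation is at most
#' `max_ltr_fraction` of the region, its overlap with the element flanks is at
#' most `max_flank_fraction`, and it does not overlap a previously accepted
#' control. Returned controls are zero-width anchor records at the region
#' center with `class_label = "control"`, so that [build_flanks()] reproduces
#' the region as its windows.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_controls number of controls to place.
#' @param ltr_track data.frame of LTR-element intervals, or NULL.
#' @param avoid data.frame of intervals to avoid (element flanking regions),
#'   or NULL.
#' @param region_kb control region span, kb (default 64).
#' @param max_ltr_fraction max LTR overlap fraction (default 0.02).
#' @param max_flank_fraction max element-flank overlap fraction (default
#'   0.01).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget (default `1000 * n_controls`).
#' @return an [elements()] table of control anchors.
#' @export
make_controls <- function(chrom_sizes, n_controls, ltr_track = NULL,
                          avoid = NULL, region_kb = 64,
                          max_ltr_fraction = 0.02, max_flank_fraction = 0.01,
                          seed = 1L, max_attempts = 1000 * n_controls) {
  span <- region_kb * 1000
  usable <- chrom_sizes[chrom_sizes >= span]
  if (!length(usable)) stop("no chromosome can hold a ", region_kb,
                            "-kb region")
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, "make_controls"), {
    attempts <- 0
    while (nrow(placed) < n_controls && attempts < max_attempts) {
      attempts <- attempts + 1
      ch <- sample(names(usable), 1, prob = usable - span + 1)
      s <- floor(runif(1, 0, usable[[ch]] - span + 1))
      e <- s + span
      if (track_overlap_bp(ch, s, e, ltr_track) > max_ltr_fraction * span)
        next
      if (track_overlap_bp(ch, s, e, avoid) > max_flank_fraction * span)
        next
      if (track_overlap_bp(ch, s, e, placed) > 0) next
      placed <- rbind(placed, data.frame(chrom = ch, start = s, end = e))
    }
  })
  if (nrow(placed) < n_controls)
    stop("control placement failed: placed ", nrow(placed), " of ",
         n_controls, " in ", max_attempts, " attempts")
  ctr <- placed$start + span / 2
  elements(chrom = placed$chrom, start = ctr, end = ctr, strand = "+",
           class_label = "control", id = sprintf("ctrl%04d", seq_len(nrow(placed))))
}
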