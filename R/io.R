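#' Read a BED file (BED3/BED4/BED6)
#'
#' Coordinates are 0-based half-open throughout the package (BED convention).
#' Columns beyond the sixth are ignored; missing name/score/strand columns are
#' filled with defaults (`.`, `0`, `+`).
#'
#' @param path path to an uncompressed BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = paste0("V", 1:6), fill = TRUE)
  bad <- which(!is.finite(df$V2) | !is.finite(df$V3) | df$V2 >= df$V3)
  if (length(bad))
    stop("malformed BED interval at line ", bad[1], " of ", path)
  data.frame(chrom = as.character(df$V1),
             start = as.numeric(df$V2), end = as.numeric(df$V3),
             name = ifelse(is.na(df$V4) | df$V4 == "", ".",
                           as.character(df$V4)),
             strand = ifelse(is.na(df$V6) | !(df$V6 %in% c("+", "-")), "+",
                             as.character(df$V6)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$name %||% ".", df$score %||% 0L, df$strand %||% "+")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph file of valued intervals
#'
#' @param path path to an uncompressed bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: ", path)
  bad <- which(!is.finite(df[[2]]) | !is.finite(df[[3]]) | df[[2]] >= df[[3]] |
                 !is.finite(df[[4]]))
  if (length(bad))
    stop("malformed bedGraph record at line ", bad[1], " of ", path)
  data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
             end = as.numeric(df[[3]]), value = as.numeric(df[[4]]),
             stringsAsFactors = FALSE)
}

#' Write valued intervals as bedGraph
#' @param df data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE), df$value)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#' @param path TSV with chromosome name and length in bp.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a curve matrix as TSV
#'
#' The header row carries the signed window labels (-K/2..-1, +1..+K/2);
#' row names are region ids.
#'
#' @param cm a [curve_matrix].
#' @param path output path.
#' @export
write_curve_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "curve_matrix"))
  df <- as.data.frame(cm$values)
  colnames(df) <- cm$window_labels
  df <- cbind(region_id = cm$region_ids, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curve matrix from TSV
#' @param path TSV written by [write_curve_tsv()].
#' @param feature_name,measure metadata to attach (not stored in the TSV).
#' @return a [curve_matrix].
#' @export
read_curve_tsv <- function(path, feature_name = basename(path),
                           measure = "weighted_average") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  curve_matrix(feature_name, measure, vals, region_ids = ids,
               window_labels = as.integer(colnames(df)[-1]))
}
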