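#' Summit windows from BED / narrowPeak peak calls
#'
#' Builds the fixed-width analysis windows around peak summits from a
#' BED or ENCODE narrowPeak file. Coordinates are BED-style 0-based
#' half-open throughout: a window is `[summit - half_width,
#' summit + half_width + 1)`, spanning `2 * half_width + 1` nucleotide
#' sites (201 for the default, the (-100,+100) window). For narrowPeak
#' input (10 columns) the summit is `start + column 10` unless that
#' offset is -1; otherwise, and for plain BED, the interval midpoint is
#' used.
#'
#' @param file Path to a BED (>= 3 columns) or narrowPeak (10 columns)
#'   file; tab-separated, no header.
#' @param half_width Half-width of the window in bases (default 100).
#' @return Data frame `region_id`, `chrom`, `start`, `end`, `summit`
#'   (all 0-based half-open; `width = end - start`); region ids come
#'   from the name column when present, else `chrom:summit`.
#' @export
read_peak_windows <- function(file, half_width = 100L) {
  if (!file.exists(file)) stop(sprintf("peak file not found: '%s'", file))
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("peak file needs at least chrom, start, end")
  chrom <- as.character(df[[1]])
  start <- as.integer(df[[2]])
  end <- as.integer(df[[3]])
  if (any(end <= start)) stop("peak intervals must satisfy start < end")
  summit <- if (ncol(df) >= 10 && is.numeric(df[[10]])) {
    off <- as.integer(df[[10]])
    ifelse(off >= 0, start + off, start + (end - start) %/% 2L)
  } else {
    start + (end - start) %/% 2L
  }
  name <- if (ncol(df) >= 4 && !all(df[[4]] %in% c(".", "")))
    as.character(df[[4]]) else paste0(chrom, ":", summit)
  if (anyDuplicated(name))
    name <- make.unique(name, sep = "_")
  out <- data.frame(region_id = name, chrom = chrom,
                    start = pmax(summit - half_width, 0L),
                    end = summit + half_width + 1L,
                    summit = summit, stringsAsFactors = FALSE)
  out
}
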