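#' Region-by-species motif count tables
#'
#' The data unit of the whole framework: for each orthologous region, its
#' width W in nucleotide sites and the number of motif occurrences observed
#' in each species (NA where the species has no orthologous sequence).
#' Stored as a plain data frame with columns `region_id`, `width`, then one
#' integer column per species; class `bd_counts`.
#'
#' @param region_id Character vector of unique region identifiers.
#' @param width Integer vector (or scalar) of region widths in nucleotide
#'   sites.
#' @param counts Matrix or data frame of counts, one column per species,
#'   one row per region; NA marks a missing (unaligned) species.
#' @return A `bd_counts` data frame.
#' @examples
#' region_counts(c("r1", "r2"), 201,
#'               cbind(human = c(1, 0), mouse = c(0, NA)))
#' @export
region_counts <- function(region_id, width, counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || any(!nzchar(colnames(counts))))
    stop("'counts' must have species names as column names")
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id)) stop("duplicate region_id")
  width <- as.integer(rep_len(width, length(region_id)))
  if (nrow(counts) != length(region_id))
    stop("'counts' must have one row per region")
  if (any(width < 1)) stop("region width must be >= 1")
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (any(counts > width, na.rm = TRUE))
    stop("counts cannot exceed region width")
  if (any(rowSums(!is.na(counts)) == 0))
    stop("every region needs at least one observed species")
  out <- data.frame(region_id = region_id, width = width,
                    stringsAsFactors = FALSE)
  cdf <- as.data.frame(counts)
  rownames(cdf) <- NULL
  out <- cbind(out, cdf)
  rownames(out) <- NULL
  class(out) <- c("bd_counts", "data.frame")
  out
}

count_species <- function(counts) setdiff(names(counts), c("region_id", "width"))

count_matrix <- function(counts) {
  m <- as.matrix(counts[, count_species(counts), drop = FALSE])
  rownames(m) <- counts$region_id
  m
}

#' Read / write the canonical count-table TSV
#'
#' Tab-separated interchange format: columns `region_id`, `width`, then one
#' column per species; missing observations written as `NA`.
#'
#' @param file Path to the TSV file.
#' @return `read_counts_tsv` returns a [region_counts] object;
#'   `write_counts_tsv` returns `file` invisibly.
#' @export
read_counts_tsv <- function(file) {
  if (!file.exists(file)) stop(sprintf("counts file not found: '%s'", file))
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("region_id", "width") %in% names(df)))
    stop("counts TSV must have 'region_id' and 'width' columns")
  sp <- setdiff(names(df), c("region_id", "width"))
  if (length(sp) == 0) stop("counts TSV has no species columns")
  region_counts(df$region_id, df$width, df[, sp, drop = FALSE])
}

#' @rdname read_counts_tsv
#' @param counts A [region_counts] object.
#' @export
write_counts_tsv <- function(counts, file) {
  stopifnot(inherits(counts, "bd_counts"))
  utils::write.table(counts, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Default state cap for a dataset
#'
#' Counts in real peak windows are almost always 0 or 1, so the likelihood
#' state space is truncated at the largest observed count plus a margin
#' (default 5), never exceeding the smallest region width.
#'
#' @param counts A [region_counts] object.
#' @param margin States allowed above the maximum observed count.
#' @return Integer state cap `n_max`.
#' @export
default_n_max <- function(counts, margin = 5L) {
  m <- count_matrix(counts)
  min(max(m, na.rm = TRUE) + margin, min(counts$width))
}

#' Default prior mean: mean observed motif count per sequence
#'
#' The root prior on counts is Poisson with mean `nu`; by default `nu` is
#' the mean of all observed (region, species) counts.
#'
#' @param counts A [region_counts] object.
#' @return Numeric prior mean.
#' @export
default_prior_mean <- function(counts) {
  mean(count_matrix(counts), na.rm = TRUE)
}

#' Truncated Poisson root prior
#'
#' Poisson(`nu`) over counts `0..n_max`, renormalized to sum to one.
#'
#' @param nu Prior mean (mean motif occurrences per sequence), >= 0.
#' @param n_max State cap.
#' @return Probability vector of length `n_max + 1`.
#' @export
poisson_prior <- function(nu, n_max) {
  if (nu < 0) stop("'nu' must be non-negative")
  p <- stats::dpois(0:n_max, nu)
  p / sum(p)
}
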