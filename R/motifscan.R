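IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' IUPAC consensus motifs
#'
#' Validates an IUPAC consensus string (length >= 4 over the 15-letter
#' nucleotide ambiguity alphabet), e.g. `"AGATAAG"` for GATA1 or
#' `"WTAACAA"` for SOX2.
#'
#' @param x Motif string.
#' @return The validated, upper-cased motif string (class
#'   `bd_consensus`).
#' @export
consensus_motif <- function(x) {
  if (!is.character(x) || length(x) != 1) stop("motif must be one string")
  x <- toupper(x)
  ch <- strsplit(x, "")[[1]]
  if (length(ch) < 4) stop("motif must be at least 4 bases long")
  bad <- setdiff(ch, IUPAC_CHARS)
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' in motif", bad[1]))
  structure(x, class = "bd_consensus")
}

check_dna <- function(sequence) {
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s))
    stop(sprintf("invalid nucleotide character in sequence: '%s'",
                 sub(".*?([^ACGTN]).*", "\\1", s)))
  s
}

#' Scan a sequence for consensus motif matches
#'
#' Reports every position at which the IUPAC pattern matches, on the
#' forward strand and (with `both_strands`) positions whose
#' reverse-complement window matches. `N` in the sequence matches only an
#' `N` in the motif (never a wildcard); ambiguity codes in the motif are
#' interpreted per IUPAC. A palindromic match hitting the same offset on
#' both strands is reported once (as `+`).
#'
#' @param sequence DNA string over `A C G T N`.
#' @param motif A [consensus_motif] (or plain string, validated).
#' @param both_strands Also scan the reverse complement.
#' @return Data frame `offset` (0-based forward-strand start) and
#'   `strand` (`"+"`/`"-"`), sorted by offset.
#' @examples
#' scan_consensus("TTAGATAAGC", "AGATAAG")
#' scan_consensus("GGCTTATCTAA", "AGATAAG", both_strands = TRUE)
#' @export
scan_consensus <- function(sequence, motif, both_strands = FALSE) {
  motif <- consensus_motif(as.character(motif))
  sequence <- check_dna(sequence)
  L <- nchar(unclass(motif))
  empty <- data.frame(offset = integer(0), strand = character(0))
  if (nchar(sequence) < L) return(empty)
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(unclass(motif))
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                    fixed = "subject")) - 1L
  hits <- data.frame(offset = fwd,
                     strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  if (both_strands) {
    rcp <- Biostrings::reverseComplement(pat)
    rev <- Biostrings::start(Biostrings::matchPattern(rcp, subj,
                                                      fixed = "subject")) - 1L
    rev <- setdiff(rev, fwd)        # palindromic coincidences count once
    hits <- rbind(hits, data.frame(offset = rev,
                                   strand = rep("-", length(rev)),
                                   stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# greedy left-to-right non-overlapping filter
drop_overlaps <- function(hits, L) {
  if (nrow(hits) < 2) return(hits)
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$offset[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$offset[i] + L - 1L
    }
  }
  hits[keep, , drop = FALSE]
}

#' Count motif occurrences per region and species
#'
#' Scans every per-species sequence of every region and assembles the
#' [region_counts] table the birth-death model consumes. The region width
#' is the sequence length (nucleotide sites). Species without a sequence
#' in a region are recorded as missing. The default overlap policy keeps
#' a greedy left-to-right non-overlapping subset of hits; `"all"` counts
#' every matching position.
#'
#' @param region_seqs Named list: region id -> named character vector of
#'   per-species sequences (possibly differing species sets per region).
#' @param motif A [consensus_motif] or string.
#' @param both_strands Count matches on both strands.
#' @param overlap `"non-overlapping"` (default) or `"all"`.
#' @return A [region_counts] object.
#' @examples
#' seqs <- list(r1 = c(human = "TTAGATAAGC", mouse = "TTTTTTTTTT"))
#' count_motifs(seqs, "AGATAAG")
#' @export
count_motifs <- function(region_seqs, motif, both_strands = FALSE,
                         overlap = c("non-overlapping", "all")) {
  overlap <- match.arg(overlap)
  motif <- consensus_motif(as.character(motif))
  L <- nchar(unclass(motif))
  if (!length(region_seqs)) stop("no regions given")
  if (is.null(names(region_seqs))) stop("'region_seqs' must be named by region")
  species <- sort(unique(unlist(lapply(region_seqs, names))))
  if (!length(species)) stop("every region needs at least one species sequence")
  cm <- matrix(NA_integer_, length(region_seqs), length(species),
               dimnames = list(names(region_seqs), species))
  width <- integer(length(region_seqs))
  for (r in seq_along(region_seqs)) {
    seqs <- region_seqs[[r]]
    if (!length(seqs)) stop(sprintf("region '%s' has no species sequences",
                                    names(region_seqs)[r]))
    width[r] <- max(nchar(seqs))
    for (spc in names(seqs)) {
      hits <- scan_consensus(seqs[[spc]], motif, both_strands = both_strands)
      if (overlap == "non-overlapping") hits <- drop_overlaps(hits, L)
      cm[r, spc] <- nrow(hits)
    }
  }
  region_counts(names(region_seqs), width, cm)
}

#' Read per-region, per-species sequences from FASTA
#'
#' Reads a combined multi-record FASTA whose headers follow the
#' `region|species` dialect (one record per species per region, e.g.
#' `>chr1_peak17|mouse`). Returns the nested list consumed by
#' [count_motifs].
#'
#' @param file Path to the FASTA file.
#' @return Named list region id -> named character vector of sequences.
#' @export
read_region_fasta <- function(file) {
  if (!file.exists(file)) stop(sprintf("FASTA file not found: '%s'", file))
  ss <- Biostrings::readDNAStringSet(file)
  if (!length(ss)) stop(sprintf("FASTA file is empty: '%s'", file))
  hdr <- names(ss)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop(sprintf("FASTA header not in 'region|species' form: '%s'",
                 hdr[lengths(parts) != 2][1]))
  region <- vapply(parts, `[`, character(1), 1)
  spc <- vapply(parts, `[`, character(1), 2)
  seqs <- as.character(ss)
  out <- split(stats::setNames(seqs, spc), region)
  out[unique(region)]
}

#' Write per-region sequences as FASTA
#'
#' Inverse of [read_region_fasta]: emits one record per (region, species)
#' with `region|species` headers.
#'
#' @param region_seqs Named list region -> named character vector.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_region_fasta <- function(region_seqs, file) {
  recs <- unlist(lapply(names(region_seqs), function(r) {
    stats::setNames(region_seqs[[r]],
                    paste(r, names(region_seqs[[r]]), sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), file)
  invisible(file)
}
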