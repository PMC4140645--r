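IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), character(1)))
}

#' Position weight matrices
#'
#' A `bd_pwm` is an L x 4 matrix of base probabilities (columns A, C, G,
#' T; each row sums to one) with the pseudocount used to build it stored
#' as an attribute.
#'
#' @param mat Numeric L x 4 matrix (columns A, C, G, T).
#' @param pseudocount Pseudocount recorded for provenance.
#' @return A validated `bd_pwm`.
#' @export
bd_pwm <- function(mat, pseudocount = NA_real_) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(mat) <- BASES
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  if (any(abs(rowSums(mat) - 1) > 1e-9))
    stop("each PWM row must sum to 1")
  structure(mat, pseudocount = pseudocount, class = c("bd_pwm", "matrix"))
}

pwm_from_substrings <- function(subs, L, pseudocount) {
  M <- matrix(pseudocount, L, 4, dimnames = list(NULL, BASES))
  ch <- matrix(unlist(strsplit(subs, "")), nrow = L)
  for (b in BASES) M[, b] <- M[, b] + rowSums(ch == b)
  bd_pwm(M / rowSums(M), pseudocount)
}

# log-odds scores vs uniform background at every offset; windows with N
# score -Inf. Returns data.frame(offset, strand, score).
score_pwm <- function(sequence, pwm, both_strands = TRUE) {
  L <- nrow(pwm)
  n <- nchar(sequence)
  out <- data.frame(offset = integer(0), strand = character(0),
                    score = numeric(0))
  if (n < L) return(out)
  code <- match(strsplit(sequence, "")[[1]], BASES)   # NA for N
  n_off <- n - L + 1L
  logp <- log(pmax(unclass(pwm), 1e-300)) - log(0.25)
  one_strand <- function(lp) {
    sc <- numeric(n_off)
    for (pos in seq_len(L)) {
      v <- lp[pos, code[pos:(pos + n_off - 1L)]]
      v[is.na(v)] <- -Inf
      sc <- sc + v
    }
    sc
  }
  sc_f <- one_strand(logp)
  res <- data.frame(offset = 0:(n_off - 1L), strand = "+", score = sc_f,
                    stringsAsFactors = FALSE)
  if (both_strands) {
    lp_r <- logp[L:1, c("T", "G", "C", "A"), drop = FALSE]
    colnames(lp_r) <- BASES
    sc_r <- one_strand(lp_r)
    res <- rbind(res, data.frame(offset = 0:(n_off - 1L), strand = "-",
                                 score = sc_r, stringsAsFactors = FALSE))
  }
  res
}

#' Iterative PWM construction from bound windows
#'
#' Builds a position weight matrix for a motif from the nucleotide
#' composition at its occurrences within a set of sequence windows
#' (e.g. peak-summit windows). Starting from the alignment of all
#' consensus-motif matches, the composition (with a per-base pseudocount)
#' defines a PWM; each iteration then re-locates the best-scoring window
#' per sequence under the current PWM (log-odds vs uniform background,
#' threshold `score_min`) and recomputes the composition, until the
#' largest column-wise probability change falls below `tol` or `max_iter`
#' is reached. Deterministic given its inputs: score ties resolve to the
#' leftmost forward-strand window.
#'
#' @param windows Character vector of DNA windows (each at least as long
#'   as the motif).
#' @param seed_motif A [consensus_motif] seeding the alignment.
#' @param pseudocount Per-base pseudocount added to each column.
#' @param max_iter Maximum refinement iterations.
#' @param tol Convergence threshold on column probabilities.
#' @param both_strands Scan both strands.
#' @param score_min Minimum log-odds score to keep a window during
#'   refinement.
#' @return A [bd_pwm] with attributes `iterations` and `n_windows_used`.
#' @examples
#' w <- c("TTAGATAAGC", "CAGATAAGTT", "AGATAAGGGG")
#' build_pwm_iterative(w, "AGATAAG", pseudocount = 1)
#' @export
build_pwm_iterative <- function(windows, seed_motif, pseudocount = 1,
                                max_iter = 20, tol = 1e-3,
                                both_strands = TRUE, score_min = 0) {
  motif <- consensus_motif(as.character(seed_motif))
  L <- nchar(unclass(motif))
  windows <- vapply(windows, check_dna, character(1), USE.NAMES = FALSE)
  if (any(nchar(windows) < L)) stop("every window must be >= motif length")
  subs <- unlist(lapply(windows, function(wn) {
    hits <- scan_consensus(wn, motif, both_strands = both_strands)
    vapply(seq_len(nrow(hits)), function(i) {
      s <- substr(wn, hits$offset[i] + 1L, hits$offset[i] + L)
      if (hits$strand[i] == "-") revcomp_chr(s) else s
    }, character(1))
  }))
  if (!length(subs))
    stop("no window contains a seed-motif match; cannot estimate a PWM")
  pwm <- pwm_from_substrings(subs, L, pseudocount)
  it <- 0L
  n_used <- length(subs)
  while (it < max_iter) {
    it <- it + 1L
    subs <- unlist(lapply(windows, function(wn) {
      sc <- score_pwm(wn, pwm, both_strands = both_strands)
      sc <- sc[sc$score >= score_min, , drop = FALSE]
      if (!nrow(sc)) return(character(0))
      sc <- sc[order(-sc$score, sc$offset, sc$strand), , drop = FALSE]
      s <- substr(wn, sc$offset[1] + 1L, sc$offset[1] + L)
      if (sc$strand[1] == "-") revcomp_chr(s) else s
    }))
    if (!length(subs)) break
    new <- pwm_from_substrings(subs, L, pseudocount)
    delta <- max(abs(unclass(new) - unclass(pwm)))
    pwm <- new
    n_used <- length(subs)
    if (delta < tol) break
  }
  attr(pwm, "iterations") <- it
  attr(pwm, "n_windows_used") <- n_used
  pwm
}

#' Enumerate candidate consensus motifs
#'
#' `mode = "exact"` lists all non-degenerate k-mers collapsed into
#' reverse-complement classes (the canonical representative is the
#' lexicographically smaller of a k-mer and its reverse complement); for
#' k = 4 this yields 136 classes. `mode = "refine"` lists all
#' single-position variants of `seed` in which one position is replaced
#' by a two-fold IUPAC code containing the original base (e.g.
#' `WGATAAG` from `AGATAAG`).
#'
#' @param k Motif length, `4 <= k <= 12` (exact mode).
#' @param mode `"exact"` or `"refine"`.
#' @param seed Seed motif for refine mode.
#' @return Character vector of motifs (all valid [consensus_motif]s).
#' @export
enumerate_candidate_motifs <- function(k = NULL, mode = c("exact", "refine"),
                                       seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (is.null(k) || k < 4 || k > 12) stop("'k' must be in [4, 12]")
    kmers <- do.call(paste0, expand.grid(rep(list(BASES), k),
                                         stringsAsFactors = FALSE))
    canon <- pmin(kmers, revcomp_chr(kmers))
    sort(unique(canon))
  } else {
    seed <- consensus_motif(as.character(seed))
    ch <- strsplit(unclass(seed), "")[[1]]
    twofold <- c("R", "Y", "S", "W", "K", "M")
    out <- character(0)
    for (i in seq_along(ch)) {
      if (!ch[i] %in% BASES) next
      for (cd in twofold) {
        if (ch[i] %in% IUPAC_SETS[[cd]]) {
          v <- ch
          v[i] <- cd
          out <- c(out, paste(v, collapse = ""))
        }
      }
    }
    unique(out)
  }
}

# one concrete instance of a consensus motif (first base of each set;
# randomized when sample = TRUE)
motif_instance <- function(motif, sample = FALSE) {
  ch <- strsplit(unclass(consensus_motif(motif)), "")[[1]]
  paste(vapply(ch, function(c) {
    s <- IUPAC_SETS[[c]]
    if (sample) s[sample.int(length(s), 1)] else s[1]
  }, character(1)), collapse = "")
}

#' Emit region sequences with planted motif occurrences
#'
#' Builds random per-region, per-species sequences that reproduce given
#' motif count tables exactly: backgrounds are rejection-sampled to be
#' free of matches to every motif, then the required number of instances
#' of each motif is planted at random non-overlapping positions, and the
#' result is verified by re-scanning. This exercises the scanning module
#' end-to-end against known counts. Uses the current RNG.
#'
#' @param counts_by_motif Named list motif string -> [region_counts];
#'   all tables must share region ids, widths, and missingness pattern.
#' @param both_strands,overlap Scanning settings the emitted sequences
#'   must reproduce the counts under.
#' @param max_tries Regeneration attempts per sequence before failing.
#' @return Named list region id -> named character vector of sequences.
#' @export
emit_region_sequences <- function(counts_by_motif, both_strands = TRUE,
                                  overlap = "non-overlapping",
                                  max_tries = 100) {
  motifs <- names(counts_by_motif)
  if (is.null(motifs)) stop("'counts_by_motif' must be named by motif")
  ref <- counts_by_motif[[1]]
  species <- count_species(ref)
  out <- vector("list", nrow(ref))
  names(out) <- ref$region_id
  for (r in seq_len(nrow(ref))) {
    W <- ref$width[r]
    seqs <- character(0)
    for (spc in species) {
      targets <- vapply(counts_by_motif, function(ct) ct[r, spc],
                        integer(1))
      if (anyNA(targets)) {
        if (!all(is.na(targets)))
          stop("missingness must agree across motif tables")
        next
      }
      seqs[spc] <- plant_sequence(W, targets, both_strands, overlap,
                                  max_tries)
    }
    out[[r]] <- seqs
  }
  out
}

plant_sequence <- function(W, targets, both_strands, overlap, max_tries) {
  motifs <- names(targets)
  for (try in seq_len(max_tries)) {
    s <- paste(sample(BASES, W, replace = TRUE), collapse = "")
    clean <- all(vapply(motifs, function(m)
      nrow(scan_consensus(s, m, both_strands = both_strands)) == 0,
      logical(1)))
    if (!clean) next
    # allocate non-overlapping slots for all instances
    occupied <- matrix(numeric(0), ncol = 2)
    ok <- TRUE
    for (m in motifs) {
      L <- nchar(m)
      for (i in seq_len(targets[[m]])) {
        slot <- find_slot(W, L, occupied)
        if (is.null(slot)) { ok <- FALSE; break }
        occupied <- rbind(occupied, slot)
        inst <- motif_instance(m, sample = TRUE)
        if (both_strands && stats::runif(1) < 0.5) inst <- revcomp_chr(inst)
        substr(s, slot[1], slot[2]) <- inst
      }
      if (!ok) break
    }
    if (!ok) next
    good <- all(vapply(motifs, function(m) {
      hits <- scan_consensus(s, m, both_strands = both_strands)
      if (overlap == "non-overlapping")
        hits <- drop_overlaps(hits, nchar(m))
      nrow(hits) == targets[[m]]
    }, logical(1)))
    if (good) return(s)
  }
  stop(sprintf("could not emit a width-%d sequence matching the target counts after %d tries",
               W, max_tries))
}

find_slot <- function(W, L, occupied, tries = 200) {
  for (i in seq_len(tries)) {
    st <- sample.int(W - L + 1L, 1)
    en <- st + L - 1L
    if (!nrow(occupied) ||
        all(en < occupied[, 1] | st > occupied[, 2])) return(c(st, en))
  }
  NULL
}
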