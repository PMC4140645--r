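test_that("consensus scanning finds exactly the IUPAC matches", {
  hits <- scan_consensus("TTAGATAAGC", "AGATAAG")
  expect_equal(hits$offset, 2L)
  expect_equal(hits$strand, "+")
  # IUPAC degeneracy: W matches A and T
  expect_equal(nrow(scan_consensus("CATAACAAC", "WTAACAA")), 1L)
  expect_equal(nrow(scan_consensus("CTTAACAAC", "WTAACAA")), 1L)
  expect_equal(nrow(scan_consensus("CGTAACAAC", "WTAACAA")), 0L)
  # reverse-complement hit on the minus strand
  rc <- scan_consensus("GGCTTATCTAA", "AGATAAG", both_strands = TRUE)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$strand, "-")
  expect_equal(nrow(scan_consensus("GGCTTATCTAA", "AGATAAG")), 0L)
  # empty / short input
  expect_equal(nrow(scan_consensus("", "AGATAAG")), 0L)
  expect_equal(nrow(scan_consensus("AGA", "AGATAAG")), 0L)
  # N is a mismatch, never a wildcard
  expect_equal(nrow(scan_consensus("TTAGATNAGC", "AGATAAG")), 0L)
  expect_error(scan_consensus("ACGTX", "AGATAAG"), "invalid nucleotide")
  expect_error(consensus_motif("AGQTAAG"), "invalid IUPAC")
  expect_error(consensus_motif("ACG"), "at least 4")
})

test_that("palindromic matches are reported once", {
  # ACGCGT is its own reverse complement
  hits <- scan_consensus("TTACGCGTTT", "ACGCGT", both_strands = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
})

test_that("scanning is position-exact under concatenation", {
  set.seed(10)
  motif <- "AGATAAG"
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    spacer <- strrep("N", 8)
    joint <- paste0(a, spacer, b)
    ha <- scan_consensus(a, motif, both_strands = TRUE)$offset
    hb <- scan_consensus(b, motif, both_strands = TRUE)$offset
    hj <- scan_consensus(joint, motif, both_strands = TRUE)$offset
    expect_equal(sort(hj), sort(c(ha, hb + nchar(a) + 8L)))
  }
})

test_that("counting honors the overlap policy and missing species", {
  seqs <- list(r1 = c(human = "TTAGATAAGC", mouse = "TTTTTTTTTT"),
               r2 = c(human = "AGATAAGATAAG"))
  cnt <- count_motifs(seqs, "AGATAAG")
  expect_s3_class(cnt, "bd_counts")
  expect_equal(cnt$human, c(1L, 1L))       # greedy non-overlapping
  expect_equal(cnt$mouse, c(0L, NA_integer_))
  cnt_all <- count_motifs(seqs, "AGATAAG", overlap = "all")
  expect_equal(cnt_all$human, c(1L, 2L))
  expect_equal(cnt$width, c(10L, 12L))
  expect_error(count_motifs(list(), "AGATAAG"), "no regions")
})

test_that("both-strand counts are invariant under reverse complement", {
  set.seed(11)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    rc <- bdtfbs:::revcomp_chr(s)
    for (motif in c("AGATAAG", "WTAACAA", "KCACGTG")) {
      n1 <- nrow(scan_consensus(s, motif, both_strands = TRUE))
      n2 <- nrow(scan_consensus(rc, motif, both_strands = TRUE))
      expect_equal(n1, n2)
    }
  }
})

test_that("PWM composition arithmetic and invariants hold", {
  # 3 sequences all showing A at a column, pseudocount 1 -> P(A) = 4/7
  w <- c("TAGATAAGT", "CAGATAAGC", "GAGATAAGA")
  pwm <- build_pwm_iterative(w, "AGATAAG", pseudocount = 1)
  expect_s3_class(pwm, "bd_pwm")
  expect_equal(unname(unclass(pwm)[1, "A"]), 4 / 7)
  expect_equal(rowSums(unclass(pwm)), rep(1, 7), tolerance = 1e-9)
  # degenerate composition: identical windows pile mass on the consensus
  w10 <- rep("TTAGATAAGCC", 10)
  p10 <- build_pwm_iterative(w10, "AGATAAG", pseudocount = 0.1)
  cons <- strsplit("AGATAAG", "")[[1]]
  for (i in 1:7)
    expect_gt(unclass(p10)[i, cons[i]], 0.95)
  expect_error(build_pwm_iterative(c("TTTTTTTT"), "AGATAAG"),
               "no window contains")
  expect_error(bd_pwm(matrix(0.5, 4, 4)), "sum to 1")
})

test_that("iterative PWM recovers a planted generating matrix", {
  set.seed(12)
  L <- 7
  gen <- matrix(0.04, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  cons <- sample(c("A", "C", "G", "T"), L, TRUE)
  for (i in 1:L) gen[i, cons[i]] <- 0.88
  windows <- vapply(1:200, function(i) {
    inst <- paste(vapply(1:L, function(p)
      sample(colnames(gen), 1, prob = gen[p, ]), character(1)),
      collapse = "")
    bg1 <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    bg2 <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    paste0(bg1, inst, bg2)
  }, character(1))
  pwm <- build_pwm_iterative(windows, paste(cons, collapse = ""),
                             pseudocount = 1, both_strands = FALSE)
  tv <- 0.5 * rowSums(abs(unclass(pwm) - gen))
  expect_lt(max(tv), 0.1)
})

test_that("candidate enumeration matches brute-force pairing", {
  cand <- enumerate_candidate_motifs(4, mode = "exact")
  # oracle: enumerate all 256 4-mers and pair by reverse complement
  all4 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                      stringsAsFactors = FALSE))
  pal <- sum(all4 == bdtfbs:::revcomp_chr(all4))
  expect_equal(length(cand), (length(all4) - pal) / 2 + pal)
  expect_equal(length(cand), 136L)
  expect_true(all(!duplicated(cand)))
  # refine mode contains the documented variant, all valid motifs
  ref <- enumerate_candidate_motifs(mode = "refine", seed = "AGATAAG")
  expect_true("WGATAAG" %in% ref)
  for (m in c(cand[1:10], ref))
    expect_silent(consensus_motif(m))
  expect_error(enumerate_candidate_motifs(3, "exact"), "k")
})

test_that("emitted sequences reproduce their target counts exactly", {
  set.seed(13)
  tr <- example_timetree()
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 60,
                          n_regions = 8, seed = 21)
  seqs <- emit_region_sequences(list(AGATAAG = sim$counts))
  rescan <- count_motifs(seqs, "AGATAAG", both_strands = TRUE)
  expect_equal(as.matrix(rescan[, leaf_labels(tr)]),
               as.matrix(sim$counts[, leaf_labels(tr)]))
})
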