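test_that("EM degenerates gracefully on motif-free data", {
  tr <- example_timetree()
  tips <- leaf_labels(tr)
  zeros <- region_counts(paste0("r", 1:5), 201,
                         matrix(0L, 5, 10, dimnames = list(NULL, tips)))
  fit <- suppressWarnings(fit_rates_em(zeros, tr, polish = FALSE))
  expect_equal(fit$rates$birth, 1e-15)
  expect_equal(fit$rates$death, 1e-15)
  expect_warning(fit_rates_em(zeros, tr, polish = FALSE),
                 "occupied site-time")
})

test_that("a converged EM fit is a fixed point of the update", {
  tr <- example_timetree()
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 201,
                          n_regions = 300, seed = 14)
  fit <- fit_rates_em(sim$counts, tr, polish = FALSE, tol = 1e-4)
  expect_true(fit$converged)
  # one more classification-EM step moves the rates by less than tol
  refit <- fit_rates_em(sim$counts, tr, init = fit$rates, polish = FALSE,
                        max_iter = 1, tol = Inf)
  expect_lt(abs(refit$rates$birth - fit$rates$birth) / fit$rates$birth,
            1e-4 * 1.01)
  expect_lt(abs(refit$rates$death - fit$rates$death) / fit$rates$death,
            1e-4 * 1.01)
  # trace is recorded and reproducible
  fit2 <- fit_rates_em(sim$counts, tr, polish = FALSE, tol = 1e-4)
  expect_identical(fit$trace, fit2$trace)
})

test_that("polished fit recovers simulation rates at moderate scale", {
  tr <- example_timetree()
  true <- bd_rates(5e-11, 5e-9)
  sim <- simulate_dataset(tr, true, W = 201, n_regions = 1500, seed = 15)
  fit <- fit_rates_em(sim$counts, tr)
  expect_lt(abs(fit$rates$birth - true$birth) / true$birth, 0.25)
  expect_lt(abs(fit$rates$death - true$death) / true$death, 0.25)
  expect_true(fit$converged)
  # polished estimate sits at a likelihood no worse than the truth
  eng_ll <- sum(region_loglik(sim$counts, tr, fit$rates,
                              n_max = fit$n_max, nu = fit$nu))
  true_ll <- sum(region_loglik(sim$counts, tr, true,
                               n_max = fit$n_max, nu = fit$nu))
  expect_gte(eng_ll + 1e-6, true_ll)
})

test_that("the LRT statistic is non-negative and df-consistent", {
  tr <- example_timetree()
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 50,
                          n_regions = 300, seed = 16)
  res <- suppressWarnings(
    lineage_lrt(sim$counts, tr, focal = "simiiformes"))
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 2L)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_gte(res$loglik_alt + 1e-6, res$loglik_null)
  res1 <- suppressWarnings(
    lineage_lrt(sim$counts, tr, focal = "simiiformes",
                one_sided_birth = TRUE))
  expect_equal(res1$df, 1L)
})

test_that("the LRT is invariant to joint time/rate rescaling", {
  tr <- example_timetree()
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 50,
                          n_regions = 400, seed = 17)
  res <- suppressWarnings(
    lineage_lrt(sim$counts, tr, focal = "simiiformes"))
  tr2 <- scale_branch_lengths(tr, 1000)
  res2 <- suppressWarnings(
    lineage_lrt(sim$counts, tr2, focal = "simiiformes"))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-4)
  expect_equal(res2$fit_null$rates$birth * 1000,
               res$fit_null$rates$birth, tolerance = 1e-4)
  expect_equal(res2$fit_null$rates$death * 1000,
               res$fit_null$rates$death, tolerance = 1e-4)
})

test_that("a strong focal birth excess is detected", {
  tr <- example_timetree()
  base <- bd_rates(5e-11, 5e-9)
  shifted <- branch_rates(base,
                          overrides = list(simiiformes = bd_rates(5e-10, 5e-9)))
  sim <- simulate_dataset(tr, shifted, W = 50, n_regions = 500, seed = 18)
  res <- suppressWarnings(
    lineage_lrt(sim$counts, tr, focal = "simiiformes"))
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$fit_alt$focal_rates$birth, 3 * res$fit_alt$rates$birth)
})

test_that("motif ranking places a lineage-enriched motif first", {
  tr <- example_timetree()
  set.seed(19)
  focal <- "simiiformes"
  # species below the focal branch carry extra planted occurrences of M1
  below <- c("human", "chimp", "gorilla", "orangutan", "macaque", "marmoset")
  m1 <- "AGATAAG"
  decoys <- c("TACGCAT", "GGTACCA")
  n_reg <- 60
  tips <- leaf_labels(tr)
  base <- matrix(0L, n_reg, length(tips), dimnames = list(NULL, tips))
  counts_list <- list()
  cm1 <- base
  cm1[, below] <- matrix(rbinom(n_reg * length(below), 1, 0.75),
                         n_reg, length(below))
  counts_list[[m1]] <- region_counts(paste0("r", 1:n_reg), 201, cm1)
  for (d in decoys) {
    cmd <- base
    cmd[] <- rbinom(length(cmd), 1, 0.12)
    counts_list[[d]] <- region_counts(paste0("r", 1:n_reg), 201, cmd)
  }
  seqs <- emit_region_sequences(counts_list)
  rank <- suppressWarnings(
    rank_motifs_by_lineage_birth(c(decoys, m1), seqs, tr, focal = focal,
                                 max_iter = 30))
  expect_equal(rank$motif[1], m1)
  expect_lt(rank$p_value[1], 0.01)
  # ranking is invariant to candidate order
  rank2 <- suppressWarnings(
    rank_motifs_by_lineage_birth(c(m1, rev(decoys)), seqs, tr,
                                 focal = focal, max_iter = 30))
  expect_equal(rank$motif, rank2$motif)
})

test_that("a motif absent everywhere gets p = 1 and ranks last", {
  tr <- read_timetree(text = "(A:2e7,(B:1e7,C:1e7):1e7);")
  seqs <- list(r1 = c(A = strrep("ACGT", 20), B = strrep("TGCA", 20),
                      C = strrep("AACC", 20)))
  seqs$r1[] <- vapply(seqs$r1, function(s)
    paste0(substr(s, 1, 40), "AGATAAG", substr(s, 48, 80)), character(1))
  rank <- suppressWarnings(
    rank_motifs_by_lineage_birth(c("AGATAAG", "CGCGCGCG"), seqs, tr,
                                 focal = "B"))
  expect_equal(rank$motif[2], "CGCGCGCG")
  expect_equal(rank$p_value[2], 1)
})
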