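# hand-built assignment over the bundled tree's human path
path_assignment <- function(tree, path_counts, other = 0L) {
  ids <- tree$ids
  a <- matrix(other, 1, length(ids), dimnames = list("r1", ids))
  path <- c(ids[tree$root], lineage_path(tree, "human"))
  a[1, path] <- path_counts
  structure(a, class = c("bd_assignment", "matrix"))
}

test_that("the contiguous-run rule dates single sites correctly", {
  tr <- example_timetree()
  split <- "euarchontoglires"
  # present all the way to the root: ancestral
  a <- path_assignment(tr, rep(1L, 9))
  calls <- branch_of_origin(a, tr, "human", split_node = split)
  expect_equal(calls$origin, "ancestral")
  # gained on the terminal branch
  a2 <- path_assignment(tr, c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(branch_of_origin(a2, tr, "human", split)$origin, "human")
  # loss and re-gain: the oldest node of the most recent run wins,
  # not "ancestral" (the site was re-gained below the loss)
  a3 <- path_assignment(tr, c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(branch_of_origin(a3, tr, "human", split)$origin,
               "simiiformes")
  # count >= i at the split node itself is ancestral
  a4 <- path_assignment(tr, c(0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(branch_of_origin(a4, tr, "human", split)$origin,
               "ancestral")
  # absent in the target leaf: no calls
  a5 <- path_assignment(tr, rep(0L, 9))
  expect_equal(nrow(branch_of_origin(a5, tr, "human", split)), 0L)
})

test_that("multi-site regions assign ranks oldest-first", {
  tr <- example_timetree()
  # two sites: one ancestral, one gained on the hominini branch
  a <- path_assignment(tr, c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L))
  calls <- branch_of_origin(a, tr, "human", "euarchontoglires")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$origin[calls$site_index == 1], "ancestral")
  expect_equal(calls$origin[calls$site_index == 2], "hominini")
})

test_that("per-region calls equal the target-leaf count", {
  tr <- example_timetree()
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 201,
                          n_regions = 150, seed = 23)
  calls <- sim$origins
  by_region <- table(calls$region_id)
  h <- sim$counts$human
  names(h) <- sim$counts$region_id
  expect_equal(unname(h[names(by_region)]), as.integer(by_region))
  expect_equal(sum(h), nrow(calls))
})

test_that("truth origins are the origin rule applied to true states", {
  tr <- example_timetree()
  sim <- simulate_dataset(tr, bd_rates(8e-11, 3e-9), W = 100,
                          n_regions = 200, seed = 24,
                          split_node = "euarchontoglires")
  again <- branch_of_origin(sim$node_counts, tr, "human",
                            split_node = "euarchontoglires")
  expect_identical(sim$origins$origin, again$origin)
  expect_identical(sim$origins$position, again$position)
})

test_that("age distributions partition the calls", {
  tr <- example_timetree()
  cls <- example_age_classes()
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 201,
                          n_regions = 300, seed = 25,
                          split_node = "euarchontoglires")
  ad <- age_distribution(sim$origins, cls)
  expect_equal(sum(ad$count), nrow(sim$origins))
  expect_equal(sum(ad$fraction), 1, tolerance = 1e-12)
  expect_setequal(ad$class,
                  c("primate", "simian", "hominid", "human", "ancestral"))
  # all-ancestral corner
  a <- path_assignment(tr, rep(1L, 9))
  one <- branch_of_origin(a, tr, "human", "euarchontoglires")
  ad1 <- age_distribution(one, cls)
  expect_equal(ad1$fraction[ad1$class == "ancestral"], 1)
})

test_that("per-branch creation rates are sites over branch time", {
  tr <- example_timetree()
  a <- path_assignment(tr, c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  calls <- branch_of_origin(a, tr, "human", "euarchontoglires")
  rates <- origin_rate_per_branch(calls, tr)
  expect_equal(rates$n_sites[rates$branch == "human"], 1L)
  expect_equal(rates$rate_per_My[rates$branch == "human"], 1 / 7)
  expect_true(all(rates$rate_per_My[rates$branch != "human"] == 0))
  # conservation: rates times durations recover non-ancestral calls
  sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 201,
                          n_regions = 200, seed = 26,
                          split_node = "euarchontoglires")
  rr <- origin_rate_per_branch(sim$origins, tr)
  expect_equal(sum(rr$rate_per_My * rr$duration_My),
               sum(sim$origins$origin != "ancestral"))
})

test_that("origin-call comparison histograms shifts correctly", {
  tr <- example_timetree()
  a <- path_assignment(tr, c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  b <- path_assignment(tr, c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  ca <- branch_of_origin(a, tr, "human", "euarchontoglires")
  cb <- branch_of_origin(b, tr, "human", "euarchontoglires")
  same <- compare_origin_calls(ca, ca)
  expect_equal(unname(same$shifts["0"]), 1L)
  expect_equal(same$unchanged_fraction, 1)
  moved <- compare_origin_calls(ca, cb)   # ancestral (pos 1) -> primates (pos 2)
  expect_equal(unname(moved$shifts["1"]), 1L)
  expect_equal(moved$unchanged_fraction, 0)
  expect_equal(sum(moved$shifts), 1L)
})
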