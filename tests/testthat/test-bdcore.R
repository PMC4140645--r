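test_that("occupancy probabilities honor initial conditions and limits", {
  r <- bd_rates(2e-9, 1e-8)
  expect_equal(occupancy_prob(0, r, TRUE), 1)
  expect_equal(occupancy_prob(0, r, FALSE), 0)
  # absorbing cases
  expect_equal(occupancy_prob(1e9, bd_rates(0, 1e-8), FALSE), 0)
  expect_equal(occupancy_prob(1e9, bd_rates(2e-9, 0), TRUE), 1)
  # equilibrium limit from both initial conditions
  pi0 <- r$birth / (r$birth + r$death)
  expect_equal(occupancy_prob(1e12, r, TRUE), pi0, tolerance = 1e-12)
  expect_equal(occupancy_prob(1e12, r, FALSE), pi0, tolerance = 1e-12)
  # frozen dynamics return the initial state
  expect_equal(occupancy_prob(5, bd_rates(0, 0), TRUE), 1)
  expect_equal(occupancy_prob(5, bd_rates(0, 0), FALSE), 0)
  expect_error(occupancy_prob(-1, r, TRUE), "non-negative")
})

test_that("closed-form occupancy matches numerical ODE integration", {
  set.seed(1)
  dP <- function(t, y, p) list(p$birth * (1 - y) - p$death * y)
  for (i in 1:10) {
    birth <- 10^runif(1, -11, -8)
    death <- 10^runif(1, -10, -8)
    t_end <- 10^runif(1, 6, 8)
    for (init in c(1, 0)) {
      num <- deSolve::ode(y = init, times = c(0, t_end), func = dP,
                          parms = list(birth = birth, death = death),
                          method = "ode45", atol = 1e-12, rtol = 1e-12)
      expect_equal(occupancy_prob(t_end, bd_rates(birth, death),
                                  initially_present = init == 1),
                   unname(num[2, 2]), tolerance = 1e-10)
    }
  }
})

test_that("survival and gain distributions are correct binomials", {
  r <- bd_rates(2e-9, 1e-8)
  # point masses at t = 0 and for degenerate inputs
  expect_equal(survival_pmf(0:3, 3, 0, r), c(0, 0, 0, 1))
  expect_equal(survival_pmf(0, 0, 1e7, r), 1)
  expect_equal(gain_pmf(0:2, 2, 0, r), c(1, 0, 0))
  expect_equal(gain_pmf(0, 5, 1e8, bd_rates(0, 1e-8)), 1)
  expect_error(survival_pmf(4, 3, 1, r), "exceed")
  expect_error(gain_pmf(3, 2, 1, r), "exceed")

  set.seed(2)
  for (i in 1:20) {
    rr <- bd_rates(10^runif(1, -11, -8), 10^runif(1, -10, -8))
    t <- 10^runif(1, 6, 8)
    # survival equals a binomial with an independently computed P1
    p1 <- rr$birth / (rr$birth + rr$death) +
      (1 - rr$birth / (rr$birth + rr$death)) *
        exp(-(rr$birth + rr$death) * t)
    expect_equal(survival_pmf(0:5, 5, t, rr), dbinom(0:5, 5, p1),
                 tolerance = 1e-12)
    expect_equal(sum(survival_pmf(0:5, 5, t, rr)), 1, tolerance = 1e-12)
    expect_equal(sum(gain_pmf(0:7, 7, t, rr)), 1, tolerance = 1e-12)
  }
  # analytic mean of the gain distribution
  rr <- bd_rates(5e-11, 5e-9)
  t <- 1e6
  p0 <- occupancy_prob(t, rr, FALSE)
  expect_equal(sum((0:200) * gain_pmf(0:200, 200, t, rr)), 200 * p0,
               tolerance = 1e-12)
})

test_that("count transitions match the matrix-exponential oracle", {
  # identity at t = 0 and single-site reduction
  r <- bd_rates(1e-3, 2e-3)
  expect_equal(transition_prob(2, 2, 3, 0, r), 1)
  expect_equal(transition_prob(2, 1, 3, 0, r), 0)
  expect_equal(transition_prob(0, 1, 1, 100, r),
               occupancy_prob(100, r, FALSE))
  expect_equal(transition_prob(1, 1, 1, 100, r),
               occupancy_prob(100, r, TRUE))

  oracle <- expm_transition(3, 100, 1e-3, 2e-3)
  Tm <- transition_matrix(3, 100, r)
  expect_lt(max(abs(Tm - oracle)), 1e-8)

  set.seed(3)
  for (i in 1:15) {
    W <- sample(1:5, 1)
    birth <- 10^runif(1, -4, -2)
    death <- 10^runif(1, -4, -2)
    t <- 10^runif(1, 0, 2.5)
    Tm <- transition_matrix(W, t, bd_rates(birth, death))
    expect_lt(max(abs(Tm - expm_transition(W, t, birth, death))), 1e-8)
    expect_equal(rowSums(Tm), rep(1, W + 1), tolerance = 1e-12)
  }
})

test_that("Chapman-Kolmogorov and stationarity hold", {
  set.seed(4)
  for (i in 1:10) {
    W <- sample(2:5, 1)
    r <- bd_rates(10^runif(1, -4, -2), 10^runif(1, -4, -2))
    t1 <- 10^runif(1, 0, 2)
    t2 <- 10^runif(1, 0, 2)
    A <- transition_matrix(W, t1, r)
    B <- transition_matrix(W, t2, r)
    AB <- transition_matrix(W, t1 + t2, r)
    expect_lt(max(abs(A %*% B - AB)), 1e-10)
  }
  # rows converge to Binomial(W, birth/(birth+death)) as t grows
  r <- bd_rates(2e-3, 5e-3)
  W <- 4
  Tm <- transition_matrix(W, 1e5, r)
  statn <- dbinom(0:W, W, r$birth / (r$birth + r$death))
  for (m in 0:W)
    expect_equal(unname(Tm[m + 1, ]), statn, tolerance = 1e-8)
})

test_that("state truncation keeps rows stochastic and loses little mass", {
  r <- bd_rates(5e-11, 5e-9)
  W <- 201
  t <- 1e7                      # genomic regime: lambda * W * t = 0.1
  full <- transition_matrix(W, t, r)
  max_obs <- 1
  n_max <- max_obs + 5
  trunc <- transition_matrix(W, t, r, n_max = n_max)
  expect_equal(rowSums(trunc), rep(1, n_max + 1), tolerance = 1e-12)
  # rows reachable from the data (m <= max observed) lose almost nothing
  reach <- seq_len(max_obs + 1)
  expect_lt(max(attr(trunc, "tail_mass")[reach]), 1e-6)
  expect_lt(max(abs(trunc[reach, ] - full[reach, 1:(n_max + 1)])), 1e-6)
  expect_error(transition_matrix(3, 1, r, n_max = 5), "n_max")
})

test_that("branch sampling follows the transition distribution", {
  expect_equal(sample_branch_count(3, 10, 50, bd_rates(0, 0), n = 5),
               rep(3L, 5))
  expect_equal(sample_branch_count(4, 10, 0, bd_rates(1e-3, 1e-3), n = 5),
               rep(4L, 5))
  set.seed(5)
  r <- bd_rates(3e-3, 6e-3)
  W <- 10
  t <- 120
  m <- 3
  draws <- sample_branch_count(m, W, t, r, n = 1e5)
  pmf <- sapply(0:W, function(n) transition_prob(m, n, W, t, r))
  obs <- tabulate(draws + 1L, nbins = W + 1)
  keep <- pmf * 1e5 >= 5
  chi <- chisq.test(obs[keep], p = pmf[keep] / sum(pmf[keep]))
  expect_gt(chi$p.value, 0.001)
})
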