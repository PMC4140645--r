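#' Birth-death rates
#'
#' Constructs a pair of per-site, per-year rates: `birth` is the rate at
#' which a motif appears at a single unoccupied nucleotide site in one year
#' of evolutionary time, `death` the rate at which an existing occurrence
#' is lost per year. Typical genome-wide magnitudes are 1e-12 to 1e-8.
#'
#' @param birth Birth rate (per unoccupied site-year), >= 0.
#' @param death Death rate (per occupied site-year), >= 0.
#' @return A `bd_rates` object (named list with `birth` and `death`).
#' @examples
#' bd_rates(5e-11, 5e-9)
#' @export
bd_rates <- function(birth, death) {
  if (!is.numeric(birth) || length(birth) != 1 || is.na(birth) || birth < 0)
    stop("'birth' must be a single non-negative number")
  if (!is.numeric(death) || length(death) != 1 || is.na(death) || death < 0)
    stop("'death' must be a single non-negative number")
  structure(list(birth = as.numeric(birth), death = as.numeric(death)),
            class = "bd_rates")
}

#' @export
print.bd_rates <- function(x, ...) {
  cat(sprintf("bd_rates: birth %.4g, death %.4g (per site-year)\n",
              x$birth, x$death))
  invisible(x)
}

#' Single-site occupancy probability
#'
#' Closed-form solution of the two-state gain/loss chain at one nucleotide
#' site. With total rate r = birth + death and equilibrium occupancy
#' pi = birth / r, the probability that the site carries a motif after time
#' t is `pi + (1 - pi) * exp(-r t)` when it started occupied and
#' `pi * (1 - exp(-r t))` when it started empty. When both rates are zero
#' the site is frozen and the initial state is returned.
#'
#' @param t Elapsed time in years (vectorized), >= 0.
#' @param rates A [bd_rates] object.
#' @param initially_present Logical: was the site occupied at time 0?
#' @return Probability (same length as `t`) that the site is occupied.
#' @examples
#' occupancy_prob(5e7, bd_rates(2e-9, 1e-8), initially_present = TRUE)
#' @export
occupancy_prob <- function(t, rates, initially_present) {
  stopifnot(inherits(rates, "bd_rates"))
  if (any(t < 0)) stop("'t' must be non-negative")
  r <- rates$birth + rates$death
  if (r == 0) return(rep(as.numeric(initially_present), length(t)))
  pi0 <- rates$birth / r
  if (initially_present) pi0 + (1 - pi0) * exp(-r * t)
  else pi0 * (1 - exp(-r * t))
}

#' Survival distribution of existing motif occurrences
#'
#' Of `m` occurrences present at time 0, each survives to time t
#' independently with probability `P1(t)` ([occupancy_prob] with
#' `initially_present = TRUE`), so the surviving number is
#' Binomial(m, P1(t)).
#'
#' @param j Number surviving (vectorized), 0 <= j <= m.
#' @param m Initial number of occurrences.
#' @inheritParams occupancy_prob
#' @return P(j of m survive).
#' @export
survival_pmf <- function(j, m, t, rates) {
  if (any(j > m)) stop("'j' cannot exceed 'm'")
  stats::dbinom(j, m, occupancy_prob(t, rates, initially_present = TRUE))
}

#' Gain distribution at unoccupied sites
#'
#' Each of `u` unoccupied sites independently acquires a motif by time t
#' with probability `P0(t)`, so the number of gains is Binomial(u, P0(t)).
#'
#' @param k Number gained (vectorized), 0 <= k <= u.
#' @param u Number of initially unoccupied sites.
#' @inheritParams occupancy_prob
#' @return P(k of u sites become occupied).
#' @export
gain_pmf <- function(k, u, t, rates) {
  if (any(k > u)) stop("'k' cannot exceed 'u'")
  stats::dbinom(k, u, occupancy_prob(t, rates, initially_present = FALSE))
}

#' Region-level count transition probability
#'
#' Probability that a region of `W` nucleotide sites holding `m` motif
#' occurrences holds `n` after time t: the convolution of the binomial
#' survival distribution of the m occupied sites with the binomial gain
#' distribution of the W - m unoccupied sites,
#' `sum_j P(j survive) * P(n - j gained)`.
#'
#' @param m,n Counts in `0..W`.
#' @param W Region width in nucleotide sites.
#' @inheritParams occupancy_prob
#' @return The transition probability.
#' @examples
#' transition_prob(0, 1, W = 201, t = 3e7, rates = bd_rates(5e-11, 5e-9))
#' @export
transition_prob <- function(m, n, W, t, rates) {
  if (m < 0 || m > W || n < 0 || n > W) stop("counts must lie in [0, W]")
  j <- max(0, n - (W - m)):min(m, n)
  sum(survival_pmf(j, m, t, rates) * gain_pmf(n - j, W - m, t, rates))
}

#' Count transition matrix over states 0..n_max
#'
#' Assembles the full matrix of [transition_prob] values over a truncated
#' state space. With `n_max = W` the matrix has full support and each row
#' sums to one exactly; with `n_max < W` the tail mass beyond `n_max` is
#' (optionally) folded back by renormalizing each row, and the discarded
#' mass is reported in the `"tail_mass"` attribute. Truncation is safe in
#' the genomic regime because per-region counts are almost always 0 or 1.
#'
#' @param W Region width (nucleotide sites).
#' @param t Branch time in years.
#' @param rates A [bd_rates] object.
#' @param n_max State cap, `1 <= n_max <= W` (default: full support `W`).
#' @param renormalize Renormalize rows to sum to one (default `TRUE`).
#' @return `(n_max+1) x (n_max+1)` matrix, rows = starting count `m`,
#'   columns = ending count `n`, both 0-based; attribute `tail_mass` gives
#'   the per-row truncated probability before renormalization.
#' @export
transition_matrix <- function(W, t, rates, n_max = W, renormalize = TRUE) {
  stopifnot(inherits(rates, "bd_rates"))
  if (n_max > W) stop("'n_max' cannot exceed region width W")
  if (n_max < 0) stop("'n_max' must be >= 0")
  p1 <- occupancy_prob(t, rates, initially_present = TRUE)
  p0 <- occupancy_prob(t, rates, initially_present = FALSE)
  S <- n_max + 1L
  m <- 0:n_max
  # survival: Sv[m+1, j+1] = dbinom(j, m, p1); gains: G[m+1, k+1] = dbinom(k, W-m, p0)
  Sv <- outer(m, 0:n_max, function(mm, jj) stats::dbinom(jj, mm, p1))
  G  <- outer(m, 0:n_max, function(mm, kk) stats::dbinom(kk, W - mm, p0))
  Tm <- matrix(0, S, S)
  for (j in 0:n_max) {
    cols <- (j:n_max) + 1L
    Tm[, cols] <- Tm[, cols] + Sv[, j + 1L] * G[, cols - j]
  }
  rs <- rowSums(Tm)
  tail_mass <- pmax(0, 1 - rs)
  if (renormalize) Tm <- Tm / rs
  attr(Tm, "tail_mass") <- tail_mass
  Tm
}

#' Sample a child count along one branch
#'
#' Exact forward draw of the count transition: survivors are
#' Binomial(m, P1(t)) and gains Binomial(W - m, P0(t)), so the returned
#' value is distributed as row `m` of the full-support transition matrix.
#' Uses the current R random number generator; seed with [set.seed()].
#'
#' @param m Parent count, `0 <= m <= W`.
#' @param W Region width.
#' @inheritParams occupancy_prob
#' @param n Number of independent draws.
#' @return Integer vector of child counts in `[0, W]`.
#' @export
sample_branch_count <- function(m, W, t, rates, n = 1) {
  if (m < 0 || m > W) stop("'m' must lie in [0, W]")
  p1 <- occupancy_prob(t, rates, initially_present = TRUE)
  p0 <- occupancy_prob(t, rates, initially_present = FALSE)
  stats::rbinom(n, m, p1) + stats::rbinom(n, W - m, p0)
}
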