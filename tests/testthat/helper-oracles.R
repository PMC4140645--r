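# Independent oracles and fixture builders used across the suite.
# Everything here deliberately avoids the package's own computational
# paths: likelihoods by exhaustive enumeration, transition probabilities
# by matrix exponentials, parsimony by brute force, and so on.

# random time tree with n tips; branch lengths scaled to a given depth
rand_tree <- function(n_tips, depth = 1e8) {
  phy <- ape::rcoal(n_tips, tip.label = paste0("sp", seq_len(n_tips)))
  phy$edge.length <- phy$edge.length * depth / max(ape::node.depth.edgelength(phy))
  read_timetree(text = ape::write.tree(phy))
}

# generator matrix of the independent-sites count chain on 0..W
bd_generator <- function(W, birth, death) {
  Q <- matrix(0, W + 1, W + 1)
  for (k in 0:W) {
    if (k < W) Q[k + 1, k + 2] <- (W - k) * birth
    if (k > 0) Q[k + 1, k] <- k * death
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# transition matrix oracle: matrix exponential of the generator
expm_transition <- function(W, t, birth, death) {
  as.matrix(Matrix::expm(bd_generator(W, birth, death) * t))
}

# exhaustive likelihood oracle: sum over every combination of internal
# node states of the product of transition probabilities and leaf
# indicators (plus root prior for the total likelihood)
enum_region_lik <- function(tree, obs, W, birth, death, n_max, nu) {
  internal <- setdiff(seq_along(tree$ids), seq_len(tree$n_tip))
  states <- 0:n_max
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  prior <- dpois(states, nu) / sum(dpois(states, nu))
  Tm <- lapply(seq_along(tree$ids), function(v) {
    if (v == tree$root) return(NULL)
    o <- sapply(states, function(m) sapply(states, function(n)
      transition_prob(m, n, W, tree$blen[v], bd_rates(birth, death))))
    t(o) / rowSums(t(o))     # renormalized over the truncated space
  })
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(length(tree$ids))
    st[internal] <- grid[g, ]
    st[seq_len(tree$n_tip)] <- NA
    p <- prior[st[tree$root] + 1]
    for (v in seq_along(tree$ids)) {
      if (v == tree$root) next
      if (v <= tree$n_tip) {
        lab <- tree$ids[v]
        if (is.na(obs[lab])) {
          # missing leaf: marginalize (transition row sums to 1)
          next
        }
        p <- p * Tm[[v]][st[tree$parent[v]] + 1, obs[lab] + 1]
      } else {
        p <- p * Tm[[v]][st[tree$parent[v]] + 1, st[v] + 1]
      }
    }
    total <- total + p
  }
  total
}

# conditional likelihood oracle L_v(x): brute force over the subtree of v
enum_conditional <- function(tree, obs, W, birth, death, n_max, v, x) {
  kids <- tree$children[[v]]
  if (!length(kids)) {
    lab <- tree$ids[v]
    if (is.na(obs[lab])) return(1)
    return(as.numeric(obs[lab] == x))
  }
  out <- 1
  states <- 0:n_max
  for (d in kids) {
    Td <- sapply(states, function(n)
      transition_prob(x, n, W, tree$blen[d], bd_rates(birth, death)))
    Td <- Td / sum(Td)
    out <- out * sum(sapply(states, function(y)
      Td[y + 1] * enum_conditional(tree, obs, W, birth, death, n_max, d, y)))
  }
  out
}

# independent re-implementation of the greedy top-down rule, computing
# every argmax from the brute-force conditional likelihoods
greedy_oracle <- function(tree, obs, W, birth, death, n_max, nu) {
  states <- 0:n_max
  prior <- dpois(states, nu) / sum(dpois(states, nu))
  Lroot <- sapply(states, function(x)
    enum_conditional(tree, obs, W, birth, death, n_max, tree$root, x))
  st <- integer(length(tree$ids))
  st[tree$root] <- states[which.max(prior * Lroot)]
  for (v in tree$preorder) {
    if (v == tree$root) next
    xp <- st[tree$parent[v]]
    Td <- sapply(states, function(n)
      transition_prob(xp, n, W, tree$blen[v], bd_rates(birth, death)))
    Td <- Td / sum(Td)
    Ld <- sapply(states, function(y)
      enum_conditional(tree, obs, W, birth, death, n_max, v, y))
    st[v] <- states[which.max(Td * Ld)]
  }
  names(st) <- tree$ids
  st
}

# exhaustive Sankoff oracle: minimum total |change| over all assignments
sankoff_oracle_cost <- function(tree, obs, n_max) {
  internal <- setdiff(seq_along(tree$ids), seq_len(tree$n_tip))
  grid <- as.matrix(expand.grid(rep(list(0:n_max), length(internal))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- integer(length(tree$ids))
    st[internal] <- grid[g, ]
    cost <- 0
    ok <- TRUE
    for (v in seq_along(tree$ids)) {
      if (v == tree$root) next
      if (v <= tree$n_tip) {
        o <- unname(obs[tree$ids[v]])
        if (is.na(o)) next
        cost <- cost + abs(st[tree$parent[v]] - o)
      } else {
        cost <- cost + abs(st[tree$parent[v]] - st[v])
      }
    }
    if (ok && cost < best) best <- cost
  }
  best
}

# one-region count table from a named observation vector
obs_counts <- function(obs, W, id = "r1") {
  region_counts(id, W, t(as.matrix(obs[!is.na(obs)])))
}

# small random observation vector over the tips of a tree
rand_obs <- function(tree, n_max, p_missing = 0.2) {
  tips <- leaf_labels(tree)
  obs <- sample(0:n_max, length(tips), replace = TRUE,
                prob = dpois(0:n_max, 0.8) + 0.02)
  obs[runif(length(tips)) < p_missing] <- NA
  if (all(is.na(obs))) obs[1] <- 1L
  names(obs) <- tips
  obs
}
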