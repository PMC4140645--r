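#' Forward-simulate one region's site-level history
#'
#' Runs the generative model for a single region of `W` independent
#' nucleotide sites: the root state of each site is Bernoulli at the
#' stationary occupancy `birth / (birth + death)` (`root_mode =
#' "stationary"`) or all-absent (`"empty"`), and along every branch a
#' present site survives with probability `P1(t)` while an absent site is
#' gained with probability `P0(t)`. Uses the current RNG; seed with
#' [set.seed()].
#'
#' @param tree A [bd_tree].
#' @param rates A [bd_rates] or [branch_rates] object.
#' @param W Region width (number of sites).
#' @param root_mode `"stationary"` or `"empty"`.
#' @return Integer 0/1 matrix nodes x sites (rows named by node id).
#' @export
simulate_history <- function(tree, rates, W,
                             root_mode = c("stationary", "empty")) {
  sim <- simulate_presence(tree, rates, W, n_regions = 1L,
                           root_mode = match.arg(root_mode))
  M <- do.call(rbind, lapply(sim$states, function(x) x[1, ]))
  rownames(M) <- tree$ids
  M
}

# shared core: per-node R x W presence matrices
simulate_presence <- function(tree, rates, W, n_regions, root_mode) {
  rr <- resolve_ratemap(tree, rates)
  n_cells <- n_regions * W
  states <- vector("list", length(tree$ids))
  if (root_mode == "stationary") {
    b <- as_ratemap(rates)$default
    tot <- b$birth + b$death
    pi0 <- if (tot > 0) b$birth / tot else 0
    root_state <- matrix(stats::rbinom(n_cells, 1L, pi0), n_regions, W)
  } else if (root_mode == "empty") {
    root_state <- matrix(0L, n_regions, W)
  } else stop(sprintf("invalid root_mode: '%s'", root_mode))
  states[[tree$root]] <- root_state
  for (v in tree$preorder) {
    if (v == tree$root) next
    rb <- bd_rates(rr$birth[v], rr$death[v])
    p1 <- occupancy_prob(tree$blen[v], rb, initially_present = TRUE)
    p0 <- occupancy_prob(tree$blen[v], rb, initially_present = FALSE)
    parent <- states[[tree$parent[v]]]
    u <- stats::runif(n_cells)
    flip_p <- p0 + (p1 - p0) * parent      # per-cell survival/gain prob
    states[[v]] <- matrix((u < flip_p) + 0L, n_regions, W)
  }
  names(states) <- tree$ids
  list(states = states)
}

#' Simulate a dataset of regions with recorded ground truth
#'
#' Independent forward simulations of `n_regions` regions under the
#' birth-death model, returning the observable leaf count table together
#' with the full truth: per-node counts, per-branch gain/loss event
#' totals, and the true branch of origin of every site present in
#' `target_leaf` (obtained by applying the origin rule of
#' [branch_of_origin] to the true node counts). Fully reproducible from
#' `seed`.
#'
#' @inheritParams simulate_history
#' @param n_regions Number of regions (>= 1).
#' @param target_leaf Leaf whose sites receive truth origin calls.
#' @param split_node Passed to [branch_of_origin] for the truth calls.
#' @param seed Integer seed governing all randomness.
#' @param store_sites Keep the per-node site-level presence matrices
#'   (memory grows as nodes x regions x W).
#' @return A `bd_sim` list: `counts` ([region_counts]), `node_counts`
#'   (`bd_assignment` regions x nodes), `origins` (truth calls),
#'   `events` (per-branch data frame of true gains/losses), `sites`
#'   (list or NULL), plus `tree`, `rates`, `W`, `seed`, `target_leaf`,
#'   `split_node`.
#' @examples
#' sim <- simulate_dataset(example_timetree(), bd_rates(5e-11, 5e-9),
#'                         W = 201, n_regions = 10, seed = 1)
#' head(sim$counts)
#' @export
simulate_dataset <- function(tree, rates, W, n_regions,
                             root_mode = c("stationary", "empty"),
                             target_leaf = "human", split_node = NULL,
                             seed = 1L, store_sites = TRUE) {
  stopifnot(inherits(tree, "bd_tree"))
  root_mode <- match.arg(root_mode)
  if (n_regions < 1) stop("'n_regions' must be >= 1")
  if (W < 1) stop("'W' must be >= 1")
  set.seed(seed)
  sim <- simulate_presence(tree, rates, W, n_regions, root_mode)
  node_counts <- vapply(sim$states, rowSums, numeric(n_regions))
  if (n_regions == 1L) node_counts <- matrix(node_counts, nrow = 1,
                                             dimnames = list(NULL, tree$ids))
  storage.mode(node_counts) <- "integer"
  region_id <- sprintf("region%04d", seq_len(n_regions))
  rownames(node_counts) <- region_id
  node_counts <- structure(node_counts,
                           class = c("bd_assignment", "matrix"))
  tips <- leaf_labels(tree)
  counts <- region_counts(region_id, W,
                          node_counts[, tips, drop = FALSE])
  # true per-branch event totals from site-level endpoint flips
  ev <- data.frame(branch = branch_ids(tree), gains = 0L, losses = 0L,
                   stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ev))) {
    v <- node_index(tree, ev$branch[k])
    d <- sim$states[[v]] - sim$states[[tree$parent[v]]]
    ev$gains[k] <- sum(d == 1L)
    ev$losses[k] <- sum(d == -1L)
  }
  if (!target_leaf %in% tips) stop(sprintf("unknown target leaf: '%s'",
                                           target_leaf))
  origins <- branch_of_origin(node_counts, tree, target_leaf,
                              split_node = split_node)
  structure(list(counts = counts, node_counts = node_counts,
                 origins = origins, events = ev,
                 sites = if (store_sites) sim$states else NULL,
                 tree = tree, rates = rates, W = W, seed = seed,
                 root_mode = root_mode, target_leaf = target_leaf,
                 split_node = attr(origins, "split_node")),
            class = "bd_sim")
}

#' @export
print.bd_sim <- function(x, ...) {
  cat(sprintf("bd_sim: %d regions of width %d, seed %d; %d sites in %s\n",
              nrow(x$counts), x$W, x$seed,
              sum(x$counts[[x$target_leaf]], na.rm = TRUE), x$target_leaf))
  invisible(x)
}

#' Perturb leaf counts (sensitivity analysis)
#'
#' Emulates noise in the number of binding sites observed at the leaves:
#' each observed (region, species) count outside the protected leaf is,
#' with probability `fraction`, moved by +1 or -1 with equal odds (clamped
#' to `[0, W]`). Used to check the stability of branch-of-origin calls
#' under miscounted sites in non-target species.
#'
#' @param counts A [region_counts] object.
#' @param fraction Perturbation probability per observation, in `[0, 1]`.
#' @param protected_leaf Species whose counts are never touched.
#' @return A perturbed [region_counts] object.
#' @export
perturb_counts <- function(counts, fraction, protected_leaf = "human") {
  stopifnot(inherits(counts, "bd_counts"))
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  cm <- count_matrix(counts)
  for (spc in setdiff(colnames(cm), protected_leaf)) {
    obs <- which(!is.na(cm[, spc]))
    hit <- obs[stats::runif(length(obs)) < fraction]
    if (!length(hit)) next
    delta <- ifelse(stats::runif(length(hit)) < 0.5, -1L, 1L)
    cm[hit, spc] <- pmin(pmax(cm[hit, spc] + delta, 0L),
                         counts$width[hit])
  }
  region_counts(counts$region_id, counts$width, cm)
}

#' Perturb branch lengths (sensitivity analysis)
#'
#' Multiplies every branch length by an independent
#' Uniform(1 - max_rel_change, 1 + max_rel_change) draw, leaving the
#' topology unchanged. Used to check robustness of origin calls to
#' uncertainty in the time calibration.
#'
#' @param tree A [bd_tree].
#' @param max_rel_change Maximum relative change, in `[0, 1)`.
#' @return A perturbed [bd_tree].
#' @export
perturb_branch_lengths <- function(tree, max_rel_change) {
  stopifnot(inherits(tree, "bd_tree"))
  if (max_rel_change < 0 || max_rel_change >= 1)
    stop("'max_rel_change' must be in [0, 1)")
  f <- stats::runif(length(tree$phy$edge.length),
                    1 - max_rel_change, 1 + max_rel_change)
  tree$phy$edge.length <- tree$phy$edge.length * f
  tree$blen[tree$phy$edge[, 2]] <- tree$phy$edge.length
  tree
}

#' Compare two sets of origin calls
#'
#' Matches calls by (region, site index) and histograms the signed
#' path-distance between the origin branches: 0 means the call is
#' unchanged, negative values are rootward moves, positive values
#' leafward moves (ancestral calls sit at the split position). Sites
#' present in only one call set are tallied separately.
#'
#' @param calls_a,calls_b Outputs of [branch_of_origin] on the same
#'   lineage path.
#' @return List with `shifts` (named count vector over signed distances),
#'   `unmatched_a`, `unmatched_b`, and `unchanged_fraction` (fraction of
#'   matched pairs at shift 0).
#' @export
compare_origin_calls <- function(calls_a, calls_b) {
  pa <- attr(calls_a, "path"); pb <- attr(calls_b, "path")
  if (is.null(pa) || is.null(pb) || !identical(pa, pb))
    stop("call sets must share the same lineage path")
  key_a <- paste(calls_a$region_id, calls_a$site_index)
  key_b <- paste(calls_b$region_id, calls_b$site_index)
  i <- match(key_a, key_b)
  matched <- !is.na(i)
  d <- calls_b$position[i[matched]] - calls_a$position[matched]
  shifts <- table(factor(d, levels = seq(-length(pa), length(pa))))
  shifts <- shifts[shifts > 0 | names(shifts) == "0"]
  list(shifts = c(shifts),
       unmatched_a = sum(!matched),
       unmatched_b = sum(!(key_b %in% key_a)),
       unchanged_fraction = if (any(matched)) mean(d == 0) else NA_real_)
}
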