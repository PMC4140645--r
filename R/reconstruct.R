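#' Parsimony reconstruction of ancestral motif counts
#'
#' Sankoff dynamic programming with linear cost: the cost of a branch whose
#' endpoints hold counts a and b is |a - b| (one unit per gained or lost
#' site). Returns, per region, an assignment of counts to every node that
#' minimizes the total cost; ties are broken toward the smaller count so
#' the result is deterministic. Missing leaves carry zero cost in every
#' state. Used to initialize the rate-estimation EM.
#'
#' @param counts A [region_counts] object.
#' @param tree A [bd_tree].
#' @param n_max State cap for the search (default: max observed count + 1,
#'   which always contains a minimum-cost assignment under linear cost).
#' @return Integer matrix regions x nodes (columns named by node id) of
#'   class `bd_assignment`, with attribute `cost` holding the per-region
#'   minimum cost.
#' @export
parsimony_reconstruct <- function(counts, tree, n_max = NULL) {
  stopifnot(inherits(counts, "bd_counts"), inherits(tree, "bd_tree"))
  cm <- count_matrix(counts)
  if (is.null(n_max)) n_max <- max(cm, na.rm = TRUE) + 1L
  S <- n_max + 1L
  R <- nrow(cm)
  tips <- seq_len(tree$n_tip)
  sp <- colnames(cm)
  big <- .Machine$double.xmax / 4
  # step cost between states
  step <- abs(outer(0:n_max, 0:n_max, "-"))
  C <- vector("list", length(tree$ids))        # node cost tables S x R
  for (v in tree$postorder) {
    if (v %in% tips) {
      lab <- tree$ids[v]
      M <- matrix(0, S, R)
      if (lab %in% sp) {
        obs <- cm[, lab]
        seen <- which(!is.na(obs))
        if (length(seen)) {
          if (any(obs[seen] > n_max))
            stop(sprintf("observed count %d exceeds n_max = %d",
                         max(obs[seen]), n_max))
          M[, seen] <- big
          M[cbind(obs[seen] + 1L, seen)] <- 0
        }
      }
      C[[v]] <- M
    } else {
      M <- matrix(0, S, R)
      for (d in tree$children[[v]]) {
        # D[x, r] = min_y (|x - y| + C_d[y, r])
        D <- matrix(0, S, R)
        for (x in seq_len(S)) {
          D[x, ] <- do.call(pmin, asplit(step[x, ] + C[[d]], 1))
        }
        M <- M + D
      }
      C[[v]] <- M
    }
  }
  assign <- matrix(NA_integer_, R, length(tree$ids),
                   dimnames = list(counts$region_id, tree$ids))
  rootC <- C[[tree$root]]
  assign[, tree$root] <- max.col(t(-rootC), ties.method = "first") - 1L
  cost <- rootC[cbind(assign[, tree$root] + 1L, seq_len(R))]
  for (v in tree$preorder) {
    if (v == tree$root) next
    xp <- assign[, tree$parent[v]]
    # choose y minimizing |xp - y| + C_v[y, r]; ties -> smaller y
    Sc <- step[xp + 1L, , drop = FALSE] + t(C[[v]])
    assign[, v] <- max.col(-Sc, ties.method = "first") - 1L
  }
  structure(assign, cost = unname(cost), class = c("bd_assignment", "matrix"))
}

#' Most-likely ancestral counts (greedy maximum likelihood)
#'
#' Top-down reconstruction from the pruning tables: the root takes the
#' state maximizing `prior(x) * L_root(x)`; each child d of a parent fixed
#' at x takes `argmax_y T(x -> y; t_d) * L_d(y)`. Ties break toward the
#' smaller count. Observed leaves keep their observations; missing leaves
#' receive model-imputed states.
#'
#' @inheritParams region_loglik
#' @return Integer matrix regions x nodes (class `bd_assignment`).
#' @examples
#' tr <- example_timetree()
#' sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 201,
#'                         n_regions = 5, seed = 1)
#' ml_reconstruct(sim$counts, tr, bd_rates(5e-11, 5e-9))
#' @export
ml_reconstruct <- function(counts, tree, rates, n_max = NULL, nu = NULL) {
  if (is.null(n_max)) n_max <- default_n_max(counts)
  if (is.null(nu)) nu <- default_prior_mean(counts)
  # identical leaf patterns get identical assignments: reconstruct each
  # distinct (width, counts) pattern once and expand
  cm <- count_matrix(counts)
  key <- paste(counts$width, apply(cm, 1, paste, collapse = ","))
  uniq <- which(!duplicated(key))
  map <- match(key, key[uniq])
  sub <- counts[uniq, , drop = FALSE]
  class(sub) <- class(counts)
  pr <- prune_dataset(sub, tree, rates, n_max, nu = nu,
                      keep_tables = TRUE)
  asg <- reconstruct_from_tables(pr, tree)
  out <- asg[map, , drop = FALSE]
  rownames(out) <- counts$region_id
  structure(out, class = c("bd_assignment", "matrix"))
}

reconstruct_from_tables <- function(pr, tree) {
  counts <- pr$counts
  assign <- matrix(NA_integer_, nrow(counts), length(tree$ids),
                   dimnames = list(counts$region_id, tree$ids))
  S <- pr$n_max + 1L
  for (g in pr$groups) {
    idx <- g$idx
    tabs <- g$tables
    mats <- g$matrices
    rootL <- tabs[[tree$root]]$L * pr$prior
    assign[idx, tree$root] <- max.col(t(rootL), ties.method = "first") - 1L
    for (v in tree$preorder) {
      if (v == tree$root) next
      xp <- assign[idx, tree$parent[v]]
      Sc <- mats[[v]][xp + 1L, , drop = FALSE] * t(tabs[[v]]$L)
      assign[idx, v] <- max.col(Sc, ties.method = "first") - 1L
    }
  }
  structure(assign, class = c("bd_assignment", "matrix"))
}

#' Empirical birth-death rates from ancestral assignments
#'
#' Counts the events implied by a hard ancestral assignment and divides by
#' the exposure: the birth rate is total gains over total unoccupied
#' site-time `sum (W - n_parent) * t`, the death rate total losses over
#' total occupied site-time `sum n_parent * t`. A zero denominator or zero
#' event count yields the rate floor, with a warning for empty exposure.
#' When `classes` is given (named vector mapping branch ids to class
#' labels) rates are computed per class, as used by the lineage-specific
#' alternative model.
#'
#' @param assign A `bd_assignment` matrix (regions x nodes).
#' @param counts The [region_counts] the assignment was computed from
#'   (provides region widths).
#' @param tree A [bd_tree].
#' @param classes Optional named character vector branch id -> class.
#' @param rate_floor Lower bound replacing zero/undefined rates.
#' @return A [bd_rates] object, or a named list of them (one per class).
#' @export
empirical_rates <- function(assign, counts, tree, classes = NULL,
                            rate_floor = 1e-15) {
  stopifnot(inherits(assign, "bd_assignment"))
  W <- counts$width
  if (is.null(classes)) {
    classes <- stats::setNames(rep("all", length(branch_ids(tree))),
                               branch_ids(tree))
  }
  cls <- sort(unique(classes))
  gains <- losses <- up_time <- occ_time <- stats::setNames(
    numeric(length(cls)), cls)
  for (v in seq_along(tree$ids)) {
    if (v == tree$root) next
    cl <- classes[[tree$ids[v]]]
    p <- assign[, tree$parent[v]]
    ch <- assign[, v]
    t_b <- tree$blen[v]
    gains[cl] <- gains[cl] + sum(pmax(ch - p, 0))
    losses[cl] <- losses[cl] + sum(pmax(p - ch, 0))
    up_time[cl] <- up_time[cl] + sum((W - p) * t_b)
    occ_time[cl] <- occ_time[cl] + sum(p * t_b)
  }
  mk <- function(cl) {
    if (up_time[cl] <= 0) warning("no unoccupied site-time; birth rate at floor")
    if (occ_time[cl] <= 0) warning("no occupied site-time; death rate at floor")
    bd_rates(max(if (up_time[cl] > 0) gains[cl] / up_time[cl] else 0, rate_floor),
             max(if (occ_time[cl] > 0) losses[cl] / occ_time[cl] else 0, rate_floor))
  }
  out <- lapply(cls, mk)
  names(out) <- cls
  if (identical(cls, "all")) out[["all"]] else out
}
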