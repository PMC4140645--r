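#' Branch of origin for each present-day binding site
#'
#' Converts a per-region ancestral count assignment into per-site origin
#' calls along the lineage from the root to `target_leaf`. Writing the
#' reconstructed counts along that path as `c_0 (root), ..., c_K (leaf)`,
#' the leaf's h = c_K sites are ranked i = 1..h and site i originates on
#' the branch entering the oldest node of the most recent contiguous run
#' of path nodes with count >= i ending at the leaf. Sites are
#' exchangeable within a region, so this oldest-first convention is the
#' minimal-assumption matching of sites to count changes; for the dominant
#' 0/1 counts it reduces to the obvious rule. If the run reaches
#' `split_node` (or the root), the site predates the designated split and
#' its origin is reported as `"ancestral"`. A loss and re-gain below the
#' split yields the re-gain branch: a re-gained site is young.
#'
#' @param assign A `bd_assignment` matrix (from [ml_reconstruct],
#'   [parsimony_reconstruct], or simulator truth).
#' @param tree A [bd_tree].
#' @param target_leaf Leaf whose present-day sites are dated.
#' @param split_node Node id on the target lineage path at (or above)
#'   which an origin is called `"ancestral"`; default is the node right
#'   below the root on the path (i.e. only root-level presence is
#'   ancestral). For the bundled tree use `"euarchontoglires"`, the
#'   human-mouse ancestor.
#' @return Data frame of origin calls: `region_id`, `site_index`,
#'   `origin` (branch id or `"ancestral"`), and `position` (1-based index
#'   of the origin branch along the path; the split position for
#'   ancestral calls). Regions whose target-leaf count is 0 contribute no
#'   rows.
#' @examples
#' tr <- example_timetree()
#' sim <- simulate_dataset(tr, bd_rates(5e-11, 5e-9), W = 201,
#'                         n_regions = 50, seed = 3)
#' calls <- branch_of_origin(sim$node_counts, tr, "human",
#'                           split_node = "euarchontoglires")
#' head(calls)
#' @export
branch_of_origin <- function(assign, tree, target_leaf,
                             split_node = NULL) {
  stopifnot(inherits(assign, "bd_assignment"))
  path <- lineage_path(tree, target_leaf)
  if (is.null(split_node)) split_node <- path[1]
  split_pos <- match(split_node, path)
  if (is.na(split_pos))
    stop(sprintf("split node '%s' is not on the path to '%s'",
                 split_node, target_leaf))
  # counts along root, then each path node
  pc <- cbind(assign[, tree$ids[tree$root], drop = FALSE],
              assign[, path, drop = FALSE])
  K <- length(path)
  h <- pc[, K + 1L]
  keep <- which(h > 0)
  out <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    r <- keep[ii]
    c_path <- pc[r, ]
    hr <- h[r]
    orig <- character(hr)
    pos <- integer(hr)
    for (i in seq_len(hr)) {
      ok <- c_path >= i          # positions 0..K (1-based index 1..K+1)
      j <- K + 1L                # node index in c_path
      while (j > 1L && ok[j - 1L]) j <- j - 1L
      j0 <- j - 1L               # 0-based path node index of run top
      if (j0 <= split_pos) {
        orig[i] <- "ancestral"
        pos[i] <- split_pos
      } else {
        orig[i] <- path[j0]
        pos[i] <- j0
      }
    }
    out[[ii]] <- data.frame(region_id = rownames(pc)[r],
                            site_index = seq_len(hr), origin = orig,
                            position = pos, stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out)
  else data.frame(region_id = character(0), site_index = integer(0),
                  origin = character(0), position = integer(0))
  attr(calls, "path") <- path
  attr(calls, "split_node") <- split_node
  attr(calls, "target_leaf") <- target_leaf
  calls
}

#' Age-class map for a target lineage
#'
#' Maps every branch of the root-to-leaf path below the ancestral split to
#' a named age class (e.g. human-specific, hominid, simian, primate);
#' origins at or above the split are the `"ancestral"` class. The classes
#' partition the path.
#'
#' @param tree A [bd_tree].
#' @param target_leaf Target leaf label.
#' @param split_node Node id defining `"ancestral"`.
#' @param classes Named character vector branch id -> class label covering
#'   every path branch below the split.
#' @return An `bd_age_classes` list used by [age_distribution].
#' @export
age_class_map <- function(tree, target_leaf, split_node, classes) {
  path <- lineage_path(tree, target_leaf)
  split_pos <- match(split_node, path)
  if (is.na(split_pos)) stop("split node must lie on the target path")
  below <- path[(split_pos + 1L):length(path)]
  missing <- setdiff(below, names(classes))
  if (length(missing))
    stop(sprintf("no age class for path branch '%s'", missing[1]))
  structure(list(path = path, split_node = split_node,
                 classes = classes[below],
                 levels = c(unique(unname(classes[below])), "ancestral")),
            class = "bd_age_classes")
}

#' Age classes for the bundled 10-taxon tree
#'
#' Human-lineage classification used in examples: ancestral (at or above
#' the human-mouse ancestor), then primate, simian, hominid and human
#' specific, from the primate stem down to the terminal human branch.
#'
#' @return A `bd_age_classes` object for [example_timetree].
#' @export
example_age_classes <- function() {
  age_class_map(example_timetree(), "human", "euarchontoglires",
                c(primates = "primate", simiiformes = "simian",
                  catarrhini = "simian", hominidae = "hominid",
                  homininae = "hominid", hominini = "hominid",
                  human = "human"))
}

#' Age distribution of origin calls
#'
#' Tallies origin calls into age classes and reports counts and fractions
#' (fractions sum to one).
#'
#' @param calls Output of [branch_of_origin].
#' @param class_map An [age_class_map].
#' @return Data frame `class`, `count`, `fraction`, ordered young to old
#'   per the class map.
#' @export
age_distribution <- function(calls, class_map) {
  stopifnot(inherits(class_map, "bd_age_classes"))
  if (nrow(calls) == 0) stop("no origin calls to classify")
  cl <- ifelse(calls$origin == "ancestral", "ancestral",
               unname(class_map$classes[calls$origin]))
  if (anyNA(cl))
    stop(sprintf("origin branch '%s' missing from the age-class map",
                 calls$origin[is.na(cl)][1]))
  lv <- class_map$levels
  n <- vapply(lv, function(l) sum(cl == l), numeric(1))
  data.frame(class = lv, count = as.integer(n), fraction = n / sum(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-branch binding-site creation rate
#'
#' Divides the number of sites originating on each path branch by the
#' branch duration, in sites per million years; only sites currently
#' existing in the target species contribute. Ancestral calls are not
#' assigned to a branch and are excluded.
#'
#' @param calls Output of [branch_of_origin].
#' @param tree A [bd_tree].
#' @return Data frame `branch`, `n_sites`, `duration_My`, `rate_per_My`
#'   over the non-ancestral path branches.
#' @export
origin_rate_per_branch <- function(calls, tree) {
  path <- attr(calls, "path")
  if (is.null(path)) stop("'calls' must come from branch_of_origin()")
  split_pos <- match(attr(calls, "split_node"), path)
  below <- path[(split_pos + 1L):length(path)]
  dur <- tree$blen[node_index(tree, below)] / 1e6
  if (any(dur <= 0)) stop("zero-duration branch on the path")
  n <- vapply(below, function(b) sum(calls$origin == b), numeric(1))
  data.frame(branch = below, n_sites = as.integer(n), duration_My = dur,
             rate_per_My = n / dur, row.names = NULL,
             stringsAsFactors = FALSE)
}
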