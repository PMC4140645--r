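#' Rooted time-calibrated trees
#'
#' A `bd_tree` is a rooted phylogeny whose branch lengths are divergence
#' times in years. It wraps an [ape::phylo] object and adds the bookkeeping
#' the birth-death machinery needs: stable node identifiers, parent links,
#' and traversal orders. Every non-root node carries the length (in years)
#' of the branch entering it; a branch is therefore identified throughout
#' the package by the id of its child node.
#'
#' Internal nodes keep their Newick labels when present; unlabeled internal
#' nodes receive deterministic post-order ids (`node1`, `node2`, ...) so
#' results are reproducible across runs and machines.
#'
#' @name bd_tree
#' @keywords internal
NULL

new_bd_tree <- function(phy, unit = c("years", "My")) {
  unit <- match.arg(unit)
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length)) {
    stop("Newick parse error: branch lengths are required on all non-root edges")
  }
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    bad <- which(is.na(phy$edge.length) | !is.finite(phy$edge.length))[1]
    stop(sprintf("Newick parse error: missing/non-finite branch length on edge to node %d",
                 phy$edge[bad, 2]))
  }
  if (any(phy$edge.length < 0)) {
    bad <- which(phy$edge.length < 0)[1]
    stop(sprintf("branch length negative on edge to node %d", phy$edge[bad, 2]))
  }
  tips <- phy$tip.label
  if (anyDuplicated(tips)) {
    stop(sprintf("duplicate leaf label: '%s'", tips[duplicated(tips)][1]))
  }
  if (any(!nzchar(tips))) stop("empty leaf label")
  if (unit == "My") phy$edge.length <- phy$edge.length * 1e6

  n_tip <- length(tips)
  n_node <- phy$Nnode
  n_all <- n_tip + n_node
  parent <- rep(NA_integer_, n_all)
  blen <- rep(NA_real_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  root <- which(is.na(parent[seq_len(n_all)]) & seq_len(n_all) > n_tip)
  if (length(root) != 1L) stop("tree must have exactly one root")

  # deterministic post-order over nodes (children before parents)
  po_edges <- ape::reorder.phylo(phy, "postorder")$edge
  post <- unique(c(po_edges[, 2], root))

  ids <- character(n_all)
  ids[seq_len(n_tip)] <- tips
  has_lab <- !is.null(phy$node.label) && any(nzchar(phy$node.label))
  k <- 0L
  for (v in post) {
    if (v <= n_tip) next
    lab <- if (has_lab) phy$node.label[v - n_tip] else ""
    if (is.na(lab) || !nzchar(lab)) {
      k <- k + 1L
      lab <- paste0("node", k)
    }
    ids[v] <- lab
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate node id: '%s'", ids[duplicated(ids)][1]))
  }
  children <- vector("list", n_all)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    children[[p]] <- c(children[[p]], phy$edge[e, 2])
  }
  structure(list(
    phy = phy, ids = ids, parent = parent, blen = blen,
    n_tip = n_tip, root = root, postorder = post,
    preorder = rev(post), children = children
  ), class = "bd_tree")
}

#' Read a time-calibrated tree from Newick
#'
#' Parses a strict Newick string (branch lengths required on every non-root
#' edge) into a [bd_tree]. Branch lengths are normalized internally to
#' years so that birth/death rates are always per site-year.
#'
#' @param file Path to a Newick file (exactly one tree).
#' @param text Newick string; give either `file` or `text`.
#' @param unit Unit of the branch lengths in the input: `"years"` or
#'   `"My"` (million years; multiplied by 1e6 on input).
#' @return A `bd_tree` object.
#' @examples
#' tr <- read_timetree(text = "((A:1,B:1):1,C:2);")
#' leaf_labels(tr)
#' @export
read_timetree <- function(file = NULL, text = NULL, unit = c("years", "My")) {
  if (is.null(text)) {
    if (is.null(file)) stop("give either 'file' or 'text'")
    if (!file.exists(file)) stop(sprintf("tree file not found: '%s'", file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop(sprintf("Newick parse error in: '%s'",
                                 substr(text, 1, 60)))
  new_bd_tree(phy, unit = match.arg(unit))
}

#' Write a tree as Newick
#'
#' @param tree A [bd_tree].
#' @param file Optional output path; if `NULL` the Newick string is returned.
#' @param unit Unit for the emitted branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, unit = c("years", "My")) {
  stopifnot(inherits(tree, "bd_tree"))
  unit <- match.arg(unit)
  phy <- tree$phy
  if (unit == "My") phy$edge.length <- phy$edge.length / 1e6
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @export
print.bd_tree <- function(x, ...) {
  cat(sprintf("bd_tree: %d leaves, %d internal nodes, depth %.4g years\n",
              x$n_tip, length(x$ids) - x$n_tip,
              max(node_depths(x)[seq_len(x$n_tip)])))
  invisible(x)
}

#' Leaf labels of a tree
#' @param tree A [bd_tree].
#' @return Character vector of species names.
#' @export
leaf_labels <- function(tree) tree$phy$tip.label

#' All branch ids of a tree
#'
#' A branch is identified by the id of its child node; the root has no
#' entering branch.
#' @param tree A [bd_tree].
#' @return Character vector of branch ids.
#' @export
branch_ids <- function(tree) tree$ids[-tree$root]

node_index <- function(tree, id) {
  i <- match(id, tree$ids)
  if (anyNA(i)) stop(sprintf("unknown node id: '%s'", id[is.na(i)][1]))
  i
}

node_depths <- function(tree) {
  d <- numeric(length(tree$ids))
  for (v in tree$preorder) {
    if (v == tree$root) next
    d[v] <- d[tree$parent[v]] + tree$blen[v]
  }
  d
}

#' Root-to-leaf lineage path
#'
#' Returns the ordered branches from the root down to a named leaf. Each
#' branch is identified by the id of its child node, so the last element
#' is the leaf itself.
#'
#' @param tree A [bd_tree].
#' @param leaf Leaf label.
#' @return Character vector of branch ids, ordered root to leaf.
#' @examples
#' tr <- read_timetree(text = "((A:1,B:1):1,C:2);")
#' lineage_path(tr, "A")
#' @export
lineage_path <- function(tree, leaf) {
  stopifnot(inherits(tree, "bd_tree"))
  v <- match(leaf, leaf_labels(tree))
  if (is.na(v)) stop(sprintf("unknown leaf: '%s'", leaf))
  path <- integer(0)
  while (v != tree$root) {
    path <- c(v, path)
    v <- tree$parent[v]
  }
  tree$ids[path]
}

#' Rescale all branch lengths
#'
#' Multiplies every branch length by a positive factor, e.g. for unit
#' conversion. Topology and labels are unchanged.
#'
#' @param tree A [bd_tree].
#' @param factor Positive scaling factor.
#' @return A `bd_tree` with scaled branch lengths.
#' @export
scale_branch_lengths <- function(tree, factor) {
  stopifnot(inherits(tree, "bd_tree"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    stop("'factor' must be a single positive number")
  }
  tree$phy$edge.length <- tree$phy$edge.length * factor
  tree$blen <- tree$blen * factor
  tree
}

#' Bundled 10-taxon vertebrate timetree
#'
#' A toy time-calibrated phylogeny of ten vertebrates (human, chimp,
#' gorilla, orangutan, macaque, marmoset, bushbaby, mouse, dog, cow) with
#' round-number divergence times totalling 100 My of depth. It is the
#' default substrate for simulations and examples; any user-supplied
#' timetree can be used instead.
#'
#' @return A [bd_tree] with branch lengths in years.
#' @examples
#' tr <- example_timetree()
#' lineage_path(tr, "human")
#' @export
example_timetree <- function() {
  read_timetree(file = system.file("extdata", "timetree10.nwk",
                                   package = "bdtfbs"),
                unit = "My")
}
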