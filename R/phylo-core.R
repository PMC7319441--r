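#' Validate a time-calibrated tree as a chronogram
#'
#' Checks that a phylogeny is a rooted, ultrametric time tree with
#' non-negative branch lengths (in Myr) and unique tip labels, and snaps tip
#' ages to exactly zero when they are within tolerance. All time-indexed
#' statistics in the package assume a tree that passes this check.
#'
#' Ages throughout the package are measured in Ma before present: tips sit at
#' age 0 and the root at the crown age of the clade.
#'
#' @param phy an object of class `"phylo"` (see [ape::read.tree()]).
#' @param tolerance absolute tolerance (Myr) for the ultrametricity check.
#'   Defaults to `1e-6` times the root age, which absorbs the rounding error
#'   real dated trees carry.
#' @return the validated `"phylo"` object, with pendant branch lengths
#'   adjusted so every tip age is exactly 0.
#' @seealso [read_chronogram()], [node_ages()]
#' @export
as_chronogram <- function(phy, tolerance = NULL) {
  if (!inherits(phy, "phylo")) stop_ccl("`phy` must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop_ccl("tree has no branch lengths")
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
    stop_ccl("branch lengths must be non-negative and non-missing")
  if (anyDuplicated(phy$tip.label))
    stop_ccl("duplicate tip labels: ",
             paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                   collapse = ", "))
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop_ccl("a chronogram needs at least 2 tips")

  depth <- ape::node.depth.edgelength(phy)  # root-to-node path lengths
  root_age <- max(depth[seq_len(ntip)])
  if (root_age <= 0) stop_ccl("root age must be positive")
  tol <- tolerance %||% (1e-6 * root_age)
  off <- root_age - depth[seq_len(ntip)]    # tip ages before snapping
  worst <- which.max(abs(off))
  if (abs(off[worst]) > tol)
    stop_ccl(sprintf(
      "tree is not ultrametric within tolerance %g: tip \"%s\" has age %g Ma",
      tol, phy$tip.label[worst], off[worst]))

  # snap: absorb the residual into the pendant branches so tip ages are 0
  pend <- match(seq_len(ntip), phy$edge[, 2L])
  phy$edge.length[pend] <- phy$edge.length[pend] + off
  if (any(phy$edge.length < 0)) phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Read a chronogram from Newick
#'
#' Thin wrapper around [ape::read.tree()] that accepts either a file path or a
#' literal Newick string and validates the result with [as_chronogram()].
#'
#' @param source path to a Newick file, or a Newick string (recognised by a
#'   `(` character).
#' @inheritParams as_chronogram
#' @return a validated `"phylo"` chronogram.
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' root_age(tr)
#' @export
read_chronogram <- function(source, tolerance = NULL) {
  stopifnot(is.character(source), length(source) == 1L)
  phy <- if (grepl("(", source, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(source)) stop_ccl("file not found: ", source)
    tryCatch(ape::read.tree(file = source),
             error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(phy)) stop_ccl("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  as_chronogram(phy, tolerance)
}

#' Write a chronogram to Newick
#'
#' @param tree a chronogram (`"phylo"`).
#' @param path output file; `NULL` returns the Newick string only.
#' @param digits significant digits for branch lengths (default 10, enough
#'   for round-trip identity at Myr scale).
#' @return the Newick string, invisibly when written to a file.
#' @export
write_chronogram <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Node ages of a chronogram
#'
#' @param tree a chronogram (`"phylo"`), validated via [as_chronogram()].
#' @return numeric vector of ages (Ma before present) for all nodes, indexed
#'   by node number (tips `1..Ntip`, then internal nodes); tips are exactly 0
#'   and the root is maximal. Tip entries are named by tip label.
#' @export
node_ages <- function(tree) {
  tree <- as_chronogram(tree)
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  age <- max(depth[seq_len(ntip)]) - depth
  age[seq_len(ntip)] <- 0
  names(age) <- c(tree$tip.label, rep("", length(age) - ntip))
  age
}

#' Crown (root) age of a chronogram
#' @inheritParams node_ages
#' @return root age in Ma.
#' @export
root_age <- function(tree) max(node_ages(tree))

#' Branches alive at a given age
#'
#' A branch subtending node `k` occupies the half-open age interval
#' `[age(k), age(parent(k)))`, so every age maps each extant lineage to
#' exactly one branch. Queries at exactly the root age return the root's two
#' (or more) child branches, the crown lineages.
#'
#' @inheritParams node_ages
#' @param age age in Ma, within `[0, root age]`.
#' @return integer vector of edge indices (rows of `tree$edge`), named by the
#'   subtending (child) node number.
#' @export
lineages_at <- function(tree, age) {
  stopifnot(is.numeric(age), length(age) == 1L)
  ages <- node_ages(tree)
  ra <- max(ages)
  if (age < 0 || age > ra)
    stop_ccl(sprintf("age %g outside [0, %g]", age, ra))
  parent_age <- ages[tree$edge[, 1L]]
  child_age <- ages[tree$edge[, 2L]]
  idx <- which(child_age <= age & age < parent_age)
  if (length(idx) == 0L) {                       # age == root age
    root <- length(tree$tip.label) + 1L
    idx <- which(tree$edge[, 1L] == root)
  }
  names(idx) <- tree$edge[idx, 2L]
  idx
}

#' Randomly resolve polytomies into a binary chronogram
#'
#' Multifurcations are broken by uniform random sequential binarisation with
#' zero-length internal branches (via [ape::multi2di()]), so node ages and the
#' total branch length are unchanged. Deterministic for a fixed seed.
#'
#' @inheritParams node_ages
#' @param seed integer seed controlling the random resolution.
#' @return a strictly binary chronogram.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  tree <- as_chronogram(tree)
  if (ape::is.binary(tree)) return(tree)
  out <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  as_chronogram(out)
}

#' Prune a chronogram to a set of tips
#'
#' Keeps the induced subtree on `labels`, suppressing degree-two nodes and
#' summing their branch lengths, so root-to-tip depths of retained tips are
#' preserved.
#'
#' @inheritParams node_ages
#' @param labels tip labels to retain (at least 2, all present in the tree).
#' @return the pruned chronogram.
#' @export
prune_to_taxa <- function(tree, labels) {
  tree <- as_chronogram(tree)
  labels <- as.character(labels)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    stop_ccl("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(labels) < 2L) stop_ccl("need at least 2 tip labels to prune to")
  as_chronogram(ape::keep.tip(tree, labels))
}
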