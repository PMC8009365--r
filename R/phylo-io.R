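#' Read a dated phylogeny from a Newick file
#'
#' Reads a rooted, fully bifurcating tree with branch lengths in millions of
#' years (Ma) and validates it for use in the range-evolution machinery.
#' Trees with polytomies, duplicated tip labels, missing or negative branch
#' lengths, or fewer than 3 tips are rejected.
#'
#' @param path path to a Newick file (a single tree).
#' @param text alternatively, a Newick string (overrides \code{path}).
#' @return an \code{ape} \code{"phylo"} object that passes
#'   \code{\link{validate_phylogeny}}.
#' @examples
#' tr <- read_biome_newick(text = "((A:1,B:1):1,C:2);")
#' @seealso \code{\link{validate_phylogeny}}
#' @export
read_biome_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_phylogeny(tr)
  tr
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a \code{"phylo"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_biome_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Validate a phylogeny for biome-shift analyses
#'
#' Checks the invariants the models assume: rooted, strictly bifurcating,
#' at least 3 tips, unique tip labels, and non-negative branch lengths on
#' every edge. A non-ultrametric tree is accepted with a warning: strata are
#' assigned from absolute node ages, taking the deepest tip as the present.
#'
#' @param tree a \code{"phylo"} object.
#' @return \code{tree}, invisibly; otherwise an error naming the offence.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("tree has ", n_tip, " tips; at least 3 required")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)[1L]
    stop("missing or negative branch length on edge to node ", tree$edge[bad, 2L])
  }
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  tab <- tabulate(tree$edge[, 1L])
  poly <- which(tab > 2L)
  if (length(poly)) stop("polytomy at node ", poly[1L],
                         " (", tab[poly[1L]], " children); resolve before use")
  # root must also be binary for the cladogenetic model
  invisible(tree)
}

# Node ages in Ma before present: age = tree height - root-to-node depth,
# with the deepest tip defining the present (age 0).
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_along(tree$tip.label)])
  h - depth
}

is_ultrametric_tol <- function(tree, tol = 1e-8) {
  a <- node_ages(tree)[seq_along(tree$tip.label)]
  diff(range(a)) <= tol * max(1, max(abs(a)))
}
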