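#' Read and validate a Newick tree
#'
#' Parses a Newick string (or a file containing one) into an `ape::phylo`
#' tree and validates the properties downstream analyses rely on: unique tip
#' labels, branch lengths present on every edge, and no negative lengths.
#' Zero-length branches are allowed (they produce tips with identical
#' phylogenetic covariance); polytomies are allowed and treated as true
#' multifurcations.
#'
#' @param text A Newick string, or the path of a file holding one.
#' @return A `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- if (file.exists(text) && !grepl("\\(", text)) {
    tryCatch(ape::read.tree(text), error = function(e) NULL, warning = function(w) NULL)
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick input: ", substr(text, 1, 60), call. = FALSE)
  }
  validate_phylogeny(tr)
}

# Shared tree validation; returns the tree invisibly-compatible.
validate_phylogeny <- function(tr) {
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("tree is missing branch lengths", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree, digits = 15))
  ape::write.tree(tree, file = file, digits = 15)
  invisible(ape::write.tree(tree, digits = 15))
}

#' Graft a new species next to an existing tip
#'
#' Attaches `new_tip` to the terminal branch of `sister_taxon`, at
#' `stem_fraction` of that branch measured from the sister tip. The new tip's
#' branch length equals the attachment depth, so grafting onto an
#' ultrametric tree keeps it ultrametric and never changes path lengths
#' among pre-existing tips. This mirrors the manual placement of species
#' absent from a published timetree.
#'
#' @param tree A `phylo` object.
#' @param new_tip Label for the grafted species (must be new).
#' @param sister_taxon Existing tip label the new species attaches next to.
#' @param stem_fraction Position of the attachment point along the sister's
#'   terminal branch, in (0, 1), measured from the sister tip.
#' @return A `phylo` object with one extra tip.
#' @export
graft_species <- function(tree, new_tip, sister_taxon, stem_fraction = 0.5) {
  validate_phylogeny(tree)
  idx <- match(sister_taxon, tree$tip.label)
  if (is.na(idx)) stop("sister taxon not found: ", sister_taxon, call. = FALSE)
  if (new_tip %in% tree$tip.label) {
    stop("tip label already present: ", new_tip, call. = FALSE)
  }
  if (!is.numeric(stem_fraction) || stem_fraction <= 0 || stem_fraction >= 1) {
    stop("stem_fraction must lie strictly inside (0, 1)", call. = FALSE)
  }
  edge_row <- which(tree$edge[, 2] == idx)
  pos <- stem_fraction * tree$edge.length[edge_row]
  tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                        tip.label = new_tip,
                        edge.length = pos,
                        Nnode = 1L),
                   class = "phylo")
  out <- ape::bind.tree(tree, tip, where = idx, position = pos)
  validate_phylogeny(out)
}

#' Phylogenetic variance-covariance matrix
#'
#' The among-species covariance implied by Brownian motion on the tree:
#' entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j, and the diagonal holds root-to-tip
#' depths. Every phylogenetic regression and imputation model in the package
#' consumes this matrix (possibly after [lambda_transform()]).
#'
#' @param tree A `phylo` object.
#' @param tip_order Optional character vector ordering (and subsetting) the
#'   rows/columns; defaults to the tree's tip order.
#' @param normalize_depth Divide the matrix by its maximum depth so the
#'   deepest tip has unit variance? Off by default; it only rescales the
#'   Brownian rate and leaves test statistics unchanged.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree, tip_order = NULL, normalize_depth = FALSE) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(tip_order)) {
    missing_tips <- setdiff(tip_order, rownames(C))
    if (length(missing_tips)) {
      stop("tip(s) not in tree: ", paste(missing_tips, collapse = ", "),
           call. = FALSE)
    }
    C <- C[tip_order, tip_order, drop = FALSE]
  }
  if (normalize_depth) C <- C / max(diag(C))
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies every off-diagonal entry by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` returns the full Brownian expectation,
#' `lambda = 0` the star phylogeny (no phylogenetic signal); intermediate
#' values interpolate, which accommodates a range of patterns of
#' phylogenetic dependence.
#'
#' @param C A phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda Signal strength in \[0, 1\].
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}
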