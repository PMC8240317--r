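#' Taxon-taxon phylogenetic distance matrix
#'
#' Converts a phylogeny into the distance matrix used to weight the L1
#' penalty on taxon-taxon coefficients. The default metric is the number of
#' branches (tree edges) on the path connecting two leaf taxa; with
#' `use_branch_lengths = TRUE` the patristic (summed branch length) distance
#' is used instead. A pre-computed square distance matrix can be supplied in
#' place of a tree, and with neither, all between-taxon distances are set to
#' 1 so the penalty is unweighted.
#'
#' @param tree A `phylo` object, a newick string, or a path to a newick
#'   file. Leaves not in `taxon_ids` are pruned; every taxon must be a leaf.
#' @param distance Alternatively, a square symmetric matrix (or path to a
#'   TSV/CSV with ids in the first column) over `taxon_ids`.
#' @param taxon_ids Character vector of taxa, in count-matrix column order.
#' @param use_branch_lengths If `TRUE`, sum branch lengths along paths
#'   instead of counting edges.
#' @return An `m x m` symmetric numeric matrix with zero diagonal and
#'   strictly positive off-diagonal entries, rows/columns in `taxon_ids`
#'   order.
#' @examples
#' phylo_distances(tree = "((A,B),C);", taxon_ids = c("A", "B", "C"))
#' phylo_distances(taxon_ids = c("A", "B", "C"))  # no tree: all distances 1
#' @export
phylo_distances <- function(tree = NULL, distance = NULL, taxon_ids,
                            use_branch_lengths = FALSE) {
  m <- length(taxon_ids)
  stopifnot(m >= 2, !anyDuplicated(taxon_ids))

  if (!is.null(distance)) {
    if (is.character(distance) && length(distance) == 1L) {
      df <- read_delimited(distance)
      distance <- as.matrix(df[, -1, drop = FALSE])
      rownames(distance) <- as.character(df[[1]])
    }
    distance <- as.matrix(distance)
    if (is.null(rownames(distance))) rownames(distance) <- colnames(distance)
    missing <- setdiff(taxon_ids, rownames(distance))
    if (length(missing)) {
      stop("taxa absent from distance matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    D <- distance[taxon_ids, taxon_ids]
    if (max(abs(D - t(D))) > 1e-8) {
      stop("user distance matrix is not symmetric", call. = FALSE)
    }
    D <- (D + t(D)) / 2
    diag(D) <- 0
    if (any(D[upper.tri(D)] <= 0)) {
      stop("off-diagonal distances must be positive", call. = FALSE)
    }
    return(D)
  }

  if (is.null(tree)) {
    D <- matrix(1, m, m, dimnames = list(taxon_ids, taxon_ids))
    diag(D) <- 0
    return(D)
  }

  phy <- as_phylo(tree)
  missing <- setdiff(taxon_ids, phy$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(phy$tip.label) > m) {
    phy <- ape::keep.tip(phy, taxon_ids)
  }
  if (!use_branch_lengths || is.null(phy$edge.length)) {
    # branch-count metric: unit edge lengths, pairwise path lengths
    phy$edge.length <- rep(1, nrow(phy$edge))
  }
  D <- ape::cophenetic.phylo(phy)[taxon_ids, taxon_ids]
  diag(D) <- 0
  D
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a newick string, or a file path",
       call. = FALSE)
}
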