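#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream host-range models rely on: the tree must parse, be rooted, have
#' unique tip labels, and carry a branch length on every non-root edge (no
#' silent defaults). Tip order is the order of first appearance in the Newick
#' string.
#'
#' @param text a Newick string (must end in ';')
#' @param file path to a Newick file (used when \code{text} is NULL)
#' @return an object of class \code{phylo}
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  if (!inherits(tree, "phylo")) tree <- tree[[1]]
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch length on one or more edges; ",
         "all non-root edges must carry a length")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (!ape::is.rooted(tree)) stop("tree must be rooted (single root node)")
  tree
}

# locate the first structural problem so the error can name a character
# position, which read.tree does not do
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' (string ends at character %d)",
                 depth, length(chars)))
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("malformed Newick: no terminating ';' (string ends at character %d)",
                 length(chars)))
  invisible(TRUE)
}

#' Validate that a tree is ultrametric and return its height
#'
#' All tips must be equidistant from the root within a relative tolerance:
#' \code{max |depth_tip - H| / H <= tol}, with \code{H} the mean tip depth.
#' Ultrametricity is a requirement of the relatedness structure used by the
#' phylogenetic mixed models (the MRCA-depth matrix has constant diagonal
#' only on an ultrametric tree).
#'
#' @param tree a \code{phylo} object with branch lengths
#' @param tol relative tolerance (default 1e-6)
#' @return the tree height \eqn{H}
#' @examples
#' validateUltrametric(readNewick("((A:1,B:1):1,C:2);")) # 2
#' @export
validateUltrametric <- function(tree, tol = 1e-6) {
  depths <- .tip_depths(tree)
  H <- mean(depths)
  if (H <= 0) stop("tree height must be positive")
  dev <- abs(depths - H) / H
  if (max(dev) > tol) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric at tol %g: tip '%s' has depth %.6g vs height %.6g (relative deviation %.3g)",
      tol, tree$tip.label[worst], depths[worst], H, dev[worst]))
  }
  H
}

.tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_along(tree$tip.label)]
}

.tip_index <- function(tree, label, what = "tip") {
  i <- match(label, tree$tip.label)
  if (anyNA(i))
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(label[is.na(i)], collapse = ", ")))
  i
}

#' Cophenetic (patristic) distance between two tips
#'
#' Sum of branch lengths on the path between tips \code{a} and \code{b};
#' on an ultrametric tree of height \eqn{H} this equals
#' \eqn{2(H - \mathrm{depth}(\mathrm{MRCA}(a,b)))}.
#'
#' @param tree a \code{phylo} object
#' @param a,b tip labels
#' @return the path-length distance (0 iff \code{a == b})
#' @export
copheneticDistance <- function(tree, a, b) {
  .tip_index(tree, c(a, b))
  D <- ape::cophenetic.phylo(tree)
  unname(D[a, b])
}

#' Cophenetic distances from a focal tip
#'
#' Distance of every tip from a designated focal host (in the study design,
#' \emph{C. elegans}); used as the fixed-effect covariate "phylogenetic
#' distance from the focal host" in the mixed models.
#'
#' @param tree a \code{phylo} object
#' @param focal the focal tip label
#' @return named numeric vector over all tips (tip order of the tree);
#'   the focal entry is 0
#' @examples
#' distanceFromFocal(readNewick("((A:1,B:1):1,C:2);"), "A") # A=0 B=2 C=4
#' @export
distanceFromFocal <- function(tree, focal) {
  .tip_index(tree, focal, "focal tip")
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, focal]
}

#' Build the phylogenetic relatedness structure
#'
#' Computes the matrix \eqn{A} with \eqn{A[i,j]} the distance from the root
#' to the MRCA of tips \eqn{i} and \eqn{j} (the Brownian-motion trait
#' covariance on the tree, as returned by [ape::vcv.phylo()]) and its dense
#' inverse. The tree is first validated as ultrametric. A minimum effective
#' tip separation of \code{1e-9 * H} is imposed so that duplicate rows from
#' zero-length terminal pairs cannot make \eqn{A} singular; if factorization
#' still fails the error advises enforcing a minimum branch length.
#'
#' @param tree a validated ultrametric \code{phylo} object
#' @param tol ultrametricity tolerance passed to [validateUltrametric()]
#' @return a [RelatednessStructure-class] object
#' @examples
#' rel <- relatednessMatrix(readNewick("((A:1,B:1):1,C:2);"))
#' relMatrix(rel) # diag 2, MRCA depths off-diagonal
#' @export
relatednessMatrix <- function(tree, tol = 1e-6) {
  H <- validateUltrametric(tree, tol)
  A <- ape::vcv.phylo(tree)
  A <- A[tree$tip.label, tree$tip.label, drop = FALSE]
  # clamp off-diagonal MRCA depths below H: zero-length terminal pairs would
  # otherwise duplicate rows and break positive-definiteness
  eps <- 1e-9 * H
  off <- row(A) != col(A)
  A[off] <- pmin(A[off], H - eps)
  diag(A) <- H
  A <- (A + t(A)) / 2
  R <- tryCatch(chol(A), error = function(e)
    stop("relatedness matrix is not positive definite (", conditionMessage(e),
         "); enforce a minimum branch length between near-identical tips",
         call. = FALSE))
  Ainv <- chol2inv(R)
  dimnames(Ainv) <- dimnames(A)
  new("RelatednessStructure", taxa = tree$tip.label, A = A, Ainv = Ainv,
      height = H)
}

#' Prune a tree to a subset of tips
#'
#' Returns the induced subtree on \code{keep}, with degree-2 internal nodes
#' suppressed and their branch lengths summed, so cophenetic distances among
#' the kept tips (and the height of an ultrametric tree) are unchanged.
#'
#' @param tree a \code{phylo} object
#' @param keep character vector of tip labels to retain (at least 2)
#' @return the pruned \code{phylo}
#' @export
pruneToTaxa <- function(tree, keep) {
  .tip_index(tree, keep)
  if (length(keep) < 2) stop("keep at least 2 tips")
  ape::keep.tip(tree, keep)
}

#' Write / read a relatedness matrix as labelled TSV
#'
#' Plain-text serialization of the \eqn{A} matrix with taxon labels as the
#' header row and first column.
#'
#' @param rel a [RelatednessStructure-class]
#' @param path output file
#' @return \code{writeRelatedness}: the path, invisibly.
#'   \code{readRelatednessTSV}: the labelled matrix.
#' @export
writeRelatedness <- function(rel, path) {
  A <- relMatrix(rel)
  df <- data.frame(taxon = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRelatedness
#' @export
readRelatednessTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  A
}
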