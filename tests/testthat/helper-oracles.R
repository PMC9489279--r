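# Brute-force tree oracles working directly on the phylo edge list, kept
# independent of the package's (ape-backed) implementations.

# list of node indices on the path root -> tip
.oracle_root_path <- function(tree, tip_index) {
  root <- length(tree$tip.label) + 1L
  path <- tip_index
  node <- tip_index
  while (node != root) {
    node <- tree$edge[tree$edge[, 2] == node, 1]
    path <- c(node, path)
  }
  path
}

.oracle_edge_len <- function(tree, parent, child) {
  tree$edge.length[tree$edge[, 1] == parent & tree$edge[, 2] == child]
}

.oracle_depth <- function(tree, node) {
  path <- .oracle_root_path(tree, node)
  if (length(path) < 2) return(0)
  sum(vapply(seq_len(length(path) - 1), function(i)
    .oracle_edge_len(tree, path[i], path[i + 1]), numeric(1)))
}

# depth of the MRCA of two tips: deepest shared node on the two root paths
oracle_mrca_depth <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- .oracle_root_path(tree, ia); pb <- .oracle_root_path(tree, ib)
  shared <- intersect(pa, pb)
  mrca <- shared[which.max(match(shared, pa))]
  .oracle_depth(tree, mrca)
}

# path-sum cophenetic distance: depth(a) + depth(b) - 2 depth(mrca)
oracle_cophenetic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  .oracle_depth(tree, ia) + .oracle_depth(tree, ib) -
    2 * oracle_mrca_depth(tree, a, b)
}

# short chains for MCMC tests that only need >= 100 stored draws
test_chain <- function(seed, niter = 12000, burnin = 2000, thin = 10)
  chainSettings(niter, burnin, thin, seed = seed)

# minimal Ct record constructor
ct_row <- function(strain, ct, role = "experimental", species = strain,
                   block = 1L, replicate = seq_along(ct))
  data.frame(strain = strain, species = species, block = block,
             replicate = replicate, role = role, ct = ct)
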