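# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Haplotype table built directly from sequences and copy counts.
table_from_counts <- function(seqs, counts, pop = "all") {
  ids <- sprintf("s%03d", seq_len(sum(counts)))
  expanded <- rep(seqs, counts)
  names(expanded) <- ids
  collapse_haplotypes(expanded,
                      populations = stats::setNames(rep(pop, length(ids)), ids))
}

# Brute-force haplotype diversity: the probability that a random unordered
# pair of sequences (drawn without replacement) differs. This equals Nei's
# n/(n-1)-corrected estimator: n/(n-1) * (1 - sum p_i^2) =
# (n^2 - sum c_i^2) / (n (n-1)) = #differing pairs / #pairs.
hd_bruteforce <- function(counts) {
  n <- sum(counts)
  ids <- rep(seq_along(counts), counts)
  diff_pairs <- 0L
  total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    if (ids[i] != ids[j]) diff_pairs <- diff_pairs + 1L
  }
  diff_pairs / total
}

# Exhaustive union of all minimum spanning trees: enumerate every
# (h-1)-edge subset of the complete graph, keep the spanning trees, find
# the minimum total weight and return the union of all trees attaining it.
# Fully independent of the Kruskal weight-class construction.
msn_bruteforce <- function(d) {
  h <- nrow(d)
  stopifnot(h >= 2L, h <= 7L)
  if (h == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[upper.tri(d)]
  m <- nrow(pairs)
  subsets <- utils::combn(m, h - 1L)
  wsum <- colSums(matrix(ew[subsets], nrow = h - 1L))
  is_tree <- function(sel) {
    parent <- seq_len(h)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in sel) {
      a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
      if (a == b) return(FALSE)   # cycle
      parent[a] <- b
    }
    TRUE                           # h-1 acyclic edges on h nodes: spanning
  }
  union_edges <- NULL
  for (tier in sort(unique(wsum))) {
    cols <- which(wsum == tier)
    valid <- cols[vapply(cols, function(j) is_tree(subsets[, j]), TRUE)]
    if (length(valid)) {
      eidx <- unique(as.vector(subsets[, valid]))
      union_edges <- cbind(pairs[eidx, 1L], pairs[eidx, 2L])
      break
    }
  }
  union_edges
}

edge_key_set <- function(edges_df, ids) {
  apply(cbind(match(edges_df$from, ids), match(edges_df$to, ids)), 1L,
        function(e) paste(sort(e), collapse = "-"))
}

# Additive (tree-realisable) distance matrix from a random binary topology
# with positive branch lengths, plus the defining quartet splits.
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.5, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Counts of differing-site codon positions between two in-frame sequences.
diff_positions <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sites <- which(x != y)
  ((sites - 1L) %% 3L) + 1L
}

# position-uniform mutation (internal generator primitive)
mutate_uniform_for_test <- function(seq, n) {
  as.character(numtscreen:::mutate_uniform(seq, n))
}
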