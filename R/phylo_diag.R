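# Distance trees with column-resampling bootstrap, codon-position
# partitioning, and the first-codon-position resolution-retention
# diagnostic.
#
# The diagnostic logic: functional coding sequences accumulate most
# substitutions at third codon positions (synonymous), so restricting the
# alignment to first positions collapses the resolution of functional
# haplogroups; pseudogene (NUMT) lineages substitute uniformly across
# positions, so their grouping keeps long, well-supported stems. Trees are
# neighbour-joining on p/JC69/K80 distances; group support is the bootstrap
# frequency of the bipartition separating the group from everything else.

#' Subset an in-frame alignment to chosen codon positions
#'
#' @param seqs Named character vector, equal lengths.
#' @param frame_offset 0, 1 or 2.
#' @param positions "all", "pos1", "pos2", "pos3" or "pos12".
#' @return Named character vector of subset columns.
#' @export
subset_codon_positions <- function(seqs, frame_offset = 0L,
                                   positions = c("all", "pos1", "pos2", "pos3", "pos12")) {
  positions <- match.arg(positions)
  m <- seq_matrix(seqs)
  L <- ncol(m)
  if (L < 3L) stop("window shorter than one codon")
  stopifnot(frame_offset %in% 0:2)
  if (positions == "all") return(seqs)
  codon_pos <- ((seq_len(L) - 1L - frame_offset) %% 3L) + 1L
  keep <- switch(positions,
                 pos1 = codon_pos == 1L, pos2 = codon_pos == 2L,
                 pos3 = codon_pos == 3L, pos12 = codon_pos %in% 1:2)
  keep <- keep & seq_len(L) > frame_offset  # leading out-of-frame bases drop
  matrix_seqs(m[, keep, drop = FALSE])
}

# character string set -> ape DNAbin matrix
.as_dnabin <- function(seqs) {
  ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
}

.dist_fun <- function(model) {
  model <- match.arg(model, c("p", "JC", "K2P"))
  ape_model <- switch(model, p = "raw", JC = "JC69", K2P = "K80")
  function(bin) {
    d <- ape::dist.dna(bin, model = ape_model, pairwise.deletion = TRUE)
    if (any(!is.finite(d))) {
      warning("undefined distances under ", model, "; falling back to p")
      d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
    }
    d
  }
}

# all non-trivial splits of an unrooted phylo, as a list of tip-label sets
.tree_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- lapply(pp, function(idx) labs[idx])
  out[lengths(out) > 1L & lengths(out) < length(labs)]
}

.has_group_split <- function(splits, group, all_tips) {
  comp <- setdiff(all_tips, group)
  for (s in splits)
    if (setequal(s, group) || setequal(s, comp)) return(TRUE)
  FALSE
}

# length of the internal edge defining the group's split (0 if absent)
.stem_length <- function(tree, group) {
  tips <- tree$tip.label
  if (length(group) >= length(tips) - 1L) return(0)
  if (!ape::is.monophyletic(tree, group, reroot = TRUE)) return(0)
  rt <- ape::root(tree, outgroup = setdiff(tips, group)[1L], resolve.root = TRUE)
  node <- ape::getMRCA(rt, group)
  if (is.null(node)) return(0)
  e <- which(rt$edge[, 2L] == node)
  if (length(e) == 0L) return(0)
  rt$edge.length[e]
}

# synapomorphy density of a group: fraction of alignment columns at which
# the group is monomorphic for a state found in no other taxon. This is
# the character-based stem length used by the retention diagnostic; unlike
# an NJ edge length it is deterministic and is not inflated by
# least-squares smearing on sparse (e.g. pos1-only) alignments.
.stem_density <- function(seqs, group) {
  m <- seq_matrix(seqs)
  inside <- m[group, , drop = FALSE]
  outside <- m[setdiff(rownames(m), group), , drop = FALSE]
  if (nrow(outside) == 0L) return(NA_real_)
  syn <- vapply(seq_len(ncol(m)), function(j) {
    g <- unique(inside[, j])
    length(g) == 1L && !(g %in% outside[, j])
  }, TRUE)
  mean(syn)
}

#' Neighbour-joining diagnostic tree with bootstrap
#'
#' @param seqs Named character vector (>= 4 taxa).
#' @param model Distance model: "p", "JC" (Jukes-Cantor) or "K2P".
#' @param B Bootstrap replicates (0 for none); resampling is over alignment
#'   columns with replacement.
#' @param seed RNG seed for the bootstrap (mandatory when B > 0).
#' @return Object of class `diag_tree`: `tree` (phylo), `boot_splits`
#'   (list of split lists, one per replicate), `model`, `B`.
#' @export
build_diag_tree <- function(seqs, model = "p", B = 0L, seed = NULL) {
  if (length(seqs) < 4L) stop("need at least 4 taxa")
  df <- .dist_fun(model)
  bin <- .as_dnabin(seqs)
  tree <- ape::nj(df(bin))
  boot_splits <- NULL
  if (B > 0L) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    set.seed(seed)
    L <- ncol(bin)
    boot_splits <- vector("list", B)
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      tb <- ape::nj(df(bin[, cols]))
      boot_splits[[b]] <- .tree_splits(tb)
    }
  }
  structure(list(tree = tree, boot_splits = boot_splits, model = model,
                 B = as.integer(B)), class = "diag_tree")
}

#' @export
print.diag_tree <- function(x, ...) {
  cat("NJ diagnostic tree (", x$model, " distances, ",
      length(x$tree$tip.label), " taxa, B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Bootstrap support of a group
#'
#' Percentage of bootstrap replicates in which the group forms a split
#' (bipartition) of the tree. A group covering all taxa, or all but one, is
#' trivially supported at 100.
#'
#' @param dt A `diag_tree` with bootstrap replicates.
#' @param group Character vector of tip labels.
#' @return Support in [0, 100].
#' @export
group_support <- function(dt, group) {
  tips <- dt$tree$tip.label
  stopifnot(all(group %in% tips))
  if (length(group) >= length(tips) - 1L || length(group) <= 1L) return(100)
  if (is.null(dt$boot_splits)) return(NA_real_)
  hits <- vapply(dt$boot_splits, .has_group_split, TRUE,
                 group = group, all_tips = tips)
  100 * mean(hits)
}

#' Export a diagnostic tree to newick with support labels
#'
#' @param dt A `diag_tree`.
#' @param groups Optional named list of groups; supports are attached to
#'   matching internal nodes.
#' @param path Output file.
#' @export
write_diag_tree <- function(dt, path, groups = NULL) {
  tr <- dt$tree
  if (!is.null(dt$boot_splits)) {
    # per-node support for the clade below each internal node
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    supports <- vapply(pp, function(idx)
      group_support(dt, labs[idx]), 0)
    tr$node.label <- formatC(supports, format = "f", digits = 0)
  }
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' First-codon-position resolution retention report
#'
#' For each candidate group, compares trees built on all positions and on
#' first codon positions only. The retention flag fires when the group
#' keeps both bootstrap support (>= `tau_support`) and stem length
#' (>= `tau_stem` x the all-positions stem) on first positions alone — the
#' pseudogene signature. Functional haplogroups lose both. Stem length is
#' measured as per-column synapomorphy density (see the methods vignette);
#' the NJ edge lengths are also reported for reference.
#'
#' @param seqs Named aligned character vector (in frame after
#'   `frame_offset`).
#' @param groups Named list of tip-label vectors (each >= 2 members).
#' @param frame_offset Reading-frame offset.
#' @param model,B,seed Passed to [build_diag_tree()].
#' @param tau_support Support threshold (default 70).
#' @param tau_stem Stem-length ratio threshold (default 0.5).
#' @return data.frame per group: support_all, support_pos1, stem_all,
#'   stem_pos1, stem_ratio, retention, degenerate.
#' @export
resolution_retention <- function(seqs, groups, frame_offset = 0L, model = "p",
                                 B = 100L, seed = 1L, tau_support = 70,
                                 tau_stem = 0.5) {
  stopifnot(length(groups) >= 1L)
  missing <- unlist(groups)[!unlist(groups) %in% names(seqs)]
  if (length(missing)) stop("group members not among taxa: ",
                            paste(missing, collapse = ", "))
  dt_all <- build_diag_tree(seqs, model, B, seed)
  pos1 <- subset_codon_positions(seqs, frame_offset, "pos1")
  dt_p1 <- build_diag_tree(pos1, model, B, seed + 1L)
  out <- lapply(names(groups), function(g) {
    grp <- groups[[g]]
    degenerate <- length(grp) >= length(seqs) - 1L
    s_all <- group_support(dt_all, grp)
    s_p1 <- group_support(dt_p1, grp)
    st_all <- if (degenerate) NA_real_ else .stem_density(seqs, grp)
    st_p1 <- if (degenerate) NA_real_ else .stem_density(pos1, grp)
    ratio <- if (!is.na(st_all) && st_all > 0) st_p1 / st_all else NA_real_
    retention <- if (degenerate) TRUE else
      (s_p1 >= tau_support) && (st_p1 >= tau_stem * st_all)
    data.frame(group = g, support_all = s_all, support_pos1 = s_p1,
               stem_all = st_all, stem_pos1 = st_p1, stem_ratio = ratio,
               branch_all = .stem_length(dt_all$tree, grp),
               branch_pos1 = .stem_length(dt_p1$tree, grp),
               retention = retention, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "trees") <- list(all = dt_all, pos1 = dt_p1)
  out
}
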