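# Minimum spanning haplotype networks and the star-expansion score.
#
# The MSN here is the strict (epsilon = 0) network: the union of all
# minimum spanning trees of the haplotype Hamming-distance graph. It is
# built by Kruskal's algorithm processed one weight class at a time: within
# a class, every edge that joins components which were distinct before the
# class was processed belongs to some MST (its weight equals the minimax
# bottleneck between its endpoints); an edge belongs to every MST iff it is
# a bridge of its class subgraph contracted on those components.

#' Pairwise mutation-step (Hamming) distance matrix
#'
#' Counts mismatching columns between fully resolved haplotype sequences;
#' a gap is a fifth state and counts as a mismatch against a base.
#'
#' @param tab A `haplotype_table`, or a named character vector of
#'   equal-length sequences.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(tab) {
  seqs <- if (inherits(tab, "haplotype_table"))
    stats::setNames(tab$haplotypes$sequence, tab$haplotypes$haplotype)
  else tab
  if (length(seqs) < 2L) stop("need at least 2 haplotypes")
  m <- seq_matrix(seqs)
  h <- nrow(m)
  d <- matrix(0L, h, h, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
    dij <- sum(m[i, ] != m[j, ])
    d[i, j] <- dij; d[j, i] <- dij
  }
  d
}

# union-find helpers
.uf_find <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }

#' Build a minimum spanning network
#'
#' @param d Symmetric distance matrix (positive off-diagonal entries).
#' @param tab Optional `haplotype_table` supplying node frequencies and
#'   trait (population) composition.
#' @param epsilon Relaxation: an edge is kept if its weight is within
#'   `epsilon` of the weight at which its endpoints' components merged.
#'   0 gives the strict union-of-all-MSTs network.
#' @return Object of class `haplo_network`: `nodes` (data.frame id, freq),
#'   `edges` (data.frame from, to, weight, in_every_mst), `traits` (matrix
#'   node x population, or NULL), `dist` (the input matrix).
#' @export
build_msn <- function(d, tab = NULL, epsilon = 0) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  h <- nrow(d)
  if (h < 2L) stop("need at least 2 haplotypes")
  ids <- rownames(d)
  if (is.null(ids)) ids <- rownames(d) <- colnames(d) <- sprintf("H%02d", 1:h)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[upper.tri(d)]
  if (any(ew <= 0)) stop("distinct haplotypes must differ (weights >= 1)")
  ord <- order(ew)
  pairs <- pairs[ord, , drop = FALSE]; ew <- ew[ord]

  parent <- seq_len(h)
  edges <- NULL
  for (w in unique(ew)) {
    sel <- which(ew == w)
    comp_before <- vapply(seq_len(h), function(i) .uf_find(parent, i), 0L)
    cls <- pairs[sel, , drop = FALSE][comp_before[pairs[sel, 1L]] !=
                                        comp_before[pairs[sel, 2L]], , drop = FALSE]
    if (nrow(cls)) {
      # contracted class graph on pre-class components
      cu <- comp_before[cls[, 1L]]; cv <- comp_before[cls[, 2L]]
      in_every <- vapply(seq_len(nrow(cls)), function(k) {
        # bridge test: without edge k, are its contracted endpoints still
        # connected inside the class subgraph?
        others <- setdiff(seq_len(nrow(cls)), k)
        if (length(others) == 0L) return(TRUE)
        reach <- cu[k]
        repeat {
          add <- others[(cu[others] %in% reach & !(cv[others] %in% reach)) |
                          (cv[others] %in% reach & !(cu[others] %in% reach))]
          if (length(add) == 0L) break
          reach <- unique(c(reach, cu[add], cv[add]))
          others <- setdiff(others, add)
        }
        !(cv[k] %in% reach)
      }, TRUE)
      edges <- rbind(edges, data.frame(
        from = ids[cls[, 1L]], to = ids[cls[, 2L]], weight = w,
        in_every_mst = in_every, stringsAsFactors = FALSE))
      for (k in seq_len(nrow(cls))) {
        ri <- .uf_find(parent, cls[k, 1L]); rj <- .uf_find(parent, cls[k, 2L])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  if (epsilon > 0) {
    # minimax bottleneck per pair = merge weight propagated through the MSN
    bn <- .bottleneck_matrix(ids, edges, h)
    extra <- which(upper.tri(d) & d <= bn + epsilon & d > bn, arr.ind = TRUE)
    if (length(extra))
      edges <- rbind(edges, data.frame(from = ids[extra[, 1L]],
                                       to = ids[extra[, 2L]],
                                       weight = d[extra],
                                       in_every_mst = FALSE,
                                       stringsAsFactors = FALSE))
  }
  freq <- if (!is.null(tab)) {
    stats::setNames(tab$haplotypes$count, tab$haplotypes$haplotype)[ids]
  } else stats::setNames(rep(1L, h), ids)
  traits <- if (!is.null(tab)) tab$counts[ids, , drop = FALSE] else NULL
  structure(list(nodes = data.frame(id = ids, freq = as.integer(freq),
                                    stringsAsFactors = FALSE),
                 edges = edges, traits = traits, dist = d,
                 epsilon = epsilon),
            class = "haplo_network")
}

# all-pairs minimax bottleneck over the network edges (small h, Floyd-style)
.bottleneck_matrix <- function(ids, edges, h) {
  bn <- matrix(Inf, h, h, dimnames = list(ids, ids))
  diag(bn) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$from[k], ids); j <- match(edges$to[k], ids)
    bn[i, j] <- bn[j, i] <- min(bn[i, j], edges$weight[k])
  }
  for (k in seq_len(h)) for (i in seq_len(h)) for (j in seq_len(h)) {
    v <- max(bn[i, k], bn[k, j])
    if (v < bn[i, j]) bn[i, j] <- bn[j, i] <- v
  }
  bn
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Minimum spanning network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges (epsilon =", x$epsilon, ")\n")
  cat("Total frequency:", sum(x$nodes$freq), "\n")
  invisible(x)
}

#' Star-expansion score of a population subnetwork
#'
#' score = (frequency share of the modal haplotype) x (fraction of the
#' remaining haplotypes within <= 2 mutations of it). A founder/bottleneck
#' expansion — one dominant haplotype ringed by rare 1-2 mutation
#' satellites — scores near 1; balanced, scattered variant sets (the NUMT
#' demographic signature) score near 0. A single-haplotype population
#' scores 1 by convention.
#'
#' @param net A `haplo_network` built from a `haplotype_table` (traits
#'   required unless `population` is NULL and `tab` had one population).
#' @param population Population label; NULL uses total frequencies.
#' @return List: `score` in [0,1], `hub` (modal haplotype id).
#' @export
star_score <- function(net, population = NULL) {
  stopifnot(inherits(net, "haplo_network"))
  freq <- if (is.null(population)) {
    stats::setNames(net$nodes$freq, net$nodes$id)
  } else {
    if (is.null(net$traits) || !population %in% colnames(net$traits))
      stop("population '", population, "' not in network traits")
    net$traits[, population]
  }
  freq <- freq[freq > 0]
  if (length(freq) == 0L) stop("empty population subnetwork")
  if (length(freq) == 1L)
    return(list(score = 1, hub = names(freq)))
  hub <- names(freq)[which.max(freq)]  # first mode on ties
  share <- max(freq) / sum(freq)
  others <- setdiff(names(freq), hub)
  close <- mean(net$dist[hub, others] <= 2)
  list(score = share * close, hub = hub)
}

#' Write a network to GML
#'
#' @param net A `haplo_network`.
#' @param path Output file.
#' @export
write_gml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph [", con)
  writeLines("  directed 0", con)
  for (i in seq_len(nrow(net$nodes)))
    writeLines(sprintf('  node [ id %d label "%s" freq %d ]',
                       i - 1L, net$nodes$id[i], net$nodes$freq[i]), con)
  idx <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$id)
  for (k in seq_len(nrow(net$edges)))
    writeLines(sprintf("  edge [ source %d target %d weight %d ]",
                       idx[[net$edges$from[k]]], idx[[net$edges$to[k]]],
                       as.integer(net$edges$weight[k])), con)
  writeLines("]", con)
  invisible(path)
}

#' Write a PopART-flavoured nexus network block
#'
#' Emits a TAXA block, a trait matrix (population composition per
#' haplotype) and the edge list of the network.
#'
#' @param net A `haplo_network`.
#' @param path Output file.
#' @export
write_network_nexus <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- net$nodes$id
  writeLines("#NEXUS", con)
  writeLines(c("BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", length(ids)),
               paste0("  TAXLABELS ", paste(ids, collapse = " "), ";"),
               "END;"), con)
  if (!is.null(net$traits)) {
    writeLines(c("BEGIN TRAITS;",
                 sprintf("  Dimensions NTRAITS=%d;", ncol(net$traits)),
                 "  Format labels=yes missing=? separator=Comma;",
                 paste0("  TraitLabels ", paste(colnames(net$traits), collapse = " "), ";"),
                 "  Matrix"), con)
    for (i in seq_along(ids))
      writeLines(paste0("    ", ids[i], " ",
                        paste(net$traits[ids[i], ], collapse = ",")), con)
    writeLines(c("  ;", "END;"), con)
  }
  writeLines("BEGIN NETWORK;", con)
  writeLines(sprintf("  DIMENSIONS NVERTICES=%d NEDGES=%d;",
                     length(ids), nrow(net$edges)), con)
  writeLines("  EDGES", con)
  for (k in seq_len(nrow(net$edges)))
    writeLines(sprintf("    %d %s %s %d", k, net$edges$from[k],
                       net$edges$to[k], as.integer(net$edges$weight[k])), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' @export
plot.haplo_network <- function(x, ...) {
  ids <- x$nodes$id
  n <- length(ids)
  # simple circular layout with the highest-frequency node centred
  ord <- order(-x$nodes$freq)
  xy <- matrix(0, n, 2, dimnames = list(ids[ord], NULL))
  if (n > 1L) {
    th <- seq(0, 2 * pi, length.out = n)[-1]
    xy[2:n, ] <- cbind(cos(th), sin(th))
  }
  xy <- xy[ids, , drop = FALSE]
  plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
       xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1, ...)
  for (k in seq_len(nrow(x$edges))) {
    i <- x$edges$from[k]; j <- x$edges$to[k]
    lines(xy[c(i, j), 1L], xy[c(i, j), 2L],
          lty = if (x$edges$in_every_mst[k]) 1L else 2L)
  }
  r <- 0.08 + 0.12 * sqrt(x$nodes$freq / max(x$nodes$freq))
  symbols(xy[, 1L], xy[, 2L], circles = r, inches = FALSE, add = TRUE,
          bg = "grey85")
  text(xy[, 1L], xy[, 2L], ids, cex = 0.7)
  invisible(x)
}
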