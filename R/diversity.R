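# Per-population diversity statistics and the farm mitochondrial profile
# classification used to order farms in summary figures.

#' Per-population haplotype diversity statistics
#'
#' Computes, over the retained (fully resolved) rows of one population:
#' n, the number of haplotypes h, the number of segregating sites S, the
#' haplotype diversity Hd and the ratio S/h. Hd uses Nei's small-sample
#' corrected estimator
#' \deqn{Hd = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with \eqn{p_i} the haplotype frequencies — the probability that two
#' sequences drawn without replacement carry different haplotypes.
#'
#' @param tab A [collapse_haplotypes()] table.
#' @param population Population (column of `tab$counts`); NULL pools all.
#' @return data.frame row: population, n, h, S, Hd, S_over_h.
#' @export
diversity_stats <- function(tab, population = NULL) {
  stopifnot(inherits(tab, "haplotype_table"))
  if (is.null(population)) {
    counts <- rowSums(tab$counts)
    population <- "all"
  } else {
    if (!population %in% colnames(tab$counts))
      stop("unknown population: ", population)
    counts <- tab$counts[, population]
  }
  keep <- counts > 0
  counts <- counts[keep]
  n <- sum(counts)
  if (n < 2L) stop("need n >= 2 sequences in population '", population, "'")
  h <- sum(counts > 0)
  p <- counts / n
  hd <- n * (1 - sum(p^2)) / (n - 1)
  seqs <- tab$haplotypes$sequence[keep]
  S <- if (h == 1L) 0L else {
    m <- seq_matrix(stats::setNames(seqs, names(counts)))
    sum(apply(m, 2L, function(col) length(unique(col[col %in% DNA_BASES])) >= 2L))
  }
  data.frame(population = population, n = n, h = h, S = as.integer(S),
             Hd = hd, S_over_h = S / h, stringsAsFactors = FALSE)
}

#' Diversity profile table for every population
#'
#' @param tab A `haplotype_table`.
#' @return data.frame, one row per population with >= 2 sequences.
#' @export
diversity_table <- function(tab) {
  pops <- colnames(tab$counts)[colSums(tab$counts) >= 2L]
  do.call(rbind, lapply(pops, function(p) diversity_stats(tab, p)))
}

#' Classify a farm's mitochondrial profile
#'
#' Farms fall into three classes: carrying a single typical haplogroup,
#' carrying two or three typical haplogroups including C, or carrying any
#' atypical haplogroup. Mixed-with-C farms are flagged for high S/h: mixing
#' deeply diverged typical groups inflates segregating sites per haplotype
#' without necessarily raising Hd.
#'
#' @param calls Character vector of per-sequence haplogroup calls
#'   ("typical_A", "typical_B", "typical_C", "cryptic_D",
#'   "atypical_unassigned").
#' @return List: `profile` one of "single_typical", "mixed_including_C",
#'   "atypical_present"; `flags` (character vector, may contain "high_S_h").
#' @export
classify_farm_profile <- function(calls) {
  if (length(calls) == 0L || anyNA(calls)) stop("missing haplogroup calls")
  if (any(calls == "atypical_unassigned"))
    return(list(profile = "atypical_present", flags = character(0)))
  groups <- unique(sub("^typical_", "", calls[startsWith(calls, "typical_")]))
  if (length(groups) >= 2L && "C" %in% groups)
    return(list(profile = "mixed_including_C", flags = "high_S_h"))
  list(profile = "single_typical", flags = character(0))
}
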