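# Allele phasing for heterozygous nuclear-intron consensus sequences.
#
# A Sanger trace of a heterozygote carrying one short indel shows, from the
# indel onward, the superposition of the longer allele and the shorter
# allele shifted by the indel length; each position is an IUPAC union of
# the two bases. The decoder scans (position, length) hypotheses and, for
# each, reconstructs the two alleles by dynamic programming along the
# shift chains i, i+L, i+2L, ... anchored in the unambiguous tail (where
# only the longer allele remains), minimising the number of columns that
# the overlay cannot explain (allele SNPs). The argmax-explained hypothesis
# is returned, with the count of tied optimal allele pairs so callers can
# detect non-identifiable inputs.

# Bitmask encoding of IUPAC sets: A=1, C=2, G=4, T=8; a set is the OR of
# its bases, so the overlay constraint "union(a, b) equals the observed
# set" is a single integer comparison.
.BASE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.IUPAC_MASK <- vapply(IUPAC_SETS, function(b) sum(.BASE_MASK[b]), 0L)
.MASK_BASES <- lapply(0:15, function(m)
  .BASE_MASK[bitwAnd(m, .BASE_MASK) > 0L])

.cons_masks <- function(consensus) {
  ch <- strsplit(toupper(consensus), "")[[1]]
  if (any(ch == "-")) stop("consensus must be gap-free")
  m <- .IUPAC_MASK[ch]
  if (anyNA(m)) stop("non-IUPAC character in consensus")
  unname(m)
}

.mask_chr <- function(mask) names(.MASK_BASES[[mask + 1L]])

# Decode one (p, L) hypothesis over column set-masks. Returns list(A, B,
# cost, explained, unexpl_fixed, n_ambig, n_solutions) or NULL if out of
# range. cost counts overlay-inconsistent columns inside the overlay
# (inferred allele SNPs); unexpl_fixed counts ambiguous columns the
# hypothesis cannot reach (upstream of p or in the single-allele tail).
.decode_hypothesis <- function(masks, p, L) {
  n <- length(masks)
  nB <- n - L
  if (p < 1L || p > nB) return(NULL)
  w <- vapply(.MASK_BASES[masks + 1L], length, 0L)
  A <- integer(n)   # base masks (single bit) of the longer allele
  B <- integer(nB)
  unexpl_fixed <- 0L
  n_solutions <- 1
  for (i in (nB + 1L):n) {
    A[i] <- .MASK_BASES[[masks[i] + 1L]][1L]
    if (w[i] > 1L) unexpl_fixed <- unexpl_fixed + 1L
  }
  if (p > 1L) for (i in 1:(p - 1L)) {
    bs <- .MASK_BASES[[masks[i] + 1L]]
    A[i] <- bs[1L]
    B[i] <- if (w[i] == 2L) bs[2L] else bs[1L]
    if (w[i] > 1L) {
      unexpl_fixed <- unexpl_fixed + 1L
      n_solutions <- n_solutions * 2
    }
  }
  total_cost <- 0L
  for (r in seq_len(L) - 1L) {
    idx <- seq.int(p + r, nB, by = L)
    if (length(idx) == 0L) next
    idx <- rev(idx)            # top (tail-anchored) first
    K <- length(idx)
    cand <- .MASK_BASES[masks[idx] + 1L]
    cost <- vector("list", K); cnt <- vector("list", K); back <- vector("list", K)
    anchor <- A[idx[1L] + L]
    for (k in seq_len(K)) {
      ck <- cand[[k]]
      set_k <- masks[idx[k]]
      if (k == 1L) {
        cost[[k]] <- as.integer(bitwOr(ck, anchor) != set_k)
        cnt[[k]] <- rep(1, length(ck))
      } else {
        prev <- cand[[k - 1L]]
        nk <- length(ck)
        cost[[k]] <- integer(nk); cnt[[k]] <- numeric(nk); back[[k]] <- integer(nk)
        for (ai in seq_len(nk)) {
          cc <- cost[[k - 1L]] + as.integer(bitwOr(ck[ai], prev) != set_k)
          m <- min(cc)
          cost[[k]][ai] <- m
          cnt[[k]][ai] <- min(sum(cnt[[k - 1L]][cc == m]), 1e9)
          back[[k]][ai] <- which(cc == m)[1L]
        }
      }
    }
    m <- min(cost[[K]])
    total_cost <- total_cost + m
    n_solutions <- min(n_solutions * sum(cnt[[K]][cost[[K]] == m]), 1e9)
    pick <- which(cost[[K]] == m)[1L]
    states <- integer(K); states[K] <- pick
    if (K >= 2L) for (k in K:2) states[k - 1L] <- back[[k]][states[k]]
    A[idx] <- vapply(seq_len(K), function(k) cand[[k]][states[k]], 0L)
  }
  explained <- 0L
  for (i in p:nB) {
    rest <- bitwAnd(masks[i], bitwNot(A[i]))
    B[i] <- if (w[i] == 1L) A[i] else .MASK_BASES[[bitwAnd(rest, 15L) + 1L]][1L]
    if (w[i] > 1L && B[i] == A[i + L] && bitwOr(A[i], B[i]) == masks[i])
      explained <- explained + 1L
  }
  list(A = paste(vapply(A, .mask_chr, ""), collapse = ""),
       B = paste(vapply(B, .mask_chr, ""), collapse = ""),
       cost = total_cost, explained = explained,
       unexpl_fixed = unexpl_fixed,
       n_ambig = sum(w > 1L), n_solutions = n_solutions)
}

# Vectorised lower bound on a hypothesis total score (inferred SNPs +
# unreachable ambiguous columns): columns whose overlay partner is
# unambiguous and cannot complete the observed set are forced mismatches.
.hypothesis_bound <- function(masks, w, p, L) {
  n <- length(masks)
  nB <- n - L
  if (p < 1L || p > nB) return(Inf)
  outside <- sum(w[seq_len(n) < p | seq_len(n) > nB] > 1L)
  i <- p:nB
  nxt <- i + L
  determined <- w[nxt] == 1L
  feasible <- bitwAnd(masks[i], masks[nxt]) == masks[nxt] & w[i] <= 2L
  outside + sum(determined & !feasible)
}

#' Phase a heterozygous consensus sequence
#'
#' Separates the two alleles of an IUPAC-coded heterozygote consensus. An
#' input without ambiguity codes is returned as a homozygote. A consensus
#' with exactly one ambiguous site and no indel signal is phased into the
#' two single-SNP alleles. Otherwise (position, length) deletion hypotheses
#' with length 1..`max_indel` are scanned near the first ambiguous column
#' and decoded by the shift-chain dynamic program; the hypothesis explaining
#' the largest number of ambiguous columns (ties: fewest inferred allele
#' SNPs, then shortest indel, then smallest position) wins. Results
#' explaining less than `min_explained` of the ambiguous columns, multi-site
#' SNP-only heterozygotes (unknowable linkage from one trace), and inputs
#' with tied optimal allele pairs are reported with `confidence = "low"`.
#'
#' @param consensus IUPAC DNA string (gap-free).
#' @param max_indel Largest indel length tried (default 7).
#' @param min_explained Minimum explained fraction for a confident call.
#' @return Object of class `phased_pair`: list with `allele_1` (longer),
#'   `allele_2`, `indel` (NULL or list(pos, len), pos 1-based in allele_1),
#'   `explained` fraction, `n_ambig`, `n_optimal` (distinct optimal pairs),
#'   `confidence` ("high"/"low") and `note`.
#' @export
phase_heterozygote <- function(consensus, max_indel = 7L, min_explained = 0.9) {
  stopifnot(length(consensus) == 1L, nchar(consensus) >= 2L)
  masks <- .cons_masks(consensus)
  w <- vapply(.MASK_BASES[masks + 1L], length, 0L)
  n <- length(masks)
  ambig <- which(w > 1L)
  res <- function(a1, a2, indel, expl, n_opt, conf, note = "") {
    structure(list(allele_1 = a1, allele_2 = a2, indel = indel,
                   explained = expl, n_ambig = length(ambig),
                   n_optimal = n_opt, confidence = conf, note = note),
              class = "phased_pair")
  }
  up <- toupper(consensus)
  if (length(ambig) == 0L)
    return(res(up, up, NULL, 1, 1L, "high", "no ambiguity: homozygote"))
  if (length(ambig) == 1L && w[ambig] == 2L) {
    bs <- .MASK_BASES[[masks[ambig] + 1L]]
    ch <- strsplit(up, "")[[1]]
    a <- ch; a[ambig] <- names(bs)[1L]
    b <- ch; b[ambig] <- names(bs)[2L]
    snp_pair <- res(paste(a, collapse = ""), paste(b, collapse = ""),
                    NULL, 1, 1L, "high", "single-SNP heterozygote")
    return(snp_pair)
  }

  a1 <- ambig[1L]
  # candidate (p, L) grid near the first ambiguous column, decoded in order
  # of a cheap lower bound on the total score (branch & bound: once the
  # bound exceeds the best decoded score the remainder cannot win)
  hyp <- do.call(rbind, lapply(seq_len(max_indel), function(L) {
    p_lo <- max(1L, a1 - 7L)
    p_hi <- min(a1, n - L)
    if (p_lo > p_hi) return(NULL)
    data.frame(p = p_lo:p_hi, L = L)
  }))
  if (!is.null(hyp)) {
    hyp$bound <- vapply(seq_len(nrow(hyp)), function(k)
      .hypothesis_bound(masks, w, hyp$p[k], hyp$L[k]), 0)
    hyp <- hyp[order(hyp$bound, hyp$L, hyp$p), , drop = FALSE]
  }
  best <- NULL; best_score <- Inf
  pairs_at_best <- character(0)
  for (k in seq_len(NROW(hyp))) {
    if (hyp$bound[k] > best_score) break
    d <- .decode_hypothesis(masks, hyp$p[k], hyp$L[k])
    if (is.null(d)) next
    score <- d$cost + d$unexpl_fixed  # inferred SNPs + unreachable ambiguities
    if (score < best_score) {
      best <- c(d, list(p = hyp$p[k], L = hyp$L[k])); best_score <- score
      pairs_at_best <- paste(sort(c(d$A, d$B)), collapse = "|")
    } else if (score == best_score) {
      pairs_at_best <- union(pairs_at_best,
                             paste(sort(c(d$A, d$B)), collapse = "|"))
    }
  }
  if (is.null(best))
    return(res(NA_character_, NA_character_, NULL, 0, 0L, "low",
               "no indel hypothesis applicable"))
  expl_frac <- best$explained / best$n_ambig
  n_opt <- best$n_solutions
  if (length(pairs_at_best) > 1L) n_opt <- max(n_opt, length(pairs_at_best))
  conf <- if (expl_frac >= min_explained && n_opt == 1L) "high" else "low"
  note <- if (expl_frac < min_explained)
    "overlay explains too few ambiguities (multi-indel or poor trace?)"
  else if (n_opt > 1L) "tied optimal allele pairs: not identifiable" else ""
  res(best$A, best$B, list(pos = best$p, len = best$L), expl_frac, n_opt,
      conf, note)
}

#' @export
print.phased_pair <- function(x, ...) {
  cat("Phased pair (confidence:", x$confidence, ")\n")
  if (!is.null(x$indel))
    cat("  indel: pos", x$indel$pos, "len", x$indel$len, "\n")
  cat("  explained:", format(x$explained, digits = 3),
      "of", x$n_ambig, "ambiguous sites\n")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Match phased alleles against a homozygote allele catalog
#'
#' Exact-sequence lookup of each phased allele in a catalog of alleles
#' observed in homozygotes. Novel alleles are flagged, never silently
#' merged.
#'
#' @param pair A [phase_heterozygote()] result.
#' @param catalog Named character vector of unambiguous allele sequences.
#' @return data.frame with one row per allele: allele, match (catalog name
#'   or NA), novel (logical).
#' @export
match_against_catalog <- function(pair, catalog) {
  validate_dna(catalog, allow_gap = FALSE)
  if (any(vapply(strsplit(toupper(catalog), ""), function(x)
    any(!x %in% DNA_BASES), TRUE)))
    stop("catalog sequences must be unambiguous")
  alleles <- c(pair$allele_1, pair$allele_2)
  hit <- vapply(alleles, function(a) {
    i <- match(toupper(a), toupper(catalog))
    if (is.na(i)) NA_character_ else names(catalog)[i]
  }, "", USE.NAMES = FALSE)
  data.frame(allele = c("allele_1", "allele_2"), match = hit,
             novel = is.na(hit), stringsAsFactors = FALSE)
}
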