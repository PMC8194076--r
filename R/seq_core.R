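# Sequence set I/O and DnaSP-style preprocessing: common-window trimming and
# haplotype individualisation. Coordinates are 0-based half-open throughout.

#' Read an alignment or sequence set from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' The sample sheet is the authoritative metadata source: a TSV with columns
#' `id`, `farm`, `country`, `marker`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "farm", "country", "marker")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("id", "marker")]))
    stop("duplicate id/marker rows in sample sheet")
  df
}

#' @rdname read_samples
#' @param df Sample sheet data.frame.
#' @export
write_samples <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim an alignment to a common analysis window
#'
#' Merged multi-study alignments carry non-overlapping flanks (represented
#' as '-' or 'N'). Two policies are supported: `trim_columns` keeps every
#' row but restricts the alignment to the longest contiguous column interval
#' in which at least `min_coverage` of rows are resolved (rows still missing
#' data inside that window are dropped and logged); `drop_sequences` keeps
#' the full column span and removes rows with missing flanks.
#'
#' @param seqs Named character vector, equal lengths (aligned).
#' @param policy "trim_columns" or "drop_sequences".
#' @param min_coverage Fraction of rows that must be resolved per window
#'   column (trim_columns policy).
#' @return List: `seqs` (trimmed), `window` (0-based half-open c(start, end)
#'   in input coordinates), `dropped` (ids), `report` (data.frame id/reason).
#' @export
trim_to_common_window <- function(seqs, policy = c("trim_columns", "drop_sequences"),
                                  min_coverage = 1.0) {
  policy <- match.arg(policy)
  stopifnot(min_coverage > 0, min_coverage <= 1)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- seq_matrix(seqs)
  resolved <- !(m == "-" | m == "N")
  if (policy == "drop_sequences") {
    has_missing_flank <- apply(resolved, 1L, function(r) !r[1L] || !r[length(r)])
    keep <- !has_missing_flank
    if (!any(keep)) stop("all rows dropped: every sequence has missing flanks")
    report <- data.frame(id = rownames(m)[!keep],
                         reason = rep("missing_flank", sum(!keep)),
                         stringsAsFactors = FALSE)
    return(list(seqs = matrix_seqs(m[keep, , drop = FALSE]),
                window = c(0L, ncol(m)),
                dropped = rownames(m)[!keep], report = report))
  }
  cov <- colMeans(resolved)
  ok <- cov >= min_coverage
  if (!any(ok)) stop("empty result window: no column reaches min_coverage")
  # longest run of qualifying columns (first one on ties)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  w0 <- starts[best]; w1 <- ends[best]
  mm <- m[, w0:w1, drop = FALSE]
  inside_missing <- apply(mm, 1L, function(r) any(r == "-" | r == "N"))
  keep <- !inside_missing
  if (!any(keep)) stop("all rows dropped inside the trimmed window")
  report <- data.frame(id = rownames(m)[!keep],
                       reason = rep("missing_in_window", sum(!keep)),
                       stringsAsFactors = FALSE)
  list(seqs = matrix_seqs(mm[keep, , drop = FALSE]),
       window = c(w0 - 1L, w1),
       dropped = rownames(m)[!keep], report = report)
}

#' Collapse aligned sequences into haplotypes
#'
#' A haplotype is a unique, fully resolved nucleotide sequence over the
#' analysis window. Rows containing ambiguity codes, N or gaps inside the
#' window are excluded and logged (the default policy mirrors discarding
#' poor-chromatogram reads); identical resolved rows are merged and counted
#' per population.
#'
#' @param seqs Named character vector, equal lengths.
#' @param populations Named character vector mapping sequence id -> farm /
#'   population label. Unlisted ids get population "unknown".
#' @param window Optional 0-based half-open c(start, end); default full span.
#' @param exclude_ambiguous Exclude rows with non-ACGT characters in-window
#'   (TRUE, default) or keep them as their own states (FALSE).
#' @return Object of class `haplotype_table`: list with `haplotypes`
#'   (data.frame haplotype/sequence/count), `counts` (matrix haplotype x
#'   population), `members` (list of ids), `excluded` (data.frame id/reason),
#'   `window`.
#' @export
collapse_haplotypes <- function(seqs, populations = NULL, window = NULL,
                                exclude_ambiguous = TRUE) {
  m <- seq_matrix(seqs)
  if (is.null(window)) window <- c(0L, ncol(m))
  stopifnot(window[1] >= 0, window[2] <= ncol(m), window[1] < window[2])
  mm <- m[, (window[1] + 1L):window[2], drop = FALSE]
  if (is.null(populations))
    populations <- stats::setNames(rep("all", nrow(m)), rownames(m))
  pops <- populations[rownames(m)]
  pops[is.na(pops)] <- "unknown"

  excluded <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(mm))
  if (exclude_ambiguous) {
    for (i in seq_len(nrow(mm))) {
      row <- mm[i, ]
      if (any(row == "-")) {
        keep[i] <- FALSE
        excluded <- rbind(excluded, data.frame(id = rownames(mm)[i],
                                               reason = "gap", stringsAsFactors = FALSE))
      } else if (any(!row %in% DNA_BASES)) {
        keep[i] <- FALSE
        excluded <- rbind(excluded, data.frame(id = rownames(mm)[i],
                                               reason = "ambiguity", stringsAsFactors = FALSE))
      }
    }
  }
  if (!any(keep)) stop("zero retained rows after ambiguity/gap exclusion")
  strs <- matrix_seqs(mm[keep, , drop = FALSE])
  pops_kept <- pops[keep]
  uniq <- unique(unname(strs))
  hap_ids <- sprintf("H%02d", seq_along(uniq))
  idx <- match(unname(strs), uniq)
  members <- split(names(strs), hap_ids[idx])
  members <- members[hap_ids]  # stable order
  pop_levels <- sort(unique(pops_kept))
  counts <- matrix(0L, length(uniq), length(pop_levels),
                   dimnames = list(hap_ids, pop_levels))
  for (i in seq_along(strs)) {
    counts[idx[i], pops_kept[i]] <- counts[idx[i], pops_kept[i]] + 1L
  }
  structure(list(
    haplotypes = data.frame(haplotype = hap_ids, sequence = uniq,
                            count = as.integer(rowSums(counts)),
                            stringsAsFactors = FALSE),
    counts = counts, members = members, excluded = excluded,
    window = as.integer(window)), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", nrow(x$haplotypes), "haplotypes,",
      sum(x$haplotypes$count), "sequences,",
      nrow(x$excluded), "excluded\n")
  cat("Window: [", x$window[1], ", ", x$window[2], ")\n", sep = "")
  print(utils::head(x$haplotypes[, c("haplotype", "count")], 10L))
  invisible(x)
}

#' Write a haplotype table to TSV
#' @param tab A `haplotype_table`.
#' @param path Output file.
#' @export
write_haplotype_table <- function(tab, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(tab$counts)), function(i) {
    pops <- colnames(tab$counts)[tab$counts[i, ] > 0]
    data.frame(haplotype = rownames(tab$counts)[i],
               sequence = tab$haplotypes$sequence[i],
               farm = pops, count = tab$counts[i, pops],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locate and strip primer sites from a sequence set
#'
#' Primers are located by exact or 1-mismatch search of the forward primer
#' (and the reverse complement of the reverse primer); matched spans are
#' removed, mirroring the convention that the primer region is omitted from
#' analysis.
#'
#' @param seqs Named character vector (unaligned, gap-free).
#' @param forward,reverse Primer strings (IUPAC allowed in primers).
#' @param max_mismatch Maximum mismatches tolerated (default 1).
#' @return Named character vector with primer spans removed where found.
#' @export
strip_primers <- function(seqs, forward, reverse, max_mismatch = 1L) {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  out <- vapply(seqs, function(s) {
    subj <- Biostrings::DNAString(s)
    for (pr in c(forward, rc(reverse))) {
      hit <- Biostrings::matchPattern(pr, subj, max.mismatch = max_mismatch,
                                      fixed = FALSE)
      if (length(hit) >= 1L) {
        st <- Biostrings::start(hit)[1L]; en <- Biostrings::end(hit)[1L]
        s <- paste0(substring(s, 1L, st - 1L), substring(s, en + 1L))
        subj <- Biostrings::DNAString(s)
      }
    }
    s
  }, "")
  stats::setNames(out, names(seqs))
}

#' Published CO1 region definitions
#'
#' The two CO1 analysis regions with a representative published primer
#' pair each and the alignment lengths at which they are analysed
#' (region 1: 470 bp; region 2: 273 bp). The reading-frame offset is a
#' convention of the assembled window, 0 for the bundled generator.
#'
#' @return Named list of `region_def` objects: name, primer_forward,
#'   primer_reverse, expected_length_bp, frame_offset.
#' @export
region_defs <- function() {
  mk <- function(name, fwd, rev, len) {
    structure(list(name = name, primer_forward = fwd, primer_reverse = rev,
                   expected_length_bp = len, frame_offset = 0L),
              class = "region_def")
  }
  list(
    region1 = mk("region1", "GAAAGAGGAGCAGGCACTGG",
                 "CCAGTAATACCTCCAATTGTAAAT", 470L),
    region2 = mk("region2", "TGATTTTTTGGTCACCCAGAAG",
                 "TACAGCTCCTATAGATAAAAC", 273L))
}
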