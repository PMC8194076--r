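# IUPAC nucleotide ambiguity codes mapped to the base sets they denote.
# Gap characters and N are handled separately by callers that care.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Reverse map: sorted base-set key -> IUPAC letter.
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(x) paste(sort(x), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
})

DNA_BASES <- c("A", "C", "G", "T")
AMBIGUITY_CODES <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Expand an IUPAC code to the set of bases it denotes
#'
#' @param x Single upper-case IUPAC character.
#' @return Character vector of plain bases ("A","C","G","T").
#' @keywords internal
iupac_expand <- function(x) {
  s <- IUPAC_SETS[[x]]
  if (is.null(s)) stop("not an IUPAC nucleotide code: '", x, "'")
  s
}

#' IUPAC union of two nucleotide characters
#'
#' Returns the single IUPAC letter denoting the union of the base sets of
#' `a` and `b`. Used to build heterozygote / co-amplification consensus
#' sequences (the in-silico proxy for chromatogram double peaks).
#'
#' @param a,b Upper-case IUPAC characters.
#' @return Single character.
#' @export
iupac_union <- function(a, b) {
  key <- paste(sort(unique(c(iupac_expand(a), iupac_expand(b)))), collapse = "")
  IUPAC_FROM_SET[[key]]
}

#' Split sequence strings into a character matrix
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return Character matrix, one row per sequence.
#' @export
seq_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths: ", paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse a character matrix back to sequence strings
#' @param m Character matrix.
#' @return Named character vector.
#' @export
matrix_seqs <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Validate IUPAC DNA sequences
#'
#' @param seqs Character vector of sequences.
#' @param allow_gap Allow '-' characters.
#' @return Invisibly TRUE; stops with the offending ids otherwise.
#' @export
validate_dna <- function(seqs, allow_gap = TRUE) {
  ok_chars <- c(names(IUPAC_SETS), if (allow_gap) "-")
  bad <- vapply(strsplit(toupper(seqs), ""), function(x) any(!x %in% ok_chars), TRUE)
  if (any(bad))
    stop("non-IUPAC characters in sequence(s): ",
         paste(utils::head(names(seqs)[bad], 5L), collapse = ", "))
  invisible(TRUE)
}

#' Fetch a genetic code table
#'
#' Thin wrapper around the NCBI translation tables shipped with Biostrings.
#' The default is table 5 (invertebrate mitochondrial), the code under which
#' arthropod CO1 fragments are translated; its stop set is {TAA, TAG}.
#'
#' @param table_id NCBI translation table id as a string (e.g. "1", "5").
#' @return Object of class `genetic_code`: list with `id`, `map`
#'   (named character, codon -> amino acid, stops as "*") and `stops`.
#' @export
genetic_code <- function(table_id = "5") {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  structure(list(id = as.character(table_id), map = map,
                 stops = names(map)[map == "*"]),
            class = "genetic_code")
}

#' Translate a DNA sequence and locate in-frame stop codons
#'
#' Gap characters are stripped before translation (a deletion in an aligned
#' pseudogene then shifts the downstream frame, which is exactly the signal
#' the stop-codon screen looks for). Codons containing ambiguity codes or N
#' translate to 'X'. The trailing partial codon is ignored.
#'
#' @param seq Single DNA string (IUPAC, may contain '-').
#' @param code A [genetic_code()] object.
#' @param frame_offset 0, 1 or 2: number of leading bases skipped.
#' @return List with `aa` (amino-acid string), `stop_codons` (0-based codon
#'   indices of in-frame stops) and `n_codons`.
#' @export
translate_dna <- function(seq, code = genetic_code("5"), frame_offset = 0L) {
  stopifnot(length(seq) == 1L, frame_offset %in% 0:2)
  s <- gsub("-", "", toupper(seq), fixed = TRUE)
  s <- substring(s, frame_offset + 1L)
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 1L) stop("sequence too short to translate at this frame")
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(code$map[codons])
  aa[is.na(aa)] <- "X"
  list(aa = paste(aa, collapse = ""),
       stop_codons = which(aa == "*") - 1L,
       n_codons = n_codons)
}

#' Infer the reading frame of a coding fragment
#'
#' Picks the frame offset minimising the total number of in-frame stop
#' codons across a panel of sequences; ties resolve toward frame 0. If no
#' frame is stop-free for any panel member the result carries a warning
#' flag rather than failing (random or junk input).
#'
#' @param seqs Character vector of DNA sequences.
#' @param code A [genetic_code()] object.
#' @return List: `frame_offset`, `stop_counts` (length 3), `clean` (TRUE if
#'   the chosen frame is stop-free for at least one sequence), `warning`.
#' @export
infer_frame <- function(seqs, code = genetic_code("5")) {
  stopifnot(length(seqs) >= 1L)
  counts <- integer(3)
  any_clean <- logical(3)
  for (f in 0:2) {
    st <- vapply(seqs, function(s)
      length(translate_dna(s, code, f)$stop_codons), 0L)
    counts[f + 1L] <- sum(st)
    any_clean[f + 1L] <- any(st == 0L)
  }
  best <- which.min(counts) - 1L  # which.min takes the first minimum: frame 0 wins ties
  clean <- any_clean[best + 1L]
  if (!clean)
    warning("no reading frame is stop-free for any sequence; returning the least-stop frame")
  list(frame_offset = best, stop_counts = counts, clean = clean,
       warning = !clean)
}

#' Proportion of differing sites between two aligned sequences
#'
#' Sites where either sequence carries a gap, N or an ambiguity code are
#' excluded from both numerator and denominator (pairwise deletion).
#'
#' @param a,b Equal-length DNA strings.
#' @return p-distance in [0, 1].
#' @export
p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(x) == length(y))
  use <- x %in% DNA_BASES & y %in% DNA_BASES
  if (!any(use)) return(NA_real_)
  sum(x[use] != y[use]) / sum(use)
}
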