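# Haplogroup naming, cross-study synonymy and nearest-reference assignment.
#
# The published studies of Dermanyssus gallinae mitochondrial structure use
# several identifier systems for the same lineages (Lmt1/Lmt2/Lmt3 vs
# haplogroups A/B/C, clade F vs L1 vs D, plus the pseudogene groups). The
# bundled synonymy table maps every identifier to a canonical label and a
# taxonomic status: typical (D. gallinae s.s.), cryptic (D. gallinae L1) or
# numt (pseudogene artifact groups).

.synonymy_rows <- function() {
  rbind(
    data.frame(scheme = "RO0", identifier = "Clade E",     label = "Co21-22", status = "numt"),
    data.frame(scheme = "RO1", identifier = "Co21 & Co22", label = "Co21-22", status = "numt"),
    data.frame(scheme = "RO1", identifier = "JOW",         label = "JOW",     status = "numt"),
    data.frame(scheme = "RO1", identifier = "Lmt3", label = "A", status = "typical"),
    data.frame(scheme = "RO1", identifier = "Lmt2", label = "B", status = "typical"),
    data.frame(scheme = "RO1", identifier = "Lmt1", label = "C", status = "typical"),
    data.frame(scheme = "RB",  identifier = "Lmt3", label = "A", status = "typical"),
    data.frame(scheme = "RB",  identifier = "Lmt2", label = "B", status = "typical"),
    data.frame(scheme = "RB",  identifier = "Lmt1", label = "C", status = "typical"),
    data.frame(scheme = "OB",  identifier = "A", label = "A", status = "typical"),
    data.frame(scheme = "OB",  identifier = "B", label = "B", status = "typical"),
    data.frame(scheme = "OB",  identifier = "C", label = "C", status = "typical"),
    data.frame(scheme = "OB",  identifier = "D", label = "D", status = "cryptic"),
    data.frame(scheme = "CHU", identifier = "A", label = "A", status = "typical"),
    data.frame(scheme = "CHU", identifier = "B", label = "B", status = "typical"),
    data.frame(scheme = "CHU", identifier = "C", label = "C", status = "typical"),
    data.frame(scheme = "CHU", identifier = "D", label = "D", status = "cryptic"),
    data.frame(scheme = "KT",  identifier = "A", label = "A", status = "typical"),
    data.frame(scheme = "KT",  identifier = "B", label = "B", status = "typical"),
    data.frame(scheme = "KT",  identifier = "C", label = "C", status = "typical"),
    data.frame(scheme = "KT",  identifier = "D", label = "D", status = "cryptic"),
    data.frame(scheme = "CIL", identifier = "A", label = "A", status = "typical"),
    data.frame(scheme = "CIL", identifier = "B", label = "B", status = "typical"),
    data.frame(scheme = "CIL", identifier = "C", label = "C", status = "typical"),
    data.frame(scheme = "CIL", identifier = "D", label = "D", status = "cryptic"),
    data.frame(scheme = "CIL", identifier = "E", label = "E", status = "numt"),
    data.frame(scheme = "CIL", identifier = "F", label = "F", status = "numt"),
    data.frame(scheme = "RO0", identifier = "clade F", label = "D", status = "cryptic"),
    data.frame(scheme = "RO1", identifier = "L1",      label = "D", status = "cryptic"),
    data.frame(scheme = "RB",  identifier = "L1",      label = "D", status = "cryptic"),
    data.frame(scheme = "Present", identifier = "A", label = "A", status = "typical"),
    data.frame(scheme = "Present", identifier = "B", label = "B", status = "typical"),
    data.frame(scheme = "Present", identifier = "C", label = "C", status = "typical"),
    data.frame(scheme = "Present", identifier = "D", label = "D", status = "cryptic"),
    data.frame(scheme = "Present", identifier = "E", label = "E", status = "numt"),
    data.frame(scheme = "Present", identifier = "F", label = "F", status = "numt"),
    data.frame(scheme = "Present", identifier = "H", label = "H", status = "numt"),
    data.frame(scheme = "Present", identifier = "JOW",     label = "JOW",     status = "numt"),
    data.frame(scheme = "Present", identifier = "Co21-22", label = "Co21-22", status = "numt"))
}

#' The bundled cross-study haplogroup synonymy table
#'
#' Scheme keys: RO0 and RO1 (the 2009/2010 morpho-molecular studies), OB
#' (the Scandinavian haplogroup study that coined A/B/C), RB (the
#' population-structure study using Lmt1-3/L1), CHU, KT, CIL (later farm
#' surveys), and "Present" (the canonical labels).
#'
#' @return data.frame: scheme, identifier, label, status.
#' @export
haplogroup_synonymy <- function() {
  df <- .synonymy_rows()
  rownames(df) <- NULL
  df
}

#' Translate a study-specific identifier to its canonical haplogroup label
#'
#' @param identifier Identifier string as printed in the source study.
#' @param scheme Study key (see [haplogroup_synonymy()]); NULL searches all
#'   schemes and requires an unambiguous hit.
#' @return List: `label`, `status`, `known` (FALSE for identifiers outside
#'   the table — never guessed).
#' @export
synonymize <- function(identifier, scheme = NULL) {
  df <- haplogroup_synonymy()
  hit <- if (is.null(scheme)) df[df$identifier == identifier, , drop = FALSE]
  else df[df$identifier == identifier & df$scheme == scheme, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(list(label = NA_character_, status = NA_character_, known = FALSE))
  if (length(unique(hit$label)) > 1L)
    stop("identifier '", identifier, "' is ambiguous across schemes; pass scheme=")
  list(label = hit$label[1L], status = hit$status[1L], known = TRUE)
}

#' Assign haplotypes to haplogroups by nearest reference
#'
#' Desk-scale stand-in for tree placement: each query is assigned the label
#' of its nearest reference by p-distance; queries farther than
#' `tau_assign` from every reference are atypical_unassigned. The default
#' threshold 0.03 sits between the within-group star scale (1-2 mutations)
#' and the ~5-9% between-group scale.
#'
#' @param queries Named character vector of haplotype sequences (window
#'   comparable with the panel).
#' @param panel Named character vector of reference sequences.
#' @param panel_labels data.frame label/status, rows matching `panel` names
#'   (names(panel) must be the labels, or supply a `label` column keyed by
#'   reference id).
#' @param tau_assign Maximum p-distance for assignment.
#' @return data.frame: haplotype, label, status, distance, call.
#' @export
assign_haplogroups <- function(queries, panel, panel_labels = NULL,
                               tau_assign = 0.03) {
  if (length(panel) == 0L) stop("empty reference panel")
  if (is.null(panel_labels))
    panel_labels <- data.frame(label = names(panel),
                               status = ifelse(names(panel) == "D", "cryptic",
                                               "typical"),
                               stringsAsFactors = FALSE)
  out <- lapply(names(queries), function(q) {
    dd <- vapply(panel, function(r) p_distance(queries[[q]], r), 0)
    i <- which.min(dd)
    lab <- panel_labels$label[i]; st <- panel_labels$status[i]
    if (dd[i] > tau_assign) {
      call <- "atypical_unassigned"
    } else {
      call <- switch(st, typical = paste0("typical_", lab),
                     cryptic = paste0("cryptic_", lab),
                     "atypical_unassigned")
    }
    data.frame(haplotype = q, label = if (call == "atypical_unassigned")
      NA_character_ else lab,
      status = if (call == "atypical_unassigned") "atypical" else st,
      distance = unname(dd[i]), call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
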