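# Composite NUMT screening: five warning signs combined into a per-group
# verdict (typical / cryptic_candidate / numt_suspect).
#
# W1: amino-acid segregating differences against the reference panel,
#     and/or retained first-codon-position resolution.
# W2: tree placement discordant with the taxonomic framework (the group
#     falls on the outgroup side of the species clade).
# W3: multiple related haplotypes within one building at balanced
#     frequencies (Hd above threshold with no star pattern).
# W4: ambiguity-code density (the chromatogram double-peak proxy for
#     co-amplification).
# W5: nuclear alleles shared with mites carrying typical haplotypes.
# An in-frame stop codon overrides everything: the sequence cannot be a
# functional mitochondrial CO1.

#' Screening thresholds
#'
#' @param tau_hd Within-building haplotype diversity threshold for W3
#'   (default 0.70).
#' @param tau_aa_seg Minimum amino-acid segregating differences for W1
#'   (default 3, quantifying "several").
#' @param tau_assign Assignment p-distance threshold shared with
#'   [assign_haplogroups()].
#' @param tau_ambig Maximum in-window ambiguity-code fraction per sequence
#'   before it counts toward W4 (default 0.02).
#' @param tau_support,tau_stem Retention thresholds shared with
#'   [resolution_retention()].
#' @param min_sample Guidance sample size per building for W3 (default 20).
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(tau_hd = 0.70, tau_aa_seg = 3L, tau_assign = 0.03,
                          tau_ambig = 0.02, tau_support = 70, tau_stem = 0.5,
                          min_sample = 20L) {
  stopifnot(tau_hd > 0, tau_hd <= 1, tau_aa_seg >= 1, tau_assign > 0,
            tau_ambig >= 0, tau_ambig <= 1)
  structure(list(tau_hd = tau_hd, tau_aa_seg = as.integer(tau_aa_seg),
                 tau_assign = tau_assign, tau_ambig = tau_ambig,
                 tau_support = tau_support, tau_stem = tau_stem,
                 min_sample = as.integer(min_sample)),
            class = "screen_config")
}

#' W1: amino-acid divergence and/or first-position resolution retention
#'
#' Counts amino-acid positions at which the candidate group shares no
#' state with the reference panel; fires when that count reaches
#' `tau_aa_seg` or when the group's first-codon-position resolution is
#' retained. In-frame stop codons are recorded separately (they force the
#' final verdict regardless of warnings).
#'
#' @param group_seqs Named sequences of the candidate group (aligned with
#'   the panel; gaps allowed).
#' @param panel_seqs Reference sequences (typical + cryptic).
#' @param retention Logical retention flag for the group (from
#'   [resolution_retention()]), NA if unavailable.
#' @param code A [genetic_code()].
#' @param frame_offset Reading frame.
#' @param config A [screen_config()].
#' @return List: fired, aa_segregating, stop_codon_present, retention.
#' @export
warning_w1 <- function(group_seqs, panel_seqs, retention = NA, code = genetic_code("5"),
                       frame_offset = 0L, config = screen_config()) {
  tr_g <- lapply(group_seqs, translate_dna, code = code, frame_offset = frame_offset)
  tr_p <- lapply(panel_seqs, translate_dna, code = code, frame_offset = frame_offset)
  stop_present <- any(vapply(tr_g, function(t) length(t$stop_codons) > 0L, TRUE))
  aa_mat <- function(tr) {
    aa <- strsplit(vapply(tr, `[[`, "", "aa"), "")
    w <- max(lengths(aa))
    do.call(rbind, lapply(aa, function(x) c(x, rep("X", w - length(x)))))
  }
  g_aa <- aa_mat(tr_g)
  p_aa <- aa_mat(tr_p)
  ncmp <- min(ncol(g_aa), ncol(p_aa))
  aa_seg <- sum(vapply(seq_len(ncmp), function(j) {
    gs <- setdiff(unique(g_aa[, j]), c("X", "*"))
    ps <- setdiff(unique(p_aa[, j]), c("X", "*"))
    length(gs) > 0L && length(ps) > 0L && !any(gs %in% ps)
  }, TRUE))
  fired <- (aa_seg >= config$tau_aa_seg) || isTRUE(retention)
  list(fired = fired, aa_segregating = as.integer(aa_seg),
       stop_codon_present = stop_present, retention = retention)
}

#' W2: discordance with the taxonomic framework
#'
#' Roots the diagnostic tree on the outgroup and asks whether the smallest
#' clade containing both the candidate group and all typical references
#' also contains an outgroup taxon. If it does, the group attaches on the
#' outgroup side of the species clade (the JOW-type signature); a lineage
#' sister to the species clade (the cryptic-species pattern) does not fire.
#'
#' @param dt A `diag_tree` whose taxa include group members, typical
#'   references and >= 2 outgroup taxa.
#' @param group Tip labels of the candidate group.
#' @param typical_refs Tip labels of the typical references.
#' @param outgroup Tip labels of the outgroup taxa.
#' @return List: fired, note.
#' @export
warning_w2 <- function(dt, group, typical_refs, outgroup) {
  tree <- dt$tree
  tips <- tree$tip.label
  if (length(outgroup) < 1L) stop("need outgroup taxa")
  stopifnot(all(c(group, typical_refs, outgroup) %in% tips))
  root_tip <- outgroup[1L]
  if (root_tip %in% group)
    return(list(fired = FALSE, note = "indeterminate: group contains root"))
  rt <- tryCatch(ape::root(tree, outgroup = root_tip, resolve.root = TRUE),
                 error = function(e) NULL)
  if (is.null(rt))
    return(list(fired = FALSE, note = "indeterminate: unresolved placement"))
  node <- ape::getMRCA(rt, unique(c(group, typical_refs)))
  clade_tips <- ape::extract.clade(rt, node)$tip.label
  fired <- any(outgroup %in% clade_tips)
  list(fired = fired, note = if (fired) "group attaches among outgroups" else "")
}

#' W3: balanced multiplicity within a building
#'
#' @param stats A [diversity_stats()] row for the building.
#' @param star A [star_score()] result for the building.
#' @param config A [screen_config()].
#' @return List: fired, low_n (TRUE when n < min_sample).
#' @export
warning_w3 <- function(stats, star, config = screen_config()) {
  if (stats$n < 2L) stop("need n >= 2")
  list(fired = (stats$Hd > config$tau_hd) && (star$score < 0.5),
       low_n = stats$n < config$min_sample)
}

#' W4: ambiguity-code density (double-peak proxy)
#'
#' Fires when more than 10% of a building's raw (pre-exclusion) sequences
#' have an in-window IUPAC-ambiguity fraction above `tau_ambig`. N and gap
#' characters count as missing data, not as double peaks.
#'
#' @param raw_seqs Named raw sequences of one building.
#' @param config A [screen_config()].
#' @return List: fired, frac_flagged, per_seq (named fractions).
#' @export
warning_w4 <- function(raw_seqs, config = screen_config()) {
  per <- vapply(strsplit(toupper(raw_seqs), ""), function(x) {
    mean(x %in% AMBIGUITY_CODES)
  }, 0)
  frac <- mean(per > config$tau_ambig)
  list(fired = frac > 0.10, frac_flagged = frac, per_seq = per)
}

#' Combine warnings and nuclear evidence into a verdict
#'
#' Verdict rule: an in-frame stop codon forces numt_suspect; otherwise two
#' or more of W1-W4 force numt_suspect; otherwise a divergent group
#' (distance to every typical reference above `tau_assign`) is a
#' cryptic_candidate when its nuclear alleles are private and a
#' numt_suspect when they are shared with typical-haplogroup carriers;
#' otherwise typical. With no nuclear data a divergent group with fewer
#' than two warnings stays a cryptic_candidate flagged "nuclear data
#' unavailable" (review manually); a single-warning non-divergent group is
#' typical with a review flag.
#'
#' @param group Group id string.
#' @param warnings Named logical vector with entries W1, W2, W3, W4 (NA
#'   allowed; treated as not fired).
#' @param stop_codon_present Logical.
#' @param divergent Logical: beyond `tau_assign` from all typical refs.
#' @param group_alleles Character vector of nuclear allele ids carried by
#'   group members (NULL when unavailable).
#' @param typical_alleles Character vector of allele ids carried by typical
#'   mites (NULL when unavailable).
#' @return Object of class `numt_verdict`: list(group, warnings, W5,
#'   stop_codon_present, verdict, review, rationale).
#' @export
numt_verdict <- function(group, warnings, stop_codon_present, divergent,
                         group_alleles = NULL, typical_alleles = NULL) {
  w <- c(W1 = FALSE, W2 = FALSE, W3 = FALSE, W4 = FALSE)
  w[names(warnings)] <- !is.na(warnings) & warnings
  nuclear_available <- !is.null(group_alleles) && !is.null(typical_alleles)
  shared <- if (nuclear_available) any(group_alleles %in% typical_alleles) else NA
  w5 <- isTRUE(shared) && divergent
  n_warn <- sum(w)
  rationale <- character(0)
  review <- FALSE
  if (stop_codon_present) {
    verdict <- "numt_suspect"
    rationale <- "in-frame stop codon(s): cannot be functional CO1"
  } else if (n_warn >= 2L) {
    verdict <- "numt_suspect"
    rationale <- paste("warnings fired:", paste(names(w)[w], collapse = "+"))
  } else if (divergent) {
    if (!nuclear_available) {
      verdict <- "cryptic_candidate"
      review <- TRUE
      rationale <- "divergent mito group; nuclear data unavailable"
    } else if (shared) {
      verdict <- "numt_suspect"
      rationale <- "divergent mito group sharing nuclear alleles with typical mites"
    } else {
      verdict <- "cryptic_candidate"
      rationale <- "divergent mito group with private nuclear alleles"
    }
  } else {
    verdict <- "typical"
    if (n_warn == 1L) {
      review <- TRUE
      rationale <- paste("single warning", names(w)[w], "- review manually")
    }
  }
  structure(list(group = group, warnings = w, W5 = w5,
                 stop_codon_present = stop_codon_present,
                 nuclear_available = nuclear_available,
                 verdict = verdict, review = review,
                 rationale = rationale), class = "numt_verdict")
}

#' @export
print.numt_verdict <- function(x, ...) {
  cat("Group", x$group, "->", x$verdict,
      if (x$review) "(review manually)" else "", "\n")
  cat("  warnings:", paste(names(x$warnings)[x$warnings], collapse = " "),
      if (x$W5) "W5", "\n")
  if (length(x$rationale)) cat("  rationale:", x$rationale, "\n")
  invisible(x)
}

#' Screen every candidate group of a dataset
#'
#' Driver used by the pipeline: collapses the per-individual alignment to
#' unique haplotypes for the tree stages, computes W1-W4 per candidate
#' group (retention and tree placement on the haplotype level, diversity
#' and ambiguity on the building level), then issues verdicts.
#'
#' @param aln Named aligned sequences (retained individuals, one marker).
#' @param groups Named list: candidate group -> sequence ids.
#' @param farms Named character vector id -> farm/building.
#' @param panel Reference panel sequences (typical + cryptic), named by
#'   label, aligned with `aln`.
#' @param panel_labels data.frame label/status, rows in `panel` order.
#' @param outgroup_seqs Named outgroup sequences (aligned with `aln`).
#' @param raw_seqs Raw pre-exclusion sequences for W4; default `aln`.
#' @param nuclear Optional data.frame id/allele of nuclear allele calls.
#' @param typical_ids Ids of typical-haplogroup carriers for allele
#'   sharing; default all ids outside candidate groups.
#' @param config A [screen_config()].
#' @param code,frame_offset Translation settings.
#' @param B,seed Bootstrap settings for the retention diagnostic.
#' @return Named list of `numt_verdict` (attribute "retention" holds the
#'   resolution report).
#' @export
screen_groups <- function(aln, groups, farms, panel, panel_labels,
                          outgroup_seqs, raw_seqs = aln, nuclear = NULL,
                          typical_ids = NULL, config = screen_config(),
                          code = genetic_code("5"), frame_offset = 0L,
                          B = 100L, seed = 1L) {
  stopifnot(length(groups) >= 1L)
  # haplotype-level view for the tree stages
  uh <- unique(unname(aln))
  hap_ids <- sprintf("U%03d", seq_along(uh))
  rep_of <- stats::setNames(hap_ids[match(unname(aln), uh)], names(aln))
  hap_seqs <- stats::setNames(uh, hap_ids)
  refs <- panel[setdiff(names(panel), names(hap_seqs))]
  tree_seqs <- c(hap_seqs, refs, outgroup_seqs)
  hgroups <- lapply(groups, function(ids) unique(rep_of[ids]))
  big <- hgroups[vapply(hgroups, length, 0L) >= 2L]
  ret <- if (length(big))
    resolution_retention(tree_seqs, big, frame_offset, model = "p", B = B,
                         seed = seed, tau_support = config$tau_support,
                         tau_stem = config$tau_stem)
  else NULL
  dt <- if (!is.null(ret)) attr(ret, "trees")$all
  else build_diag_tree(tree_seqs, "p", B = 0L)
  typical_refs <- panel_labels$label[panel_labels$status == "typical"]
  typical_refs <- intersect(typical_refs, names(tree_seqs))

  verdicts <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    gseqs <- aln[ids]
    retention <- if (!is.null(ret) && g %in% ret$group)
      ret$retention[ret$group == g] else NA
    w1 <- warning_w1(gseqs, panel, retention, code, frame_offset, config)
    w2 <- tryCatch(
      warning_w2(dt, unique(rep_of[ids]), typical_refs, names(outgroup_seqs)),
      error = function(e) list(fired = FALSE, note = conditionMessage(e)))
    # building-level balanced-multiplicity warning
    bld <- unique(farms[ids])
    w3_fired <- FALSE
    for (b in bld) {
      bids <- intersect(names(farms)[farms == b], names(aln))
      if (length(bids) < 2L) next
      tb <- tryCatch(collapse_haplotypes(aln[bids]), error = function(e) NULL)
      if (is.null(tb)) next
      st <- tryCatch(diversity_stats(tb), error = function(e) NULL)
      if (is.null(st)) next
      ss <- if (nrow(tb$haplotypes) >= 2L)
        star_score(build_msn(pairwise_distance_matrix(tb), tb))
      else list(score = 1)
      w3b <- warning_w3(st, ss, config)
      w3_fired <- w3_fired || w3b$fired
    }
    w4_ids <- intersect(names(raw_seqs), names(farms)[farms %in% bld])
    w4 <- if (length(w4_ids)) warning_w4(raw_seqs[w4_ids], config)
    else list(fired = FALSE)
    dmin <- min(vapply(gseqs, function(s)
      min(vapply(panel[typical_refs], function(r) p_distance(s, r), 0)), 0))
    divergent <- dmin > config$tau_assign
    ga <- ta <- NULL
    if (!is.null(nuclear)) {
      tid <- if (is.null(typical_ids)) setdiff(names(farms), unlist(groups))
      else typical_ids
      ga <- nuclear$allele[nuclear$id %in% ids]
      ta <- nuclear$allele[nuclear$id %in% tid]
      if (length(ga) == 0L || length(ta) == 0L) { ga <- NULL; ta <- NULL }
    }
    verdicts[[g]] <- numt_verdict(
      g, c(W1 = w1$fired, W2 = w2$fired, W3 = w3_fired, W4 = w4$fired),
      stop_codon_present = w1$stop_codon_present, divergent = divergent,
      group_alleles = ga, typical_alleles = ta)
  }
  attr(verdicts, "retention") <- ret
  verdicts
}

#' Run the seeded screening benchmark
#'
#' Simulates replicate haplogroup panels with farm-level copy structure and
#' nuclear allele assignments, screens every group, and tabulates verdicts
#' against the generator truth. Typical groups are emitted as star farms
#' (one dominant haplotype, rare satellites), NUMT groups as balanced
#' variant sets, and the cryptic lineage D as a star farm with private
#' nuclear alleles.
#'
#' @param n_rep Number of replicate panels.
#' @param base_config A [synth_config()]; n_haplogroups is forced to 4.
#' @param B Bootstrap replicates per tree.
#' @param seed Master seed; replicate r uses seed + r.
#' @param config A [screen_config()].
#' @return data.frame: replicate, group, truth_class, verdict, review.
#' @export
run_screen_benchmark <- function(n_rep = 25L, base_config = synth_config(),
                                 B = 60L, seed = 1L,
                                 config = screen_config()) {
  cfg <- base_config
  cfg$n_haplogroups <- 4L
  out <- list()
  for (r in seq_len(n_rep)) {
    set.seed(seed + r)
    dp <- simulate_diag_panel(cfg, n_per_group = 4L, include_numt = TRUE,
                              seed = NULL)
    aln <- character(0); farms <- character(0); groups <- list()
    nuclear <- NULL
    star_counts <- c(14L, 2L, 1L, 1L)
    bal_counts <- c(6L, 5L, 5L, 4L)
    for (g in names(dp$groups)) {
      mem <- dp$groups[[g]]
      counts <- if (g == "NUMT") bal_counts else star_counts
      ids <- sprintf("%s_f%02d", g, seq_len(sum(counts)))
      seqs <- rep(dp$seqs[mem], counts)
      names(seqs) <- ids
      aln <- c(aln, seqs)
      farms <- c(farms, stats::setNames(rep(paste0("farm", g), length(ids)), ids))
      groups[[g]] <- ids
      alleles <- if (g == "D") sample(c("L1a", "L1b"), length(ids), TRUE)
      else sample(c("Tro1", "Tro2", "Tro3"), length(ids), TRUE)
      nuclear <- rbind(nuclear, data.frame(id = ids, allele = alleles,
                                           stringsAsFactors = FALSE))
    }
    panel <- dp$panel$centroids
    verdicts <- screen_groups(
      aln, groups, farms, panel, dp$panel$labels,
      outgroup_seqs = dp$seqs[dp$outgroup], nuclear = nuclear,
      typical_ids = unlist(groups[c("A", "B", "C")]),
      config = config, code = dp$panel$code, B = B, seed = seed + r)
    truth <- c(A = "typical", B = "typical", C = "typical",
               D = "cryptic", NUMT = "numt")
    for (g in names(verdicts))
      out[[length(out) + 1L]] <- data.frame(
        replicate = r, group = g, truth_class = truth[[g]],
        verdict = verdicts[[g]]$verdict, review = verdicts[[g]]$review,
        stop_codon = verdicts[[g]]$stop_codon_present,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
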