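# End-to-end runner: trim -> collapse -> diversity -> network -> assign ->
# codon-position diagnostics -> NUMT screen (-> phasing when an intron
# dataset is supplied). All outputs are plain text and carry a provenance
# header, so a re-run with identical inputs and seed is byte-identical.

.provenance <- function(config_list, seed) {
  cfg <- paste(vapply(names(config_list), function(k)
    paste0(k, "=", paste(config_list[[k]], collapse = ",")), ""),
    collapse = "; ")
  sprintf("# numtscreen %s | seed=%s | %s",
          as.character(utils::packageVersion("numtscreen")), seed, cfg)
}

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' @param co1_fasta Aligned CO1 FASTA path.
#' @param samples_tsv Sample sheet (id, farm, country, marker).
#' @param panel_fasta Reference panel FASTA (names = haplogroup labels).
#' @param panel_labels_tsv TSV with columns label/status matching the panel.
#' @param outdir Output directory.
#' @param outgroup_fasta Optional outgroup FASTA (enables the taxonomic
#'   discordance warning).
#' @param tpm_fasta Optional intron consensus FASTA (enables phasing and
#'   the nuclear-sharing evidence).
#' @param trim_policy,min_coverage Passed to [trim_to_common_window()].
#' @param screen A [screen_config()].
#' @param B Bootstrap replicates for the diagnostic trees.
#' @param seed Seed for all stochastic stages.
#' @return Invisible list with every stage result and output paths.
#' @export
run_pipeline <- function(co1_fasta, samples_tsv, panel_fasta, panel_labels_tsv,
                         outdir, outgroup_fasta = NULL, tpm_fasta = NULL,
                         trim_policy = "trim_columns", min_coverage = 1.0,
                         screen = screen_config(), B = 100L, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(co1_fasta)
  if (length(seqs) == 0L) stop("empty FASTA: ", co1_fasta)
  samples <- read_samples(samples_tsv)
  missing <- setdiff(names(seqs), samples$id)
  if (length(missing))
    stop("sequence ids absent from the sample sheet: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  panel <- read_fasta(panel_fasta)
  panel_labels <- utils::read.table(panel_labels_tsv, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  panel <- panel[panel_labels$label]
  outgroup <- if (!is.null(outgroup_fasta)) read_fasta(outgroup_fasta)
  else stats::setNames(character(0), character(0))
  farms <- stats::setNames(samples$farm, samples$id)
  header <- .provenance(list(trim_policy = trim_policy,
                             min_coverage = min_coverage,
                             tau_hd = screen$tau_hd,
                             tau_assign = screen$tau_assign, B = B), seed)

  # 1. trim + collapse
  tr <- trim_to_common_window(seqs, trim_policy, min_coverage)
  tab <- collapse_haplotypes(tr$seqs, populations = farms)
  write_haplotype_table(tab, file.path(outdir, "haplotypes.tsv"))
  jsonlite::write_json(
    list(window = tab$window,
         trimmed = tr$report, excluded = tab$excluded),
    file.path(outdir, "exclusions.json"), auto_unbox = TRUE, pretty = TRUE)

  # 2. frame + assignment
  code <- genetic_code("5")
  frame <- infer_frame(panel, code)$frame_offset
  haps <- stats::setNames(tab$haplotypes$sequence, tab$haplotypes$haplotype)
  win_panel <- vapply(panel, function(p)
    substring(p, tr$window[1] + 1L, tr$window[2]), "")
  assign <- assign_haplogroups(haps, win_panel, panel_labels,
                               tau_assign = screen$tau_assign)
  .write_tsv(assign, file.path(outdir, "assignments.tsv"), header)

  # 3. diversity + farm profiles
  div <- diversity_table(tab)
  seq_call <- character(0)
  for (i in seq_len(nrow(assign)))
    seq_call[tab$members[[assign$haplotype[i]]]] <- assign$call[i]
  profiles <- do.call(rbind, lapply(div$population, function(f) {
    ids <- intersect(names(seq_call), names(farms)[farms == f])
    pr <- classify_farm_profile(seq_call[ids])
    data.frame(population = f, profile = pr$profile,
               flags = paste(pr$flags, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  summary_df <- merge(div, profiles, by = "population", sort = TRUE)
  .write_tsv(summary_df, file.path(outdir, "summary.tsv"), header)

  # 4. network
  net <- NULL
  if (nrow(tab$haplotypes) >= 2L) {
    net <- build_msn(pairwise_distance_matrix(tab), tab)
    write_gml(net, file.path(outdir, "network.gml"))
    write_network_nexus(net, file.path(outdir, "network.nex"))
  }

  # 5. phasing (optional)
  phased <- NULL; nuclear <- NULL
  if (!is.null(tpm_fasta)) {
    tpm <- read_fasta(tpm_fasta)
    hom <- tpm[!vapply(strsplit(tpm, ""), function(x)
      any(x %in% AMBIGUITY_CODES), TRUE)]
    catalog <- stats::setNames(unique(unname(hom)),
                               sprintf("Tpm%02d", seq_along(unique(unname(hom)))))
    rows <- list(); allele_rows <- list()
    for (id in names(tpm)) {
      ph <- phase_heterozygote(tpm[[id]])
      cat_hit <- if (!is.na(ph$allele_1) && length(catalog))
        match_against_catalog(ph, catalog) else NULL
      a1m <- if (!is.null(cat_hit)) cat_hit$match[1L] else NA
      a2m <- if (!is.null(cat_hit)) cat_hit$match[2L] else NA
      rows[[id]] <- data.frame(
        id = id, confidence = ph$confidence,
        indel_pos = if (is.null(ph$indel)) NA_integer_ else ph$indel$pos,
        indel_len = if (is.null(ph$indel)) NA_integer_ else ph$indel$len,
        explained = ph$explained, allele_1 = a1m, allele_2 = a2m,
        stringsAsFactors = FALSE)
      if (ph$confidence == "high")
        # sharing is decided on the allele sequence itself, so novel
        # alleles recovered in two mites still count as shared
        allele_rows[[id]] <- data.frame(
          id = id, allele = c(ph$allele_1, ph$allele_2),
          stringsAsFactors = FALSE)
    }
    phased <- do.call(rbind, rows)
    nuclear <- do.call(rbind, allele_rows)
    .write_tsv(phased, file.path(outdir, "phasing.tsv"), header)
  }

  # 6. candidate groups: atypical haplotypes grouped per farm
  atyp <- assign$haplotype[assign$call == "atypical_unassigned"]
  verdicts <- NULL
  if (length(atyp)) {
    groups <- list()
    for (hap in atyp) for (f in unique(farms[tab$members[[hap]]])) {
      key <- paste0(f, "_atypical")
      groups[[key]] <- c(groups[[key]],
                         intersect(tab$members[[hap]], names(farms)[farms == f]))
    }
    typical_ids <- names(seq_call)[startsWith(seq_call, "typical")]
    verdicts <- screen_groups(
      tr$seqs, groups, farms, win_panel, panel_labels, outgroup,
      raw_seqs = seqs, nuclear = nuclear, typical_ids = typical_ids,
      config = screen, code = code, frame_offset = frame, B = B, seed = seed)
    vj <- lapply(verdicts, function(v)
      list(verdict = v$verdict, warnings = as.list(v$warnings), W5 = v$W5,
           stop_codon_present = v$stop_codon_present, review = v$review,
           rationale = v$rationale))
    jsonlite::write_json(vj, file.path(outdir, "verdicts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    vt <- do.call(rbind, lapply(names(verdicts), function(g) {
      v <- verdicts[[g]]
      data.frame(group = g, verdict = v$verdict,
                 warnings = paste(names(v$warnings)[v$warnings],
                                  collapse = "+"),
                 W5 = v$W5, stop_codon = v$stop_codon_present,
                 review = v$review, stringsAsFactors = FALSE)
    }))
    .write_tsv(vt, file.path(outdir, "verdicts.tsv"), header)
    ret <- attr(verdicts, "retention")
    if (!is.null(ret)) {
      .write_tsv(ret, file.path(outdir, "retention.tsv"), header)
      write_diag_tree(attr(ret, "trees")$all,
                      file.path(outdir, "diag_tree.nwk"))
    }
  }

  invisible(list(trim = tr, haplotypes = tab, assignments = assign,
                 summary = summary_df, network = net, phasing = phased,
                 verdicts = verdicts,
                 paths = list(outdir = outdir)))
}
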