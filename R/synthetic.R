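# Synthetic CO1/Tpm data generator.
#
# Emulates the statistical structure the screening pipeline assumes:
# three deeply diverged functional haplogroups whose substitutions are
# third-codon-position biased and whose within-farm demography is a star
# expansion (one dominant haplotype plus rare 1-2 mutation satellites);
# NUMT pseudogene lineages evolving position-uniformly, optionally carrying
# a frameshifting indel, present at balanced within-farm frequencies; and a
# nuclear intron allele pool with fixed-length 3-7 bp heterozygous indels
# rendered as IUPAC ambiguity-code consensus sequences. Every emitted
# sequence carries a ground-truth record so parameter recovery is testable.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the study conditions the rest of the package is exercised
#' under: a 471 bp (157 codon) in-frame CO1-like fragment, three typical
#' haplogroups at ~5% mutual divergence with 90% of functional substitutions
#' on third codon positions, farms of 20 mites, satellites at 1-2 mutations,
#' NUMTs at ~12% position-uniform divergence, and a tropomyosin-like intron
#' with 3-7 bp heterozygous indels.
#'
#' @param seed Integer RNG seed.
#' @param cds_length_bp Fragment length, multiple of 3.
#' @param n_haplogroups 3 (A, B, C) or 4 (adds the cryptic lineage D).
#' @param intergroup_divergence Pairwise p-distance between haplogroup
#'   centroids, in (0, 0.15].
#' @param q3 Probability that a functional substitution lands on codon
#'   position 3.
#' @param farm_size Sequences sampled per farm.
#' @param star_mutations Support of per-satellite mutation counts.
#' @param satellite_fraction Expected fraction of non-central copies in a
#'   star farm.
#' @param numt_rate Probability that a farm in a mixed simulation carries a
#'   co-amplified NUMT lineage.
#' @param numt_divergence Position-uniform divergence of a NUMT founder from
#'   the ancestral haplotype.
#' @param numt_indel_prob Probability the NUMT lineage carries a
#'   frameshifting 1 bp deletion.
#' @param numt_fraction Share of a NUMT-carrying farm made up of NUMT reads.
#' @param cryptic_depth Multiplier on the centroid distance for the cryptic
#'   lineage D (its mitochondrial branch is deeper than the typical ones).
#' @param tpm_length Intron length in bp.
#' @param tpm_allele_pool Number of intron alleles in the pool.
#' @param tpm_indel_lengths Set of heterozygous indel lengths, subset of 3:7.
#' @param tpm_max_snps Maximum allele SNP differences within an indel
#'   heterozygote.
#' @param code_table NCBI genetic code table id (default "5", invertebrate
#'   mitochondrial).
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         cds_length_bp = 471L,
                         n_haplogroups = 3L,
                         intergroup_divergence = 0.05,
                         q3 = 0.9,
                         farm_size = 20L,
                         star_mutations = c(1L, 2L),
                         satellite_fraction = 0.15,
                         numt_rate = 0.25,
                         numt_divergence = 0.12,
                         numt_indel_prob = 0.5,
                         numt_fraction = 0.4,
                         cryptic_depth = 1.6,
                         tpm_length = 360L,
                         tpm_allele_pool = 6L,
                         tpm_indel_lengths = 3:7,
                         tpm_max_snps = 5L,
                         code_table = "5") {
  cfg <- list(seed = as.integer(seed), cds_length_bp = as.integer(cds_length_bp),
              n_haplogroups = as.integer(n_haplogroups),
              intergroup_divergence = intergroup_divergence, q3 = q3,
              farm_size = as.integer(farm_size),
              star_mutations = as.integer(star_mutations),
              satellite_fraction = satellite_fraction,
              numt_rate = numt_rate, numt_divergence = numt_divergence,
              numt_indel_prob = numt_indel_prob, numt_fraction = numt_fraction,
              cryptic_depth = cryptic_depth,
              tpm_length = as.integer(tpm_length),
              tpm_allele_pool = as.integer(tpm_allele_pool),
              tpm_indel_lengths = as.integer(tpm_indel_lengths),
              tpm_max_snps = as.integer(tpm_max_snps),
              code_table = as.character(code_table))
  stopifnot(cfg$cds_length_bp %% 3L == 0L,
            cfg$q3 >= 0, cfg$q3 <= 1,
            cfg$intergroup_divergence > 0, cfg$intergroup_divergence <= 0.15,
            cfg$n_haplogroups %in% c(3L, 4L),
            cfg$farm_size >= 2L,
            all(cfg$star_mutations >= 1L),
            all(cfg$tpm_indel_lengths %in% 3:7),
            cfg$satellite_fraction >= 0, cfg$satellite_fraction < 1)
  structure(cfg, class = "synth_config")
}

# Random in-frame stop-free CDS of length L (multiple of 3).
random_cds <- function(L, code) {
  n_codons <- L %/% 3L
  codons <- names(code$map)[code$map != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# Apply n substitutions with codon-position bias q3, never creating an
# in-frame stop. Sites in `avoid` (1-based) are not touched, so centroids
# built with disjoint site sets keep exact pairwise distances. Returns the
# mutated string with the chosen sites as an attribute.
mutate_functional <- function(seq, n, q3, code, avoid = integer(), max_retry = 200L) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  chosen <- integer(0)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      pos_in_codon <- if (stats::runif(1) < q3) 3L else sample(1:2, 1L)
      codon_i <- sample.int(L %/% 3L, 1L)
      site <- (codon_i - 1L) * 3L + pos_in_codon
      if (site %in% avoid || site %in% chosen) next
      old <- x[site]
      new <- sample(setdiff(DNA_BASES, old), 1L)
      x[site] <- new
      codon <- paste(x[(codon_i - 1L) * 3L + 1:3], collapse = "")
      if (code$map[[codon]] == "*") { x[site] <- old; next }
      chosen <- c(chosen, site)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("unsatisfiable substitution placement (stop-free constraint); ",
           "divergence too high for this fragment")
  }
  structure(paste(x, collapse = ""), sites = chosen)
}

# Apply n substitutions at positions uniform over the sequence (NUMT mode:
# no codon-position bias, stops permitted).
mutate_uniform <- function(seq, n, avoid = integer()) {
  x <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(x), avoid)
  sites <- sample(free, n)
  for (site in sites) x[site] <- sample(setdiff(DNA_BASES, x[site]), 1L)
  structure(paste(x, collapse = ""), sites = sites)
}

#' Simulate the haplogroup centroid panel
#'
#' Builds a stop-free ancestral CDS and one stop-free in-frame centroid per
#' haplogroup. Centroids receive disjoint substitution sets of
#' `round(L * divergence / 2)` sites each, so every centroid pair sits at
#' (close to) the configured divergence; substitutions land on third codon
#' positions with probability `q3`. When `n_haplogroups = 4` the fourth
#' centroid is the cryptic lineage D, placed `cryptic_depth` times deeper.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed (default `config$seed`); pass NULL to leave the
#'   RNG stream untouched (e.g. inside a larger simulation).
#' @return List: `ancestral` (string), `centroids` (named character vector,
#'   labels A, B, C and optionally D), `labels` (data.frame label/status),
#'   `code` (genetic_code).
#' @export
simulate_haplogroup_panel <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  code <- genetic_code(config$code_table)
  L <- config$cds_length_bp
  anc <- random_cds(L, code)
  d <- max(1L, round(L * config$intergroup_divergence / 2))
  labels <- c("A", "B", "C", if (config$n_haplogroups == 4L) "D")
  used <- integer(0)
  centroids <- character(0)
  for (lab in labels) {
    dd <- if (lab == "D") max(1L, round(d * config$cryptic_depth)) else d
    cen <- mutate_functional(anc, dd, config$q3, code, avoid = used)
    used <- c(used, attr(cen, "sites"))
    centroids[lab] <- as.character(cen)
  }
  status <- ifelse(labels == "D", "cryptic", "typical")
  list(ancestral = anc, centroids = centroids,
       labels = data.frame(label = labels, status = status,
                           stringsAsFactors = FALSE),
       code = code)
}

# One star: hub sequence plus satellites at 1-2 functional mutations.
# Returns named character vector of n copies (ids appended later).
star_copies <- function(hub, n, config, code) {
  out <- character(n)
  for (i in seq_len(n)) {
    if (i > 1L && stats::runif(1) < config$satellite_fraction) {
      k <- sample(config$star_mutations, 1L)
      out[i] <- as.character(mutate_functional(hub, k, config$q3, code))
    } else out[i] <- hub
  }
  out
}

# NUMT founder: ancestral haplotype evolved position-uniformly, optionally
# carrying a frameshifting 1 bp deletion (kept as '-' so the matrix stays
# aligned). The deletion position is retried until at least one in-frame
# stop appears downstream of it in the degapped translation.
numt_founder <- function(panel, config, with_indel) {
  L <- config$cds_length_bp
  fdr <- as.character(mutate_uniform(panel$ancestral,
                                     max(1L, round(L * config$numt_divergence))))
  indel_pos <- NA_integer_
  if (with_indel) {
    for (try in 1:100) {
      pos <- sample.int(L - 60L, 1L)  # keep some downstream room for stops
      x <- strsplit(fdr, "")[[1]]
      x[pos] <- "-"
      cand <- paste(x, collapse = "")
      tr <- translate_dna(cand, panel$code, 0L)
      stops_down <- tr$stop_codons[tr$stop_codons * 3L >= pos - 3L]
      if (length(stops_down) >= 1L) { fdr <- cand; indel_pos <- pos; break }
    }
    if (is.na(indel_pos))
      stop("could not place a frameshift deletion producing a downstream stop")
  }
  structure(fdr, indel_pos = indel_pos)
}

# Mutate a NUMT copy uniformly without touching the gap column.
numt_variant <- function(seq, k) {
  gap <- which(strsplit(seq, "")[[1]] == "-")
  as.character(mutate_uniform(seq, k, avoid = gap))
}

#' Simulate one farm sample
#'
#' @param config A [synth_config()].
#' @param panel Output of [simulate_haplogroup_panel()].
#' @param profile "single_group" (one star), "mixed_with_C" (two or three
#'   stars, one of them haplogroup C) or "with_numt" (a star plus a NUMT
#'   lineage at balanced copy frequencies).
#' @param farm Farm id used as sequence-id prefix.
#' @param group Haplogroup for the (dominant) star; default random typical.
#' @param coamplified For "with_numt": emit NUMT reads as ambiguity-code
#'   consensus of mitochondrial hub + NUMT copy (chromatogram double-peak
#'   proxy) instead of clean NUMT reads.
#' @param seed Optional seed; NULL (default) continues the RNG stream.
#' @return List: `sequences` (named, aligned, gap for the NUMT indel),
#'   `truth` (data.frame id/farm/lineage_class/haplogroup), `profile`.
#' @export
simulate_farm_sample <- function(config, panel,
                                 profile = c("single_group", "mixed_with_C", "with_numt"),
                                 farm = "F01", group = NULL,
                                 coamplified = FALSE, seed = NULL) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  if (config$farm_size < 2L) stop("farm_size must be >= 2")
  n <- config$farm_size
  code <- panel$code
  typical <- panel$labels$label[panel$labels$status == "typical"]
  seqs <- character(0); cls <- character(0); hg <- character(0)

  add <- function(s, class_, label_) {
    seqs <<- c(seqs, s); cls <<- c(cls, rep(class_, length(s)))
    hg <<- c(hg, rep(label_, length(s)))
  }

  if (profile == "single_group") {
    g <- if (is.null(group)) sample(panel$labels$label, 1L) else group
    status <- panel$labels$status[panel$labels$label == g]
    add(star_copies(panel$centroids[[g]], n, config, code),
        if (identical(status, "cryptic")) "cryptic" else "typical", g)
  } else if (profile == "mixed_with_C") {
    k <- sample(2:3, 1L)
    gs <- c("C", sample(setdiff(typical, "C"), k - 1L))
    sizes <- rep(n %/% k, k); sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    for (i in seq_along(gs))
      add(star_copies(panel$centroids[[gs[i]]], sizes[i], config, code),
          "typical", gs[i])
  } else { # with_numt
    g <- if (is.null(group)) sample(typical, 1L) else group
    n_numt <- max(4L, round(n * config$numt_fraction))
    n_mito <- n - n_numt
    hub <- panel$centroids[[g]]
    add(star_copies(hub, n_mito, config, code), "typical", g)
    with_indel <- stats::runif(1) < config$numt_indel_prob
    fdr <- numt_founder(panel, config, with_indel)
    n_var <- sample(3:5, 1L)
    variants <- c(as.character(fdr),
                  vapply(seq_len(n_var - 1L),
                         function(i) numt_variant(as.character(fdr), sample(1:3, 1L)),
                         ""))
    copy_counts <- rep(n_numt %/% n_var, n_var)
    copy_counts[seq_len(n_numt %% n_var)] <- copy_counts[seq_len(n_numt %% n_var)] + 1L
    for (v in seq_len(n_var)) {
      s <- rep(variants[v], copy_counts[v])
      if (coamplified) {
        s <- vapply(s, function(z)
          consensus_from_alleles(hub, gsub("-", "", z, fixed = TRUE)), "",
          USE.NAMES = FALSE)
        # co-amplified overlays are one base short when the NUMT carries the
        # deletion; pad with N to keep the matrix rectangular
        s <- vapply(s, function(z)
          paste0(z, strrep("N", config$cds_length_bp - nchar(z))), "",
          USE.NAMES = FALSE)
        add(s, "numt_coamplified", "NUMT")
      } else add(s, "numt", "NUMT")
    }
  }
  ids <- sprintf("%s_m%02d", farm, seq_along(seqs))
  names(seqs) <- ids
  truth <- data.frame(id = ids, farm = farm, lineage_class = cls,
                      haplogroup = hg, stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth, profile = profile)
}

#' Positional IUPAC consensus of two alleles (left-aligned overlay)
#'
#' Models a Sanger trace of a heterozygote: both alleles start at the same
#' primer, so after a heterozygous deletion the shorter allele's downstream
#' sequence overlays the longer one's with an offset, and each position is
#' the IUPAC union of the two bases present. Positions beyond the shorter
#' allele's end show the longer allele alone.
#'
#' @param x,y Unambiguous DNA strings (lengths may differ).
#' @return Consensus string of length `max(nchar(x), nchar(y))`.
#' @export
consensus_from_alleles <- function(x, y) {
  if (nchar(y) > nchar(x)) { tmp <- x; x <- y; y <- tmp }
  a <- strsplit(toupper(x), "")[[1]]
  b <- strsplit(toupper(y), "")[[1]]
  out <- a
  for (i in seq_along(b)) out[i] <- iupac_union(a[i], b[i])
  paste(out, collapse = "")
}

#' Simulate a tropomyosin-like intron dataset
#'
#' Builds an allele pool (SNP variants of an ancestral intron), then emits
#' homozygotes and heterozygotes. Heterozygotes with an indel pair an allele
#' with a copy of itself carrying one fixed-length deletion (lengths from
#' `tpm_indel_lengths`) plus up to `tpm_max_snps` SNPs placed downstream of
#' the indel overlay; each such consensus is checked to be uniquely
#' decodable by minimum-SNP overlay phasing and the SNPs are re-drawn
#' otherwise (the generator's identifiability contract: differences strictly
#' upstream of a heterozygous indel are assignment-symmetric in a single
#' trace, so no method can recover them). SNP-only heterozygotes carry a
#' single ambiguous site (phasable) or several (emitted as unphasable).
#'
#' @param config A [synth_config()].
#' @param n_individuals Number of mites to emit.
#' @param farm Farm id prefix.
#' @param seed Optional seed; NULL continues the RNG stream.
#' @return List: `sequences` (named consensus/homozygote strings, unaligned),
#'   `truth` (data.frame id, type, allele_1, allele_2, indel_pos (1-based),
#'   indel_len, n_snps, phasable), `pool` (named allele strings).
#' @export
simulate_tpm_dataset <- function(config, n_individuals = 30L, farm = "T01",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$tpm_allele_pool < 1L) stop("empty allele pool")
  L <- config$tpm_length
  anc <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  pool <- character(config$tpm_allele_pool)
  pool[1] <- anc
  for (i in seq_len(config$tpm_allele_pool - 1L))
    pool[i + 1L] <- as.character(mutate_uniform(anc, sample(2:6, 1L)))
  names(pool) <- sprintf("Tro%d", seq_along(pool))

  ids <- sprintf("%s_t%02d", farm, seq_len(n_individuals))
  seqs <- character(n_individuals)
  truth <- data.frame(id = ids, type = NA_character_,
                      allele_1 = NA_character_, allele_2 = NA_character_,
                      indel_pos = NA_integer_, indel_len = NA_integer_,
                      n_snps = NA_integer_, phasable = NA,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_individuals)) {
    u <- stats::runif(1)
    if (u < 0.3) { # homozygote
      a <- pool[[sample.int(length(pool), 1L)]]
      seqs[i] <- a
      truth[i, c("type", "allele_1", "allele_2")] <- c("hom", a, a)
      truth$n_snps[i] <- 0L; truth$phasable[i] <- TRUE
    } else if (u < 0.8) { # indel heterozygote
      h <- simulate_indel_het(pool, config)
      seqs[i] <- h$consensus
      truth$type[i] <- "het_indel"
      truth$allele_1[i] <- h$allele_1; truth$allele_2[i] <- h$allele_2
      truth$indel_pos[i] <- h$indel_pos; truth$indel_len[i] <- h$indel_len
      truth$n_snps[i] <- h$n_snps; truth$phasable[i] <- TRUE
    } else { # SNP-only heterozygote
      a <- pool[[sample.int(length(pool), 1L)]]
      k <- if (stats::runif(1) < 0.6) 1L else sample(2:4, 1L)
      b <- as.character(mutate_uniform(a, k))
      seqs[i] <- consensus_from_alleles(a, b)
      truth$type[i] <- "het_snp"
      truth$allele_1[i] <- a; truth$allele_2[i] <- b
      truth$n_snps[i] <- k; truth$phasable[i] <- k <= 1L
    }
  }
  names(seqs) <- ids
  list(sequences = seqs, truth = truth, pool = pool)
}

#' Construct one identifiable indel heterozygote
#'
#' @param pool Named allele pool (the long allele is drawn from it).
#' @param config A [synth_config()].
#' @param max_redraw SNP placement retries before falling back to zero SNPs.
#' @return List: consensus, allele_1 (long), allele_2 (short), indel_pos
#'   (1-based position of the first deleted base in the long allele),
#'   indel_len, n_snps.
#' @export
simulate_indel_het <- function(pool, config, max_redraw = 25L) {
  x <- pool[[sample.int(length(pool), 1L)]]
  n <- nchar(x)
  Lind <- sample(config$tpm_indel_lengths, 1L)
  p <- sample(2:(n %/% 3L), 1L)  # 5'-ward indel leaves a long overlay
  y0 <- paste0(substring(x, 1L, p - 1L), substring(x, p + Lind))
  n_snps_target <- sample(0:config$tpm_max_snps, 1L)
  for (try in seq_len(max_redraw)) {
    k <- if (try == max_redraw) 0L else n_snps_target
    y <- y0
    if (k > 0L) {
      yc <- strsplit(y, "")[[1]]
      # SNPs downstream of the overlay start (consensus column >= p + L)
      lo <- min(p + Lind, length(yc)); hi <- length(yc)
      sites <- sample(lo:hi, min(k, hi - lo + 1L))
      for (s in sites) yc[s] <- sample(setdiff(DNA_BASES, yc[s]), 1L)
      y <- paste(yc, collapse = "")
    }
    cons <- consensus_from_alleles(x, y)
    ph <- phase_heterozygote(cons, max_indel = max(config$tpm_indel_lengths))
    ok <- identical(ph$confidence, "high") && ph$n_optimal == 1L &&
      setequal(c(ph$allele_1, ph$allele_2), c(x, y))
    if (ok)
      return(list(consensus = cons, allele_1 = x, allele_2 = y,
                  indel_pos = p, indel_len = Lind, n_snps = k))
  }
  stop("failed to construct an identifiable indel heterozygote")
}

#' Write a full synthetic dataset to disk
#'
#' Runs the whole generator deterministically from `config$seed`: haplogroup
#' panel, a set of farms with the requested profile mix, and a Tpm intron
#' sample. All outputs are plain text (FASTA/TSV/key=value) so identical
#' configs give byte-identical files.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param profiles Named integer vector: farms per profile, names from
#'   single_group / mixed_with_C / with_numt.
#' @param tpm_individuals Individuals in the Tpm sample (0 skips it).
#' @param coamplified_numts Emit NUMT farms in co-amplified consensus mode.
#' @return Invisible list of the in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, dir,
                             profiles = c(single_group = 4L, mixed_with_C = 2L,
                                          with_numt = 2L),
                             tpm_individuals = 30L,
                             coamplified_numts = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  panel <- simulate_haplogroup_panel(config, seed = NULL)
  countries <- c("France", "Italy", "Norway", "Belgium", "Turkey", "Poland")
  farms <- list(); truth <- list(); meta <- list()
  fi <- 0L
  labs <- panel$labels$label
  for (prof in names(profiles)) {
    for (j in seq_len(profiles[[prof]])) {
      fi <- fi + 1L
      fid <- sprintf("F%02d", fi)
      # single-group farms rotate through the haplogroups so every lineage
      # (including cryptic D when configured) is represented in the truth
      grp <- if (prof == "single_group") labs[(j - 1L) %% length(labs) + 1L]
      else NULL
      fs <- simulate_farm_sample(config, panel, profile = prof, farm = fid,
                                 group = grp)
      farms[[fid]] <- fs
      truth[[fid]] <- cbind(fs$truth, profile = prof, marker = "CO1_region1",
                            stringsAsFactors = FALSE)
      meta[[fid]] <- data.frame(id = fs$truth$id, farm = fid,
                                country = countries[(fi - 1L) %% length(countries) + 1L],
                                marker = "CO1_region1", stringsAsFactors = FALSE)
    }
  }
  co1 <- unlist(unname(lapply(farms, function(f) f$sequences)))
  co1_truth <- do.call(rbind, truth)
  samples <- do.call(rbind, meta)

  paths <- list(co1_fasta = file.path(dir, "co1_region1.fasta"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.tsv"),
                panel_fasta = file.path(dir, "panel.fasta"),
                panel_labels = file.path(dir, "panel_labels.tsv"),
                config = file.path(dir, "config.txt"))
  write_fasta(co1, paths$co1_fasta)
  write_fasta(panel$centroids, paths$panel_fasta)
  utils::write.table(panel$labels, paths$panel_labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tpm <- NULL
  if (tpm_individuals > 0L) {
    # linked intron genotypes: a subsample of the same mites (same ids,
    # marker Tpm) so the pipeline can test nuclear allele sharing between
    # atypical-mitochondria carriers and typical ones
    pool <- character(max(3L, config$tpm_allele_pool))
    anc <- paste(sample(DNA_BASES, config$tpm_length, replace = TRUE),
                 collapse = "")
    pool[1] <- anc
    for (i in seq_len(length(pool) - 1L))
      pool[i + 1L] <- as.character(mutate_uniform(anc, sample(2:6, 1L)))
    names(pool) <- sprintf("Tro%d", seq_along(pool))
    picked <- character(0)
    for (fid in names(farms)) {
      tt <- farms[[fid]]$truth
      aty <- tt$id[tt$lineage_class %in% c("numt", "numt_coamplified")]
      typ <- tt$id[tt$lineage_class == "typical"]
      picked <- c(picked,
                  utils::head(aty, 3L), utils::head(typ, if (length(aty)) 3L else 2L))
    }
    picked <- utils::head(picked, tpm_individuals)
    tpm_seqs <- character(0)
    tpm_truth <- list()
    for (id in picked) {
      u <- stats::runif(1)
      if (u < 0.4) { # homozygote
        a <- pool[[sample.int(length(pool), 1L)]]
        tpm_seqs[id] <- a
        tpm_truth[[id]] <- data.frame(id = id, type = "hom", allele_1 = a,
                                      allele_2 = a, indel_pos = NA_integer_,
                                      indel_len = NA_integer_, n_snps = 0L,
                                      phasable = TRUE, stringsAsFactors = FALSE)
      } else {
        h <- simulate_indel_het(pool, config)
        tpm_seqs[id] <- h$consensus
        tpm_truth[[id]] <- data.frame(id = id, type = "het_indel",
                                      allele_1 = h$allele_1, allele_2 = h$allele_2,
                                      indel_pos = h$indel_pos,
                                      indel_len = h$indel_len,
                                      n_snps = h$n_snps, phasable = TRUE,
                                      stringsAsFactors = FALSE)
      }
    }
    tpm <- list(sequences = tpm_seqs, truth = do.call(rbind, tpm_truth),
                pool = pool)
    paths$tpm_fasta <- file.path(dir, "tpm.fasta")
    paths$tpm_truth <- file.path(dir, "tpm_truth.tsv")
    write_fasta(tpm$sequences, paths$tpm_fasta)
    utils::write.table(tpm$truth, paths$tpm_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    link <- samples[match(names(tpm_seqs), samples$id), ]
    link$marker <- "Tpm"
    samples <- rbind(samples, link)
  }
  write_samples(samples, paths$samples)
  utils::write.table(co1_truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0(names(unclass(config)), "=",
                    vapply(unclass(config), function(v) paste(v, collapse = ","), "")),
             paths$config)
  invisible(list(panel = panel, farms = farms, co1 = co1,
                 co1_truth = co1_truth, samples = samples, tpm = tpm,
                 paths = paths))
}

#' Simulate a haplotype panel for tree diagnostics
#'
#' Builds a small aligned taxon set for the codon-position diagnostic: a few
#' haplotypes per haplogroup, attached along the distal part of each group's
#' substitution path (a cross-study haplogroup panel has internal
#' phylogenetic depth, unlike a single farm's star), the cryptic lineage D
#' when configured, two outgroup taxa, and optionally a NUMT lineage derived
#' from an ancient mitochondrial copy (it shares part of one outgroup's
#' substitution path, so trees place it between the outgroup clades).
#'
#' @param config A [synth_config()].
#' @param n_per_group Haplotypes per haplogroup.
#' @param include_numt Add the NUMT group.
#' @param numt_indel Give the NUMT lineage a frameshifting 1 bp deletion;
#'   NA (default) draws it with probability `config$numt_indel_prob`.
#' @param seed Optional seed; NULL continues the RNG stream.
#' @return List: `seqs` (named aligned strings), `groups` (named list of
#'   taxon ids incl. "NUMT" when present), `outgroup` (ids), `panel`.
#' @export
simulate_diag_panel <- function(config, n_per_group = 4L, include_numt = TRUE,
                                numt_indel = NA, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  code <- genetic_code(config$code_table)
  L <- config$cds_length_bp
  anc <- random_cds(L, code)
  d <- max(1L, round(L * config$intergroup_divergence / 2))
  labels <- c("A", "B", "C", if (config$n_haplogroups == 4L) "D")
  seqs <- character(0); groups <- list()
  centroids <- character(0)
  used <- integer(0)
  for (lab in labels) {
    dd <- if (lab == "D") max(1L, round(d * config$cryptic_depth)) else d
    # ordered functional substitution path from the ancestor to the group
    # centroid; members attach along its distal part (a cross-study
    # haplogroup has internal depth, unlike a single farm's star)
    path <- character(dd)
    cur <- anc
    sites_lab <- integer(0)
    for (step in seq_len(dd)) {
      nxt <- mutate_functional(cur, 1L, config$q3, code,
                               avoid = c(used, sites_lab))
      sites_lab <- c(sites_lab, attr(nxt, "sites"))
      cur <- as.character(nxt)
      path[step] <- cur
    }
    used <- c(used, sites_lab)
    centroids[lab] <- path[dd]
    depths <- c(dd, sample(max(1L, ceiling(0.6 * dd)):dd,
                           n_per_group - 1L, replace = TRUE))
    ids <- sprintf("%s%d", lab, seq_len(n_per_group))
    mem <- vapply(seq_len(n_per_group), function(j) {
      if (j == 1L) path[depths[j]]
      else as.character(mutate_functional(path[depths[j]], sample(1:2, 1L),
                                          config$q3, code))
    }, "")
    names(mem) <- ids
    seqs <- c(seqs, mem)
    groups[[lab]] <- ids
  }
  panel <- list(ancestral = anc, centroids = centroids,
                labels = data.frame(label = labels,
                                    status = ifelse(labels == "D", "cryptic",
                                                    "typical"),
                                    stringsAsFactors = FALSE),
                code = code)
  # two independent outgroup lineages, each an ordered path of uniform
  # substitutions from the ancestor; the NUMT (when present) branches off
  # partway along the second path, so trees place it between the outgroup
  # clades rather than sister to the species
  n_og <- round(0.20 * L)
  x <- strsplit(panel$ancestral, "")[[1]]
  make_path <- function() {
    sites <- sample.int(L, n_og)
    bases <- vapply(sites, function(s) sample(setdiff(DNA_BASES, x[s]), 1L), "")
    function(k) {
      y <- x
      y[sites[seq_len(k)]] <- bases[seq_len(k)]
      paste(y, collapse = "")
    }
  }
  path1 <- make_path(); path2 <- make_path()
  og1 <- path1(n_og)
  og2 <- path2(n_og)
  seqs <- c(seqs, OG1 = og1, OG2 = og2)
  outgroup <- c("OG1", "OG2")
  if (include_numt) {
    stem <- path2(round(0.4 * n_og))  # ancient copy on the outgroup side
    fdr <- as.character(mutate_uniform(stem, round(0.05 * L)))
    if (is.na(numt_indel)) numt_indel <- stats::runif(1) < config$numt_indel_prob
    if (numt_indel) {
      for (try in 1:100) {
        pos <- sample.int(L - 60L, 1L)
        x2 <- strsplit(fdr, "")[[1]]
        x2[pos] <- "-"
        cand <- paste(x2, collapse = "")
        tr <- translate_dna(cand, code, 0L)
        if (length(tr$stop_codons[tr$stop_codons * 3L >= pos - 3L]) >= 1L) {
          fdr <- cand
          break
        }
      }
    }
    ids <- sprintf("NUMT%d", seq_len(n_per_group))
    mem <- c(fdr, vapply(seq_len(n_per_group - 1L), function(i)
      numt_variant(fdr, sample(2:4, 1L)), ""))
    names(mem) <- ids
    seqs <- c(seqs, mem)
    groups[["NUMT"]] <- ids
  }
  list(seqs = seqs, groups = groups, outgroup = outgroup, panel = panel)
}
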