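test_that("haplogroup panel centroids honour divergence and codon bias", {
  cfg <- synth_config(seed = 21, q3 = 1.0, intergroup_divergence = 0.02)
  pan <- simulate_haplogroup_panel(cfg)
  # q3 = 1 forces every centroid difference onto codon position 3
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C")))
    expect_true(all(diff_positions(pan$centroids[[pair[1]]],
                                   pan$centroids[[pair[2]]]) == 3L))

  cfg2 <- synth_config(seed = 22)
  pan2 <- simulate_haplogroup_panel(cfg2)
  code <- pan2$code
  for (cen in pan2$centroids)
    expect_length(translate_dna(cen, code)$stop_codons, 0L)
  dd <- c(p_distance(pan2$centroids[["A"]], pan2$centroids[["B"]]),
          p_distance(pan2$centroids[["A"]], pan2$centroids[["C"]]),
          p_distance(pan2$centroids[["B"]], pan2$centroids[["C"]]))
  expect_true(all(abs(dd - 0.05) / 0.05 <= 0.2))
  # intergroup scale clears the 1-2 mutation star scale by a wide margin
  expect_true(all(dd > 2 / cfg2$cds_length_bp))
})

test_that("farm profiles produce the documented demographic structure", {
  cfg <- synth_config(seed = 7)
  pan <- simulate_haplogroup_panel(cfg)
  fs <- simulate_farm_sample(cfg, pan, "single_group", farm = "F01", seed = 7)
  tab <- collapse_haplotypes(fs$sequences)
  hub_count <- max(tab$haplotypes$count)
  expect_gte(hub_count, ceiling(20 * (1 - cfg$satellite_fraction)) - 3L)
  d <- pairwise_distance_matrix(tab)
  hub <- tab$haplotypes$haplotype[which.max(tab$haplotypes$count)]
  expect_true(all(d[hub, ] <= 2L))
  expect_true(all(fs$truth$lineage_class == "typical"))

  # frameshifted NUMTs always carry a downstream in-frame stop
  cfg2 <- synth_config(seed = 8, numt_indel_prob = 1)
  pan2 <- simulate_haplogroup_panel(cfg2)
  fs2 <- simulate_farm_sample(cfg2, pan2, "with_numt", farm = "F02", seed = 8)
  numt_ids <- fs2$truth$id[fs2$truth$lineage_class == "numt"]
  expect_gt(length(numt_ids), 0L)
  for (id in numt_ids)
    expect_gt(length(translate_dna(fs2$sequences[[id]], pan2$code)$stop_codons), 0L)
  # balanced copy numbers among NUMT variants: max/min count ratio <= 3
  ntab <- table(fs2$sequences[numt_ids])
  expect_lte(max(ntab) / min(ntab), 3)

  # truth table covers every emitted sequence exactly once
  expect_setequal(fs2$truth$id, names(fs2$sequences))
  expect_false(anyDuplicated(fs2$truth$id) > 0L)

  expect_error(simulate_farm_sample(cfg, pan, "nonsense"), "arg")
})

test_that("functional substitutions are third-position biased, NUMT ones uniform", {
  cfg <- synth_config(seed = 31)
  # pool pairwise differences across several independent panels
  pos_fun <- integer(0)
  for (s in 1:8) {
    pan <- simulate_haplogroup_panel(synth_config(seed = 300 + s))
    pos_fun <- c(pos_fun,
                 diff_positions(pan$centroids[["A"]], pan$centroids[["B"]]),
                 diff_positions(pan$centroids[["A"]], pan$centroids[["C"]]))
  }
  expect_gte(length(pos_fun), 200L)
  ci <- stats::binom.test(sum(pos_fun == 3L), length(pos_fun))$conf.int
  expect_true(cfg$q3 >= ci[1] && cfg$q3 <= ci[2])

  pos_numt <- integer(0)
  set.seed(77)
  pan <- simulate_haplogroup_panel(synth_config(seed = 77), seed = NULL)
  for (s in 1:8) {
    numt <- mutate_uniform_for_test(pan$ancestral, 56L)
    pos_numt <- c(pos_numt, diff_positions(pan$ancestral, numt))
  }
  expect_gte(length(pos_numt), 300L)
  gof <- stats::chisq.test(tabulate(pos_numt, 3L))
  expect_gt(gof$p.value, 0.01)
})

test_that("Tpm heterozygote consensus follows the overlay construction", {
  cfg <- synth_config(seed = 41)
  a <- random_dna(120)
  expect_equal(consensus_from_alleles(a, a), a)

  # single 3 bp indel: ambiguity codes only downstream of the indel site
  b <- paste0(substring(a, 1, 39), substring(a, 43))
  cons <- consensus_from_alleles(a, b)
  ch <- strsplit(cons, "")[[1]]
  amb <- which(!ch %in% c("A", "C", "G", "T"))
  expect_true(all(amb >= 40L))

  # configured indel lengths are the only ones emitted
  cfg2 <- synth_config(seed = 42, tpm_indel_lengths = c(3L, 7L))
  tpm <- simulate_tpm_dataset(cfg2, n_individuals = 25, seed = 42)
  lens <- tpm$truth$indel_len[!is.na(tpm$truth$indel_len)]
  expect_gt(length(lens), 0L)
  expect_true(all(lens %in% c(3L, 7L)))
  expect_setequal(tpm$truth$id, names(tpm$sequences))
})

test_that("identical seed and config give byte-identical datasets", {
  cfg <- synth_config(seed = 51)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1, profiles = c(single_group = 2L, with_numt = 1L),
                   tpm_individuals = 6L)
  simulate_dataset(cfg, d2, profiles = c(single_group = 2L, with_numt = 1L),
                   tpm_individuals = 6L)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("dataset generation rotates every configured haplogroup into truth", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 61, n_haplogroups = 4L)
  ds <- simulate_dataset(cfg, dir, profiles = c(single_group = 4L),
                         tpm_individuals = 0L)
  expect_setequal(unique(ds$co1_truth$haplogroup), c("A", "B", "C", "D"))
  expect_equal(length(unique(ds$co1_truth$farm)), 4L)
})
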