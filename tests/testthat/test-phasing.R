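test_that("degenerate phasing cases behave as documented", {
  a <- random_dna(120)
  # no ambiguity: homozygote, both alleles equal the input
  ph <- phase_heterozygote(a)
  expect_equal(ph$allele_1, a)
  expect_equal(ph$allele_2, a)
  expect_null(ph$indel)
  expect_equal(ph$confidence, "high")

  # the IUPAC union of two identical alleles is the allele itself
  expect_equal(consensus_from_alleles(a, a), a)

  # single-SNP heterozygote resolves into the two point alleles
  b <- a
  substr(b, 50L, 50L) <- setdiff(c("A", "C", "G", "T"),
                                 substring(a, 50L, 50L))[1L]
  cons <- consensus_from_alleles(a, b)
  ph2 <- phase_heterozygote(cons)
  expect_setequal(c(ph2$allele_1, ph2$allele_2), c(a, b))

  # multi-site SNP-only heterozygote: linkage unknowable from one trace
  b2 <- b
  substr(b2, 80L, 80L) <- setdiff(c("A", "C", "G", "T"),
                                  substring(a, 80L, 80L))[1L]
  ph3 <- phase_heterozygote(consensus_from_alleles(a, b2))
  expect_equal(ph3$confidence, "low")
})

test_that("indel heterozygotes phase exactly across the 3-7 bp range", {
  set.seed(111)
  for (L in c(3L, 5L, 7L)) {
    x <- random_dna(300)
    p <- 60L + L
    y <- paste0(substring(x, 1, p - 1L), substring(x, p + L))
    cons <- consensus_from_alleles(x, y)
    ph <- phase_heterozygote(cons)
    expect_setequal(c(ph$allele_1, ph$allele_2), c(x, y))
    expect_equal(ph$indel$len, L)
    # the reported deletion applied to the long allele yields the short one
    # (the position itself may be a left-shift-equivalent placement)
    expect_equal(paste0(substring(ph$allele_1, 1, ph$indel$pos - 1L),
                        substring(ph$allele_1, ph$indel$pos + ph$indel$len)),
                 ph$allele_2)
    # reconstruction identity: the union of the alleles is the input
    expect_equal(consensus_from_alleles(ph$allele_1, ph$allele_2), cons)
  }
})

test_that("generator heterozygotes round-trip with SNPs present", {
  cfg <- synth_config(seed = 121)
  set.seed(121)
  pool <- stats::setNames(replicate(4, random_dna(cfg$tpm_length)),
                          sprintf("Tro%d", 1:4))
  n_exact <- 0L
  snp_seen <- 0L
  for (rep in 1:40) {
    h <- simulate_indel_het(pool, cfg)
    ph <- phase_heterozygote(h$consensus)
    ok <- setequal(c(ph$allele_1, ph$allele_2), c(h$allele_1, h$allele_2))
    n_exact <- n_exact + ok
    snp_seen <- snp_seen + h$n_snps
    expect_equal(ph$confidence, "high")
    expect_equal(consensus_from_alleles(ph$allele_1, ph$allele_2),
                 h$consensus)
  }
  expect_equal(n_exact, 40L)
  expect_gt(snp_seen, 0L)  # the batch did exercise SNP-carrying pairs
})

test_that("catalog matching flags known and novel alleles", {
  set.seed(131)
  catalog <- stats::setNames(replicate(3, random_dna(200)),
                             c("Tro1", "Tro2", "Tro3"))
  x <- catalog[["Tro2"]]
  y <- paste0(substring(x, 1, 49), substring(x, 53))  # novel: 3 bp deletion
  ph <- phase_heterozygote(consensus_from_alleles(x, y))
  m <- match_against_catalog(ph, catalog)
  expect_equal(m$match[1], "Tro2")
  expect_true(m$novel[2])

  # homozygote confirmation: both alleles hit the same entry
  ph2 <- phase_heterozygote(x)
  m2 <- match_against_catalog(ph2, catalog)
  expect_equal(m2$match, c("Tro2", "Tro2"))
  expect_error(match_against_catalog(ph2, c(q = "ACGR")), "unambiguous")
})

test_that("overlay failure is reported, not guessed", {
  set.seed(141)
  # two unrelated sequences produce a consensus no single indel explains
  x <- random_dna(150)
  z <- random_dna(150)
  ph <- phase_heterozygote(consensus_from_alleles(x, z))
  expect_equal(ph$confidence, "low")
  expect_lt(ph$explained, 0.9)
})
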