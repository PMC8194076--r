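make_aln <- function(strings) {
  stats::setNames(strings, sprintf("s%02d", seq_along(strings)))
}

test_that("trimming to a common window handles both policies", {
  core <- random_dna(30)
  full <- make_aln(rep(core, 4))
  # fully resolved input passes through untouched
  tr <- trim_to_common_window(full, "trim_columns", 1.0)
  expect_equal(tr$seqs, full)
  expect_equal(tr$window, c(0L, 30L))
  expect_length(tr$dropped, 0L)

  # 3 long rows + 2 rows with N-padded flanks: window = overlap interval
  short <- paste0(strrep("N", 5), substring(core, 6, 25), strrep("N", 5))
  mix <- make_aln(c(rep(core, 3), rep(short, 2)))
  tr2 <- trim_to_common_window(mix, "trim_columns", 1.0)
  expect_equal(tr2$window, c(5L, 25L))
  expect_length(tr2$dropped, 0L)
  expect_true(all(nchar(tr2$seqs) == 20L))
  # window is maximal: extending one column either side breaks coverage
  m <- seq_matrix(mix)
  resolved <- !(m == "-" | m == "N")
  expect_lt(mean(resolved[, 5L]), 1)
  expect_lt(mean(resolved[, 26L]), 1)

  # drop_sequences keeps the full span, removes padded rows
  tr3 <- trim_to_common_window(mix, "drop_sequences")
  expect_equal(length(tr3$seqs), 3L)
  expect_true(all(nchar(tr3$seqs) == 30L))
  expect_equal(tr3$report$reason, rep("missing_flank", 2L))
})

test_that("haplotype collapsing merges, excludes and is idempotent", {
  core <- random_dna(40)
  tab <- collapse_haplotypes(make_aln(rep(core, 20)))
  expect_equal(nrow(tab$haplotypes), 1L)
  expect_equal(tab$haplotypes$count, 20L)

  # star farm: 17 hub copies + three distinct single-mutation variants
  vars <- vapply(c(5L, 15L, 25L), function(i) {
    x <- strsplit(core, "")[[1]]
    x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1L]
    paste(x, collapse = "")
  }, "")
  sk <- make_aln(c(rep(core, 17), vars))
  tab2 <- collapse_haplotypes(sk)
  expect_equal(sort(tab2$haplotypes$count), c(1L, 1L, 1L, 17L))

  # ambiguity exclusion is logged with its reason
  amb <- core
  substr(amb, 10L, 10L) <- "R"
  tab3 <- collapse_haplotypes(make_aln(c(rep(core, 3), amb)))
  expect_equal(nrow(tab3$excluded), 1L)
  expect_equal(tab3$excluded$reason, "ambiguity")
  expect_equal(sum(tab3$haplotypes$count) + nrow(tab3$excluded), 4L)

  # collapsing the haplotype sequences again changes nothing
  again <- collapse_haplotypes(stats::setNames(tab2$haplotypes$sequence,
                                               tab2$haplotypes$haplotype))
  expect_equal(sort(again$haplotypes$sequence),
               sort(tab2$haplotypes$sequence))
})

test_that("FASTA and sample sheet round-trip through disk", {
  dir <- withr::local_tempdir()
  seqs <- make_aln(c(random_dna(50), random_dna(50)))
  fa <- file.path(dir, "x.fasta")
  write_fasta(seqs, fa)
  expect_equal(read_fasta(fa), seqs)
  df <- data.frame(id = names(seqs), farm = "F01", country = "France",
                   marker = "CO1_region1", stringsAsFactors = FALSE)
  tsv <- file.path(dir, "samples.tsv")
  write_samples(df, tsv)
  expect_equal(read_samples(tsv), df)
})

test_that("primer stripping tolerates one mismatch and region defs are sane", {
  rd <- region_defs()
  expect_equal(rd$region1$expected_length_bp, 470L)
  expect_equal(rd$region2$expected_length_bp, 273L)
  core <- random_dna(120)
  fwd <- rd$region2$primer_forward
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rd$region2$primer_reverse)))
  amplicon <- paste0(fwd, core, rc)
  out <- strip_primers(c(a = amplicon), fwd, rd$region2$primer_reverse)
  expect_equal(unname(out), core)
  # one mismatch in the forward primer is still located and removed
  fwd_mm <- fwd
  substr(fwd_mm, 3L, 3L) <- setdiff(c("A","C","G","T"), substring(fwd, 3L, 3L))[1L]
  out2 <- strip_primers(c(a = paste0(fwd_mm, core, rc)), fwd,
                        rd$region2$primer_reverse)
  expect_equal(unname(out2), core)
})
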