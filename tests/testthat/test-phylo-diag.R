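test_that("codon-position subsetting partitions the window exactly", {
  cfg <- synth_config(seed = 71)
  pan <- simulate_haplogroup_panel(cfg)
  seqs <- pan$centroids
  p1 <- subset_codon_positions(seqs, 0L, "pos1")
  expect_true(all(nchar(p1) == 157L))
  expect_equal(subset_codon_positions(c(x = "ATGTTTAAA"), 0L, "pos3")[["x"]],
               "GTA")
  p2 <- subset_codon_positions(seqs, 0L, "pos2")
  p3 <- subset_codon_positions(seqs, 0L, "pos3")
  expect_equal(nchar(p1[[1]]) + nchar(p2[[1]]) + nchar(p3[[1]]),
               cfg$cds_length_bp)
  # interleaving the three partitions reassembles the original window
  re <- character(1)
  a <- strsplit(p1[[1]], "")[[1]]; b <- strsplit(p2[[1]], "")[[1]]
  c3 <- strsplit(p3[[1]], "")[[1]]
  re <- paste(as.vector(rbind(a, b, c3)), collapse = "")
  expect_equal(re, seqs[[1]])
})

test_that("NJ recovers the unique topology on additive matrices", {
  set.seed(81)
  for (n_leaves in c(4L, 6L, 8L)) {
    for (rep in 1:5) {
      fx <- random_additive_matrix(n_leaves)
      # verify additivity via the four-point condition on sampled quartets
      d <- fx$d
      quartet_ok <- TRUE
      combs <- utils::combn(rownames(d), 4L)
      for (k in seq_len(min(ncol(combs), 10L))) {
        q <- combs[, k]
        sums <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                       d[q[1], q[3]] + d[q[2], q[4]],
                       d[q[1], q[4]] + d[q[2], q[3]]))
        quartet_ok <- quartet_ok && (abs(sums[2] - sums[3]) < 1e-8)
      }
      expect_true(quartet_ok)
      nj_tree <- ape::nj(as.dist(d))
      expect_equal(ape::dist.topo(ape::unroot(nj_tree), ape::unroot(fx$tree)),
                   0, ignore_attr = TRUE)
    }
  }
})

test_that("bootstrap trees are seeded and B=0 omits support", {
  cfg <- synth_config(seed = 91)
  dp <- simulate_diag_panel(cfg, include_numt = FALSE, seed = 91)
  dt0 <- build_diag_tree(dp$seqs, B = 0L)
  expect_null(dt0$boot_splits)
  dt1 <- build_diag_tree(dp$seqs, B = 25L, seed = 5L)
  dt2 <- build_diag_tree(dp$seqs, B = 25L, seed = 5L)
  expect_equal(group_support(dt1, dp$groups[["A"]]),
               group_support(dt2, dp$groups[["A"]]))
  expect_error(build_diag_tree(dp$seqs[1:3]), "4 taxa")
  expect_error(build_diag_tree(dp$seqs, B = 10L), "seed")
})

test_that("haplogroups are monophyletic with strong support on all positions", {
  cfg <- synth_config(seed = 95, n_haplogroups = 4L)
  dp <- simulate_diag_panel(cfg, include_numt = FALSE, seed = 95)
  dt <- build_diag_tree(dp$seqs, B = 100L, seed = 7L)
  for (g in names(dp$groups))
    expect_gte(group_support(dt, dp$groups[[g]]), 90)
})

test_that("first-position retention separates pseudogene from functional groups", {
  flags <- list(typical = logical(0), numt = logical(0))
  for (s in 1:6) {
    cfg <- synth_config(seed = 900 + s)
    dp <- simulate_diag_panel(cfg, include_numt = TRUE, seed = 900 + s)
    rr <- resolution_retention(dp$seqs, dp$groups, B = 80L, seed = s)
    flags$typical <- c(flags$typical,
                       rr$retention[rr$group %in% c("A", "B", "C")])
    flags$numt <- c(flags$numt, rr$retention[rr$group == "NUMT"])
  }
  expect_lte(mean(flags$typical), 0.2)
  expect_gte(mean(flags$numt), 0.8)

  # degenerate group spanning (almost) everything is trivially retained
  cfg <- synth_config(seed = 99)
  dp <- simulate_diag_panel(cfg, include_numt = FALSE, seed = 99)
  all_grp <- list(everything = setdiff(names(dp$seqs), "OG1"))
  rr2 <- resolution_retention(dp$seqs, all_grp, B = 10L, seed = 1L)
  expect_true(rr2$degenerate[1])
  expect_true(rr2$retention[1])
})

test_that("newick export carries bootstrap support as node labels", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 97)
  dp <- simulate_diag_panel(cfg, include_numt = FALSE, seed = 97)
  dt <- build_diag_tree(dp$seqs, B = 20L, seed = 2L)
  path <- write_diag_tree(dt, file.path(dir, "t.nwk"))
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, names(dp$seqs))
  expect_true(length(tr$node.label) > 0L)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(stats::na.omit(sup) >= 0 & stats::na.omit(sup) <= 100))
})
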