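test_that("balanced-multiplicity warning follows the Hd and star thresholds", {
  base <- random_dna(60)
  sat <- vapply(c(2L, 12L, 22L), function(i) {
    x <- strsplit(base, "")[[1]]
    x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1L]
    paste(x, collapse = "")
  }, "")
  star_tab <- table_from_counts(c(base, sat), c(17L, 1L, 1L, 1L))
  st <- diversity_stats(star_tab)
  ss <- star_score(build_msn(pairwise_distance_matrix(star_tab), star_tab))
  w <- warning_w3(st, ss)
  expect_false(w$fired)           # Hd ~ 0.284: expansion, not co-amplification

  set.seed(55)
  far <- vapply(1:3, function(i) mutate_uniform_for_test(base, 5L), "")
  bal_tab <- table_from_counts(c(base, far), c(6L, 5L, 5L, 4L))
  st2 <- diversity_stats(bal_tab)
  expect_equal(st2$Hd, 20 * (1 - 102 / 400) / 19, tolerance = 1e-12)
  expect_gt(st2$Hd, 0.70)
  ss2 <- star_score(build_msn(pairwise_distance_matrix(bal_tab), bal_tab))
  expect_true(warning_w3(st2, ss2)$fired)

  uni_tab <- table_from_counts(base, 20L)
  expect_false(warning_w3(diversity_stats(uni_tab), list(score = 1))$fired)
})

test_that("ambiguity-density warning uses the per-sequence threshold", {
  clean <- stats::setNames(replicate(20, random_dna(100)),
                           sprintf("c%02d", 1:20))
  expect_false(warning_w4(clean)$fired)

  # a single ambiguous base in one sequence stays under the radar
  one <- clean
  substr(one[["c01"]], 5L, 5L) <- "R"
  expect_false(warning_w4(one)$fired)

  # co-amplification: a quarter of the farm full of double peaks
  messy <- clean
  for (id in sprintf("c%02d", 1:5)) {
    x <- strsplit(messy[[id]], "")[[1]]
    x[seq(2, 60, by = 3)] <- "Y"
    messy[id] <- paste(x, collapse = "")
  }
  expect_true(warning_w4(messy)$fired)
})

test_that("amino-acid segregation warning sees pseudogene divergence", {
  cfg <- synth_config(seed = 151)
  pan <- simulate_haplogroup_panel(cfg)
  sat <- as.character(numtscreen:::mutate_functional(
    pan$centroids[["A"]], 2L, cfg$q3, pan$code))
  typ <- c(t1 = pan$centroids[["A"]], t2 = sat)
  w_typ <- warning_w1(typ, pan$centroids, retention = FALSE, pan$code)
  expect_false(w_typ$fired)
  expect_false(w_typ$stop_codon_present)

  set.seed(151)
  numt <- mutate_uniform_for_test(pan$ancestral, 56L)
  w_numt <- warning_w1(c(n1 = numt), pan$centroids, retention = NA, pan$code)
  expect_true(w_numt$fired)
  expect_gte(w_numt$aa_segregating, 3L)

  # a stop-free pseudogene can still fire through retained pos1 resolution
  w_ret <- warning_w1(typ, pan$centroids, retention = TRUE, pan$code)
  expect_true(w_ret$fired)
})

test_that("verdict rule: stops dominate, warnings combine, nuclear decides", {
  v1 <- numt_verdict("g", c(W1 = FALSE), stop_codon_present = TRUE,
                     divergent = TRUE)
  expect_equal(v1$verdict, "numt_suspect")

  v2 <- numt_verdict("g", c(W1 = TRUE, W3 = TRUE), FALSE, divergent = TRUE)
  expect_equal(v2$verdict, "numt_suspect")

  v3 <- numt_verdict("g", c(W1 = FALSE), FALSE, divergent = TRUE,
                     group_alleles = c("L1a", "L1b"),
                     typical_alleles = c("Tro1", "Tro2"))
  expect_equal(v3$verdict, "cryptic_candidate")

  v4 <- numt_verdict("g", c(W1 = FALSE), FALSE, divergent = TRUE,
                     group_alleles = c("Tro1"),
                     typical_alleles = c("Tro1", "Tro2"))
  expect_equal(v4$verdict, "numt_suspect")
  expect_true(v4$W5)

  v5 <- numt_verdict("g", c(W1 = FALSE, W2 = FALSE), FALSE, divergent = FALSE)
  expect_equal(v5$verdict, "typical")
  expect_false(v5$review)

  v6 <- numt_verdict("g", c(W3 = TRUE), FALSE, divergent = FALSE)
  expect_equal(v6$verdict, "typical")
  expect_true(v6$review)

  # monotonicity: adding a stop codon can only move toward numt_suspect
  for (w in list(c(W1 = FALSE), c(W1 = TRUE), c(W1 = TRUE, W3 = TRUE))) {
    for (div in c(TRUE, FALSE)) {
      base_v <- numt_verdict("g", w, FALSE, div)$verdict
      stop_v <- numt_verdict("g", w, TRUE, div)$verdict
      rank <- c(typical = 1, cryptic_candidate = 2, numt_suspect = 3)
      expect_gte(rank[[stop_v]], rank[[base_v]])
    }
  }
})

test_that("outgroup-side placement fires W2, sister placement does not", {
  cfg <- synth_config(seed = 161, n_haplogroups = 4L)
  dp <- simulate_diag_panel(cfg, include_numt = TRUE, seed = 161)
  dt <- build_diag_tree(dp$seqs, B = 0L)
  w_numt <- warning_w2(dt, dp$groups[["NUMT"]],
                       typical_refs = c("A1", "B1", "C1"),
                       outgroup = dp$outgroup)
  expect_true(w_numt$fired)
  w_d <- warning_w2(dt, dp$groups[["D"]],
                    typical_refs = c("A1", "B1", "C1"),
                    outgroup = dp$outgroup)
  expect_false(w_d$fired)
  w_c <- warning_w2(dt, dp$groups[["C"]],
                    typical_refs = c("A1", "B1"),
                    outgroup = dp$outgroup)
  expect_false(w_c$fired)
})

test_that("screening benchmark separates the three classes", {
  bench <- run_screen_benchmark(n_rep = 6L, B = 50L, seed = 171)
  typ <- bench[bench$truth_class == "typical", ]
  numt <- bench[bench$truth_class == "numt", ]
  cry <- bench[bench$truth_class == "cryptic", ]
  expect_gte(mean(numt$verdict == "numt_suspect"), 0.8)
  expect_gte(mean(typ$verdict == "typical"), 0.8)
  expect_false(any(cry$verdict == "typical"))
  expect_true(all(bench$verdict[bench$stop_codon] == "numt_suspect"))
})
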