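test_that("pairwise distances equal the per-column mismatch count", {
  expect_equal(pairwise_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0L)
  expect_equal(pairwise_distance_matrix(c(a = "ACGT", b = "ACGA"))["a", "b"], 1L)
  set.seed(9)
  seqs <- c(x = random_dna(80), y = random_dna(80), z = random_dna(80))
  d <- pairwise_distance_matrix(seqs)
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    a <- strsplit(seqs[[pair[1]]], "")[[1]]
    b <- strsplit(seqs[[pair[2]]], "")[[1]]
    cnt <- 0L
    for (i in seq_along(a)) if (a[i] != b[i]) cnt <- cnt + 1L
    expect_equal(d[pair[1], pair[2]], cnt)
  }
  expect_true(isSymmetric(d))
})

test_that("MSN reproduces the star, the single edge and tied cycles", {
  # hub + 3 satellites at distance 1, satellites mutually at 2
  d <- matrix(2L, 4L, 4L, dimnames = list(c("hub", "s1", "s2", "s3"),
                                          c("hub", "s1", "s2", "s3")))
  diag(d) <- 0L
  d["hub", c("s1", "s2", "s3")] <- d[c("s1", "s2", "s3"), "hub"] <- 1L
  net <- build_msn(d)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1L))
  expect_true(all(net$edges$from == "hub" | net$edges$to == "hub"))
  expect_true(all(net$edges$in_every_mst))

  d2 <- matrix(c(0L, 5L, 5L, 0L), 2L, dimnames = list(c("a", "b"), c("a", "b")))
  net2 <- build_msn(d2)
  expect_equal(net2$edges$weight, 5L)

  # 4-cycle with tied weight-1 edges: all four belong to some MST
  d3 <- matrix(2L, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  diag(d3) <- 0L
  for (e in list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
    d3[e[1], e[2]] <- d3[e[2], e[1]] <- 1L
  net3 <- build_msn(d3)
  expect_equal(nrow(net3$edges), 4L)
  expect_true(all(net3$edges$weight == 1L))
  expect_false(any(net3$edges$in_every_mst))
  # the brute-force union over all labelled spanning trees agrees
  oracle <- msn_bruteforce(d3)
  expect_setequal(edge_key_set(net3$edges, rownames(d3)),
                  apply(oracle, 1L, function(e) paste(sort(e), collapse = "-")))
})

test_that("MSN equals the exhaustive union of all MSTs on random instances", {
  set.seed(33)
  for (rep in 1:40) {
    h <- sample(3:6, 1L)
    # small integer weights make ties frequent
    d <- matrix(0L, h, h)
    w <- sample(1:4, h * (h - 1L) / 2L, replace = TRUE)
    d[upper.tri(d)] <- w
    d <- d + t(d)
    dimnames(d) <- list(sprintf("h%d", 1:h), sprintf("h%d", 1:h))
    net <- build_msn(d)
    oracle <- msn_bruteforce(d)
    expect_setequal(edge_key_set(net$edges, rownames(d)),
                    apply(oracle, 1L, function(e) paste(sort(e), collapse = "-")))
  }
})

test_that("every MSN contains each single MST and respects trait sums", {
  set.seed(44)
  base <- random_dna(60)
  vars <- vapply(1:5, function(i) mutate_uniform_for_test(base, i + 1L), "")
  seqs <- c(base, vars)
  counts <- c(8L, 3L, 3L, 2L, 2L, 2L)
  tab <- table_from_counts(seqs, counts)
  d <- pairwise_distance_matrix(tab)
  net <- build_msn(d, tab)
  expect_gte(nrow(net$edges), nrow(d) - 1L)
  # an independently computed MST (igraph) is a subgraph of the MSN
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  mst_edges <- apply(igraph::as_edgelist(mst), 1L, function(e)
    paste(sort(match(e, rownames(d))), collapse = "-"))
  expect_true(all(mst_edges %in% edge_key_set(net$edges, rownames(d))))
  expect_equal(unname(rowSums(net$traits)), net$nodes$freq)
  expect_equal(sum(net$nodes$freq), sum(counts))
})

test_that("star score separates expansion stars from balanced scatter", {
  base <- random_dna(50)
  sat <- vapply(c(3L, 13L, 23L), function(i) {
    x <- strsplit(base, "")[[1]]
    x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1L]
    paste(x, collapse = "")
  }, "")
  tab <- table_from_counts(c(base, sat), c(17L, 1L, 1L, 1L))
  net <- build_msn(pairwise_distance_matrix(tab), tab)
  ss <- star_score(net)
  expect_equal(ss$score, 0.85)
  expect_equal(ss$hub,
               tab$haplotypes$haplotype[which.max(tab$haplotypes$count)])

  # scattered balanced variants at >= 3 mutations: no star signal
  far <- vapply(1:3, function(i) mutate_uniform_for_test(base, 4L), "")
  tab2 <- table_from_counts(c(base, far), c(6L, 5L, 5L, 4L))
  d2 <- pairwise_distance_matrix(tab2)
  skip_if(any(d2[1, -1] <= 2L))  # mutation collision made a variant close
  ss2 <- star_score(build_msn(d2, tab2))
  expect_equal(ss2$score, 0)

  # degenerate population: one haplotype present -> score 1
  tab3 <- table_from_counts(c(base, far[1]), c(9L, 1L), pop = "P")
  tab3$counts[2, "P"] <- 0L  # only the hub remains in this population
  net3 <- build_msn(pairwise_distance_matrix(tab3), tab3)
  expect_equal(star_score(net3, "P")$score, 1)
})

test_that("network exports are well-formed text", {
  base <- random_dna(40)
  tab <- table_from_counts(c(base, mutate_uniform_for_test(base, 1L)),
                           c(5L, 2L))
  net <- build_msn(pairwise_distance_matrix(tab), tab)
  dir <- withr::local_tempdir()
  gml <- write_gml(net, file.path(dir, "n.gml"))
  nex <- write_network_nexus(net, file.path(dir, "n.nex"))
  gml_lines <- readLines(gml)
  expect_equal(sum(grepl("^  node", gml_lines)), 2L)
  expect_equal(sum(grepl("^  edge", gml_lines)), 1L)
  nex_lines <- readLines(nex)
  expect_equal(nex_lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN NETWORK;", nex_lines)))
})
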