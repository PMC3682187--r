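# Gower dissimilarity, UPGMA, tree cutting, group-rule assignment.

test_that("Gower dissimilarity is the mismatch proportion over 7 binary variables", {
  x <- c(1, 0, 1, 0, 1, 0, 1)
  y <- c(1, 1, 1, 0, 0, 0, 1)
  st <- make_states(rbind(x, y, x, 1 - x), gene_id = c("a", "b", "c", "d"))
  d <- gower_dissimilarity(st)
  expect_equal(d["a", "b"], 2 / 7)
  expect_equal(d["a", "c"], 0)     # identical patterns
  expect_equal(d["a", "d"], 1)     # complement patterns
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  st$S5p_TSS[1] <- 2
  expect_error(gower_dissimilarity(st), "0 or 1")
})

test_that("pattern-collapsed Gower matches an independent mixed-data implementation", {
  skip_if_not_installed("cluster")
  set.seed(53)
  m <- all_patterns_m()[sample(128, 40), ]
  st <- make_states(m)
  d <- gower_dissimilarity(st)
  # daisy treats 0/1 columns as interval-scaled (range 1), which is exactly
  # the symmetric-binary mismatch proportion; silence its note about that
  ref <- suppressWarnings(
    as.matrix(cluster::daisy(as.data.frame(m), metric = "gower")))
  expect_equal(unname(unclass(d)), unname(ref), tolerance = 1e-10)
})

test_that("UPGMA reproduces the hand-computed three-leaf dendrogram", {
  D <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.7,
                0.5, 0.7, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  up <- average_linkage(D)
  expect_equal(up$height, c(0.1, 0.6))
  expect_equal(up$merge[1, ], c(-2L, -1L))
  cut2 <- cut_tree(up, 2)
  expect_equal(cut2$cluster[1], cut2$cluster[2])     # {A, B} together
  expect_false(cut2$cluster[1] == cut2$cluster[3])   # C apart
  expect_setequal(cut2$cluster, 1:2)
})

test_that("tied dissimilarities merge in lexicographic cluster-index order", {
  D <- matrix(0.4, 4, 4); diag(D) <- 0
  up <- average_linkage(D)
  expect_equal(up$height, rep(0.4, 3))
  # lexicographic cluster-index tie-break: (1,2), then (3,4), then (5,6)
  expect_equal(up$merge[1, ], c(-2L, -1L))
  expect_equal(up$merge[2, ], c(-4L, -3L))
  expect_equal(up$merge[3, ], c(1L, 2L))
})

test_that("UPGMA equals the O(n^3) brute-force agglomeration on random matrices", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:8, 1)
    m <- matrix(runif(n * n), n)
    D <- round((m + t(m)) / 2, 3)  # rounding creates occasional ties
    diag(D) <- 0
    up <- average_linkage(D)
    oracle <- naive_upgma(D)
    expect_equal(up$height, oracle$heights, tolerance = 1e-12)
    expect_equal(upgma_merge_ids(up), oracle$merges)
    # merge heights are non-decreasing (average linkage is reducible)
    expect_true(all(diff(up$height) >= -1e-12))
  }
})

test_that("UPGMA heights agree with hclust average linkage when ties are absent", {
  set.seed(59)
  n <- 15
  m <- matrix(runif(n * n), n)
  D <- (m + t(m)) / 2; diag(D) <- 0
  up <- average_linkage(D)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  expect_equal(up$height, hc$height, tolerance = 1e-12)
})

test_that("cut_tree covers the degenerate cuts and rejects impossible k", {
  set.seed(61)
  m <- matrix(runif(25), 5)
  D <- (m + t(m)) / 2; diag(D) <- 0
  up <- average_linkage(D)
  expect_equal(unique(cut_tree(up, 1)$cluster), 1)
  expect_equal(sort(cut_tree(up, 5)$cluster), 1:5)
  expect_error(cut_tree(up, 0), "between 1 and 5")
  expect_error(cut_tree(up, 9), "between 1 and 5")
})

test_that("canonical patterns are labelled by exactly one rule each", {
  pats <- all_patterns_m()
  st <- make_states(pats, gene_id = sprintf("p%03d", 1:128))
  asg <- assign_groups(st)
  rules <- prcstates:::group_rules()
  n_matched <- vapply(seq_len(128), function(i) {
    sum(vapply(rules, function(r) r(pats[i, ]), logical(1)))
  }, numeric(1))
  expect_true(all(n_matched <= 1))  # rules are mutually exclusive
  canonical <- n_matched == 1
  expect_equal(asg$rule_trace[canonical],
               rep("canonical", sum(canonical)))
  expect_true(all(grepl("^nearest", asg$rule_trace[!canonical])))
  # every gene gets one of the six labels
  expect_false(anyNA(asg$group))
})

test_that("marker combinations printed for the groups map to their labels", {
  # order: S5p_TSS, 8WG16, S7p, S5p_TESdown, S2p_TESup, K27, H2Aub1
  cases <- list(
    list(bits = c(1, 0, 0, 0, 0, 1, 1), label = "PRCrepressed"),
    list(bits = c(1, 1, 1, 1, 1, 1, 1), label = "PRCactive"),
    list(bits = c(1, 1, 1, 0, 0, 1, 1), label = "PRCintermediate"),
    list(bits = c(0, 0, 0, 0, 0, 1, 0), label = "PRConly"),
    list(bits = c(1, 1, 1, 1, 1, 0, 0), label = "Active"),
    list(bits = c(0, 0, 0, 0, 0, 0, 0), label = "Inactive")
  )
  st <- make_states(do.call(rbind, lapply(cases, `[[`, "bits")))
  asg <- assign_groups(st)
  expect_equal(as.character(asg$group),
               vapply(cases, `[[`, "", "label"))
})

test_that("non-canonical patterns go to the nearest rule with fixed precedence", {
  # (S5p, 8WG16 on, no S7p/S2p, both PRC marks): distance 1/7 to PRCactive
  # (flip S2p), PRCintermediate (flip S7p) and PRCrepressed (flip 8WG16)
  # patterns alike; the fixed precedence picks PRCactive
  st <- make_states(rbind(c(1, 1, 0, 0, 0, 1, 1)))
  asg <- assign_groups(st)
  expect_equal(as.character(asg$group), "PRCactive")
  expect_match(asg$rule_trace, "nearest")
  # non-PRC pattern with 8WG16 only: ties between Active (flip S2p) and
  # Inactive (flip 8WG16); precedence picks Active
  st2 <- make_states(rbind(c(1, 1, 0, 0, 0, 0, 0)))
  asg2 <- assign_groups(st2)
  expect_equal(as.character(asg2$group), "Active")
})

test_that("a two-way cut separates expressed from silent canonical patterns", {
  # canonical class patterns plus 5% bit-flip noise; the top split should
  # align with the elongating-RNAPII (S2p) axis far above chance
  ok <- 0
  for (seed in 1:50) {
    sim <- simulate_chromatin(sim_config(seed = seed, n_genes = 300,
                                         depth_per_marker = 2e4,
                                         bit_flip_prob = 0.05))
    m <- as.matrix(sim$truth[, clustering_variables()])
    st <- make_states(m, gene_id = sim$truth$gene_id)
    up <- average_linkage(gower_dissimilarity(st))
    cl <- cut_tree(up, 2)$cluster
    s2p <- m[, "S2p_TESup"]
    agree <- max(mean((cl == 1) == (s2p == 1)),
                 mean((cl == 1) == (s2p == 0)))
    if (agree >= 0.75) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.95)
})

test_that("group-mean centering subtracts per-condition group means", {
  m <- tibble::tibble(gene_id = c("a", "b", "c"),
                      c1 = c(1, 2, 6), c2 = c(10, 20, 60))
  out <- relative_to_group_mean(m, c("a", "b"))
  expect_equal(out$c1, c(1, 2, 6) - 1.5)
  expect_equal(out$c2, c(10, 20, 60) - 15)
  const <- tibble::tibble(gene_id = c("a", "b"), c1 = c(3, 3))
  expect_equal(relative_to_group_mean(const, c("a", "b"))$c1, c(0, 0))
  single <- relative_to_group_mean(m, "b")
  expect_equal(single$c1[2], 0)
  expect_error(relative_to_group_mean(m, "zz"), "empty")
})
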