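# Correlations, derepression meta-analysis, set enrichment, contingency
# tests, and the small enrichment arithmetic.

mk_groups <- function(ids, label) tibble::tibble(gene_id = ids, group = label)

test_that("Spearman correlation matches hand-ranked examples and is monotone-invariant", {
  em <- prcstates:::new_enrichment_matrix(
    tibble::tibble(gene_id = sprintf("g%d", 1:4),
                   A = c(1, 2, 3, 4), B = c(2, 1, 4, 3), C = c(1, 2, 3, 4)))
  g <- mk_groups(em$gene_id, "all")
  res <- spearman_by_group(em, list(c("A", "B"), c("A", "C")), g)
  expect_equal(res$rho[res$marker2 == "B"], 0.6)
  expect_equal(res$rho[res$marker2 == "C"], 1)
  # strictly monotone transforms leave rho unchanged
  em2 <- em
  em2$A <- exp(em2$A); em2$B <- em2$B^3
  res2 <- spearman_by_group(em2, list(c("A", "B")), g)
  expect_equal(res2$rho, 0.6)
  # zero variance -> NA with warning
  em3 <- prcstates:::new_enrichment_matrix(
    tibble::tibble(gene_id = sprintf("g%d", 1:4), A = 1:4, B = rep(2, 4)))
  expect_warning(res3 <- spearman_by_group(em3, list(c("A", "B")), g),
                 "zero variance")
  expect_true(is.na(res3$rho))
})

test_that("copula-correlated simulated signals recover their rank correlation", {
  set.seed(67)
  n <- 1500
  r <- 2 * sin(pi * 0.7 / 6)
  z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  em <- prcstates:::new_enrichment_matrix(
    tibble::tibble(gene_id = sprintf("g%d", 1:n),
                   A = qlnorm(pnorm(z1)), B = qlnorm(pnorm(z2))))
  res <- spearman_by_group(em, list(c("A", "B")), mk_groups(em$gene_id, "PRCr"))
  expect_equal(res$rho, 0.7, tolerance = 0.05 / 0.7)
})

test_that("derepression analysis reproduces the closed-form extreme Fisher table", {
  ids <- sprintf("g%d", 1:20)
  fc <- tibble::tibble(gene_id = ids, fc = c(rep(3, 10), rep(1, 10)))
  res <- derepression_analysis(fc, ids[1:10], ids[11:20], cutoff = 1.5)
  expect_equal(res$frac_up, 1)
  expect_equal(res$mean_fc, 3)
  expect_equal(res$fisher_p, 1 / choose(20, 10), tolerance = 1e-12)
  # cutoff above every fold change
  res2 <- derepression_analysis(fc, ids[1:10], ids[11:20], cutoff = 10)
  expect_equal(res2$frac_up, 0)
  expect_error(derepression_analysis(fc, character(), ids), "group")
})

test_that("one-tailed Fisher p equals the hypergeometric tail of extreme tables", {
  # oracle: sum of hypergeometric probabilities of tables at least as extreme
  set.seed(71)
  for (trial in 1:25) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    up1 <- sample(0:n1, 1); up2 <- sample(0:n2, 1)
    tab <- matrix(c(up1, n1 - up1, up2, n2 - up2), 2, 2, byrow = TRUE)
    p_pkg <- fisher.test(tab, alternative = "greater")$p.value
    K <- up1 + up2
    p_oracle <- sum(vapply(up1:min(K, n1), function(j)
      choose(n1, j) * choose(n2, K - j), numeric(1))) / choose(n1 + n2, K)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  }
})

test_that("hypergeometric enrichment matches exact enumeration and BH ties", {
  universe <- sprintf("u%02d", 1:20)
  sets <- tibble::tibble(set_id = rep(c("s1", "s1dup", "s0"), c(5, 5, 3)),
                         gene_id = c(universe[1:5], universe[1:5],
                                     universe[18:20]))
  group <- universe[1:10]
  res <- hypergeom_enrichment(sets, group, universe)
  expect_equal(res$p[res$set_id == "s1"],
               choose(15, 5) / choose(20, 10), tolerance = 1e-12)
  # overlap 0 -> p = 1
  expect_equal(res$overlap[res$set_id == "s0"], 0)
  expect_equal(res$p[res$set_id == "s0"], 1)
  # identical sets share p and FDR
  expect_equal(res$p[res$set_id == "s1"], res$p[res$set_id == "s1dup"])
  expect_equal(res$fdr[res$set_id == "s1"], res$fdr[res$set_id == "s1dup"])
  expect_error(hypergeom_enrichment(sets, group, character()), "empty")
})

test_that("hypergeometric p matches enumeration to 1e-12 on small universes", {
  set.seed(73)
  for (trial in 1:50) {
    N <- sample(5:30, 1)
    m <- sample(1:N, 1); k <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    sets <- tibble::tibble(set_id = "s", gene_id = universe[1:m])
    group <- sample(universe, k)
    ov <- length(intersect(universe[1:m], group))
    res <- hypergeom_enrichment(sets, group, universe)
    expect_equal(res$p, enum_hyper(ov, m, N, k), tolerance = 1e-12)
  }
})

test_that("BH-adjusted values are non-decreasing in raw p order", {
  set.seed(79)
  universe <- sprintf("u%03d", 1:100)
  sets <- tibble::tibble(
    set_id = rep(sprintf("s%02d", 1:20), each = 8),
    gene_id = sample(universe, 160, replace = TRUE))
  res <- hypergeom_enrichment(sets, sample(universe, 30), universe)
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("chi-squared colocalization matches the 2x2 closed form", {
  even <- matrix(c(10, 10, 10, 10), 2, 2)
  res <- chi2_colocalization(even)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  tab <- matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE)
  res2 <- chi2_colocalization(tab)
  # n(ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res2$chisq, 60 * (20 * 20 - 10 * 10)^2 / 30^4)
  expect_equal(res2$chisq, chi2_colocalization(t(tab))$chisq)
  expect_error(chi2_colocalization(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "marginal")
})

test_that("re-ChIP and qRT-PCR arithmetic follow their definitions", {
  expect_equal(rechip_enrichment(5, 5), 1)
  expect_equal(rechip_enrichment(0, 10), 0)
  expect_equal(rechip_enrichment(0.5, 10), 0.05)
  expect_error(rechip_enrichment(1, 0), "input")
  expect_equal(qpcr_relative_expression(c(10, 30), c(5, 10), t0 = 1),
               c(1, 1.5))
  expect_equal(qpcr_relative_expression(c(4, 8), c(2, 2))[2], 2)
  expect_error(qpcr_relative_expression(c(1, 2), c(0, 1)), "housekeeping")
})

test_that("detection fractions are simple overlap ratios", {
  grp <- sprintf("g%02d", 1:20)
  expect_equal(detection_fraction(grp, grp), 1)
  expect_equal(detection_fraction(grp, "zz"), 0)
  expect_equal(detection_fraction(grp, grp[1:3]), 0.15)
  expect_error(detection_fraction(character(), grp), "empty")
})

test_that("gene-length comparison reports fractions and the exact rank-sum p", {
  genes <- make_genes(c("a1", "a2", "b1", "b2"), "chr1",
                      c(0, 0, 0, 0), c(1000, 6000, 10000, 20000),
                      rep("+", 4))
  res <- length_comparison(c("a1", "a2"), c("b1", "b2"), genes,
                           cutoff_bp = 5000)
  expect_equal(res$frac_a_above, 0.5)
  expect_equal(res$frac_b_above, 1)
  # all of a below all of b: the most extreme of choose(4,2) rank splits
  expect_equal(res$wilcoxon_p, 1 / choose(4, 2), tolerance = 1e-12)
  # identical sets: no shift, p >= 0.5
  res2 <- length_comparison(c("a1", "a2"), c("a1", "a2"), genes)
  expect_gte(res2$wilcoxon_p, 0.5)
  # all lengths above cutoff
  res3 <- length_comparison(c("b1", "b2"), c("b1", "b2"), genes, 5000)
  expect_equal(res3$frac_a_above, 1)
})
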