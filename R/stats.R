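# Downstream statistics: group-wise Spearman correlations, knockout
# derepression meta-analysis, hypergeometric gene-set enrichment,
# contingency-table colocalization tests, and the small enrichment
# arithmetic used for re-ChIP, qRT-PCR and proteome-overlap summaries.

#' Spearman correlations between marker pairs, per gene group
#'
#' Computes Spearman's rank correlation (average ranks for ties) between the
#' log-enrichment columns of each marker pair, separately within each gene
#' group.  Groups with fewer than 3 genes are skipped; a zero-variance
#' variable yields `NA` with a warning.
#'
#' @param matrix An `enrichment_matrix` (typically log10 TSS-window
#'   enrichment).
#' @param pairs A list of length-2 character vectors naming column pairs.
#' @param groups A `group_assignment` tibble (`gene_id`, `group`), or any
#'   tibble with those columns.
#' @return A tibble with `marker1`, `marker2`, `group`, `rho`, `n`.
#' @export
spearman_by_group <- function(matrix, pairs, groups) {
  if (is.character(pairs)) pairs <- list(pairs)
  res <- list()
  for (g in unique(as.character(groups$group))) {
    ids <- groups$gene_id[as.character(groups$group) == g]
    sub <- matrix[matrix$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) < 3) next
    for (p in pairs) {
      x <- sub[[p[1]]]; y <- sub[[p[2]]]
      if (sd(x) == 0 || sd(y) == 0) {
        warn(sprintf("zero variance for pair (%s, %s) in group %s; rho undefined",
                     p[1], p[2], g))
        rho <- NA_real_
      } else {
        rho <- cor(x, y, method = "spearman")
      }
      res[[length(res) + 1]] <- tibble(marker1 = p[1], marker2 = p[2],
                                       group = g, rho = rho, n = nrow(sub))
    }
  }
  dplyr::bind_rows(res)
}

#' Derepression meta-analysis of knockout fold changes
#'
#' For a gene group and a comparison set, reports the fraction of group
#' genes with fold change above `cutoff`, a one-tailed Fisher's exact test
#' on the 2x2 table (group vs comparison) x (up vs not up) with alternative
#' "group enriched for up", a one-tailed Wilcoxon rank-sum test on the fold
#' changes (alternative: group greater; exact enumeration when both sets
#' have at most 25 genes and no ties, normal approximation with tie
#' correction otherwise), and the group mean fold change.
#'
#' @param fc Tibble with `gene_id` and `fc` (knockout/wild-type linear fold
#'   change).
#' @param group,comparison Character vectors of gene ids.
#' @param cutoff Derepression cutoff on the linear fold change (default
#'   1.5).
#' @return A one-row tibble with `n`, `n_comparison`, `frac_up`, `mean_fc`,
#'   `fisher_p`, `wilcoxon_p`.
#' @export
derepression_analysis <- function(fc, group, comparison, cutoff = 1.5) {
  fg <- fc$fc[fc$gene_id %in% group]
  fcmp <- fc$fc[fc$gene_id %in% comparison]
  if (length(fg) == 0) abort("group has no fold-change data")
  if (length(fcmp) == 0) abort("comparison has no fold-change data")
  up_g <- sum(fg > cutoff); up_c <- sum(fcmp > cutoff)
  tab <- matrix(c(up_g, length(fg) - up_g,
                  up_c, length(fcmp) - up_c), 2, 2, byrow = TRUE)
  fisher_p <- fisher.test(tab, alternative = "greater")$p.value
  exact <- length(fg) <= 25 && length(fcmp) <= 25
  wilcox_p <- suppressWarnings(
    wilcox.test(fg, fcmp, alternative = "greater", exact = exact,
                correct = FALSE)$p.value)
  tibble(n = length(fg), n_comparison = length(fcmp),
         frac_up = up_g / length(fg), mean_fc = mean(fg),
         fisher_p = fisher_p, wilcoxon_p = wilcox_p)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` of each set against the
#' group, both intersected with the universe, with Benjamini-Hochberg false
#' discovery rates across sets.
#'
#' @param sets Tibble with `set_id` and `gene_id` (long format).
#' @param group Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector of gene ids.
#' @return A tibble with `set_id`, `overlap`, `set_size`, `group_size`,
#'   `universe_size`, `p`, `fdr`, ordered as the sets first appear.
#' @export
hypergeom_enrichment <- function(sets, group, universe) {
  if (length(universe) == 0) abort("universe is empty")
  universe <- unique(universe)
  group <- intersect(unique(group), universe)
  if (length(setdiff(group, universe))) abort("group must be a subset of universe")
  set_ids <- unique(sets$set_id)
  res <- purrr::map_dfr(set_ids, function(s) {
    members <- intersect(unique(sets$gene_id[sets$set_id == s]), universe)
    ov <- length(intersect(members, group))
    tibble(set_id = s, overlap = ov, set_size = length(members),
           group_size = length(group), universe_size = length(universe),
           p = phyper(ov - 1, length(members),
                      length(universe) - length(members),
                      length(group), lower.tail = FALSE))
  })
  res$fdr <- p.adjust(res$p, method = "BH")
  res
}

#' Chi-squared test of colocalization contingency tables
#'
#' Pearson chi-squared without continuity correction on an r x c table of
#' (colocalized, separate) counts across strata.
#'
#' @param table Integer matrix of counts (r x c, r, c >= 2).
#' @return A one-row tibble with `chisq`, `df`, `p`.
#' @export
chi2_colocalization <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("contingency table has a zero marginal")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ht$expected <= 0)) abort("all expected counts must be > 0")
  tibble(chisq = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Re-ChIP enrichment relative to input
#'
#' @param target_quantity qPCR quantity recovered after the (sequential)
#'   immunoprecipitation.
#' @param input_quantity qPCR quantity of the original input, must be > 0.
#' @return `target_quantity / input_quantity`.
#' @export
rechip_enrichment <- function(target_quantity, input_quantity) {
  if (any(input_quantity <= 0)) abort("input_quantity must be > 0")
  target_quantity / input_quantity
}

#' qRT-PCR double normalization (housekeeping, then time zero)
#'
#' `fold(t) = (target(t) / housekeeping(t)) / (target(t0) / housekeeping(t0))`.
#'
#' @param target,housekeeping Numeric vectors of per-timepoint quantities.
#' @param t0 Index (or name) of the reference timepoint.
#' @return Numeric vector of fold changes; the reference timepoint is 1 by
#'   construction.
#' @export
qpcr_relative_expression <- function(target, housekeeping, t0 = 1) {
  if (any(housekeeping <= 0)) abort("housekeeping quantities must be > 0")
  norm <- target / housekeeping
  ref <- norm[t0]
  if (length(ref) != 1 || is.na(ref) || ref <= 0) {
    abort("reference timepoint quantity must be > 0")
  }
  norm / ref
}

#' Fraction of a gene group detected in an external set
#'
#' @param group Non-empty character vector of gene ids.
#' @param detected Character vector of detected gene ids (e.g. proteome
#'   hits).
#' @return `|group intersect detected| / |group|`.
#' @export
detection_fraction <- function(group, detected) {
  if (length(group) == 0) abort("group is empty")
  length(intersect(unique(group), unique(detected))) / length(unique(group))
}

#' Compare gene lengths between two sets
#'
#' Reports the fraction of each set longer than `cutoff_bp` and a one-tailed
#' Wilcoxon rank-sum p-value for the alternative that set `a` genes are
#' shorter than set `b` genes.
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @param genes A `gene_models` tibble with lengths for all ids.
#' @param cutoff_bp Length cutoff in bp (default 5000).
#' @return A one-row tibble with `frac_a_above`, `frac_b_above`, `n_a`,
#'   `n_b`, `wilcoxon_p`.
#' @export
length_comparison <- function(a, b, genes, cutoff_bp = 5000) {
  if (length(a) == 0 || length(b) == 0) abort("gene sets must be non-empty")
  la <- genes$length[match(a, genes$gene_id)]
  lb <- genes$length[match(b, genes$gene_id)]
  if (anyNA(la) || anyNA(lb)) abort("gene set contains ids absent from annotation")
  exact <- length(la) <= 25 && length(lb) <= 25
  p <- suppressWarnings(
    wilcox.test(la, lb, alternative = "less", exact = exact,
                correct = FALSE)$p.value)
  tibble(frac_a_above = mean(la > cutoff_bp),
         frac_b_above = mean(lb > cutoff_bp),
         n_a = length(la), n_b = length(lb), wilcoxon_p = p)
}
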