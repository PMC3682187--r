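# Gower dissimilarity over the seven binary occupancy variables, UPGMA
# (average-linkage) agglomeration with deterministic tie-breaking, tree
# cutting, and the rule table mapping binary patterns to the six
# chromatin-state groups.

states_matrix <- function(states, vars = NULL) {
  vars <- vars %||% attr(states, "clustering_vars") %||%
    intersect(CLUSTERING_VARIABLES, names(states))
  missing_vars <- setdiff(CLUSTERING_VARIABLES, vars)
  if (length(missing_vars)) {
    abort(paste0("states lacks clustering variable(s): ",
                 paste(missing_vars, collapse = ", ")))
  }
  m <- as.matrix(as_tibble(states)[, CLUSTERING_VARIABLES])
  if (!all(m %in% c(0, 1))) abort("state values must be 0 or 1")
  storage.mode(m) <- "double"
  rownames(m) <- states$gene_id
  m
}

#' Gower dissimilarity of binary state vectors
#'
#' All seven variables are treated as symmetric binary (absence is
#' informative), so the Gower coefficient reduces to the proportion of
#' mismatching variables.  Dissimilarities are computed over the unique
#' state patterns and expanded, and rounded at 12 decimals so equal rational
#' values compare exactly.
#'
#' @param states A `binary_states` tibble containing the seven clustering
#'   variables.
#' @param collapse `"genes"` (one row/column per gene) or `"patterns"` (one
#'   per distinct pattern, with a `counts` attribute giving multiplicities).
#' @return A symmetric matrix of class `gower_dissim` with zero diagonal and
#'   values in \[0, 1\].
#' @export
gower_dissimilarity <- function(states, collapse = c("genes", "patterns")) {
  collapse <- match.arg(collapse)
  m <- states_matrix(states)
  pat_key <- apply(m, 1, paste0, collapse = "")
  u <- !duplicated(pat_key)
  pm <- m[u, , drop = FALSE]
  ukey <- pat_key[u]
  # mismatches(x, y) = x(1-y)' + (1-x)y'
  k <- ncol(pm)
  mm <- pm %*% (1 - t(pm)) + (1 - pm) %*% t(pm)
  d_pat <- round(mm / k, 12)
  if (collapse == "patterns") {
    dimnames(d_pat) <- list(ukey, ukey)
    return(structure(d_pat, counts = as.vector(table(pat_key)[ukey]),
                     patterns = pm, class = c("gower_dissim", "matrix", "array")))
  }
  idx <- match(pat_key, ukey)
  d <- d_pat[idx, idx, drop = FALSE]
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(d, class = c("gower_dissim", "matrix", "array"))
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Repeatedly merges the pair of clusters with the smallest mean
#' inter-cluster dissimilarity (Lance-Williams average update).  Ties are
#' broken deterministically by the lexicographically smallest pair of
#' cluster indices (leaves are 1..n in input order; the cluster formed at
#' merge m gets index n + m).
#'
#' @param D A symmetric dissimilarity matrix (e.g. from
#'   [gower_dissimilarity()]), n >= 2.
#' @return An object of class `upgma`: list with `merge` (hclust
#'   convention), `height`, `labels`, `order`.
#' @export
average_linkage <- function(D) {
  D <- unclass(D)
  n <- nrow(D)
  if (n < 2) abort("need at least two items to cluster")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)) || any(diag(D) != 0)) {
    abort("D must be symmetric with zero diagonal")
  }
  labels <- rownames(D) %||% as.character(seq_len(n))
  work <- D
  active <- seq_len(n)            # cluster indices of the active rows
  sizes <- rep(1L, n)
  code <- -seq_len(n)             # hclust codes for active rows
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    na <- length(active)
    dm <- work
    dm[!upper.tri(dm)] <- Inf
    best <- min(dm)
    # tolerance so mathematically equal averages tie despite float noise
    cand <- which(dm <= best + 1e-12, arr.ind = TRUE)
    # lexicographically smallest (cluster index i, cluster index j)
    pair_ids <- cbind(pmin(active[cand[, 1]], active[cand[, 2]]),
                      pmax(active[cand[, 1]], active[cand[, 2]]))
    pick <- order(pair_ids[, 1], pair_ids[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    height[m] <- work[i, j]
    merge[m, ] <- sort(c(code[i], code[j]))
    # Lance-Williams average-linkage update into row/col i
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- (ni * work[i, ] + nj * work[j, ]) / (ni + nj)
    work[i, ] <- new_d
    work[, i] <- new_d
    work[i, i] <- 0
    keep <- setdiff(seq_len(na), j)
    work <- work[keep, keep, drop = FALSE]
    sizes[i] <- ni + nj
    sizes <- sizes[keep]
    active[i] <- n + m
    active <- active[keep]
    code[i] <- m
    code <- code[keep]
  }
  order <- upgma_leaf_order(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = order, n = n),
            class = "upgma")
}

upgma_leaf_order <- function(merge, n) {
  if (n == 1) return(1L)
  out <- integer(0)
  stack <- nrow(merge)  # start at the root merge
  # iterative pre-order traversal: negative entries are leaves
  expand <- function(node) {
    res <- integer(0)
    st <- node
    while (length(st)) {
      x <- st[1]; st <- st[-1]
      if (x < 0) res <- c(res, -x)
      else st <- c(merge[x, 1], merge[x, 2], st)
    }
    res
  }
  expand(nrow(merge))
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf("<upgma> %d leaves, %d merges, height range [%.4g, %.4g]\n",
              x$n, nrow(x$merge), min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.upgma <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "gower"),
            class = "hclust")
}

#' Cut a UPGMA tree into exactly k clusters
#'
#' Cutting is by merge count (the last `k - 1` merges are undone), which
#' resolves height ties by the later-merge-first rule; cluster labels are
#' numbered 1..k by order of first appearance along the dendrogram leaf
#' order.
#'
#' @param dendrogram An `upgma` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A tibble with `id` (leaf label) and `cluster` (integer).
#' @export
cut_tree <- function(dendrogram, k) {
  n <- dendrogram$n
  if (k < 1 || k > n) {
    abort(sprintf("k must be between 1 and %d (nearest reachable: %d)",
                  n, max(1, min(n, k))))
  }
  cl <- cutree(as.hclust(dendrogram), k = k)
  # renumber by leaf order
  first_seen <- unique(cl[dendrogram$order])
  relab <- match(cl, first_seen)
  tibble(id = dendrogram$labels, cluster = relab)
}

#' Export a UPGMA tree as Newick
#'
#' @param dendrogram An `upgma` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Rule table: canonical marker combinations of the six groups.
# Variable order: S5p_TSS, 8WG16_TSS, S7p_TSS, S5p_TESdown, S2p_TESup,
# H3K27me3_TSS, H2Aub1_TSS.  NA = unconstrained.

group_rules <- function() {
  list(
    PRCactive = function(p) (p[6] == 1 | p[7] == 1) & p[5] == 1,
    PRCintermediate = function(p) p[6] == 1 & p[7] == 1 & p[1] == 1 &
      p[2] == 1 & p[3] == 1 & p[5] == 0,
    PRCrepressed = function(p) p[6] == 1 & p[7] == 1 & p[1] == 1 &
      p[2] == 0 & p[3] == 0 & p[5] == 0,
    PRConly = function(p) p[6] == 1 & p[7] == 0 & p[1] == 0 & p[2] == 0 &
      p[3] == 0 & p[4] == 0 & p[5] == 0,
    Active = function(p) p[6] == 0 & p[7] == 0 & p[5] == 1,
    Inactive = function(p) p[6] == 0 & p[7] == 0 & p[5] == 0 & p[3] == 0 &
      p[2] == 0
  )
}

all_patterns <- function() {
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
  colnames(g) <- CLUSTERING_VARIABLES
  g
}

# label every one of the 2^7 patterns: canonical rule match, or nearest
# canonical pattern by Gower distance with fixed label-precedence tie-break
pattern_label_table <- function() {
  pats <- all_patterns()
  rules <- group_rules()
  canon <- vapply(seq_len(nrow(pats)), function(i) {
    hits <- names(rules)[vapply(rules, function(r) r(pats[i, ]), logical(1))]
    if (length(hits) == 0) NA_character_ else hits[1]
  }, character(1))
  # canonical rules are mutually exclusive; hits[1] is just unwrapping
  label <- canon
  trace <- ifelse(is.na(canon), NA_character_, "canonical")
  canon_idx <- which(!is.na(canon))
  for (i in which(is.na(canon))) {
    d <- rowSums(abs(pats[canon_idx, , drop = FALSE] -
                     matrix(pats[i, ], length(canon_idx), 7, byrow = TRUE))) / 7
    dmin <- min(d)
    close_labels <- unique(canon[canon_idx[d <= dmin + 1e-12]])
    pick <- GROUP_LEVELS[min(match(close_labels, GROUP_LEVELS))]
    label[i] <- pick
    trace[i] <- sprintf("nearest(d=%s)", format(round(dmin, 6)))
  }
  tibble(pattern = apply(pats, 1, paste0, collapse = ""),
         label = label, rule_trace = trace)
}

#' Assign genes to the six chromatin-state groups
#'
#' Canonical marker combinations are mapped directly: `PRCactive` = S2p with
#' either PRC mark; `PRCintermediate` = both PRC marks with S5p, 8WG16 and
#' S7p but no S2p; `PRCrepressed` = both PRC marks with S5p only;
#' `PRConly` = H3K27me3 without H2Aub1 or any RNAPII variable; `Active` =
#' S2p without PRC marks; `Inactive` = no PRC marks, no S2p, no S7p, no
#' 8WG16.  A gene matching no canonical combination is assigned to the
#' nearest canonical pattern by Gower distance, ties broken by the fixed
#' precedence PRCactive > PRCintermediate > PRCrepressed > PRConly >
#' Active > Inactive.
#'
#' @param states A `binary_states` tibble with the seven clustering
#'   variables.
#' @return A tibble of class `group_assignment` with `gene_id`, `group`
#'   (factor with the six levels) and `rule_trace`.
#' @export
assign_groups <- function(states) {
  m <- states_matrix(states)
  key <- apply(m, 1, paste0, collapse = "")
  tab <- pattern_label_table()
  idx <- match(key, tab$pattern)
  structure(
    tibble(gene_id = states$gene_id,
           group = factor(tab$label[idx], levels = GROUP_LEVELS),
           rule_trace = tab$rule_trace[idx]),
    class = c("group_assignment", class(tibble())))
}

#' Center an expression matrix on per-condition group means
#'
#' Subtracts, from every value, the mean of that condition (column) over the
#' given gene group; log-scale input is assumed.
#'
#' @param expr_matrix Tibble with `gene_id` plus numeric condition columns.
#' @param group Character vector of gene ids defining the reference group
#'   (must be non-empty and present in `expr_matrix`).
#' @return A tibble of the same shape, centered.
#' @export
relative_to_group_mean <- function(expr_matrix, group) {
  rows <- expr_matrix$gene_id %in% group
  if (!any(rows)) abort("group is empty or absent from expr_matrix")
  out <- expr_matrix
  for (v in setdiff(names(out), "gene_id")) {
    out[[v]] <- out[[v]] - mean(out[[v]][rows])
  }
  out
}
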