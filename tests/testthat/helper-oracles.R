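# Fixture builders and independent brute-force oracles used across tests.

make_genes <- function(gene_id, chrom, start, end, strand) {
  prcstates:::new_gene_models(tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand))
}

make_tags <- function(pos, chrom = "chr1", marker = "X") {
  prcstates:::new_tag_set(
    tibble::tibble(chrom = rep(chrom, length.out = length(pos)), pos = pos),
    marker)
}

# binary state tibble from a matrix of 0/1 rows over the 7 clustering vars
make_states <- function(m, gene_id = sprintf("g%03d", seq_len(nrow(m)))) {
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- clustering_variables()
  df <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), df)
  prcstates:::new_binary_states(df, clustering_vars = clustering_variables())
}

all_patterns_m <- function() {
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
  colnames(g) <- clustering_variables()
  g
}

# O(n^2) pairwise overlap filter
naive_nonoverlapping <- function(genes) {
  n <- nrow(genes)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && genes$chrom[i] == genes$chrom[j] &&
        genes$start[i] < genes$end[j] && genes$start[j] < genes$end[i]) {
      keep[i] <- FALSE
    }
  }
  genes[keep, ]
}

# linear-scan window count
naive_count <- function(pos, a, b) sum(pos >= a & pos < b)

# mismatch-proportion dissimilarity of two 0/1 vectors
naive_gower <- function(x, y) mean(x != y)

# O(n^3) UPGMA: recompute every inter-cluster mean from the original matrix
# at each step; same lexicographic tie rule on cluster creation indices
naive_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)  # member indices
  ids <- seq_len(n)                         # creation indices
  merges <- list()
  heights <- numeric(0)
  next_id <- n
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- Inf; best_pair <- NULL; best_ids <- c(Inf, Inf)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      pid <- sort(c(ids[i], ids[j]))
      better <- d < best - 1e-14 ||
        (abs(d - best) <= 1e-14 &&
           (pid[1] < best_ids[1] ||
              (pid[1] == best_ids[1] && pid[2] < best_ids[2])))
      if (better) { best <- d; best_pair <- c(i, j); best_ids <- pid }
    }
    i <- best_pair[1]; j <- best_pair[2]
    heights <- c(heights, best)
    merges[[length(merges) + 1]] <- sort(c(ids[i], ids[j]))
    next_id <- next_id + 1
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- next_id
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(heights = heights, merges = merges)
}

# convert a package upgma object to the oracle's (creation-index) merge list
upgma_merge_ids <- function(up) {
  n <- up$n
  lapply(seq_len(nrow(up$merge)), function(m) {
    sort(ifelse(up$merge[m, ] < 0, -up$merge[m, ], n + up$merge[m, ]))
  })
}

# exact upper-tail hypergeometric by enumeration
enum_hyper <- function(ov, m, N, k) {
  j <- ov:min(m, k)
  sum(choose(m, j) * choose(N - m, k - j)) / choose(N, k)
}
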