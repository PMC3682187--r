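# Strand-aware metagene (average signal) profiles anchored at the TSS or TES.

#' Metagene profile of tag density around an anchor
#'
#' For each gene, tags are mapped to gene-oriented offsets relative to the
#' anchor base (TSS base: `start` on `+`, `end - 1` on `-`; TES base is the
#' other boundary), minus-strand genes being reflected so 5'->3' runs
#' left-to-right.  Per-gene, per-bin density is
#' `count / (bin * total_tags / 1e6)` (tags per million per bp); the profile
#' is the unweighted mean over genes.
#'
#' @param tags A `tag_set` tibble.
#' @param genes A non-empty `gene_models` tibble (the gene set to average).
#' @param anchor `"TSS"` or `"TES"`.
#' @param span Length-2 numeric, signed bp offsets covered (default
#'   `c(-2500, 2500)`).
#' @param bin Bin width in bp (default 50).
#' @return A tibble of class `metagene_profile` with `offset_start`,
#'   `offset_mid`, `mean_signal`, `n_genes`; attributes `anchor`, `bin`,
#'   `span`, `marker`.
#' @export
metagene <- function(tags, genes, anchor = c("TSS", "TES"),
                     span = c(-2500, 2500), bin = 50) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) abort("metagene requires a non-empty gene set")
  edges <- seq(span[1], span[2], by = bin)
  if (length(edges) < 2) abort("span must cover at least one bin")
  n_bins <- length(edges) - 1
  total <- attr(tags, "total_tags") %||% nrow(tags)
  if (total == 0) abort("tag set is empty")

  plus <- genes$strand == "+"
  boundary <- if (anchor == "TSS") ifelse(plus, genes$start, genes$end)
              else ifelse(plus, genes$end, genes$start)
  # anchor base: the boundary coordinate itself on +, boundary - 1 on -
  by_chrom <- split(tags$pos, tags$chrom)
  acc <- numeric(n_bins)
  for (g in seq_len(nrow(genes))) {
    pos <- by_chrom[[genes$chrom[g]]]
    if (is.null(pos)) next
    if (plus[g]) {
      lo <- boundary[g] + edges[1]; hi <- boundary[g] + edges[n_bins + 1]
      i1 <- findInterval(lo - 0.5, pos); i2 <- findInterval(hi - 0.5, pos)
      if (i2 > i1) {
        off <- pos[(i1 + 1):i2] - boundary[g]
        acc <- acc + tabulate(floor((off - edges[1]) / bin) + 1, nbins = n_bins)
      }
    } else {
      # offset o of position p is (boundary - 1) - p; o in [e1, eK) means
      # p in (boundary - 1 - eK, boundary - 1 - e1]
      hi <- boundary[g] - 1 - edges[1]; lo <- boundary[g] - 1 - edges[n_bins + 1]
      i1 <- findInterval(lo + 0.5, pos); i2 <- findInterval(hi + 0.5, pos)
      if (i2 > i1) {
        off <- (boundary[g] - 1) - pos[(i1 + 1):i2]
        acc <- acc + tabulate(floor((off - edges[1]) / bin) + 1, nbins = n_bins)
      }
    }
  }
  mean_signal <- acc / nrow(genes) / (bin * total / 1e6)
  structure(
    tibble(offset_start = edges[-length(edges)],
           offset_mid = edges[-length(edges)] + bin / 2,
           mean_signal = mean_signal,
           n_genes = nrow(genes)),
    anchor = anchor, bin = bin, span = span,
    marker = attr(tags, "marker"),
    total_tags = total,
    class = c("metagene_profile", class(tibble())))
}

#' Write a metagene profile as TSV
#'
#' @param profile A `metagene_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
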