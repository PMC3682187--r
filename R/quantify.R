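# Windowed tag counting, depth normalization, log/pseudocount conventions
# and gene-level FPKM.

#' The seven standard marker windows
#'
#' TSS windows are +/- 1 kb around the start site for S5p, 8WG16, S7p,
#' H3K27me3 and H2Aub1; the two TES windows are S5p in `[TES, TES + 2 kb)`
#' (downstream) and S2p in `[TES - 2 kb, TES)` (upstream), gene-oriented.
#'
#' @return A tibble with columns `variable`, `marker`, `anchor`,
#'   `rel_start`, `rel_end`.
#' @export
standard_window_spec <- function() {
  tibble(
    variable  = CLUSTERING_VARIABLES,
    marker    = c("S5p", "8WG16", "S7p", "S5p", "S2p", "H3K27me3", "H2Aub1"),
    anchor    = c("TSS", "TSS", "TSS", "TES", "TES", "TSS", "TSS"),
    rel_start = c(-1000, -1000, -1000, 0, -2000, -1000, -1000),
    rel_end   = c(1000, 1000, 1000, 2000, 0, 1000, 1000)
  )
}

#' Count tags falling in windows
#'
#' Counts tag 5'-end positions `p` with `start <= p < end` for each window,
#' by binary search on the sorted per-chromosome positions.  Windows on
#' chromosomes absent from the tag set count 0.
#'
#' @param tags A `tag_set` tibble.
#' @param windows A window tibble as returned by [anchor_windows()] (needs
#'   `chrom`, `start`, `end`).
#' @return `windows` with an added integer `count` column.
#' @export
count_in_window <- function(tags, windows) {
  count <- integer(nrow(windows))
  by_chrom <- split(tags$pos, tags$chrom)
  missing_chroms <- setdiff(unique(windows$chrom), names(by_chrom))
  if (length(missing_chroms)) {
    message("no tags on chromosome(s): ", paste(missing_chroms, collapse = ", "))
  }
  for (ch in intersect(unique(windows$chrom), names(by_chrom))) {
    pos <- by_chrom[[ch]]  # sorted ascending
    i <- which(windows$chrom == ch)
    # count of pos in [a, b) = #(pos <= b - 1) - #(pos <= a - 1), positions
    # are integers so findInterval on b - 0.5 / a - 0.5 is exact
    count[i] <- findInterval(windows$end[i] - 0.5, pos) -
      findInterval(windows$start[i] - 0.5, pos)
  }
  windows$count <- count
  windows
}

new_enrichment_matrix <- function(df, transform = "raw", pseudocount = NULL,
                                  window_spec = NULL) {
  structure(as_tibble(df), transform = transform, pseudocount = pseudocount,
            window_spec = window_spec,
            class = c("enrichment_matrix", class(as_tibble(df))))
}

#' Genes-by-(marker, window) enrichment matrix
#'
#' For every `(marker, window)` pair in `window_spec`, counts tags in the
#' strand-aware anchor window of each gene and normalizes to tags per million
#' mapped tags of that marker's library.
#'
#' @param tag_sets Named list of `tag_set` tibbles, one per marker.
#' @param genes A `gene_models` tibble.
#' @param window_spec Tibble with `variable`, `marker`, `anchor`,
#'   `rel_start`, `rel_end`; defaults to [standard_window_spec()].
#' @return A tibble of class `enrichment_matrix`: `gene_id` plus one column
#'   per `variable`, with attribute `transform = "raw"`.
#' @export
enrichment_matrix <- function(tag_sets, genes, window_spec = standard_window_spec()) {
  missing_markers <- setdiff(unique(window_spec$marker), names(tag_sets))
  if (length(missing_markers)) {
    abort(paste0("no tag set for marker(s): ", paste(missing_markers, collapse = ", ")))
  }
  out <- tibble(gene_id = genes$gene_id)
  for (i in seq_len(nrow(window_spec))) {
    sp <- window_spec[i, ]
    tags <- tag_sets[[sp$marker]]
    total <- attr(tags, "total_tags") %||% nrow(tags)
    if (total == 0) abort(sprintf("marker '%s' has zero total tags", sp$marker))
    w <- anchor_windows(genes, sp$anchor, sp$rel_start, sp$rel_end)
    w <- count_in_window(tags, w)
    out[[sp$variable]] <- w$count * 1e6 / total
  }
  new_enrichment_matrix(out, transform = "raw", window_spec = window_spec)
}

#' Log10-transform enrichment or expression values
#'
#' Applies `log10(x + pseudocount)` to every value column and records the
#' transform state; transforming twice is an error.  The conventional
#' pseudocount is 1 for ChIP enrichment and 0.0001 for FPKM.
#'
#' @param x An `enrichment_matrix` or `expression_table`.
#' @param pseudocount Added before taking log10.
#' @return Same type as `x`, with `transform = "log10"` and the pseudocount
#'   recorded.
#' @export
log_transform <- function(x, pseudocount) UseMethod("log_transform")

#' @rdname log_transform
#' @export
log_transform.enrichment_matrix <- function(x, pseudocount = 1) {
  if (identical(attr(x, "transform"), "log10")) {
    abort("enrichment matrix is already log10-transformed")
  }
  vars <- setdiff(names(x), "gene_id")
  for (v in vars) x[[v]] <- log10(x[[v]] + pseudocount)
  new_enrichment_matrix(x, transform = "log10", pseudocount = pseudocount,
                        window_spec = attr(x, "window_spec"))
}

#' @rdname log_transform
#' @export
log_transform.expression_table <- function(x, pseudocount = 1e-4) {
  if (identical(attr(x, "transform"), "log10")) {
    abort("expression table is already log10-transformed")
  }
  x$fpkm <- log10(x$fpkm + pseudocount)
  new_expression_table(x, transform = "log10", pseudocount = pseudocount)
}

new_expression_table <- function(df, transform = "raw", pseudocount = NULL) {
  structure(as_tibble(df), transform = transform, pseudocount = pseudocount,
            class = c("expression_table", class(as_tibble(df))))
}

#' Gene-level FPKM from fragment counts
#'
#' `FPKM = count * 1e9 / (gene length in bp * total fragments)`.  Gene length
#' is `end - start` (the synthetic genome is intronless; this diverges from
#' exon-model FPKM).
#'
#' @param gene_counts Tibble with `gene_id` and `count`.
#' @param genes A `gene_models` tibble covering every counted gene.
#' @param total_fragments Library size; defaults to `sum(count)`.
#' @return A tibble of class `expression_table` with `gene_id`, `fpkm`.
#' @export
fpkm <- function(gene_counts, genes, total_fragments = sum(gene_counts$count)) {
  if (total_fragments <= 0) abort("total_fragments must be > 0")
  missing_ids <- setdiff(gene_counts$gene_id, genes$gene_id)
  if (length(missing_ids)) {
    abort(paste0("gene(s) missing from annotation: ",
                 paste(missing_ids, collapse = ", ")))
  }
  len <- genes$length[match(gene_counts$gene_id, genes$gene_id)]
  new_expression_table(
    tibble(gene_id = gene_counts$gene_id,
           fpkm = gene_counts$count * 1e9 / (len * total_fragments))
  )
}

#' Write an enrichment matrix or expression table as TSV
#'
#' The header comment line carries the transform state and pseudocount so a
#' re-reader can recover them.
#'
#' @param x An `enrichment_matrix` or `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  hdr <- sprintf("# transform=%s pseudocount=%s",
                 attr(x, "transform") %||% "raw",
                 format(attr(x, "pseudocount") %||% NA))
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
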