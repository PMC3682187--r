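# Readers and writers for gene models and aligned-tag files, plus the
# strand-aware anchor-window arithmetic every downstream stage relies on.
# All coordinates are 0-based half-open internally; BED is native, GTF is
# converted on read.

new_gene_models <- function(df, genome_id = "unknown") {
  df <- as_tibble(df)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  df$length <- df$end - df$start
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("duplicated gene_id(s): ",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")))
  }
  if (any(df$start < 0) || any(df$start >= df$end)) {
    abort("gene models must satisfy 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  structure(df[, c("gene_id", "chrom", "start", "end", "strand", "length")],
            genome_id = genome_id,
            class = c("gene_models", class(df)))
}

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read gene models from BED or GTF
#'
#' Parses a BED (>= 6 columns, 0-based half-open, strand in column 6) or GTF
#' (1-based inclusive, converted on read) file into a gene-model table.  GTF
#' `gene` records are used when present, otherwise `transcript` records.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @param genome_id Identifier stored on the returned annotation.
#' @return A tibble of class `gene_models` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length`; rows keep input order.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf"),
                             genome_id = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(new_gene_models(tibble(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()),
                           genome_id = genome_id))
  }
  fields <- split_fields(lines[idx])
  if (format == "bed") {
    bad <- which(vapply(fields, length, 1L) < 6L)
    if (length(bad)) abort(sprintf("malformed BED line %d in '%s': fewer than 6 fields",
                                   idx[bad[1]], path))
    df <- tibble(
      chrom  = vapply(fields, `[`, "", 1L),
      start  = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))),
      end    = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
      gene_id = vapply(fields, `[`, "", 4L),
      strand = vapply(fields, `[`, "", 6L)
    )
    bad <- which(is.na(df$start) | is.na(df$end))
    if (length(bad)) abort(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                                   idx[bad[1]], path))
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad)) abort(sprintf("unknown strand symbol '%s' on line %d of '%s'",
                                   df$strand[bad[1]], idx[bad[1]], path))
  } else {
    nf <- vapply(fields, length, 1L)
    bad <- which(nf < 9L)
    if (length(bad)) abort(sprintf("malformed GTF line %d in '%s': fewer than 9 fields",
                                   idx[bad[1]], path))
    feature <- vapply(fields, `[`, "", 3L)
    use <- if (any(feature == "gene")) feature == "gene"
           else if (any(feature == "transcript")) feature == "transcript"
           else rep(TRUE, length(feature))
    fields <- fields[use]
    idx <- idx[use]
    attr_str <- vapply(fields, function(f) paste(f[9:length(f)], collapse = " "), "")
    gid <- sub('.*gene_id[ ]+"?([^";]+)"?;?.*', "\\1", attr_str)
    bad <- which(gid == attr_str)
    if (length(bad)) abort(sprintf("GTF line %d in '%s' lacks a gene_id attribute",
                                   idx[bad[1]], path))
    start1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
    end1   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
    bad <- which(is.na(start1) | is.na(end1))
    if (length(bad)) abort(sprintf("malformed GTF line %d in '%s': non-numeric coordinates",
                                   idx[bad[1]], path))
    strand <- vapply(fields, `[`, "", 7L)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) abort(sprintf("unknown strand symbol '%s' on line %d of '%s'",
                                   strand[bad[1]], idx[bad[1]], path))
    df <- tibble(
      chrom = vapply(fields, `[`, "", 1L),
      start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
      end = end1,
      gene_id = gid,
      strand = strand
    )
  }
  new_gene_models(df, genome_id = genome_id)
}

#' Write gene models as BED6
#'
#' @param genes A `gene_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  bed <- genes[, c("chrom", "start", "end", "gene_id")]
  bed$score <- 0L
  bed$strand <- genes$strand
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Restrict an annotation to mutually non-overlapping genes
#'
#' Keeps only genes whose `[start, end)` interval overlaps no other gene on
#' the same chromosome (strand-agnostic); both members of an overlapping pair
#' are removed.  Input order is preserved.  Idempotent.
#'
#' @param genes A `gene_models` tibble.
#' @return A filtered `gene_models` tibble.
#' @export
filter_nonoverlapping <- function(genes) {
  if (nrow(genes) <= 1) return(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  n_hits <- GenomicRanges::countOverlaps(gr, gr, type = "any")
  out <- genes[n_hits == 1L, , drop = FALSE]
  structure(out, genome_id = attr(genes, "genome_id"),
            class = class(genes))
}

#' Strand-aware anchor windows at the TSS or TES
#'
#' Relative offsets are in the gene's 5'->3' direction: on a minus-strand
#' gene, a positive (downstream) offset moves toward lower genomic
#' coordinates.  The TSS boundary is `start` for `+` genes and `end` for `-`
#' genes; the TES boundary is the other.  Output intervals are half-open; a
#' window extending below coordinate 0 is clipped and flagged.
#'
#' @param genes A `gene_models` tibble (or any tibble with `gene_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param anchor `"TSS"` or `"TES"`.
#' @param rel_start,rel_end Signed offsets in bp, `rel_start < rel_end`.
#' @return A tibble with `gene_id`, `anchor`, `rel_start`, `rel_end`,
#'   `chrom`, `start`, `end`, `clipped`.
#' @export
anchor_windows <- function(genes, anchor = c("TSS", "TES"),
                           rel_start, rel_end) {
  anchor <- match.arg(anchor)
  if (!(rel_start < rel_end)) abort("rel_start must be < rel_end")
  plus <- genes$strand == "+"
  boundary <- if (anchor == "TSS") {
    ifelse(plus, genes$start, genes$end)
  } else {
    ifelse(plus, genes$end, genes$start)
  }
  abs_start <- ifelse(plus, boundary + rel_start, boundary - rel_end)
  abs_end <- ifelse(plus, boundary + rel_end, boundary - rel_start)
  clipped <- abs_start < 0
  abs_start <- pmax(abs_start, 0)
  abs_end <- pmax(abs_end, 0)
  tibble(
    gene_id = genes$gene_id, anchor = anchor,
    rel_start = rel_start, rel_end = rel_end,
    chrom = genes$chrom, start = as.numeric(abs_start),
    end = as.numeric(abs_end), clipped = clipped
  )
}

new_tag_set <- function(df, marker) {
  df <- as_tibble(df)[, c("chrom", "pos")]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  structure(df, marker = marker, total_tags = nrow(df),
            class = c("tag_set", class(df)))
}

#' Read aligned-read tag positions from BED
#'
#' Each read is reduced to its 5'-end coordinate: `start` for `+` reads,
#' `end - 1` for `-` reads; reads without a strand column are treated as
#' `+`.  No deduplication is performed.
#'
#' @param path BED file with at least 3 columns.
#' @param marker Marker (antibody) name stored on the result.
#' @param dedup If `TRUE`, collapse duplicate positions.
#' @return A tibble of class `tag_set` with columns `chrom`, `pos`, sorted
#'   per chromosome; attributes `marker` and `total_tags`.
#' @export
read_tags <- function(path, marker, dedup = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(new_tag_set(tibble(chrom = character(), pos = numeric()), marker))
  }
  fields <- split_fields(lines[idx])
  nf <- vapply(fields, length, 1L)
  bad <- which(nf < 3L)
  if (length(bad)) abort(sprintf("malformed BED line %d in '%s': fewer than 3 fields",
                                 idx[bad[1]], path))
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                                 idx[bad[1]], path))
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else "+", "")
  strand[!strand %in% c("+", "-")] <- "+"
  df <- tibble(
    chrom = vapply(fields, `[`, "", 1L),
    pos = ifelse(strand == "+", start, end - 1)
  )
  if (dedup) df <- dplyr::distinct(df)
  new_tag_set(df, marker)
}

#' Write a tag set as BED (1-bp intervals on the + strand)
#'
#' @param tags A `tag_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  marker <- attr(tags, "marker") %||% "tag"
  n <- nrow(tags)
  bed <- tibble(chrom = tags$chrom, start = tags$pos, end = tags$pos + 1,
                name = if (n) paste0(marker, "_", seq_len(n)) else character(),
                score = rep(0L, n), strand = rep("+", n))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
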