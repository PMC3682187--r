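# Fully synthetic genome, ChIP-seq tag sets, expression and knockout
# fold-changes with known per-gene class labels.  The generator is the
# ground-truth source for every pipeline test: marker occupancy follows the
# canonical rule table of the six groups, signal is Poisson peak + Poisson
# background, and S5p/H2Aub1 peak amplitudes within PRC classes share a
# Gaussian copula so their rank correlation is controlled.

default_class_bits <- function() {
  # occupancy probability per (class, variable); values strictly between 0
  # and 1 are Bernoulli (the S5p TES extension of PRCrepressed genes)
  m <- rbind(
    Active          = c(1, 1, 1, 1, 1, 0, 0),
    Inactive        = c(0, 0, 0, 0, 0, 0, 0),
    PRConly         = c(0, 0, 0, 0, 0, 1, 0),
    PRCrepressed    = c(1, 0, 0, NA, 0, 1, 1),  # NA -> s5p_end_prob
    PRCintermediate = c(1, 1, 1, 0, 0, 1, 1),
    PRCactive       = c(1, 1, 1, 1, 1, 1, 1)
  )
  colnames(m) <- CLUSTERING_VARIABLES
  m
}

default_expression_levels <- function() {
  tibble(
    class = c("Active", "PRCactive", "PRCintermediate", "PRCrepressed",
              "PRConly", "Inactive"),
    meanlog = log(c(50, 25, 1, 0.1, 0.05, 0.02)),
    sdlog = c(1, 1, 0.8, 1, 1, 1)
  )
}

default_ko_effect <- function() {
  # log2 fold-change distributions after simulated Ring1B loss; PRC-bound
  # expressed/poised classes shift up, non-targets are centred at zero
  tibble(
    class = c("Active", "Inactive", "PRConly", "PRCrepressed",
              "PRCintermediate", "PRCactive"),
    mean_log2 = c(0, 0, 0.1, 0.2, 0.1, 0.3),
    sd_log2 = c(0.4, 0.4, 0.5, 0.8, 0.5, 0.7)
  )
}

default_class_proportions <- function() {
  # paper-scale cluster sizes over the 15,404-gene universe; the non-PRC
  # remainder is split evenly between Active and Inactive
  prc <- c(PRConly = 798, PRCrepressed = 1632, PRCintermediate = 742,
           PRCactive = 1227)
  rest <- (15404 - sum(prc)) / 2
  p <- c(Active = rest, Inactive = rest, prc) / 15404
  p[c("Active", "Inactive", "PRConly", "PRCrepressed", "PRCintermediate",
      "PRCactive")]
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: class
#' proportions at the paper-scale cluster sizes, lognormal gene lengths
#' (meanlog 8.5, sdlog 1 in log-bp), 1e6 tags per marker, 12-fold peak
#' amplitude over background with per-gene lognormal dispersion (sdlog 0.4),
#' 1 kb TSS peaks and 2 kb TES windows, a 0.4 probability that a
#' PRCrepressed gene extends S5p to its TES, and a Gaussian-copula rank
#' correlation of 0.7 between S5p and H2Aub1 amplitudes within PRC classes.
#'
#' @param seed Integer seed (mandatory; the only source of randomness).
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric over the six groups, summing to 1.
#' @param gene_length_meanlog,gene_length_sdlog Lognormal length parameters
#'   (log-bp).
#' @param min_gene_length Minimum gene length in bp.
#' @param depth_per_marker Expected tags per marker library.
#' @param background_rate Background tag rate (tags/bp).  `NULL` (default)
#'   derives it from `depth_per_marker` so marker totals concentrate at the
#'   requested depth; an explicit value (including 0) overrides the
#'   background only, leaving peak intensities depth-derived.
#' @param class_bits Occupancy-probability matrix (classes x 7 variables);
#'   `NA` entries take `s5p_end_prob`.
#' @param amplitude Peak amplitude, fold over background.
#' @param amp_sdlog Per-gene lognormal dispersion of peak amplitudes.
#' @param tss_peak_width,tes_peak_width Peak widths in bp (positions are
#'   Normal(anchor, width/2) truncated to the call window).
#' @param s5p_end_prob TES-extension probability for S5p in PRCrepressed.
#' @param expression_levels Per-class lognormal FPKM parameters.
#' @param ko_effect Per-class log2 fold-change parameters for simulated
#'   Ring1B loss.
#' @param s5p_end_ko_bonus Extra mean log2 fold change for S5pEnd-positive
#'   PRCrepressed genes.
#' @param rank_correlation Target Spearman correlation between S5p and
#'   H2Aub1 peak amplitudes within PRC classes.
#' @param bit_flip_prob Probability of flipping each true occupancy bit
#'   (noise knob; default 0).
#' @param min_gap Minimum intergenic gap in bp.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 2000,
                       class_proportions = default_class_proportions(),
                       gene_length_meanlog = 8.5,
                       gene_length_sdlog = 1,
                       min_gene_length = 200,
                       depth_per_marker = 1e6,
                       background_rate = NULL,
                       class_bits = default_class_bits(),
                       amplitude = 12,
                       amp_sdlog = 0.4,
                       tss_peak_width = 1000,
                       tes_peak_width = 2000,
                       s5p_end_prob = 0.4,
                       expression_levels = default_expression_levels(),
                       ko_effect = default_ko_effect(),
                       s5p_end_ko_bonus = 0.4,
                       rank_correlation = 0.7,
                       bit_flip_prob = 0,
                       min_gap = 10000) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class_proportions must sum to 1 (tolerance 1e-9)")
  }
  if (is.null(names(class_proportions)) ||
      !setequal(names(class_proportions), rownames(class_bits))) {
    abort("class_proportions must be named with the six class labels")
  }
  structure(list(
    seed = as.integer(seed), n_genes = n_genes,
    class_proportions = class_proportions,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    min_gene_length = min_gene_length,
    depth_per_marker = depth_per_marker,
    background_rate = background_rate,
    class_bits = class_bits,
    amplitude = amplitude, amp_sdlog = amp_sdlog,
    tss_peak_width = tss_peak_width, tes_peak_width = tes_peak_width,
    s5p_end_prob = s5p_end_prob,
    expression_levels = expression_levels,
    ko_effect = ko_effect, s5p_end_ko_bonus = s5p_end_ko_bonus,
    rank_correlation = rank_correlation,
    bit_flip_prob = bit_flip_prob,
    min_gap = min_gap
  ), class = "sim_config")
}

largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(raw - base))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

rtruncnorm_int <- function(n, mean, sd, a, b) {
  # integer positions in [a, b), Normal(mean, sd) truncated to the window
  lo <- pnorm(a, mean, sd); hi <- pnorm(b, mean, sd)
  u <- runif(n, lo, hi)
  x <- floor(qnorm(u, mean, sd))
  pmin(pmax(x, a), b - 1)
}

#' Simulate a synthetic genome with chromatin states and expression
#'
#' Places non-overlapping genes on one synthetic chromosome (gaps of at
#' least `min_gap`), draws true occupancy bits per class, per-marker
#' Poisson background plus truncated-normal peak tags for occupied windows,
#' per-class lognormal expression, and per-class knockout fold changes.  All
#' randomness derives from `config$seed`; identical configurations are
#' bit-reproducible.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `chrom_sim` with elements `genes`
#'   (`gene_models`), `tags` (named list of `tag_set`), `expression`
#'   (`expression_table`), `fold_changes` (tibble `gene_id`, `fc`), `truth`
#'   (tibble with `gene_id`, `class`, the seven true bits, `s5p_end`,
#'   `fpkm`, `fc`) and `config`.
#' @export
simulate_chromatin <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  classes <- names(config$class_proportions)
  counts <- largest_remainder(config$class_proportions, n)
  class_vec <- sample(rep(classes, counts))

  # gene placement ------------------------------------------------------
  len <- pmax(round(rlnorm(n, config$gene_length_meanlog,
                           config$gene_length_sdlog)),
              config$min_gene_length)
  gap <- config$min_gap + round(rexp(n, 1 / 2000))
  start <- cumsum(c(gap[1], len[-n] + gap[-1]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- new_gene_models(
    tibble(gene_id = sprintf("g%05d", seq_len(n)), chrom = "chrS",
           start = start, end = start + len, strand = strand),
    genome_id = "synthetic")
  region_length <- genes$end[n] + config$min_gap

  # true occupancy bits --------------------------------------------------
  bits_prob <- config$class_bits[class_vec, , drop = FALSE]
  bits_prob[is.na(bits_prob)] <- config$s5p_end_prob
  bits <- matrix(rbinom(length(bits_prob), 1, as.vector(bits_prob)),
                 nrow = n, dimnames = list(genes$gene_id, CLUSTERING_VARIABLES))
  if (config$bit_flip_prob > 0) {
    flips <- matrix(rbinom(length(bits), 1, config$bit_flip_prob), nrow = n)
    bits <- abs(bits - flips)
  }

  # peak amplitudes with the S5p/H2Aub1 copula ---------------------------
  zmat <- matrix(rnorm(n * 7), nrow = n,
                 dimnames = list(NULL, CLUSTERING_VARIABLES))
  prc_classes <- class_vec %in% c("PRCrepressed", "PRCintermediate", "PRCactive")
  r <- 2 * sin(pi * config$rank_correlation / 6)  # copula parameter for
  # the target Spearman correlation of a bivariate Gaussian copula
  z2 <- rnorm(n)
  zmat[prc_classes, "H2Aub1_TSS"] <-
    r * zmat[prc_classes, "S5p_TSS"] +
    sqrt(1 - r^2) * z2[prc_classes]
  amp <- config$amplitude * exp(config$amp_sdlog * zmat)

  # tag sets --------------------------------------------------------------
  spec <- standard_window_spec()
  spec$width <- ifelse(spec$anchor == "TSS", config$tss_peak_width,
                       config$tes_peak_width)
  windows <- lapply(seq_len(nrow(spec)), function(i) {
    anchor_windows(genes, spec$anchor[i], spec$rel_start[i], spec$rel_end[i])
  })
  names(windows) <- spec$variable
  plus <- genes$strand == "+"
  tss_boundary <- ifelse(plus, genes$start, genes$end)
  tes_boundary <- ifelse(plus, genes$end, genes$start)

  tags <- list()
  for (mk in unique(spec$marker)) {
    rows <- which(spec$marker == mk)
    # depth-derived reference rate: expected total = depth_per_marker
    sum_aw <- 0
    for (i in rows) {
      v <- spec$variable[i]
      occ <- bits[, v] == 1
      sum_aw <- sum_aw + sum(amp[occ, v]) * spec$width[i]
    }
    lambda_ref <- config$depth_per_marker / (region_length + sum_aw)
    lambda_bg <- config$background_rate %||% lambda_ref
    chunks <- list()
    n_bg <- rpois(1, lambda_bg * region_length)
    if (n_bg > 0) chunks[[1]] <- floor(runif(n_bg, 0, region_length))
    for (i in rows) {
      v <- spec$variable[i]
      w <- windows[[v]]
      anchor_base <- if (spec$anchor[i] == "TSS") tss_boundary else tes_boundary
      occ <- which(bits[, v] == 1)
      if (length(occ) == 0) next
      lam <- amp[occ, v] * lambda_ref * spec$width[i]
      n_pk <- rpois(length(occ), lam)
      # vectorized truncated-normal draw: one entry per tag, grouped by gene
      g <- rep(occ, n_pk)
      if (length(g)) {
        chunks[[length(chunks) + 1]] <- rtruncnorm_int(
          length(g), anchor_base[g], spec$width[i] / 2,
          w$start[g], w$end[g])
      }
    }
    pos <- if (length(chunks)) unlist(chunks, use.names = FALSE) else numeric(0)
    tags[[mk]] <- new_tag_set(tibble(chrom = rep("chrS", length(pos)),
                                     pos = pos), mk)
  }

  # expression ------------------------------------------------------------
  el <- config$expression_levels
  ei <- match(class_vec, el$class)
  fpkm_true <- rlnorm(n, el$meanlog[ei], el$sdlog[ei])
  expression <- new_expression_table(tibble(gene_id = genes$gene_id,
                                            fpkm = fpkm_true))

  # knockout fold changes -------------------------------------------------
  ke <- config$ko_effect
  ki <- match(class_vec, ke$class)
  mu_lfc <- ke$mean_log2[ki] +
    ifelse(class_vec == "PRCrepressed" & bits[, "S5p_TESdown"] == 1,
           config$s5p_end_ko_bonus, 0)
  lfc <- rnorm(n, mu_lfc, ke$sd_log2[ki])
  fold_changes <- tibble(gene_id = genes$gene_id, fc = 2^lfc)

  truth <- dplyr::bind_cols(
    tibble(gene_id = genes$gene_id, class = class_vec),
    as_tibble(as.data.frame(bits)),
    tibble(s5p_end = bits[, "S5p_TESdown"], fpkm = fpkm_true, fc = 2^lfc)
  )
  structure(list(genes = genes, tags = tags, expression = expression,
                 fold_changes = fold_changes, truth = truth,
                 config = config),
            class = "chrom_sim")
}

#' @export
print.chrom_sim <- function(x, ...) {
  cat(sprintf("<chrom_sim> %d genes, %d markers, seed %d\n",
              nrow(x$genes), length(x$tags), x$config$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulation to standard files
#'
#' Writes the annotation (BED6), one tag BED per marker, and TSVs for
#' expression, fold changes and the per-gene truth, so the pipeline can
#' consume synthetic data through the same readers as real data.
#'
#' @param sim A `chrom_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genes = file.path(dir, "genes.bed"))
  write_gene_models(sim$genes, paths$genes)
  for (mk in names(sim$tags)) {
    p <- file.path(dir, paste0("tags_", mk, ".bed"))
    write_tags(sim$tags[[mk]], p)
    paths[[paste0("tags_", mk)]] <- p
  }
  paths$expression <- file.path(dir, "expression.tsv")
  readr::write_tsv(as_tibble(sim$expression), paths$expression)
  paths$fold_changes <- file.path(dir, "fold_changes.tsv")
  readr::write_tsv(sim$fold_changes, paths$fold_changes)
  paths$truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, paths$truth)
  invisible(paths)
}
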