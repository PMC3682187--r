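# Stage orchestration: simulate -> quantify -> profile -> classify ->
# cluster -> stats, with TSV outputs, a hash manifest, and quarantine of
# partial outputs from failed stages.

STAGE_ORDER <- c("simulate", "quantify", "profile", "classify", "cluster", "stats")
STAGE_DEPS <- list(
  simulate = character(),
  quantify = "simulate",
  profile = "quantify",
  classify = "quantify",
  cluster = "classify",
  stats = "cluster"
)

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error (named with their key path); missing keys fall
#' back to [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("invalid config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Pipeline configuration
#'
#' @param seed Integer seed for the simulation stage.
#' @param n_genes Number of simulated genes.
#' @param depth_per_marker Tags per marker library.
#' @param pseudocount Pseudocount for the ChIP log transform.
#' @param threshold_method `"mixture"` or `"quantile"`.
#' @param quantile_q Quantile for the fallback/quantile threshold.
#' @param profile_span,profile_bin Metagene span (bp, half-width) and bin
#'   width.
#' @param expression_fraction Fraction for the top/bottom expression sets.
#' @param derepression_cutoff Fold-change cutoff for derepression.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_genes = 2000, depth_per_marker = 1e6,
                            pseudocount = 1,
                            threshold_method = "mixture", quantile_q = 0.75,
                            profile_span = 2500, profile_bin = 50,
                            expression_fraction = 0.2,
                            derepression_cutoff = 1.5) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' TSV outputs under `outdir` plus a `manifest.tsv` (file, md5, bytes) and a
#' verbatim `params.yaml` echo of the configuration.  Rerunning with an
#' identical configuration reproduces byte-identical outputs.  If a stage
#' fails, its partial outputs are moved to `outdir/failed/` and the error is
#' rethrown.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param outdir Output directory.
#' @param stages Subset of
#'   `c("simulate","quantify","profile","classify","cluster","stats")`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = STAGE_ORDER) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, STAGE_ORDER, several.ok = TRUE)
  for (s in stages) {
    need <- setdiff(STAGE_DEPS[[s]], stages)
    if (length(need)) {
      abort(sprintf("stage '%s' requires outputs of stage '%s'; add it to `stages`",
                    s, need[1]))
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(outdir, "params.yaml"))
  state <- new.env(parent = emptyenv())
  written <- character()
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    written <<- c(written, p)
    p
  }
  run_stage <- function(s) {
    stage_files_before <- written
    tryCatch(
      switch(s,
        simulate = {
          state$sim <- simulate_chromatin(
            sim_config(seed = config$seed, n_genes = config$n_genes,
                       depth_per_marker = config$depth_per_marker))
          paths <- write_simulation(state$sim, file.path(outdir, "simulate"))
          written <<- c(written, unlist(paths))
        },
        quantify = {
          sim <- state$sim
          state$em <- enrichment_matrix(sim$tags, sim$genes)
          state$lem <- log_transform(state$em, pseudocount = config$pseudocount)
          emit("enrichment_raw.tsv", function(p) write_enrichment(state$em, p))
          emit("enrichment_log10.tsv", function(p) write_enrichment(state$lem, p))
          state$expr <- sim$expression
          emit("expression.tsv", function(p)
            readr::write_tsv(as_tibble(state$expr), p))
        },
        profile = {
          sim <- state$sim
          quint <- expression_quantile_sets(state$expr,
                                            fraction = config$expression_fraction)
          span <- c(-config$profile_span, config$profile_span)
          for (coh in c("top", "bottom")) {
            ids <- quint$gene_id[quint$cohort == coh]
            sub <- sim$genes[sim$genes$gene_id %in% ids, ]
            for (mk in c("S5p", "S2p")) {
              pr <- metagene(sim$tags[[mk]], sub, anchor = "TSS",
                             span = span, bin = config$profile_bin)
              emit(sprintf("profile_%s_%s_TSS.tsv", mk, coh),
                   function(p) write_profile(pr, p))
            }
          }
        },
        classify = {
          state$thresholds <- fit_thresholds(state$lem,
                                             method = config$threshold_method,
                                             quantile_q = config$quantile_q)
          state$states <- call_states(state$lem, state$thresholds)
          emit("thresholds.tsv", function(p) write_states(state$thresholds, p))
          emit("binary_states.tsv", function(p) write_states(state$states, p))
          emit("prc_cohorts.tsv", function(p)
            write_states(prc_cohorts(state$states), p))
        },
        cluster = {
          d <- gower_dissimilarity(state$states, collapse = "patterns")
          state$dendrogram <- average_linkage(d)
          state$groups <- assign_groups(state$states)
          emit("dendrogram.nwk", function(p) write_newick(state$dendrogram, p))
          emit("group_assignments.tsv", function(p)
            readr::write_tsv(as_tibble(state$groups), p))
          emit("group_counts.tsv", function(p)
            readr::write_tsv(dplyr::count(as_tibble(state$groups),
                                          .data$group, name = "n_genes"), p))
        },
        stats = {
          sim <- state$sim
          cors <- spearman_by_group(
            state$lem, list(c("S5p_TSS", "H2Aub1_TSS"),
                            c("S5p_TSS", "H3K27me3_TSS")), state$groups)
          emit("spearman_by_group.tsv", function(p) readr::write_tsv(cors, p))
          grp <- function(g) state$groups$gene_id[state$groups$group == g]
          dere <- purrr::map_dfr(
            c("PRCrepressed", "PRCactive"),
            function(g) dplyr::mutate(
              derepression_analysis(sim$fold_changes, grp(g), grp("Inactive"),
                                    cutoff = config$derepression_cutoff),
              group = g, .before = 1))
          emit("derepression.tsv", function(p) readr::write_tsv(dere, p))
        }
      ),
      error = function(e) {
        new_files <- setdiff(written, stage_files_before)
        if (length(new_files)) {
          qdir <- file.path(outdir, "failed")
          dir.create(qdir, showWarnings = FALSE)
          file.rename(new_files, file.path(qdir, basename(new_files)))
          written <<- stage_files_before
        }
        abort(sprintf("stage '%s' failed: %s", s, conditionMessage(e)),
              parent = e)
      })
  }
  for (s in intersect(STAGE_ORDER, stages)) run_stage(s)
  files <- sort(c(written, file.path(outdir, "params.yaml")))
  manifest <- tibble(file = sub(paste0("^", outdir, "/?"), "", files),
                     md5 = unname(tools::md5sum(files)),
                     bytes = file.size(files))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(list(state = as.list(state), manifest = manifest))
}
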