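# Positive/negative occupancy calling per (marker, window) and the cohort
# constructions built on the binary calls.  The decision boundary is a
# two-component Gaussian mixture fitted to log10 enrichment: the background
# (unbound) and signal (bound) populations are each modelled as a normal on
# the log scale, and the threshold is where the posterior probability of the
# signal component crosses one half.

#' Fit a positive/negative threshold to one enrichment column
#'
#' `method = "mixture"` fits a two-component Gaussian mixture to the supplied
#' (already log10-transformed) values by EM, with deterministic
#' quartile-based initialization (component means start at the first and
#' third quartiles, equal weights, common spread), convergence tolerance
#' 1e-6 on the log-likelihood, at most 500 iterations.  The threshold `tau`
#' is the point between the component means where the posterior
#' responsibility of the high component crosses 0.5.  If the components
#' collapse (`|mu1 - mu2| < 0.05`) the fit falls back to the quantile
#' method with a warning.
#'
#' `method = "quantile"` sets `tau` to the `quantile_q` quantile of the
#' values (type-7 estimator: linear interpolation between order statistics,
#' so the 0.5 quantile of an even sample is the midpoint of the two central
#' values).
#'
#' @param values Numeric vector of log-scale enrichment values.
#' @param method `"mixture"` or `"quantile"`.
#' @param quantile_q Quantile used by the fallback/quantile method.
#' @return An object of class `marker_threshold`: a list with `tau`,
#'   `method` (the method actually used), `mu`, `sigma`, `lambda` (component
#'   weights), `iterations`, `converged`, `n`.
#' @export
fit_threshold <- function(values, method = c("mixture", "quantile"),
                          quantile_q = 0.75) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  n <- length(values)
  quantile_fit <- function(note = NULL) {
    structure(list(tau = unname(quantile(values, quantile_q, type = 7)),
                   method = "quantile", quantile_q = quantile_q,
                   mu = NULL, sigma = NULL, lambda = NULL,
                   iterations = 0L, converged = TRUE, n = n, note = note,
                   values = values),
              class = "marker_threshold")
  }
  if (method == "quantile") return(quantile_fit())
  if (n < 50) abort("mixture method requires at least 50 values")

  q <- quantile(values, c(0.25, 0.75), type = 7)
  mu <- as.numeric(q)
  s0 <- max(sd(values) / 2, 1e-3)
  sigma <- c(s0, s0)
  lambda <- c(0.5, 0.5)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(500L)) {
    d1 <- lambda[1] * dnorm(values, mu[1], sigma[1])
    d2 <- lambda[2] * dnorm(values, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    new_loglik <- sum(log(tot))
    if (is.finite(loglik) && abs(new_loglik - loglik) < 1e-6) {
      converged <- TRUE
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
    w1 <- sum(r1); w2 <- sum(r2)
    if (w1 < 1e-8 || w2 < 1e-8) break
    mu <- c(sum(r1 * values) / w1, sum(r2 * values) / w2)
    sigma <- c(sqrt(sum(r1 * (values - mu[1])^2) / w1),
               sqrt(sum(r2 * (values - mu[2])^2) / w2))
    sigma <- pmax(sigma, 1e-4)
    lambda <- c(w1, w2) / n
  }
  # order components so component 2 is the high (signal) one
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sigma <- rev(sigma); lambda <- rev(lambda)
  }
  if (abs(mu[2] - mu[1]) < 0.05) {
    warn("mixture components collapsed; falling back to quantile threshold")
    return(quantile_fit(note = "mixture collapse"))
  }
  post_high <- function(x) {
    d1 <- lambda[1] * dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * dnorm(x, mu[2], sigma[2])
    d2 / (d1 + d2)
  }
  grid <- seq(mu[1], mu[2], length.out = 2048L)
  p <- post_high(grid)
  cross <- which(p[-length(p)] < 0.5 & p[-1] >= 0.5)
  if (length(cross) == 0) {
    warn("no posterior-0.5 crossing between component means; falling back to quantile threshold")
    return(quantile_fit(note = "no posterior crossing"))
  }
  i <- cross[1]
  tau <- tryCatch(
    stats::uniroot(function(x) post_high(x) - 0.5, c(grid[i], grid[i + 1]),
                   tol = 1e-10)$root,
    error = function(e) (grid[i] + grid[i + 1]) / 2
  )
  structure(list(tau = tau, method = "mixture", quantile_q = quantile_q,
                 mu = mu, sigma = sigma, lambda = lambda,
                 iterations = iter, converged = converged,
                 loglik = loglik, n = n, note = NULL, values = values),
            class = "marker_threshold")
}

#' @export
print.marker_threshold <- function(x, ...) {
  cat(sprintf("<marker_threshold> method=%s tau=%.4f n=%d\n",
              x$method, x$tau, x$n))
  if (x$method == "mixture") {
    cat(sprintf("  components: N(%.3f, %.3f) w=%.2f | N(%.3f, %.3f) w=%.2f (%d EM iterations)\n",
                x$mu[1], x$sigma[1], x$lambda[1],
                x$mu[2], x$sigma[2], x$lambda[2], x$iterations))
  }
  invisible(x)
}

#' Fit thresholds for every value column of an enrichment matrix
#'
#' @param matrix A log10-transformed `enrichment_matrix`.
#' @param method,quantile_q Passed to [fit_threshold()].
#' @return A named list of `marker_threshold` objects (class
#'   `marker_thresholds`), one per value column.
#' @export
fit_thresholds <- function(matrix, method = c("mixture", "quantile"),
                           quantile_q = 0.75) {
  method <- match.arg(method)
  vars <- setdiff(names(matrix), "gene_id")
  fits <- lapply(vars, function(v) fit_threshold(matrix[[v]], method, quantile_q))
  names(fits) <- vars
  structure(fits, class = "marker_thresholds")
}

#' @export
print.marker_thresholds <- function(x, ...) {
  for (v in names(x)) {
    cat(sprintf("%-14s tau=%8.4f  method=%s\n", v, x[[v]]$tau, x[[v]]$method))
  }
  invisible(x)
}

new_binary_states <- function(df, clustering_vars) {
  structure(as_tibble(df), clustering_vars = clustering_vars,
            class = c("binary_states", class(as_tibble(df))))
}

#' Call binary occupancy states
#'
#' A gene is called positive (1) for a variable iff its log enrichment is
#' strictly greater than that variable's threshold; values equal to the
#' threshold are called negative (conservative tie rule).
#'
#' @param matrix A log10-transformed `enrichment_matrix`.
#' @param thresholds A `marker_thresholds` list (or named numeric vector of
#'   `tau` values) covering every value column of `matrix`.
#' @return A tibble of class `binary_states`: `gene_id` plus one 0/1 column
#'   per variable; attribute `clustering_vars` lists the columns among the
#'   canonical seven.
#' @export
call_states <- function(matrix, thresholds) {
  if (!identical(attr(matrix, "transform"), "log10")) {
    abort("call_states expects a log10-transformed enrichment matrix")
  }
  vars <- setdiff(names(matrix), "gene_id")
  taus <- if (is.numeric(thresholds)) thresholds
          else vapply(thresholds, function(f) f$tau, numeric(1))
  missing_vars <- setdiff(vars, names(taus))
  if (length(missing_vars)) {
    abort(paste0("no threshold for column(s): ", paste(missing_vars, collapse = ", ")))
  }
  out <- tibble(gene_id = matrix$gene_id)
  for (v in vars) out[[v]] <- as.integer(matrix[[v]] > taus[[v]])
  new_binary_states(out, clustering_vars = intersect(CLUSTERING_VARIABLES, vars))
}

new_cohort_partition <- function(df, name) {
  structure(as_tibble(df), partition_name = name,
            class = c("cohort_partition", class(as_tibble(df))))
}

#' Polycomb-positive cohorts from the two PRC marks
#'
#' Splits genes carrying H3K27me3 and/or H2Aub1 at the TSS into three
#' disjoint cohorts: `both`, `K27only` and `H2Aub1only`; their union is the
#' PRC-positive cohort.  Genes carrying neither mark are not in any set.
#'
#' @param states A `binary_states` tibble with `H3K27me3_TSS` and
#'   `H2Aub1_TSS` columns.
#' @return A tibble of class `cohort_partition` with `gene_id`, `cohort`.
#' @export
prc_cohorts <- function(states) {
  for (v in c("H3K27me3_TSS", "H2Aub1_TSS")) {
    if (!v %in% names(states)) abort(paste0("states lacks column ", v))
  }
  k27 <- states$H3K27me3_TSS == 1
  h2a <- states$H2Aub1_TSS == 1
  cohort <- dplyr::case_when(
    k27 & h2a ~ "both",
    k27 & !h2a ~ "K27only",
    !k27 & h2a ~ "H2Aub1only",
    TRUE ~ NA_character_
  )
  keep <- !is.na(cohort)
  new_cohort_partition(tibble(gene_id = states$gene_id[keep],
                              cohort = cohort[keep]),
                       name = "prc")
}

#' Top and bottom expression-quantile gene sets
#'
#' The `top` set is the `floor(fraction * N)` genes with the highest
#' expression, the `bottom` set the same number with the lowest; ties are
#' broken by stable input order.
#'
#' @param expr An `expression_table`.
#' @param fraction Fraction of the universe per set, in (0, 0.5).
#' @return A tibble of class `cohort_partition` with `gene_id`, `cohort`
#'   (`"top"` / `"bottom"`).
#' @export
expression_quantile_sets <- function(expr, fraction = 0.2) {
  if (!(fraction > 0 && fraction < 0.5)) abort("fraction must be in (0, 0.5)")
  n <- nrow(expr)
  k <- floor(fraction * n)
  ord_desc <- order(-expr$fpkm)  # radix sort: stable in input order
  ord_asc <- order(expr$fpkm)
  top <- expr$gene_id[ord_desc[seq_len(k)]]
  bottom <- expr$gene_id[ord_asc[seq_len(k)]]
  new_cohort_partition(
    tibble(gene_id = c(top, bottom),
           cohort = rep(c("top", "bottom"), each = k)),
    name = "expression_quantiles")
}

#' Partition a gene set by S5p occupancy downstream of the TES
#'
#' @param states A `binary_states` tibble with an `S5p_TESdown` column.
#' @param scope Character vector of gene ids to partition; defaults to all
#'   genes in `states`.
#' @return A tibble of class `cohort_partition` with `gene_id`, `cohort`
#'   (`"S5pEnd_pos"` / `"S5pEnd_neg"`).
#' @export
s5p_end_partition <- function(states, scope = states$gene_id) {
  if (!"S5p_TESdown" %in% names(states)) abort("states lacks column S5p_TESdown")
  extra <- setdiff(scope, states$gene_id)
  if (length(extra)) abort("scope contains genes absent from states")
  sub <- states[match(scope, states$gene_id), , drop = FALSE]
  new_cohort_partition(
    tibble(gene_id = sub$gene_id,
           cohort = ifelse(sub$S5p_TESdown == 1, "S5pEnd_pos", "S5pEnd_neg")),
    name = "s5p_end")
}

#' Write binary states, cohorts or thresholds as TSV
#'
#' @param x A `binary_states`, `cohort_partition` or `marker_thresholds`
#'   object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(x, path) {
  if (inherits(x, "marker_thresholds")) {
    readr::write_tsv(tidy(x), path)
  } else {
    readr::write_tsv(as_tibble(x), path)
  }
  invisible(path)
}
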