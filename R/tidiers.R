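# broom-style tidiers for fitted objects.

#' @export
tidy.marker_threshold <- function(x, ...) {
  if (identical(x$method, "mixture")) {
    tibble(component = c("background", "signal"),
           mean = x$mu, sd = x$sigma, weight = x$lambda)
  } else {
    tibble(component = "quantile", mean = NA_real_, sd = NA_real_,
           weight = NA_real_)
  }
}

#' @export
glance.marker_threshold <- function(x, ...) {
  tibble(tau = x$tau, method = x$method,
         mu_background = if (is.null(x$mu)) NA_real_ else x$mu[1],
         mu_signal = if (is.null(x$mu)) NA_real_ else x$mu[2],
         iterations = x$iterations, converged = x$converged, n = x$n,
         note = x$note %||% NA_character_)
}

#' @export
tidy.marker_thresholds <- function(x, ...) {
  purrr::map_dfr(names(x), function(v)
    dplyr::mutate(glance(x[[v]]), variable = v, .before = 1))
}

#' @export
tidy.group_assignment <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.group_assignment <- function(x, ...) {
  counts <- table(x$group)
  out <- tibble(n_genes = nrow(x))
  for (g in names(counts)) out[[paste0("n_", g)]] <- as.integer(counts[[g]])
  out
}

#' @export
tidy.upgma <- function(x, ...) {
  tibble(merge = seq_along(x$height),
         left = x$merge[, 1], right = x$merge[, 2], height = x$height)
}

#' @export
glance.upgma <- function(x, ...) {
  tibble(n_leaves = x$n, n_merges = length(x$height),
         max_height = max(x$height))
}
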