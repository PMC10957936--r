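# broom-style tidiers for the package's result objects.

#' Tidy an mpdag into its edge table
#'
#' @param x An [mpdag()].
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `mark` and, when tiers are known,
#'   `from_tier`, `to_tier`.
#' @export
tidy.mpdag <- function(x, ...) {
  e <- mpdag_edges(x)
  if (!is.null(x$tiers) && nrow(e)) {
    e$from_tier <- unname(x$tiers[e$from])
    e$to_tier <- unname(x$tiers[e$to])
  }
  e
}

#' @rdname tidy.mpdag
#' @export
glance.mpdag <- function(x, ...) {
  dplyr::bind_cols(tibble(n_nodes = length(x$nodes)), graph_summary(x))
}

#' Tidy a tiered-PC fit
#'
#' `tidy()` returns the learned graph's edge table; `glance()` a one-row
#' summary including the number of CI tests performed.
#'
#' @param x A `tpc_result` from [run_tpc()].
#' @param ... Unused.
#' @export
tidy.tpc_result <- function(x, ...) tidy(x$graph)

#' @rdname tidy.tpc_result
#' @export
glance.tpc_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(alpha = x$alpha, test = x$test, n_tests = x$n_tests),
    glance(x$graph)
  )
}

#' Tidy a bootstrap graph ensemble into edge stability frequencies
#'
#' @param x A `graph_ensemble` from [run_bootstrap()].
#' @param ... Unused.
#' @export
tidy.graph_ensemble <- function(x, ...) {
  edge_frequencies(x) |> dplyr::filter(.data$freq > 0)
}

#' @rdname tidy.graph_ensemble
#' @export
glance.graph_ensemble <- function(x, ...) {
  sizes <- vapply(x$graphs, function(g) nrow(mpdag_edges(g)), numeric(1))
  tibble(B = length(x$graphs), n_nodes = length(x$graphs[[1]]$nodes),
         mean_edges = mean(sizes), min_edges = min(sizes),
         max_edges = max(sizes))
}

#' Tidy a structural causal model into its edge list
#'
#' @param x A `cohort_scm`.
#' @param ... Unused.
#' @export
tidy.cohort_scm <- function(x, ...) as_tibble(x$dag$edges)

#' @rdname tidy.cohort_scm
#' @export
glance.cohort_scm <- function(x, ...) {
  tibble(n_nodes = length(x$dag$nodes), n_edges = nrow(x$dag$edges),
         n_tiers = length(x$schema$tiers))
}
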