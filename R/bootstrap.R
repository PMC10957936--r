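# Bootstrap stability of the learned graph: resample rows, singly impute,
# re-run discovery, summarise edge and path stability across the ensemble.

#' Bootstrap graph ensemble
#'
#' For each replicate `b = 1..B`: draw `n` rows with replacement, complete
#' them by a single imputation (only when the table has missing cells),
#' and run the tiered PC algorithm with the same settings as the main
#' analysis. Replicate seeds are derived deterministically from the master
#' seed, so the ensemble is fully reproducible.
#'
#' Bootstrap graphs measure the *stability* of structures, not edge
#' probabilities: resampling with replacement induces spurious dependences
#' that tend to add edges.
#'
#' @param data Cohort tibble (with or without missing cells).
#' @param schema Its [tier_schema()].
#' @param B Number of bootstrap replicates.
#' @param alpha Nominal CI-test level.
#' @param test `"cg_lrt"` or `"fisher_z"`.
#' @param model Imputation model for [impute_single()].
#' @param imp_iterations Chained-equation sweeps per imputation.
#' @param max_cond Optional conditioning-set cap passed to [run_tpc()].
#' @param seed Master seed.
#' @return A `graph_ensemble`: list with `graphs` (B [mpdag()]s),
#'   `provenance` tibble (replicate, resample seed, imputation seed),
#'   `schema`, `settings`.
#' @export
run_bootstrap <- function(data, schema, B = 100, alpha = 0.05,
                          test = c("cg_lrt", "fisher_z"),
                          model = c("tree", "parametric"),
                          imp_iterations = 10, max_cond = Inf, seed = 1) {
  test <- match.arg(test); model <- match.arg(model)
  stopifnot(B >= 1)
  data <- validate_cohort(data, schema)
  n <- nrow(data)
  has_na <- anyNA(data)
  graphs <- vector("list", B)
  prov <- vector("list", B)
  for (b in seq_len(B)) {
    rs_seed <- sub_seed(seed, 2L * b - 1L)
    imp_seed <- sub_seed(seed, 2L * b)
    res <- tryCatch({
      idx <- with_seed(rs_seed, sample.int(n, n, replace = TRUE))
      boot <- data[idx, ]
      if (has_na) {
        boot <- impute_single(boot, schema, model = model,
                              iterations = imp_iterations, seed = imp_seed)
      }
      run_tpc(boot, schema, alpha = alpha, test = test, max_cond = max_cond,
              keep_log = FALSE)
    }, error = function(e) {
      abort(sprintf("bootstrap replicate %d failed: %s", b, conditionMessage(e)))
    })
    graphs[[b]] <- res$graph
    prov[[b]] <- tibble(replicate = b, resample_seed = rs_seed,
                        imputation_seed = if (has_na) imp_seed else NA_integer_)
  }
  structure(
    list(graphs = graphs, provenance = dplyr::bind_rows(prov), schema = schema,
         settings = list(B = B, alpha = alpha, test = test, model = model,
                         seed = seed)),
    class = "graph_ensemble"
  )
}

#' @export
print.graph_ensemble <- function(x, ...) {
  cat(sprintf("<graph_ensemble> %d graphs on %d nodes\n",
              length(x$graphs), length(x$graphs[[1]]$nodes)))
  invisible(x)
}

#' Path stability of exposures toward an outcome across an ensemble
#'
#' Per exposure: the fraction of member graphs containing at least one
#' `mode`-path to the outcome, the most frequent exact path (lexicographic
#' tie-break, reported with its count), the median per-member path count,
#' the fraction of members containing a potentially causal direct edge
#' exposure-outcome (directed toward the outcome or undirected), and the
#' top intermediate nodes by fraction of all paths pooled over members.
#'
#' @param ens A `graph_ensemble`.
#' @param exposures Character vector of exposure node names.
#' @param outcome Outcome node name.
#' @param mode `"partially_directed"` (default) or `"directed"`.
#' @param max_paths Per-member enumeration cap.
#' @return List with `by_exposure` (tibble) and `top_nodes` (named list of
#'   tibbles of pooled intermediate-node fractions per exposure).
#' @export
path_stability <- function(ens, exposures, outcome,
                           mode = c("partially_directed", "directed"),
                           max_paths = 1e5) {
  mode <- match.arg(mode)
  graphs <- ensemble_graphs(ens)
  nodes <- graphs[[1]]$nodes
  if (!all(c(exposures, outcome) %in% nodes)) abort("unknown node name(s)")
  B <- length(graphs)
  rows <- list(); tops <- list()
  for (ex in exposures) {
    per <- lapply(graphs, function(g) {
      enumerate_paths(g, ex, outcome, mode = mode, max_paths = max_paths)
    })
    counts <- vapply(per, function(ps) length(ps$paths), numeric(1))
    any_frac <- mean(counts > 0)
    direct <- vapply(graphs, function(g) {
      g$amat[ex, outcome] == 1L  # directed toward outcome, or undirected
    }, logical(1))
    all_paths <- unlist(lapply(per, function(ps) {
      vapply(ps$paths, paste, character(1), collapse = " > ")
    }))
    if (length(all_paths)) {
      tab <- sort(table(all_paths), decreasing = TRUE)
      best <- names(tab)[tab == max(tab)]
      most_frequent <- sort(best)[1]
      mf_count <- max(tab)
    } else {
      most_frequent <- NA_character_; mf_count <- 0L
    }
    mids <- unlist(lapply(per, function(ps) {
      unique(unlist(lapply(ps$paths, function(pp) pp[-c(1, length(pp))])))
    }))
    n_total_paths <- sum(counts)
    mid_all <- unlist(lapply(per, function(ps) {
      unlist(lapply(ps$paths, function(pp) pp[-c(1, length(pp))]))
    }))
    top <- if (length(mid_all)) {
      tb <- table(mid_all)
      tibble(node = names(tb), fraction = as.numeric(tb) / n_total_paths) |>
        dplyr::arrange(dplyr::desc(.data$fraction), .data$node)
    } else tibble(node = character(), fraction = numeric())
    rows[[ex]] <- tibble(
      exposure = ex, outcome = outcome, mode = mode,
      any_path_fraction = any_frac,
      direct_edge_fraction = mean(direct),
      median_path_count = stats::median(counts),
      most_frequent_path = most_frequent,
      most_frequent_path_count = as.integer(mf_count)
    )
    tops[[ex]] <- top
  }
  list(by_exposure = dplyr::bind_rows(rows), top_nodes = tops)
}

#' Patterns between repeated measurements across an ensemble
#'
#' For each triple of repeated measurements (baseline, first and second
#' follow-up of a variable) every member graph is classified by which of
#' the three directed edges it contains -- `B -> FU1`, `FU1 -> FU2`,
#' `B -> FU2` (an edge counts only when directed as written). The eight
#' resulting patterns are mutually exclusive ("most specific match"), so
#' counts sum to the ensemble size.
#'
#' @param ens A `graph_ensemble`.
#' @param triples List of character triples `c(vB, vFU1, vFU2)` (a single
#'   triple may be given as a plain vector).
#' @return Tibble with one row per triple and one column per pattern.
#' @export
repeated_measure_patterns <- function(ens, triples) {
  graphs <- ensemble_graphs(ens)
  if (is.character(triples)) triples <- list(triples)
  nodes <- graphs[[1]]$nodes
  pat_names <- c("none", "b_fu1", "b_fu2", "b_fu1_and_b_fu2", "fu1_fu2",
                 "b_fu2_and_fu1_fu2", "chain", "chain_plus_shortcut")
  rows <- lapply(triples, function(tr) {
    stopifnot(length(tr) == 3)
    if (!all(tr %in% nodes)) abort("unknown node(s) in triple")
    pats <- vapply(graphs, function(g) {
      e1 <- g$amat[tr[1], tr[2]] == 1L && g$amat[tr[2], tr[1]] == 0L  # B -> FU1
      e2 <- g$amat[tr[2], tr[3]] == 1L && g$amat[tr[3], tr[2]] == 0L  # FU1 -> FU2
      e3 <- g$amat[tr[1], tr[3]] == 1L && g$amat[tr[3], tr[1]] == 0L  # B -> FU2
      classify_rm_pattern(e1, e2, e3)
    }, character(1))
    counts <- table(factor(pats, levels = pat_names))
    dplyr::bind_cols(tibble(variable = paste(tr, collapse = "/")),
                     as_tibble(as.list(counts)))
  })
  dplyr::bind_rows(rows)
}

classify_rm_pattern <- function(e1, e2, e3) {
  if (e1 && e2 && e3) "chain_plus_shortcut"
  else if (e1 && e2) "chain"
  else if (e2 && e3) "b_fu2_and_fu1_fu2"
  else if (e1 && e3) "b_fu1_and_b_fu2"
  else if (e2) "fu1_fu2"
  else if (e3) "b_fu2"
  else if (e1) "b_fu1"
  else "none"
}
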