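# Config-driven orchestration of the whole analysis design:
# simulate/load -> impute -> discover (main + sensitivity) -> bootstrap ->
# path / metric reports, everything written to a reproducible bundle.

#' Assemble a pipeline configuration
#'
#' Defaults mirror the package's reference analysis design: tenfold
#' imputation, discovery at a nominal level of 0.05 with a 0.1 sensitivity
#' run and a test-wise-deletion sensitivity run, and 100 bootstrap
#' replicates.
#'
#' @param schema A [tier_schema()] or path to a schema file.
#' @param data Either `list(source = "simulate", edge_prob =, n =, mar =
#'   list(drivers =, target_rate =, per_variable =))` or
#'   `list(source = "file", path = "data.csv")`.
#' @param mi List: `m`, `iterations`, `model`.
#' @param discovery List: `alphas` (first entry is the main analysis),
#'   `test`, `max_cond`, `twd` (add a test-wise-deletion run?).
#' @param bootstrap List: `b` (replicates; 0 disables the stage).
#' @param report List: `exposures`, `outcome`, `thresholds` (consensus),
#'   optional `triples` for repeated-measurement patterns.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(schema,
                            data = list(source = "simulate", edge_prob = 0.05,
                                        n = 1000, mar = NULL),
                            mi = list(m = 10, iterations = 10, model = "tree"),
                            discovery = list(alphas = c(0.05, 0.1),
                                             test = "cg_lrt", max_cond = Inf,
                                             twd = TRUE),
                            bootstrap = list(b = 100),
                            report = list(exposures = NULL, outcome = NULL,
                                          thresholds = c(0.44, 0.75),
                                          triples = NULL),
                            seed = 1) {
  if (is.character(schema)) schema <- read_schema(schema)
  mi <- utils::modifyList(list(m = 10, iterations = 10, model = "tree"), mi)
  discovery <- utils::modifyList(
    list(alphas = c(0.05, 0.1), test = "cg_lrt", max_cond = Inf, twd = TRUE),
    discovery)
  bootstrap <- utils::modifyList(list(b = 100), bootstrap)
  report <- utils::modifyList(
    list(exposures = NULL, outcome = NULL, thresholds = c(0.44, 0.75),
         triples = NULL), report)
  stopifnot(all(discovery$alphas > 0 & discovery$alphas < 1))
  known <- schema$variables$name
  if (!is.null(report$outcome) && !report$outcome %in% known) {
    abort("report outcome is not a schema variable")
  }
  if (!is.null(report$exposures) && !all(report$exposures %in% known)) {
    abort("report exposures must be schema variables")
  }
  structure(list(schema = schema, data = data, mi = mi, discovery = discovery,
                 bootstrap = bootstrap, report = report, seed = seed),
            class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Executes the configured stages -- simulate or load the cohort table,
#' multiply impute it, learn the main graph and sensitivity graphs
#' (per-alpha and test-wise deletion), estimate the bootstrap ensemble,
#' and produce the report tables: possible ancestors of the outcome,
#' per-exposure path stability, repeated-measurement patterns, graph
#' characteristics, pairwise Hamming / structural Hamming distances, and
#' consensus graphs at the configured thresholds.
#'
#' All artifacts are written as plain text (CSV, JSON, GraphML, DOT) under
#' `out_dir`; `manifest.json` records the settings, derived stage seeds and
#' an MD5 checksum per file, making the run byte-reproducible.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory bundle (graphs, ensemble, tables).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "graphs"), showWarnings = FALSE)
  schema <- config$schema
  seed <- config$seed
  seeds <- list(scm = sub_seed(seed, 1), cohort = sub_seed(seed, 2),
                mar = sub_seed(seed, 3), mi = sub_seed(seed, 4),
                bootstrap = sub_seed(seed, 5))
  bundle <- list(config = config, seeds = seeds)

  # --- data ------------------------------------------------------------------
  if (identical(config$data$source, "simulate")) {
    scm <- sample_tiered_scm(schema, config$data$edge_prob, seed = seeds$scm)
    data <- sample_cohort(scm, config$data$n, seed = seeds$cohort)
    if (!is.null(config$data$mar)) {
      m <- config$data$mar
      data <- apply_mar(data, schema, drivers = m$drivers,
                        target_rate = m$target_rate,
                        per_variable = m$per_variable, seed = seeds$mar)
    }
    bundle$scm <- scm
  } else {
    data <- read_cohort(config$data$path, schema)
  }
  bundle$data <- data
  write_schema(schema, file.path(out_dir, "schema.yaml"))
  write_cohort(data, file.path(out_dir, "data.csv"))

  # --- multiple imputation ---------------------------------------------------
  has_na <- anyNA(data)
  if (has_na) {
    stack <- impute_chained(data, schema, M = config$mi$m,
                            iterations = config$mi$iterations,
                            model = config$mi$model, seed = seeds$mi)
    for (m in seq_along(stack$copies)) {
      write_cohort(stack$copies[[m]],
                   file.path(out_dir, sprintf("imputed_%02d.csv", m)))
    }
    discovery_input <- stack
    bundle$stack <- stack
  } else {
    discovery_input <- data
  }

  # --- discovery: main + sensitivity graphs ---------------------------------
  alphas <- config$discovery$alphas
  graphs <- list()
  fits <- list()
  for (i in seq_along(alphas)) {
    nm <- if (i == 1) "main" else sprintf("alpha_%s", format(alphas[i]))
    fit <- run_tpc(discovery_input, schema, alpha = alphas[i],
                   test = config$discovery$test,
                   max_cond = config$discovery$max_cond, keep_log = TRUE)
    fits[[nm]] <- fit
    graphs[[nm]] <- fit$graph
  }
  if (isTRUE(config$discovery$twd) && has_na) {
    fit <- run_tpc(data, schema, alpha = alphas[1],
                   test = config$discovery$test,
                   max_cond = config$discovery$max_cond, keep_log = TRUE)
    fits$twd <- fit
    graphs$twd <- fit$graph
  }
  bundle$fits <- fits

  # --- bootstrap -------------------------------------------------------------
  ens <- NULL
  if (config$bootstrap$b > 0) {
    ens <- run_bootstrap(data, schema, B = config$bootstrap$b,
                         alpha = alphas[1], test = config$discovery$test,
                         model = config$mi$model,
                         max_cond = config$discovery$max_cond,
                         seed = seeds$bootstrap)
    bundle$ensemble <- ens
    for (t in config$report$thresholds) {
      graphs[[sprintf("consensus_%s", format(t))]] <- consensus_graph(ens, t)
    }
  }

  # --- write graphs ----------------------------------------------------------
  for (nm in names(graphs)) {
    write_graphml(graphs[[nm]], file.path(out_dir, "graphs", paste0(nm, ".graphml")))
    write_dot(graphs[[nm]], file.path(out_dir, "graphs", paste0(nm, ".dot")))
  }
  bundle$graphs <- graphs

  # --- reports ---------------------------------------------------------------
  tables <- list()
  tables$graph_characteristics <- purrr::imap_dfr(graphs, function(g, nm) {
    row <- dplyr::bind_cols(tibble(graph = nm), graph_summary(g))
    row$mean_edge_uncertainty <- if (!is.null(ens) && grepl("^consensus_", nm)) {
      t <- as.numeric(sub("^consensus_", "", nm))
      mean_edge_uncertainty(ens, t)
    } else NA_real_
    row
  })
  pairs <- t(combn(names(graphs), 2))
  tables$graph_distances <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    g1 <- graphs[[pairs[k, 1]]]; g2 <- graphs[[pairs[k, 2]]]
    tibble(graph1 = pairs[k, 1], graph2 = pairs[k, 2],
           hamming = hamming(g1, g2), shd = shd(g1, g2))
  })
  if (!is.null(config$report$outcome)) {
    out_var <- config$report$outcome
    tables$possible_ancestors <- purrr::imap_dfr(graphs, function(g, nm) {
      anc <- possible_ancestors(g, out_var)
      if (!length(anc)) return(tibble())
      tibble(graph = nm, outcome = out_var, ancestor = anc)
    })
    if (!is.null(config$report$exposures)) {
      tables$main_paths <- purrr::map_dfr(config$report$exposures, function(ex) {
        ps <- enumerate_paths(graphs$main, ex, out_var)
        sm <- summarize_paths(ps)
        tibble(exposure = ex, outcome = out_var, n_paths = sm$n_paths,
               shortest_length = sm$shortest_length,
               shortest_path = paste(sm$shortest_path, collapse = " > "))
      })
      if (!is.null(ens)) {
        st <- path_stability(ens, config$report$exposures, out_var)
        tables$path_stability <- st$by_exposure
        bundle$path_stability <- st
      }
    }
  }
  if (!is.null(config$report$triples) && !is.null(ens)) {
    tables$repeated_measure_patterns <-
      repeated_measure_patterns(ens, config$report$triples)
  }
  if (!is.null(ens)) tables$edge_frequencies <- edge_frequencies(ens)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  bundle$tables <- tables

  # --- logs and manifest -----------------------------------------------------
  log_tbl <- purrr::imap_dfr(fits, function(f, nm) {
    if (is.null(f$log)) return(tibble())
    dplyr::bind_cols(tibble(graph = nm), f$log)
  })
  utils::write.csv(log_tbl, file.path(out_dir, "ci_tests.csv"), row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  checksums <- as.list(setNames(
    unname(tools::md5sum(file.path(out_dir, files))), files))
  manifest <- list(
    package = "ccgraph",
    seed = seed,
    stage_seeds = seeds,
    settings = list(
      data = config$data[setdiff(names(config$data), "mar")],
      mar = config$data$mar,
      mi = config$mi,
      discovery = config$discovery[c("alphas", "test", "twd")],
      max_cond = if (is.finite(config$discovery$max_cond)) config$discovery$max_cond else "unbounded",
      bootstrap = config$bootstrap,
      report = config$report
    ),
    files = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(bundle)
}
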