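test_that("a single-replicate ensemble reproduces the analysis of its resample", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 500, seed = 81)
  ens <- run_bootstrap(d, scm$schema, B = 1, alpha = 0.05, seed = 82)
  expect_length(ens$graphs, 1)
  # reconstruct the resample from the recorded provenance and re-run
  idx <- withr::with_seed(ens$provenance$resample_seed[1],
                          sample.int(nrow(d), nrow(d), replace = TRUE))
  direct <- run_tpc(d[idx, ], scm$schema, alpha = 0.05, keep_log = FALSE)
  expect_identical(ens$graphs[[1]]$amat, direct$graph$amat)
})

test_that("ensembles have the requested size and are seed-deterministic", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 300, seed = 83)
  masked <- apply_mar(d, scm$schema, drivers = "p1", target_rate = 0.1, seed = 84)
  e1 <- run_bootstrap(masked, scm$schema, B = 5, imp_iterations = 2,
                      model = "parametric", seed = 85)
  e2 <- run_bootstrap(masked, scm$schema, B = 5, imp_iterations = 2,
                      model = "parametric", seed = 85)
  expect_length(e1$graphs, 5)
  for (b in 1:5) expect_identical(e1$graphs[[b]]$amat, e2$graphs[[b]]$amat)
  expect_identical(e1$provenance, e2$provenance)
  e3 <- run_bootstrap(masked, scm$schema, B = 5, imp_iterations = 2,
                      model = "parametric", seed = 86)
  expect_false(all(vapply(1:5, function(b) {
    identical(e1$graphs[[b]]$amat, e3$graphs[[b]]$amat)
  }, logical(1))))
})

toy_ens <- function() {
  nodes <- c("A", "B", "Y")
  g_path <- mpdag(nodes, tibble::tibble(from = c("A", "B"), to = c("B", "Y"),
                                        mark = c("directed", "undirected")))
  g_path2 <- mpdag(nodes, tibble::tibble(from = c("A", "B"), to = c("B", "Y"),
                                         mark = c("directed", "directed")))
  g_none <- mpdag(nodes, tibble::tibble(from = "B", to = "Y", mark = "directed"))
  structure(list(graphs = list(g_path, g_path2, g_none),
                 provenance = tibble::tibble(replicate = 1:3),
                 schema = NULL, settings = list()),
            class = "graph_ensemble")
}

test_that("path stability reports fractions, medians and absent direct edges", {
  st <- path_stability(toy_ens(), exposures = "A", outcome = "Y")
  row <- st$by_exposure
  expect_equal(row$any_path_fraction, 2 / 3)
  expect_equal(row$direct_edge_fraction, 0)  # no member has an A-Y edge
  expect_equal(row$median_path_count, 1)
  expect_equal(row$most_frequent_path, "A > B > Y")
  expect_equal(row$most_frequent_path_count, 2L)
  expect_error(path_stability(toy_ens(), "nope", "Y"), "unknown")
  # a direct edge is itself a path: fractions are ordered
  expect_gte(row$any_path_fraction, row$direct_edge_fraction)
})

test_that("repeated-measurement patterns are the most specific match", {
  nodes <- c("vb", "vf1", "vf2")
  mk <- function(...) {
    e <- list(...)
    mpdag(nodes, if (length(e)) {
      tibble::tibble(from = vapply(e, `[`, "", 1), to = vapply(e, `[`, "", 2),
                     mark = "directed")
    } else NULL)
  }
  chain <- mk(c("vb", "vf1"), c("vf1", "vf2"))
  shortcut <- mk(c("vb", "vf1"), c("vf1", "vf2"), c("vb", "vf2"))
  only_b_fu1 <- mk(c("vb", "vf1"))
  none <- mk()
  reversed <- mk(c("vf1", "vb"))  # directed the wrong way: counts as none
  ens <- structure(list(graphs = list(chain, shortcut, only_b_fu1, none, reversed)),
                   class = "graph_ensemble")
  class(ens) <- "graph_ensemble"
  pat <- repeated_measure_patterns(ens, list(nodes))
  expect_equal(pat$chain, 1L)
  expect_equal(pat$chain_plus_shortcut, 1L)
  expect_equal(pat$b_fu1, 1L)
  expect_equal(pat$none, 2L)
  # counts partition the ensemble
  expect_equal(sum(unlist(pat[, -1])), 5L)
})

test_that("pattern counts match a brute-force reclassification on random ensembles", {
  nodes <- c("vb", "vf1", "vf2", "z")
  for (s in 1:30) {
    graphs <- withr::with_seed(1200 + s, {
      lapply(1:6, function(i) {
        edges <- list()
        for (pair in list(c("vb", "vf1"), c("vf1", "vf2"), c("vb", "vf2"),
                          c("z", "vf2"))) {
          st <- sample(c("none", "fw", "bw", "und"), 1)
          if (st == "none") next
          edges[[length(edges) + 1]] <- switch(st,
            fw = tibble::tibble(from = pair[1], to = pair[2], mark = "directed"),
            bw = tibble::tibble(from = pair[2], to = pair[1], mark = "directed"),
            und = tibble::tibble(from = pair[1], to = pair[2], mark = "undirected"))
        }
        mpdag(nodes, dplyr::bind_rows(edges))
      })
    })
    ens <- structure(list(graphs = graphs), class = "graph_ensemble")
    pat <- repeated_measure_patterns(ens, list(c("vb", "vf1", "vf2")))
    # brute force: classify each member from its three directed indicators
    expected <- table(factor(vapply(graphs, function(g) {
      dir_edge <- function(a, b) g$amat[a, b] == 1L && g$amat[b, a] == 0L
      key <- paste0(as.integer(dir_edge("vb", "vf1")),
                    as.integer(dir_edge("vf1", "vf2")),
                    as.integer(dir_edge("vb", "vf2")))
      switch(key, "000" = "none", "100" = "b_fu1", "001" = "b_fu2",
             "101" = "b_fu1_and_b_fu2", "010" = "fu1_fu2",
             "011" = "b_fu2_and_fu1_fu2", "110" = "chain",
             "111" = "chain_plus_shortcut")
    }, character(1)), levels = names(pat)[-1]))
    expect_equal(unlist(pat[, -1], use.names = FALSE), as.vector(expected))
    expect_equal(sum(unlist(pat[, -1])), 6L)
  }
})

test_that("a mediated effect shows paths but no direct edge across the ensemble", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 1200, seed = 91)
  ens <- run_bootstrap(d, scm$schema, B = 10, alpha = 0.05, seed = 92)
  st <- path_stability(ens, exposures = "x", outcome = "y")
  expect_gte(st$by_exposure$any_path_fraction, 0.8)
  expect_lte(st$by_exposure$direct_edge_fraction, 0.2)
  expect_gte(st$by_exposure$any_path_fraction,
             st$by_exposure$direct_edge_fraction)
})
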