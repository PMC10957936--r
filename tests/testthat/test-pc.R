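oracle_fit <- function(amat, tiers, forbidden = NULL, ...) {
  schema <- schema_from_tiers(tiers, forbidden = forbidden)
  run_tpc(amat, schema, keep_log = FALSE, ...)
}

test_that("oracle skeleton and sepsets are exact on chains and colliders", {
  nodes <- c("A", "B", "C")
  tiers <- setNames(c(0L, 0L, 0L), nodes)
  chain <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  chain["A", "B"] <- 1L; chain["B", "C"] <- 1L
  sch <- schema_from_tiers(tiers)
  sk <- pc_skeleton(ccgraph:::make_ci_source(chain, sch), sch, alpha = 0.05)
  expect_true(all(sk$skeleton$amat[cbind(c("A", "B"), c("B", "C"))] == 1L))
  expect_equal(sk$skeleton$amat["A", "C"], 0L)
  expect_equal(sk$sepsets[["A|C"]]$S, "B")

  collider <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  collider["A", "C"] <- 1L; collider["B", "C"] <- 1L
  sk2 <- pc_skeleton(ccgraph:::make_ci_source(collider, sch), sch, alpha = 0.05)
  expect_equal(sk2$skeleton$amat["A", "B"], 0L)
  expect_equal(sk2$sepsets[["A|B"]]$S, character(0))

  # orientation: collider becomes A -> C <- B; chain class stays undirected
  g2 <- orient_mpdag(sk2$skeleton, sk2$sepsets, sch)
  expect_equal(unname(g2$amat["A", "C"]), 1L); expect_equal(unname(g2$amat["C", "A"]), 0L)
  expect_equal(unname(g2$amat["B", "C"]), 1L); expect_equal(unname(g2$amat["C", "B"]), 0L)
  g1 <- orient_mpdag(sk$skeleton, sk$sepsets, sch)
  expect_true(all(g1$amat[cbind(c("A", "B", "B", "C"), c("B", "A", "C", "B"))] == 1L))
})

test_that("background knowledge orients cross-tier edges and Meek R1 propagates", {
  # A in tier 0, B in tier 1: A - B becomes A -> B; with C in tier 1 and
  # B - C present (A, C non-adjacent), R1 orients B -> C
  nodes <- c("A", "B", "C")
  tiers <- setNames(c(0L, 1L, 1L), nodes)
  sch <- schema_from_tiers(tiers)
  skel <- mpdag(nodes, tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                      mark = "undirected"), tiers)
  sep <- list("A|C" = list(S = "B", p = 0.5))
  g <- orient_mpdag(skel, sep, sch)
  expect_equal(unname(g$amat["A", "B"]), 1L); expect_equal(unname(g$amat["B", "A"]), 0L)
  expect_equal(unname(g$amat["B", "C"]), 1L); expect_equal(unname(g$amat["C", "B"]), 0L)
})

test_that("forbidden orientations are respected and logged when conflicting", {
  nodes <- c("A", "B")
  tiers <- setNames(c(0L, 0L), nodes)
  sch <- schema_from_tiers(tiers, forbidden = tibble::tibble(from = "A", to = "B"))
  skel <- mpdag(nodes, tibble::tibble(from = "A", to = "B", mark = "undirected"),
                tiers)
  g <- orient_mpdag(skel, list(), sch)
  # the only allowed direction is B -> A
  expect_equal(unname(g$amat["B", "A"]), 1L)
  expect_equal(unname(g$amat["A", "B"]), 0L)
})

test_that("oracle PC recovers the exact skeleton on random tiered DAGs", {
  for (s in 1:100) {
    g <- bf_random_tiered_dag(8, 3, 0.25, seed = 100 + s)
    fit <- oracle_fit(g$amat, g$tiers)
    expect_identical(unname(ccgraph:::skeleton_amat(fit$graph)),
                     unname((g$amat + t(g$amat)) > 0),
                     info = paste("seed", 100 + s))
  }
})

test_that("the PC-stable skeleton is order-independent", {
  g <- bf_random_tiered_dag(8, 3, 0.3, seed = 999)
  base <- oracle_fit(g$amat, g$tiers)
  perm <- withr::with_seed(1, sample(rownames(g$amat)))
  sch_perm <- schema_from_tiers(g$tiers[perm])
  fit_perm <- run_tpc(g$amat[perm, perm], sch_perm, keep_log = FALSE)
  nodes <- sort(rownames(g$amat))
  expect_identical(ccgraph:::skeleton_amat(base$graph)[nodes, nodes],
                   ccgraph:::skeleton_amat(fit_perm$graph)[nodes, nodes])
})

test_that("orientation closure is idempotent", {
  for (s in 1:20) {
    g <- bf_random_tiered_dag(7, 2, 0.3, seed = 200 + s)
    sch <- schema_from_tiers(g$tiers)
    src <- ccgraph:::make_ci_source(g$amat, sch)
    sk <- pc_skeleton(src, sch, alpha = 0.05)
    g1 <- orient_mpdag(sk$skeleton, sk$sepsets, sch)
    g2 <- orient_mpdag(g1, sk$sepsets, sch)
    expect_identical(g1$amat, g2$amat)
  }
})

test_that("no learned graph ever violates tiers or forbidden orientations", {
  sch <- idefics_schema()
  for (s in 1:5) {
    scm <- sample_tiered_scm(sch, 0.03, seed = 300 + s)
    fit <- run_tpc(scm, sch, keep_log = FALSE)
    expect_true(validate_mpdag(fit$graph, sch))
  }
})

test_that("data-driven discovery recovers a known model and grows with alpha", {
  scm <- demo_scm_12()
  truth <- run_tpc(scm, scm$schema, keep_log = FALSE)$graph
  shd_vals <- integer(0)
  for (s in 1:5) {
    d <- sample_cohort(scm, 4000, seed = 400 + s)
    fit05 <- run_tpc(d, scm$schema, alpha = 0.05, keep_log = FALSE)
    fit10 <- run_tpc(d, scm$schema, alpha = 0.1, keep_log = FALSE)
    shd_vals <- c(shd_vals, shd(fit05$graph, truth))
    # higher alpha makes removal harder, so the graph can only get denser
    expect_gte(nrow(mpdag_edges(fit10$graph)), nrow(mpdag_edges(fit05$graph)))
    expect_true(validate_mpdag(fit05$graph, scm$schema))
  }
  expect_lte(stats::median(shd_vals), 2)
})

test_that("an imputed stack routes every test through the pooled method", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 300, seed = 31)
  masked <- apply_mar(d, scm$schema, drivers = "p1", target_rate = 0.15, seed = 32)
  stack <- impute_chained(masked, scm$schema, M = 3, iterations = 2,
                          model = "parametric", seed = 33)
  fit <- run_tpc(stack, alpha = 0.05)
  expect_true(all(grepl("^mi_pooled:", fit$log$method)))
  expect_equal(fit$test, "mi_pooled:cg_lrt")
})

test_that("untestable TWD results never remove an edge", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 60, seed = 41)
  # y observed only when m is missing: the (m, y) pair is untestable
  d$m[1:35] <- NA
  d$y[36:60] <- NA
  fit <- run_tpc(d, scm$schema, alpha = 0.05, keep_log = TRUE)
  expect_true(ccgraph:::skeleton_amat(fit$graph)["m", "y"])
  expect_true(any(grepl("untestable", fit$log$method)))
})
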