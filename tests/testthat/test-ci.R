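# helpers for quick typed tables ---------------------------------------------

cont_schema <- function(...) {
  nm <- c(...)
  tier_schema(tibble::tibble(name = nm, kind = "continuous", tier = 0L,
                             levels = list(NULL)), tiers = "t0")
}

mixed_schema <- function(cont = character(), cat = list()) {
  vars <- dplyr::bind_rows(
    if (length(cont)) tibble::tibble(name = cont, kind = "continuous",
                                     tier = 0L, levels = list(NULL)),
    purrr::imap_dfr(cat, function(lv, nm) {
      tibble::tibble(name = nm, kind = "categorical", tier = 0L, levels = list(lv))
    })
  )
  tier_schema(vars, tiers = "t0")
}

test_that("cg_loglik matches closed forms for single variables", {
  # binary with counts (3, 1): multinomial MLE
  sch <- mixed_schema(cat = list(b = c("a", "b")))
  d <- tibble::tibble(b = factor(c("a", "a", "a", "b"), levels = c("a", "b")))
  res <- cg_loglik(d, sch, "b")
  expect_equal(res$loglik, 3 * log(3 / 4) + 1 * log(1 / 4), tolerance = 1e-12)
  expect_equal(res$nparams, 1L)

  # continuous values (-1, 1): Gaussian MLE with variance 1
  sch2 <- cont_schema("x")
  d2 <- tibble::tibble(x = c(-1, 1))
  res2 <- cg_loglik(d2, sch2, "x")
  expect_equal(res2$loglik, -log(2 * pi) - 1, tolerance = 1e-12)
  expect_equal(res2$nparams, 2L)  # 1 mean + 1 variance
})

test_that("cg_loglik agrees with a direct bivariate Gaussian density sum", {
  sch <- cont_schema("x", "y")
  d <- withr::with_seed(4, tibble::tibble(x = rnorm(50), y = rnorm(50) + 0.5))
  res <- cg_loglik(d, sch, c("x", "y"))
  X <- cbind(d$x, d$y)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)   # MLE covariance
  Sinv <- solve(S)
  dens <- apply(X, 1, function(r) {
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(r - mu) %*% Sinv %*% (r - mu))
  })
  expect_equal(res$loglik, sum(dens), tolerance = 1e-8)
})

test_that("cg_lrt_ci handles exact independence and strong dependence", {
  # 2x2 with all counts 25: G = 0, df = 1, p = 1
  sch <- mixed_schema(cat = list(a = c("0", "1"), b = c("0", "1")))
  d <- tibble::tibble(
    a = factor(rep(c("0", "1"), each = 50)),
    b = factor(rep(c("0", "1", "0", "1"), each = 25)))
  res <- cg_lrt_ci(d, sch, "a", "b")
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 1)

  # binary x, continuous y shifted by 3 between groups: decisive rejection,
  # and G equals the two-sample Gaussian LRT n * log(var0 / pooled var)
  sch2 <- mixed_schema(cont = "y", cat = list(x = c("lo", "hi")))
  d2 <- withr::with_seed(5, tibble::tibble(
    x = factor(rep(c("lo", "hi"), each = 100), levels = c("lo", "hi")),
    y = rnorm(200) + rep(c(0, 3), each = 100)))
  res2 <- cg_lrt_ci(d2, sch2, "x", "y")
  expect_lt(res2$p_value, 1e-6)
  n <- nrow(d2)
  v0 <- mean((d2$y - mean(d2$y))^2)
  vw <- mean(unlist(lapply(split(d2$y, d2$x), function(g) (g - mean(g))^2)))
  expect_equal(res2$statistic, n * log(v0 / vw), tolerance = 1e-8)
})

test_that("all-continuous cg_lrt equals the partial-correlation LRT oracle", {
  sch <- cont_schema("x", "y", "s1", "s2")
  for (seed in 1:5) {
    d <- withr::with_seed(seed, {
      s1 <- rnorm(80); s2 <- rnorm(80)
      tibble::tibble(s1 = s1, s2 = s2,
                     x = 0.5 * s1 + rnorm(80),
                     y = 0.4 * s1 - 0.3 * s2 + rnorm(80))
    })
    res <- cg_lrt_ci(d, sch, "x", "y", c("s1", "s2"))
    # oracle: residual correlation after regressing out S, G = -n log(1 - r^2)
    rx <- residuals(lm(x ~ s1 + s2, data = d))
    ry <- residuals(lm(y ~ s1 + s2, data = d))
    r <- cor(rx, ry)
    expect_equal(res$statistic, -nrow(d) * log(1 - r^2), tolerance = 1e-6)
    expect_equal(res$df, 1)
  }
})

test_that("all-discrete cg_lrt equals the stratified G-test", {
  sch <- mixed_schema(cat = list(x = c("a", "b"), y = c("a", "b"),
                                 s = c("u", "v", "w")))
  d <- withr::with_seed(6, tibble::tibble(
    x = factor(sample(c("a", "b"), 300, TRUE)),
    y = factor(sample(c("a", "b"), 300, TRUE, prob = c(0.4, 0.6))),
    s = factor(sample(c("u", "v", "w"), 300, TRUE))))
  res <- cg_lrt_ci(d, sch, "x", "y", "s")
  G <- 0
  for (lev in levels(d$s)) {
    tab <- table(d$x[d$s == lev], d$y[d$s == lev])
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    G <- G + 2 * sum(tab[nz] * log(tab[nz] / E[nz]))
  }
  expect_equal(res$statistic, G, tolerance = 1e-6)
  expect_equal(res$df, 3)  # |S| strata * (2-1) * (2-1)
})

test_that("fisher_z handles orthogonal, degenerate and powered cases", {
  sch <- cont_schema("x", "y", "z")
  d <- tibble::tibble(x = c(1, -1, 1, -1), y = c(1, 1, -1, -1), z = c(1, 2, 3, 4))
  res <- fisher_z_ci(d, sch, "x", "y")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  d2 <- tibble::tibble(x = rnorm(20), z = rnorm(20)) |>
    dplyr::mutate(y = x)
  res2 <- fisher_z_ci(d2, sch, "x", "y")
  expect_equal(res2$p_value, 0)
  expect_true("degenerate" %in% res2$flags)

  # power: true partial correlation 0.5 given one conditioner
  rej <- vapply(1:100, function(s) {
    d3 <- withr::with_seed(1000 + s, {
      z <- rnorm(1000)
      x <- z + rnorm(1000)
      # corr(eps_x, eps_y) = 0.5 after conditioning on z
      e <- MASS::mvrnorm(1000, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
      tibble::tibble(z = z, x = z + e[, 1], y = -z + e[, 2])
    })
    fisher_z_ci(d3, sch, "x", "y", "z")$p_value < 0.05
  }, logical(1))
  expect_gte(sum(rej), 99)
})

test_that("MI pooling reduces to the complete-data test on identical copies", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 200, seed = 9)
  stack <- structure(list(copies = rep(list(d), 5), schema = scm$schema,
                          provenance = list(seed = 0, M = 5, iterations = 0,
                                            model = "none")),
                     class = "imputed_stack")
  pooled_z <- pool_mi(stack, "x", "y", "m", base = "fisher_z")
  direct_z <- fisher_z_ci(d, scm$schema, "x", "y", "m")
  expect_equal(pooled_z$p_value, direct_z$p_value, tolerance = 1e-6)
  pooled_g <- pool_mi(stack, "x", "y", "m", base = "cg_lrt")
  direct_g <- cg_lrt_ci(d, scm$schema, "x", "y", "m")
  expect_equal(pooled_g$p_value, direct_g$p_value, tolerance = 1e-6)
})

test_that("Rubin pooling arithmetic matches the stated formula", {
  # M = 2, z-values 0.1 and 0.3, n = 103, |S| = 0:
  # qbar = 0.2, W = 0.01, B = 0.02, T = 0.04, statistic = 1
  zs <- c(0.1, 0.3); M <- 2; n <- 103
  qbar <- mean(zs); W <- 1 / (n - 3); B <- var(zs)
  T_ <- W + (1 + 1 / M) * B
  expect_equal(qbar, 0.2); expect_equal(W, 0.01)
  expect_equal(B, 0.02); expect_equal(T_, 0.04)
  stat <- abs(qbar) / sqrt(T_)
  expect_equal(stat, 1)
  # and the implementation reproduces it end to end on constructed copies:
  # two copies whose sample z-statistics are forced by construction
  sch <- cont_schema("x", "y")
  mk <- function(r) {
    # exact sample correlation r via orthogonalisation
    x <- scale(rnorm(n)); e <- scale(resid(lm(rnorm(n) ~ x)))
    tibble::tibble(x = as.numeric(x), y = as.numeric(r * x + sqrt(1 - r^2) * e))
  }
  copies <- withr::with_seed(10, list(mk(tanh(0.1)), mk(tanh(0.3))))
  stack <- structure(list(copies = copies, schema = sch,
                          provenance = list(seed = 0, M = 2, iterations = 0,
                                            model = "none")),
                     class = "imputed_stack")
  res <- pool_mi(stack, "x", "y", base = "fisher_z")
  expect_equal(res$statistic, 1, tolerance = 1e-8)
})

test_that("pooling is invariant to copy order and monotone in between-variance", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 300, seed = 15)
  masked <- apply_mar(d, scm$schema, drivers = "p1", target_rate = 0.2, seed = 16)
  stack <- impute_chained(masked, scm$schema, M = 5, iterations = 2,
                          model = "parametric", seed = 17)
  rev_stack <- stack
  rev_stack$copies <- rev(stack$copies)
  for (base in c("fisher_z", "cg_lrt")) {
    a <- pool_mi(stack, "x", "y", "m", base = base)
    b <- pool_mi(rev_stack, "x", "y", "m", base = base)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
  # inflating B with fixed qbar never decreases the p-value (z base)
  p_at_spread <- function(delta) {
    zs <- c(0.2 - delta, 0.2 + delta); M <- 2; n <- 103
    W <- 1 / (n - 3); B <- var(zs); T_ <- W + (1 + 1 / M) * B
    stat <- abs(mean(zs)) / sqrt(T_)
    if (B <= .Machine$double.eps) 2 * pnorm(stat, lower.tail = FALSE)
    else 2 * pt(stat, (M - 1) * (1 + W / ((1 + 1 / M) * B))^2, lower.tail = FALSE)
  }
  spreads <- seq(0, 0.5, by = 0.05)
  ps <- vapply(spreads, p_at_spread, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("test-wise deletion matches the complete-data test and flags emptiness", {
  scm <- demo_scm_mediation()
  d <- sample_cohort(scm, 400, seed = 19)
  full <- twd_ci(d, scm$schema, "x", "y", "m")
  direct <- cg_lrt_ci(d, scm$schema, "x", "y", "m")
  expect_equal(full$p_value, direct$p_value, tolerance = 1e-12)
  expect_equal(full$n_effective, nrow(d))

  # 30% MCAR rows: same alpha = 0.05 decision as complete data in >= 90/100
  sch3 <- cont_schema("x", "m", "y")
  agree <- vapply(1:100, function(s) {
    dd <- withr::with_seed(3000 + s, {
      tibble::tibble(x = rnorm(1000), m = rnorm(1000), y = rnorm(1000))
    })
    p_full <- cg_lrt_ci(dd, sch3, "x", "y", "m")$p_value
    dd2 <- dd
    drop <- withr::with_seed(4000 + s, runif(1000) < 0.3)
    dd2$y[drop] <- NA
    p_twd <- twd_ci(dd2, sch3, "x", "y", "m")$p_value
    (p_full > 0.05) == (p_twd > 0.05)
  }, logical(1))
  expect_gte(sum(agree), 90)

  # all rows missing y: untestable, never removes an edge
  d$y <- NA_real_
  d$y[1] <- 0  # keep the column imputable/validatable
  d2 <- d; d2$y <- NA_real_
  res <- twd_ci(d2, scm$schema, "x", "y", "m")
  expect_true("untestable" %in% res$flags)
  expect_true(is.na(res$p_value))
})

test_that("the d-separation oracle agrees with brute-force path enumeration", {
  # chain and collider canonical cases
  chain <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  chain["A", "B"] <- 1L; chain["B", "C"] <- 1L
  expect_equal(dsep_oracle_ci(chain, "A", "C", "B")$p_value, 1)
  expect_equal(dsep_oracle_ci(chain, "A", "C")$p_value, 0)
  collider <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  collider["A", "C"] <- 1L; collider["B", "C"] <- 1L
  expect_equal(dsep_oracle_ci(collider, "A", "B")$p_value, 1)
  expect_equal(dsep_oracle_ci(collider, "A", "B", "C")$p_value, 0)
  expect_error(dsep_oracle_ci(chain, "A", "Z"), "unknown")

  # randomised agreement with the path-enumeration oracle
  cases <- 0
  for (s in 1:120) {
    g <- bf_random_tiered_dag(6, 2, 0.4, seed = 7000 + s)
    nodes <- rownames(g$amat)
    picks <- withr::with_seed(8000 + s, {
      lapply(1:9, function(i) {
        xy <- sample(nodes, 2)
        S <- setdiff(sample(nodes, sample(0:3, 1)), xy)
        list(x = xy[1], y = xy[2], S = S)
      })
    })
    for (pk in picks) {
      cases <- cases + 1
      expect_equal(
        dsep_oracle_ci(g$amat, pk$x, pk$y, pk$S)$p_value == 1,
        bf_dsep(g$amat, pk$x, pk$y, pk$S),
        info = sprintf("seed %d: %s,%s | %s", s, pk$x, pk$y,
                       paste(pk$S, collapse = ","))
      )
    }
  }
  expect_gte(cases, 1000)
})
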