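# Conditional-independence tests for mixed discrete/continuous data.
#
# The statistical kernel consumed by the PC search: a homogeneous
# conditional-Gaussian likelihood (multinomial over discrete cells,
# cell-specific means, one pooled covariance), the likelihood-ratio CI test
# built on it, the Gaussian Fisher-z special case, test-wise deletion,
# pooling over multiply imputed data (Rubin's rules on the z scale; the
# Li-Meng-Raghunathan-Rubin D2 combination for chi-square statistics),
# and a d-separation oracle for validation.

ci_result <- function(statistic, df, p_value, method, n_effective,
                      flags = character()) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, n_effective = n_effective, flags = flags),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("<ci_test %s> stat = %.4g, df = %.3g, p = %.4g, n = %d%s\n",
              x$method, x$statistic, x$df, x$p_value, x$n_effective,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' @export
tidy.ci_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = x$method, n_effective = x$n_effective,
         flags = paste(x$flags, collapse = ","))
}

# ---- data preparation -------------------------------------------------------

# Precompute numeric matrices and discrete level codes for fast repeated
# likelihood evaluation. Rows with NA anywhere are kept; callers subset.
prep_ci_data <- function(data, schema) {
  data <- validate_cohort(data, schema)
  kinds <- schema_kinds(schema)
  nm <- names(data)
  cont <- nm[kinds[nm] == "continuous"]
  disc <- nm[kinds[nm] == "categorical"]
  list(
    n = nrow(data),
    names = nm,
    kinds = kinds[nm],
    cont = if (length(cont)) vapply(data[cont], as.numeric, numeric(nrow(data))) else NULL,
    cont_names = cont,
    disc = if (length(disc)) vapply(data[disc], as.integer, integer(nrow(data))) else NULL,
    disc_names = disc,
    nlev = vapply(data[disc], nlevels, integer(1))
  )
}

# Maximised homogeneous conditional-Gaussian log-likelihood of a variable
# set, on a row subset. Returns loglik, nparams and flags.
cg_loglik_core <- function(prep, vars, rows = NULL) {
  if (!length(vars)) return(list(loglik = 0, nparams = 0L, flags = character()))
  dvars <- intersect(vars, prep$disc_names)
  cvars <- intersect(vars, prep$cont_names)
  flags <- character()
  n <- if (is.null(rows)) prep$n else length(rows)
  cell <- NULL
  ll_disc <- 0; c_obs <- 1L
  if (length(dvars)) {
    codes <- prep$disc[, dvars, drop = FALSE]
    if (!is.null(rows)) codes <- codes[rows, , drop = FALSE]
    mult <- cumprod(c(1L, prep$nlev[dvars][-length(dvars)]))
    cell <- 1L + drop((codes - 1L) %*% mult)
    nj <- tabulate(cell, nbins = prod(prep$nlev[dvars]))
    nz <- nj[nj > 0]
    c_obs <- length(nz)
    ll_disc <- sum(nz * log(nz / n))
  }
  if (!length(cvars)) {
    return(list(loglik = ll_disc, nparams = c_obs - 1L, flags = flags))
  }
  X <- prep$cont[, cvars, drop = FALSE]
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  k <- ncol(X)
  if (is.null(cell)) {
    Xc <- sweep(X, 2, colMeans(X))
  } else {
    gidx <- match(cell, sort(unique(cell)))
    gs <- rowsum(X, gidx)
    gn <- tabulate(gidx)
    Xc <- X - (gs / gn)[gidx, , drop = FALSE]
  }
  S <- crossprod(Xc) / n
  ld <- log_det_pd(S)
  if (is.na(ld)) {
    ridge <- 1e-8 * max(sum(diag(S)), 1)
    S <- S + diag(ridge, k)
    ld <- log_det_pd(S)
    flags <- c(flags, "ridge")
    if (is.na(ld)) abort("pooled covariance singular even after ridge")
  }
  ll <- ll_disc - n / 2 * (k * log(2 * pi) + ld + k)
  npar <- (c_obs - 1L) + c_obs * k + k * (k + 1L) / 2L
  list(loglik = ll, nparams = npar, flags = flags)
}

#' Conditional-Gaussian log-likelihood of a variable set
#'
#' Fits the homogeneous conditional-Gaussian model to the named variables
#' of a complete cohort table: a saturated multinomial over the cells of
#' the discrete variables, a cell-specific mean vector for the continuous
#' variables, and one covariance matrix pooled across cells (within-cell
#' maximum-likelihood estimate). With `c` observed cells and `k` continuous
#' variables the parameter count is `(c-1) + c*k + k*(k+1)/2`; cells with
#' no observations contribute neither likelihood terms nor parameters.
#' A numerically singular pooled covariance is ridged
#' (`1e-8 * trace`) and flagged.
#'
#' @param data Complete cohort tibble.
#' @param schema Its [tier_schema()].
#' @param vars Character vector of variable names.
#' @return List with `loglik`, `nparams` and `flags`.
#' @export
cg_loglik <- function(data, schema, vars) {
  if (anyNA(data[vars])) abort("cg_loglik requires complete data on `vars`")
  prep <- prep_ci_data(data, schema)
  cg_loglik_core(prep, vars)
}

cg_lrt_core <- function(prep, x, y, S, rows = NULL, cache = NULL) {
  ll <- function(vars) {
    if (!is.null(cache)) {
      key <- set_key(match(vars, prep$names))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      out <- cg_loglik_core(prep, vars, rows)
      cache[[key]] <- out
      return(out)
    }
    cg_loglik_core(prep, vars, rows)
  }
  l_xyS <- ll(c(x, y, S)); l_S <- ll(S); l_xS <- ll(c(x, S)); l_yS <- ll(c(y, S))
  G <- max(0, 2 * (l_xyS$loglik + l_S$loglik - l_xS$loglik - l_yS$loglik))
  df <- max(1L, l_xyS$nparams + l_S$nparams - l_xS$nparams - l_yS$nparams)
  n <- if (is.null(rows)) prep$n else length(rows)
  ci_result(G, df, pchisq(G, df, lower.tail = FALSE), "cg_lrt", n,
            unique(c(l_xyS$flags, l_S$flags, l_xS$flags, l_yS$flags)))
}

#' Conditional-Gaussian likelihood-ratio test of conditional independence
#'
#' Tests `x` independent of `y` given `S` in a complete mixed-type table by
#' the likelihood-ratio statistic
#' `G = 2 * (l(x,y,S) + l(S) - l(x,S) - l(y,S))` of the homogeneous
#' conditional-Gaussian model, referred to a chi-square distribution whose
#' degrees of freedom are the corresponding parameter-count difference
#' (floored at 1). Reduces to the Gaussian partial-correlation
#' likelihood-ratio test when all variables are continuous and to the
#' G-test of conditional independence when all are discrete.
#'
#' @param data Complete cohort tibble.
#' @param schema Its [tier_schema()].
#' @param x,y Variable names; `S` a (possibly empty) character vector of
#'   conditioning variables.
#' @return A `ci_test` result.
#' @export
cg_lrt_ci <- function(data, schema, x, y, S = character()) {
  stopifnot(x != y, !(x %in% S), !(y %in% S))
  if (anyNA(data[c(x, y, S)])) abort("cg_lrt_ci requires complete data; use twd_ci()")
  prep <- prep_ci_data(data, schema)
  cg_lrt_core(prep, x, y, S)
}

fisher_z_core <- function(prep, x, y, S, rows = NULL) {
  vars <- c(x, y, S)
  X <- prep$cont[, vars, drop = FALSE]
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  n <- nrow(X)
  if (n - length(S) - 3 < 1) abort("fisher_z_ci needs n - |S| - 3 >= 1")
  C <- stats::cov(X)
  P <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(P)) {
    return(ci_result(Inf, Inf, 0, "fisher_z", n, "degenerate"))
  }
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  if (abs(r) >= 1 - 1e-12) {
    return(ci_result(Inf, Inf, 0, "fisher_z", n, "degenerate"))
  }
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(n - length(S) - 3) * abs(z)
  ci_result(stat, Inf, 2 * pnorm(stat, lower.tail = FALSE), "fisher_z", n)
}

#' Fisher-z test of vanishing partial correlation
#'
#' The Gaussian special case: the sample partial correlation `r` of `x`
#' and `y` given `S` is Fisher-transformed, `z = atanh(r)`, and
#' `sqrt(n - |S| - 3) * |z|` referred to a standard normal. All variables
#' must be continuous. A perfectly collinear pair returns `p = 0` with a
#' degeneracy flag.
#'
#' @inheritParams cg_lrt_ci
#' @return A `ci_test` result.
#' @export
fisher_z_ci <- function(data, schema, x, y, S = character()) {
  stopifnot(x != y, !(x %in% S), !(y %in% S))
  kinds <- schema_kinds(schema)
  if (!all(kinds[c(x, y, S)] == "continuous")) {
    abort("fisher_z_ci requires continuous variables only")
  }
  if (anyNA(data[c(x, y, S)])) abort("fisher_z_ci requires complete data; use twd_ci()")
  prep <- prep_ci_data(data, schema)
  fisher_z_core(prep, x, y, S)
}

# per-copy z statistic used by MI pooling (signed)
fisher_z_value <- function(prep, x, y, S) {
  X <- prep$cont[, c(x, y, S), drop = FALSE]
  C <- stats::cov(X)
  P <- solve(C)
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  0.5 * log((1 + r) / (1 - r))
}

#' Pool a conditional-independence test over multiply imputed data
#'
#' For the Fisher-z base, Rubin's rules are applied on the z scale: with
#' per-copy statistics `z_m`, within-imputation variance
#' `W = 1/(n - |S| - 3)`, between-imputation variance `B = var(z_m)` and
#' total `T = W + (1 + 1/M) B`, the statistic `|mean(z)| / sqrt(T)` is
#' referred to a Student-t with `nu = (M-1) (1 + W / ((1+1/M) B))^2`
#' degrees of freedom (standard normal in the `B -> 0` limit).
#'
#' For the conditional-Gaussian likelihood-ratio base, the D2 rule pools
#' the M chi-square statistics `d_m` with common df `k`:
#' `r = (1 + 1/M) var(sqrt(d_m))`,
#' `D2 = max(0, (mean(d)/k - (M+1)/(M-1) r) / (1 + r))`, referred to an
#' F(k, nu2) distribution with `nu2 = k^(-3/M) (M-1) (1 + 1/r)^2`; the
#' `r -> 0` limit falls back to the complete-data chi-square.
#'
#' @param stack An [impute_chained()] result.
#' @param x,y,S As in [cg_lrt_ci()].
#' @param base `"cg_lrt"` or `"fisher_z"`.
#' @return A `ci_test` result with method tag `mi_pooled:<base>`.
#' @export
pool_mi <- function(stack, x, y, S = character(), base = c("cg_lrt", "fisher_z")) {
  base <- match.arg(base)
  stopifnot(inherits(stack, "imputed_stack"))
  schema <- stack$schema
  M <- length(stack$copies)
  if (M == 1) {
    res <- if (base == "cg_lrt") cg_lrt_ci(stack$copies[[1]], schema, x, y, S)
           else fisher_z_ci(stack$copies[[1]], schema, x, y, S)
    res$method <- paste0("mi_pooled:", base)
    return(res)
  }
  preps <- lapply(stack$copies, prep_ci_data, schema = schema)
  n <- preps[[1]]$n
  if (base == "fisher_z") {
    kinds <- schema_kinds(schema)
    if (!all(kinds[c(x, y, S)] == "continuous")) {
      abort("fisher_z pooling requires continuous variables only")
    }
    zs <- vapply(preps, fisher_z_value, numeric(1), x = x, y = y, S = S)
    qbar <- mean(zs)
    W <- 1 / (n - length(S) - 3)
    B <- var(zs)
    T_ <- W + (1 + 1 / M) * B
    stat <- abs(qbar) / sqrt(T_)
    p <- if (B <= .Machine$double.eps) {
      2 * pnorm(stat, lower.tail = FALSE)
    } else {
      nu <- (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
      2 * pt(stat, nu, lower.tail = FALSE)
    }
    return(ci_result(stat, Inf, p, "mi_pooled:fisher_z", n))
  }
  tests <- lapply(preps, function(pp) cg_lrt_core(pp, x, y, S))
  d <- vapply(tests, function(t) t$statistic, numeric(1))
  k <- max(vapply(tests, function(t) t$df, numeric(1)))
  dbar <- mean(d)
  r <- (1 + 1 / M) * var(sqrt(d))
  if (r <= .Machine$double.eps) {
    p <- pchisq(dbar, k, lower.tail = FALSE)
    return(ci_result(dbar / k, k, p, "mi_pooled:cg_lrt", n))
  }
  D2 <- max(0, (dbar / k - (M + 1) / (M - 1) * r) / (1 + r))
  nu2 <- k^(-3 / M) * (M - 1) * (1 + 1 / r)^2
  p <- pf(D2, k, nu2, lower.tail = FALSE)
  ci_result(D2, k, p, "mi_pooled:cg_lrt", n,
            unique(unlist(lapply(tests, function(t) t$flags))))
}

#' Conditional-independence test under test-wise deletion
#'
#' Applies the base test to the rows that are complete on `{x, y} ∪ S`.
#' When fewer than `|S| + 5` complete rows remain the test is *untestable*:
#' the result carries `p_value = NA` and an `untestable` flag, which the
#' PC search treats as "do not remove the edge" (removal requires positive
#' evidence of independence).
#'
#' @param data Cohort tibble, possibly with missing cells.
#' @inheritParams cg_lrt_ci
#' @param base `"cg_lrt"` or `"fisher_z"`.
#' @return A `ci_test` result with method tag `twd:<base>`.
#' @export
twd_ci <- function(data, schema, x, y, S = character(),
                   base = c("cg_lrt", "fisher_z")) {
  base <- match.arg(base)
  vars <- c(x, y, S)
  data <- validate_cohort(data, schema)
  rows <- which(complete.cases(data[vars]))
  if (length(rows) < length(S) + 5) {
    return(ci_result(NA_real_, NA_real_, NA_real_,
                     paste0("twd:", base, ":untestable"), length(rows),
                     "untestable"))
  }
  prep <- prep_ci_data(data[rows, ], schema)
  res <- if (base == "cg_lrt") cg_lrt_core(prep, x, y, S)
         else fisher_z_core(prep, x, y, S)
  res$method <- paste0("twd:", base)
  res
}

#' d-separation oracle as a conditional-independence test
#'
#' Returns `p = 1` when `x` and `y` are d-separated by `S` in the DAG and
#' `p = 0` otherwise; used to validate the structure search independent of
#' any finite-sample test.
#'
#' @param dag A `cohort_scm`, a list with an `amat` adjacency matrix, or an
#'   adjacency matrix itself (`amat[a, b] = 1` meaning `a -> b`).
#' @inheritParams cg_lrt_ci
#' @return A `ci_test` result with method `"oracle"`.
#' @export
dsep_oracle_ci <- function(dag, x, y, S = character()) {
  amat <- dag_amat(dag)
  if (!all(c(x, y, S) %in% rownames(amat))) abort("unknown node name(s)")
  sep <- d_separated(amat, x, y, S)
  ci_result(if (sep) 0 else Inf, 1, if (sep) 1 else 0, "oracle", nrow(amat))
}

dag_amat <- function(dag) {
  if (inherits(dag, "cohort_scm")) return(dag$dag$amat)
  if (is.matrix(dag)) return(dag)
  if (is.list(dag) && !is.null(dag$amat)) return(dag$amat)
  abort("cannot extract a DAG adjacency matrix from `dag`")
}

# ---- CI sources for the PC search ------------------------------------------
#
# A CI source is a closure (x, y, S) -> ci_test plus metadata; run_tpc
# builds one from whatever data object it is given. Likelihood values are
# cached per variable set (and per imputed copy), which is what makes
# repeated PC testing affordable.

make_ci_source <- function(data, schema = NULL, method = c("cg_lrt", "fisher_z")) {
  method <- match.arg(method)
  if (inherits(data, "cohort_scm") || is.matrix(data)) {
    amat <- dag_amat(data)
    return(list(
      fun = function(x, y, S) dsep_oracle_ci(amat, x, y, S),
      nodes = rownames(amat), tag = "oracle"
    ))
  }
  if (inherits(data, "imputed_stack")) {
    schema <- data$schema
    preps <- lapply(data$copies, prep_ci_data, schema = schema)
    caches <- lapply(preps, function(...) new.env(parent = emptyenv()))
    M <- length(preps)
    n <- preps[[1]]$n
    fun <- function(x, y, S) {
      if (method == "fisher_z") {
        zs <- vapply(preps, fisher_z_value, numeric(1), x = x, y = y, S = S)
        qbar <- mean(zs); W <- 1 / (n - length(S) - 3); B <- var(zs)
        T_ <- W + (1 + 1 / M) * B
        stat <- abs(qbar) / sqrt(T_)
        p <- if (M == 1 || B <= .Machine$double.eps) 2 * pnorm(stat, lower.tail = FALSE)
             else 2 * pt(stat, (M - 1) * (1 + W / ((1 + 1 / M) * B))^2, lower.tail = FALSE)
        return(ci_result(stat, Inf, p, "mi_pooled:fisher_z", n))
      }
      tests <- lapply(seq_len(M), function(m) {
        cg_lrt_core(preps[[m]], x, y, S, cache = caches[[m]])
      })
      if (M == 1) { res <- tests[[1]]; res$method <- "mi_pooled:cg_lrt"; return(res) }
      d <- vapply(tests, function(t) t$statistic, numeric(1))
      k <- max(vapply(tests, function(t) t$df, numeric(1)))
      dbar <- mean(d); r <- (1 + 1 / M) * var(sqrt(d))
      if (r <= .Machine$double.eps) {
        return(ci_result(dbar / k, k, pchisq(dbar, k, lower.tail = FALSE),
                         "mi_pooled:cg_lrt", n))
      }
      D2 <- max(0, (dbar / k - (M + 1) / (M - 1) * r) / (1 + r))
      nu2 <- k^(-3 / M) * (M - 1) * (1 + 1 / r)^2
      ci_result(D2, k, pf(D2, k, nu2, lower.tail = FALSE), "mi_pooled:cg_lrt", n)
    }
    return(list(fun = fun, nodes = schema$variables$name,
                tag = paste0("mi_pooled:", method)))
  }
  # plain cohort table: complete-data test, or test-wise deletion if NAs
  data <- validate_cohort(data, schema)
  if (anyNA(data)) {
    prep <- prep_ci_data(data, schema)
    obs <- !is.na(data)
    fun <- function(x, y, S) {
      vars <- c(x, y, S)
      rows <- which(rowSums(!obs[, vars, drop = FALSE]) == 0)
      if (length(rows) < length(S) + 5) {
        return(ci_result(NA_real_, NA_real_, NA_real_,
                         paste0("twd:", method, ":untestable"), length(rows),
                         "untestable"))
      }
      res <- if (method == "cg_lrt") cg_lrt_core(prep, x, y, S, rows = rows)
             else fisher_z_core(prep, x, y, S, rows = rows)
      res$method <- paste0("twd:", method)
      res
    }
    return(list(fun = fun, nodes = schema$variables$name,
                tag = paste0("twd:", method)))
  }
  prep <- prep_ci_data(data, schema)
  cache <- new.env(parent = emptyenv())
  fun <- if (method == "cg_lrt") {
    function(x, y, S) cg_lrt_core(prep, x, y, S, cache = cache)
  } else {
    function(x, y, S) fisher_z_core(prep, x, y, S)
  }
  list(fun = fun, nodes = schema$variables$name, tag = method)
}
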