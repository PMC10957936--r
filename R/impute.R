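#' Multiple imputation by chained equations
#'
#' Missing cells are first initialised by random draws from each column's
#' observed marginal; the variables are then cycled in schema order for
#' `iterations` sweeps. In each sweep the conditional model of a variable
#' given all others is refitted on the rows where that variable was
#' observed (using current completed values of the predictors) and the
#' variable's missing cells are redrawn from the fitted model. The whole
#' procedure is repeated independently `M` times.
#'
#' Two conditional-model families are available. `"parametric"`: linear
#' regression with Gaussian noise draws for continuous targets,
#' (multinomial-)logistic draws for categorical targets. `"tree"`: a single
#' regression/classification tree (`rpart`) with leaf-wise donor draws --
#' a missing cell receives the observed value of a randomly chosen donor
#' from its terminal leaf.
#'
#' @param data Cohort tibble with missing cells.
#' @param schema Its [tier_schema()].
#' @param M Number of completed copies (>= 1).
#' @param iterations Number of chained-equation sweeps per copy.
#' @param model `"tree"` (default) or `"parametric"`.
#' @param seed Integer seed; identical inputs give an identical stack.
#' @return An `imputed_stack`: list with `copies` (M complete tibbles
#'   sharing all observed cells with the input), `schema`, and provenance.
#' @export
impute_chained <- function(data, schema, M = 10, iterations = 10,
                           model = c("tree", "parametric"), seed = 1) {
  model <- match.arg(model)
  stopifnot(M >= 1, iterations >= 1)
  data <- validate_cohort(data, schema)
  all_missing <- names(data)[vapply(data, function(c) all(is.na(c)), logical(1))]
  if (length(all_missing)) {
    abort(sprintf("column(s) entirely missing, cannot impute: %s",
                  paste(all_missing, collapse = ", ")))
  }
  copies <- lapply(seq_len(M), function(m) {
    with_seed(sub_seed(seed, m), impute_once(data, schema, iterations, model))
  })
  structure(
    list(copies = copies, schema = schema,
         provenance = list(seed = seed, M = M, iterations = iterations,
                           model = model)),
    class = "imputed_stack"
  )
}

#' Single imputation
#'
#' [impute_chained()] with `M = 1`, returning the completed table itself;
#' this is the imputation used inside each bootstrap replicate.
#'
#' @inheritParams impute_chained
#' @return A complete cohort tibble.
#' @export
impute_single <- function(data, schema, model = c("tree", "parametric"),
                          iterations = 10, seed = 1) {
  model <- match.arg(model)
  stack <- impute_chained(data, schema, M = 1, iterations = iterations,
                          model = model, seed = seed)
  stack$copies[[1]]
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> M = %d copies of %d x %d (model = %s, %d sweeps, seed %s)\n",
              length(x$copies), nrow(x$copies[[1]]), ncol(x$copies[[1]]),
              x$provenance$model, x$provenance$iterations, x$provenance$seed))
  invisible(x)
}

impute_once <- function(data, schema, iterations, model) {
  mask <- is.na(data)
  targets <- names(data)[colSums(mask) > 0]
  if (!length(targets)) return(data)
  comp <- data
  # marginal initialisation
  for (nm in targets) {
    obs <- comp[[nm]][!mask[, nm]]
    comp[[nm]][mask[, nm]] <- sample(obs, sum(mask[, nm]), replace = TRUE)
  }
  kinds <- schema_kinds(schema)
  for (it in seq_len(iterations)) {
    for (nm in targets) {
      obs <- !mask[, nm]; mis <- mask[, nm]
      others <- setdiff(names(comp), nm)
      if (model == "parametric") {
        comp[[nm]][mis] <- draw_parametric(comp, schema, nm, others, obs, mis, kinds)
      } else {
        comp[[nm]][mis] <- draw_tree(comp, nm, others, obs, mis, kinds)
      }
    }
  }
  comp
}

draw_parametric <- function(comp, schema, nm, others, obs, mis, kinds) {
  X <- cbind(1, code_parents(comp, others, schema))
  if (kinds[[nm]] == "continuous") {
    # proper Bayesian draws: sigma^2 from its scaled inverse-chi-square,
    # beta from N(beta_hat, sigma^2 (X'X)^-1) -- without them the pooled
    # between-imputation variance is understated and Rubin's rules
    # anticonservative
    y <- comp[[nm]]
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    rank <- fit$rank
    dfres <- max(1, sum(obs) - rank)
    sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, dfres)
    piv <- fit$qr$pivot[seq_len(rank)]
    Rmat <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
    beta[piv] <- beta[piv] +
      sqrt(sigma2) * backsolve(Rmat, rnorm(rank))
    drop(X[mis, , drop = FALSE] %*% beta) + rnorm(sum(mis), 0, sqrt(sigma2))
  } else {
    y <- comp[[nm]]
    lv <- levels(y)
    if (length(lv) == 2) {
      y01 <- as.integer(y) - 1L
      fit <- suppressWarnings(
        stats::glm.fit(X[obs, , drop = FALSE], y01[obs],
                       family = stats::binomial())
      )
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pm <- stats::plogis(drop(X[mis, , drop = FALSE] %*% beta))
      factor(lv[1L + (runif(sum(mis)) < pm)], levels = lv)
    } else {
      df <- data.frame(.y = y, X[, -1, drop = FALSE])
      fit <- suppressWarnings(
        nnet::multinom(.y ~ ., data = df[obs, , drop = FALSE],
                       trace = FALSE, maxit = 200)
      )
      pm <- predict(fit, newdata = df[mis, , drop = FALSE], type = "probs")
      if (is.null(dim(pm))) pm <- matrix(pm, nrow = sum(mis))
      # multinom may drop unobserved response levels; map columns back
      cols <- colnames(pm) %||% levels(droplevels(y[obs]))
      draw_from_probs(pm, cols, lv)
    }
  }
}

draw_tree <- function(comp, nm, others, obs, mis, kinds) {
  df <- data.frame(.y = comp[[nm]], comp[others], check.names = TRUE)
  method <- if (kinds[[nm]] == "continuous") "anova" else "class"
  fit <- rpart::rpart(.y ~ ., data = df[obs, , drop = FALSE], method = method,
                      control = rpart::rpart.control(cp = 0.01, minbucket = 5,
                                                     xval = 0))
  # leaf assignment via the (leaf-constant) prediction signature
  pred_all <- predict(fit, newdata = df)
  sig <- if (is.matrix(pred_all)) {
    apply(round(pred_all, 12), 1, paste, collapse = "|")
  } else as.character(round(pred_all, 12))
  sig_obs <- sig[obs]; sig_mis <- sig[mis]
  y_obs <- comp[[nm]][obs]
  out <- comp[[nm]][mis]
  for (s in unique(sig_mis)) {
    donors <- y_obs[sig_obs == s]
    if (!length(donors)) donors <- y_obs  # unseen leaf: fall back to marginal
    take <- sig_mis == s
    out[take] <- sample(donors, sum(take), replace = TRUE)
  }
  out
}

draw_from_probs <- function(pm, prob_levels, lv) {
  n <- nrow(pm)
  pm <- pm / rowSums(pm)
  u <- runif(n)
  cum <- t(apply(pm, 1, cumsum))
  pick <- rowSums(u > cum) + 1L
  factor(prob_levels[pick], levels = lv)
}
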