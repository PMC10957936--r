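# Tier-constrained PC-stable structure search and MPDAG orientation.

#' PC-stable skeleton search with tiered background knowledge
#'
#' Order-independent (PC-stable) edge deletion: starting from the complete
#' graph, at level `l = 0, 1, 2, ...` the adjacency sets are frozen and,
#' for every adjacent pair `(x, y)` scanned in lexicographic name order,
#' conditioning sets of size `l` are drawn first from `adj(x) \ {y}`, then
#' from `adj(y) \ {x}` (subsets in lexicographic order). Candidate
#' conditioning variables are restricted to tiers no later than
#' `max(tier(x), tier(y))` -- conditioning on the future is never useful
#' under the temporal ordering and skipping it saves tests. The edge is
#' removed, and the pair's separating set recorded, at the first set whose
#' test exceeds `alpha`; an untestable result (see [twd_ci()]) never
#' removes an edge.
#'
#' @param ci A CI source as built internally by [run_tpc()] -- a list with
#'   elements `fun(x, y, S)` returning a `ci_test` -- or a bare function
#'   with that signature.
#' @param schema A [tier_schema()].
#' @param alpha Nominal level of the conditional-independence tests.
#' @param max_cond Optional cap on the conditioning-set size.
#' @param keep_log Record every test performed?
#' @return List with `skeleton` (an all-undirected [mpdag()]), `sepsets`
#'   (named list keyed `"x|y"`, each with `S` and `p`), `log` (tibble of
#'   tests, or `NULL`), and `n_tests`.
#' @export
pc_skeleton <- function(ci, schema, alpha, max_cond = Inf, keep_log = FALSE) {
  if (is.function(ci)) ci <- list(fun = ci, tag = "custom")
  stopifnot(alpha > 0, alpha < 1)
  nodes <- schema$variables$name
  tiers <- schema_tiers(schema)
  p <- length(nodes)
  adj <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- list()
  log_rows <- if (keep_log) vector("list", 0) else NULL
  n_tests <- 0L
  sorted_nodes <- sort(nodes)
  l <- 0L
  repeat {
    frozen <- adj
    any_candidates <- FALSE
    for (xi in seq_len(p - 1)) {
      for (yi in (xi + 1):p) {
        x <- sorted_nodes[xi]; y <- sorted_nodes[yi]
        if (!adj[x, y]) next
        tmax <- max(tiers[[x]], tiers[[y]])
        removed <- FALSE
        for (side in list(c(x, y), c(y, x))) {
          a <- side[1]; b <- side[2]
          cand <- sort(names(which(frozen[a, ])))
          cand <- cand[cand != b & tiers[cand] <= tmax]
          if (length(cand) < l) next
          any_candidates <- TRUE
          if (l == 0L) {
            subsets <- list(character())
          } else {
            subsets <- utils::combn(cand, l, simplify = FALSE)
          }
          for (S in subsets) {
            res <- tryCatch(ci$fun(a, b, S), error = function(e) {
              abort(sprintf("CI test failed for (%s, %s | %s): %s",
                            a, b, paste(S, collapse = ","), conditionMessage(e)))
            })
            n_tests <- n_tests + 1L
            if (keep_log) {
              log_rows[[length(log_rows) + 1L]] <- tibble(
                x = a, y = b, S = paste(S, collapse = ","),
                p_value = res$p_value, method = res$method,
                n_effective = res$n_effective
              )
            }
            if (!is.na(res$p_value) && res$p_value > alpha) {
              adj[x, y] <- FALSE; adj[y, x] <- FALSE
              key <- paste(sort(c(x, y)), collapse = "|")
              sepsets[[key]] <- list(S = S, p = res$p_value)
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
    }
    l <- l + 1L
    if (l > max_cond) break
    # continue while some pair could still draw a conditioning set of size l
    sizes_ok <- FALSE
    for (xi in seq_len(p - 1)) {
      for (yi in (xi + 1):p) {
        x <- nodes[xi]; y <- nodes[yi]
        if (!adj[x, y]) next
        tmax <- max(tiers[[x]], tiers[[y]])
        for (side in list(c(x, y), c(y, x))) {
          cand <- names(which(adj[side[1], ]))
          cand <- cand[cand != side[2] & tiers[cand] <= tmax]
          if (length(cand) >= l) { sizes_ok <- TRUE; break }
        }
        if (sizes_ok) break
      }
      if (sizes_ok) break
    }
    if (!sizes_ok) break
  }
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  amat[adj] <- 1L
  list(
    skeleton = new_mpdag(amat, tiers),
    sepsets = sepsets,
    log = if (keep_log) dplyr::bind_rows(log_rows) else NULL,
    n_tests = n_tests
  )
}

#' Orient a PC skeleton into an MPDAG
#'
#' Three orientation phases: (1) background knowledge -- every cross-tier
#' edge is directed from the earlier tier, and an edge one of whose
#' directions is forbidden is directed the allowed way; these arrowheads
#' are fixed. (2) v-structures -- for every unshielded triple `x - z - y`
#' the collider `x -> z <- y` is oriented iff `z` is not in the recorded
#' separating set of `(x, y)`; an arrowhead that would point back in time,
#' follow a forbidden orientation or overturn a fixed arrowhead is skipped
#' and logged, and contradictory double arrowheads between data-driven
#' v-structures are downgraded to undirected and logged. (3) Meek rules
#' R1-R4, with background-knowledge edges treated as fixed, applied to a
#' fixed point; each rule application passes the same legality guard.
#'
#' @param skeleton All-undirected [mpdag()] from [pc_skeleton()].
#' @param sepsets Separating sets as returned by [pc_skeleton()].
#' @param schema A [tier_schema()].
#' @return An [mpdag()]; its `log` element records skipped or downgraded
#'   orientations.
#' @export
orient_mpdag <- function(skeleton, sepsets, schema) {
  nodes <- skeleton$nodes
  tiers <- schema_tiers(schema)[nodes]
  p <- length(nodes)
  amat <- skeleton$amat
  skel <- skeleton_amat(skeleton)
  forb <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(schema$forbidden)) {
    for (k in seq_len(nrow(schema$forbidden))) {
      forb[schema$forbidden$from[k], schema$forbidden$to[k]] <- TRUE
    }
  }
  fixed <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  conflicted <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  log <- character()

  # --- phase 1: background knowledge ---------------------------------------
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i >= j || !skel[i, j]) next
      ti <- tiers[i]; tj <- tiers[j]
      if (ti != tj) {
        from <- if (ti < tj) i else j
        to <- if (ti < tj) j else i
        if (forb[from, to]) {
          log <- c(log, sprintf(
            "background conflict: %s -> %s required by tiers but forbidden; left undirected",
            nodes[from], nodes[to]))
          conflicted[i, j] <- conflicted[j, i] <- TRUE
        } else {
          amat[to, from] <- 0L
          fixed[from, to] <- TRUE
        }
      } else if (forb[i, j] || forb[j, i]) {
        if (forb[i, j] && forb[j, i]) {
          log <- c(log, sprintf("both orientations of %s - %s forbidden; left undirected",
                                nodes[i], nodes[j]))
          conflicted[i, j] <- conflicted[j, i] <- TRUE
        } else {
          from <- if (forb[i, j]) j else i
          to <- if (forb[i, j]) i else j
          amat[to, from] <- 0L
          fixed[from, to] <- TRUE
        }
      }
    }
  }

  is_directed <- function(u, v) amat[u, v] == 1L && amat[v, u] == 0L
  is_und <- function(u, v) amat[u, v] == 1L && amat[v, u] == 1L

  # legality guard shared by v-structure and Meek orientations
  try_orient <- function(u, v, why) {
    if (!is_und(u, v)) return(FALSE)
    if (conflicted[u, v]) return(FALSE)
    if (tiers[u] > tiers[v]) {
      log <<- c(log, sprintf("%s: skipped %s -> %s (points back in time)",
                             why, nodes[u], nodes[v]))
      return(FALSE)
    }
    if (forb[u, v]) {
      log <<- c(log, sprintf("%s: skipped %s -> %s (forbidden)", why,
                             nodes[u], nodes[v]))
      return(FALSE)
    }
    amat[v, u] <<- 0L
    d <- amat == 1L & t(amat) == 0L
    if (has_directed_cycle(d)) {
      amat[v, u] <<- 1L
      log <<- c(log, sprintf("%s: skipped %s -> %s (would create a cycle)",
                             why, nodes[u], nodes[v]))
      return(FALSE)
    }
    TRUE
  }

  # --- phase 2: v-structures ------------------------------------------------
  ord <- order(nodes)
  for (zi in ord) {
    nb <- which(skel[zi, ])
    nb <- nb[order(nodes[nb])]
    if (length(nb) < 2) next
    for (ai in seq_len(length(nb) - 1)) {
      for (bi in (ai + 1):length(nb)) {
        x <- nb[ai]; y <- nb[bi]
        if (skel[x, y]) next
        key <- paste(sort(c(nodes[x], nodes[y])), collapse = "|")
        ss <- sepsets[[key]]
        if (is.null(ss)) next
        if (nodes[zi] %in% ss$S) next
        for (u in c(x, y)) {
          if (is_directed(u, zi)) next
          if (is_directed(zi, u)) {
            if (fixed[zi, u]) {
              log <- c(log, sprintf(
                "v-structure %s -> %s <- %s: skipped arrowhead %s -> %s (fixed opposite)",
                nodes[x], nodes[zi], nodes[y], nodes[u], nodes[zi]))
            } else {
              amat[u, zi] <- 1L
              conflicted[u, zi] <- conflicted[zi, u] <- TRUE
              log <- c(log, sprintf(
                "conflicting arrowheads on %s - %s: downgraded to undirected",
                nodes[u], nodes[zi]))
            }
            next
          }
          try_orient(u, zi, sprintf("v-structure %s -> %s <- %s",
                                    nodes[x], nodes[zi], nodes[y]))
        }
      }
    }
  }

  # --- phase 3: Meek rules R1-R4 to a fixed point ---------------------------
  repeat {
    changed <- FALSE
    dmat <- amat == 1L & t(amat) == 0L
    umat <- amat == 1L & t(amat) == 1L
    # R1: a -> b - c, a and c nonadjacent  =>  b -> c
    for (b in seq_len(p)) {
      as_ <- which(dmat[, b])
      if (!length(as_)) next
      for (c_ in which(umat[b, ])) {
        if (any(!skel[as_, c_] & as_ != c_)) {
          if (try_orient(b, c_, "Meek R1")) changed <- TRUE
        }
      }
    }
    if (changed) next
    # R2: a -> b -> c with a - c  =>  a -> c
    for (a in seq_len(p)) {
      for (c_ in which(umat[a, ])) {
        through <- which(dmat[a, ] & dmat[, c_])
        if (length(through)) {
          if (try_orient(a, c_, "Meek R2")) changed <- TRUE
        }
      }
    }
    if (changed) next
    # R3: a - b with a - c -> b, a - d -> b, c and d nonadjacent  =>  a -> b
    for (a in seq_len(p)) {
      for (b in which(umat[a, ])) {
        cs <- which(umat[a, ] & dmat[, b])
        if (length(cs) < 2) next
        found <- FALSE
        for (ci_ in seq_len(length(cs) - 1)) {
          for (di in (ci_ + 1):length(cs)) {
            if (!skel[cs[ci_], cs[di]]) { found <- TRUE; break }
          }
          if (found) break
        }
        if (found && try_orient(a, b, "Meek R3")) changed <- TRUE
      }
    }
    if (changed) next
    # R4: a - b, a - c, c -> d, d -> b, b and c nonadjacent  =>  a -> b
    for (a in seq_len(p)) {
      for (b in which(umat[a, ])) {
        found <- FALSE
        for (c_ in which(umat[a, ])) {
          if (c_ == b || skel[b, c_]) next
          if (any(dmat[c_, ] & dmat[, b])) { found <- TRUE; break }
        }
        if (found && try_orient(a, b, "Meek R4")) changed <- TRUE
      }
    }
    if (!changed) break
  }

  new_mpdag(amat, tiers, log = log)
}

#' Tiered PC: learn an MPDAG from cohort data
#'
#' Wires a conditional-independence source appropriate for the data --
#' complete-data tests for a complete table, test-wise deletion for a table
#' with missing cells, pooled tests for an [impute_chained()] stack, or the
#' d-separation oracle for a `cohort_scm`/DAG -- into [pc_skeleton()]
#' followed by [orient_mpdag()].
#'
#' @param data A cohort tibble, an `imputed_stack`, or (for oracle runs) a
#'   `cohort_scm` or DAG adjacency matrix.
#' @param schema A [tier_schema()]; taken from the stack when omitted.
#' @param alpha Nominal test level (default 0.05).
#' @param test `"cg_lrt"` (mixed-data likelihood ratio, default) or
#'   `"fisher_z"` (all-continuous).
#' @param max_cond Optional cap on conditioning-set size.
#' @param keep_log Record every CI test performed (pair, set, p-value)?
#' @return A `tpc_result`: list with `graph` (the [mpdag()]), `sepsets`
#'   tibble, `log` tibble (or `NULL`), `n_tests`, `alpha`, `test`.
#' @examples
#' scm <- demo_scm_mediation()
#' fit <- run_tpc(scm, scm$schema, alpha = 0.05)  # oracle run
#' mpdag_edges(fit$graph)
#' @export
run_tpc <- function(data, schema = NULL, alpha = 0.05,
                    test = c("cg_lrt", "fisher_z"), max_cond = Inf,
                    keep_log = TRUE) {
  test <- match.arg(test)
  if (inherits(data, "imputed_stack")) schema <- data$schema
  if (inherits(data, "cohort_scm") && is.null(schema)) schema <- data$schema
  if (is.null(schema)) abort("`schema` is required")
  src <- make_ci_source(data, schema, method = test)
  sk <- pc_skeleton(src, schema, alpha, max_cond = max_cond, keep_log = keep_log)
  g <- orient_mpdag(sk$skeleton, sk$sepsets, schema)
  sep_tbl <- purrr::imap_dfr(sk$sepsets, function(ss, key) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    tibble(x = pair[1], y = pair[2], S = paste(ss$S, collapse = ","), p_value = ss$p)
  })
  structure(
    list(graph = g, sepsets = sep_tbl, sepset_map = sk$sepsets, log = sk$log,
         n_tests = sk$n_tests, alpha = alpha, test = src$tag),
    class = "tpc_result"
  )
}

#' @export
print.tpc_result <- function(x, ...) {
  e <- mpdag_edges(x$graph)
  cat(sprintf("<tpc_result> %d nodes, %d edges (%d undirected); %d CI tests (%s, alpha = %g)\n",
              length(x$graph$nodes), nrow(e), sum(e$mark == "undirected"),
              x$n_tests, x$test, x$alpha))
  invisible(x)
}
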