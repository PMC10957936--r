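# Independent brute-force oracles used to validate the implementation.
# Everything here is deliberately naive: path enumeration, exhaustive
# orientation enumeration, closed forms -- no code shared with R/.

# all simple paths between x and y in the skeleton of a directed amat
bf_all_skeleton_paths <- function(amat, x, y) {
  nodes <- rownames(amat)
  sk <- (amat != 0) | (t(amat) != 0)
  paths <- list()
  walk <- function(v, trail) {
    for (w in nodes[sk[v, ]]) {
      if (w %in% trail) next
      if (w == y) paths[[length(paths) + 1L]] <<- c(trail, w)
      else walk(w, c(trail, w))
    }
  }
  walk(x, x)
  paths
}

bf_descendants <- function(amat, v) {
  nodes <- rownames(amat)
  out <- v
  repeat {
    nxt <- nodes[colSums(amat[out, , drop = FALSE] != 0) > 0]
    new <- setdiff(nxt, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

# d-separation by enumerating every simple path and its blocking status
bf_dsep <- function(amat, x, y, S = character()) {
  paths <- bf_all_skeleton_paths(amat, x, y)
  for (pp in paths) {
    blocked <- FALSE
    if (length(pp) > 2) {
      for (i in 2:(length(pp) - 1)) {
        a <- pp[i - 1]; v <- pp[i]; b <- pp[i + 1]
        collider <- amat[a, v] != 0 && amat[b, v] != 0
        if (collider) {
          if (!any(bf_descendants(amat, v) %in% S)) { blocked <- TRUE; break }
        } else if (v %in% S) { blocked <- TRUE; break }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

bf_is_acyclic <- function(amat) {
  n <- nrow(amat); reach <- (amat != 0)
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  !any(diag(reach))
}

# canonical string set of unshielded colliders of a DAG amat
bf_vstructs <- function(amat) {
  nodes <- rownames(amat)
  sk <- (amat != 0) | (t(amat) != 0)
  out <- character()
  for (z in nodes) {
    pa <- nodes[amat[, z] != 0]
    if (length(pa) < 2) next
    for (i in seq_len(length(pa) - 1)) for (j in (i + 1):length(pa)) {
      if (!sk[pa[i], pa[j]]) {
        pr <- sort(c(pa[i], pa[j]))
        out <- c(out, paste(pr[1], z, pr[2]))
      }
    }
  }
  sort(out)
}

# True MPDAG by exhaustive enumeration: all orientations of the skeleton
# that are acyclic, preserve the DAG's unshielded colliders, respect the
# tier order, and avoid forbidden orientations; an edge is directed in the
# MPDAG iff all such DAGs agree, undirected otherwise.
bf_true_mpdag <- function(amat, tiers, forbidden = NULL) {
  nodes <- rownames(amat)
  sk <- (amat != 0) | (t(amat) != 0)
  idx <- which(sk & upper.tri(sk), arr.ind = TRUE)
  E <- nrow(idx)
  truth_vs <- bf_vstructs(amat)
  forb <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  if (!is.null(forbidden) && nrow(forbidden)) {
    for (k in seq_len(nrow(forbidden))) forb[forbidden$from[k], forbidden$to[k]] <- TRUE
  }
  # allowed orientations per edge under tiers + forbidden
  choices <- lapply(seq_len(E), function(k) {
    a <- nodes[idx[k, 1]]; b <- nodes[idx[k, 2]]
    dirs <- list(c(a, b), c(b, a))
    keep <- vapply(dirs, function(d) {
      tiers[[d[1]]] <= tiers[[d[2]]] && !forb[d[1], d[2]]
    }, logical(1))
    dirs[keep]
  })
  members <- list()
  rec <- function(k, cur) {
    if (k > E) {
      if (bf_is_acyclic(cur) && identical(bf_vstructs(cur), truth_vs)) {
        members[[length(members) + 1L]] <<- cur
      }
      return()
    }
    for (d in choices[[k]]) {
      nxt <- cur
      nxt[d[1], d[2]] <- 1L
      rec(k + 1L, nxt)
    }
  }
  empty <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  rec(1L, empty)
  stopifnot(length(members) >= 1)
  out <- empty
  for (k in seq_len(E)) {
    a <- nodes[idx[k, 1]]; b <- nodes[idx[k, 2]]
    ab <- all(vapply(members, function(m) m[a, b] == 1L, logical(1)))
    ba <- all(vapply(members, function(m) m[b, a] == 1L, logical(1)))
    if (ab) out[a, b] <- 1L
    else if (ba) out[b, a] <- 1L
    else { out[a, b] <- 1L; out[b, a] <- 1L }
  }
  out
}

# all DAGs on given node names: every assignment of {none, ->, <-} to each
# pair, filtered for acyclicity
bf_all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  E <- nrow(pairs)
  out <- list()
  states <- rep(0L, E)
  rec <- function(k, cur) {
    if (k > E) {
      if (bf_is_acyclic(cur)) out[[length(out) + 1L]] <<- cur
      return()
    }
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rec(k + 1L, cur)
    c1 <- cur; c1[i, j] <- 1L; rec(k + 1L, c1)
    c2 <- cur; c2[j, i] <- 1L; rec(k + 1L, c2)
  }
  rec(1L, matrix(0L, p, p, dimnames = list(nodes, nodes)))
  out
}

# random tiering consistent with a DAG: random valid topological order,
# cut into tiers at random positions
bf_random_tiers <- function(amat, n_tiers, seed) {
  nodes <- rownames(amat)
  withr::with_seed(seed, {
    remaining <- nodes
    ord <- character()
    a <- amat
    while (length(remaining)) {
      src <- remaining[colSums(a[remaining, remaining, drop = FALSE] != 0) == 0]
      pick <- sample(src, 1)
      ord <- c(ord, pick)
      remaining <- setdiff(remaining, pick)
    }
    cuts <- sort(sample(0:length(nodes), n_tiers - 1, replace = TRUE))
    tiers <- setNames(rowSums(outer(seq_along(ord), cuts, ">")), ord)
  })
  tiers[nodes]
}

# random tiered DAG drawn independently of the package's generator
bf_random_tiered_dag <- function(p, n_tiers, edge_prob, seed) {
  nodes <- sprintf("v%02d", seq_len(p))
  withr::with_seed(seed, {
    ord <- sample(nodes)
    tiers <- setNames(sort(sample(0:(n_tiers - 1), p, replace = TRUE)), ord)
    amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (runif(1) < edge_prob) amat[ord[i], ord[j]] <- 1L
    }
  })
  list(amat = amat, tiers = tiers[nodes])
}

# schema of all-continuous variables from a tier vector
schema_from_tiers <- function(tiers, forbidden = NULL) {
  tier_schema(
    tibble::tibble(name = names(tiers), kind = "continuous",
                   tier = unname(tiers), levels = list(NULL)),
    tiers = paste0("t", seq_len(max(tiers) + 1)) ,
    forbidden = forbidden
  )
}

# random marked graph (not necessarily a valid MPDAG) for metric tests
rand_marked_graph <- function(nodes, seed, p_edge = 0.35) {
  withr::with_seed(seed, {
    edges <- list()
    for (i in seq_len(length(nodes) - 1)) for (j in (i + 1):length(nodes)) {
      if (runif(1) < p_edge) {
        mk <- sample(c("fw", "bw", "und"), 1)
        edges[[length(edges) + 1]] <- switch(mk,
          fw = tibble::tibble(from = nodes[i], to = nodes[j], mark = "directed"),
          bw = tibble::tibble(from = nodes[j], to = nodes[i], mark = "directed"),
          und = tibble::tibble(from = nodes[i], to = nodes[j], mark = "undirected"))
      }
    }
    mpdag(nodes, dplyr::bind_rows(edges))
  })
}

mpdag_amat_equal <- function(g, amat) {
  identical(unname(g$amat[rownames(amat), colnames(amat)]), unname(amat))
}
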