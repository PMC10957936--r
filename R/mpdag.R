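#' Partially directed graphs with directed and undirected edge marks
#'
#' An `mpdag` stores the output of constraint-based discovery: a graph over
#' named nodes in which each edge is either directed (`a -> b`) or
#' undirected (`a -- b`). Internally the graph is an integer adjacency
#' matrix `amat` with `amat[a, b] == 1, amat[b, a] == 0` for `a -> b` and
#' both entries 1 for an undirected edge. An optional named tier vector
#' records the temporal background knowledge the graph was learned under.
#'
#' @param nodes Character vector of node names.
#' @param edges Data frame with columns `from`, `to`, `mark`
#'   (`"directed"` or `"undirected"`); may be empty or `NULL`.
#' @param tiers Optional named integer vector of tier indices.
#' @return An object of class `mpdag`.
#' @examples
#' g <- mpdag(c("a", "b", "c"),
#'            tibble::tibble(from = c("a", "b"), to = c("b", "c"),
#'                           mark = c("directed", "undirected")))
#' tidy(g)
#' @export
mpdag <- function(nodes, edges = NULL, tiers = NULL) {
  p <- length(nodes)
  if (anyDuplicated(nodes)) abort("node names must be unique")
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(edges)) {
    if (!"mark" %in% names(edges)) edges$mark <- "directed"
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      if (!a %in% nodes || !b %in% nodes) abort("edge endpoint not a node")
      if (a == b) abort("self-loops are not allowed")
      if (identical(edges$mark[k], "undirected")) {
        amat[a, b] <- 1L; amat[b, a] <- 1L
      } else {
        if (amat[b, a] == 1L && amat[a, b] == 0L) abort("pair carries two marks")
        amat[a, b] <- 1L
      }
    }
  }
  new_mpdag(amat, tiers)
}

new_mpdag <- function(amat, tiers = NULL, log = NULL) {
  structure(list(nodes = rownames(amat), amat = amat, tiers = tiers,
                 log = log), class = "mpdag")
}

#' @export
print.mpdag <- function(x, ...) {
  e <- mpdag_edges(x)
  cat(sprintf("<mpdag> %d nodes, %d edges (%d undirected)\n",
              length(x$nodes), nrow(e), sum(e$mark == "undirected")))
  invisible(x)
}

#' Edge table of an mpdag
#'
#' One row per edge; undirected edges are listed once with
#' lexicographically smaller endpoint first.
#'
#' @param g An `mpdag`.
#' @return A tibble with columns `from`, `to`, `mark`.
#' @export
mpdag_edges <- function(g) {
  a <- g$amat
  dir_idx <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  und_idx <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  out <- dplyr::bind_rows(
    tibble(from = rownames(a)[dir_idx[, 1]], to = colnames(a)[dir_idx[, 2]],
           mark = rep("directed", nrow(dir_idx))),
    tibble(from = rownames(a)[und_idx[, 1]], to = colnames(a)[und_idx[, 2]],
           mark = rep("undirected", nrow(und_idx)))
  )
  dplyr::arrange(out, .data$mark == "undirected", .data$from, .data$to)
}

# skeleton adjacency (logical, symmetric)
skeleton_amat <- function(g) {
  (g$amat == 1L) | (t(g$amat) == 1L)
}

# directed part only: d[a,b] TRUE iff a -> b
directed_amat <- function(g) {
  g$amat == 1L & t(g$amat) == 0L
}

#' Check the structural invariants of an mpdag
#'
#' Verifies that no directed cycle exists among the directed edges, that no
#' edge points from a later tier into an earlier one, that cross-tier edges
#' are directed, and that no edge follows a forbidden orientation.
#'
#' @param g An `mpdag`.
#' @param schema Optional [tier_schema()]; defaults to the tier vector
#'   stored in `g` (tier checks are skipped when neither is available).
#' @return Invisibly `TRUE`; aborts with the violations otherwise.
#' @export
validate_mpdag <- function(g, schema = NULL) {
  d <- directed_amat(g)
  if (has_directed_cycle(d)) abort("directed part of the mpdag contains a cycle")
  tiers <- if (!is.null(schema)) schema_tiers(schema) else g$tiers
  problems <- character()
  if (!is.null(tiers)) {
    e <- mpdag_edges(g)
    for (k in seq_len(nrow(e))) {
      tf <- tiers[[e$from[k]]]; tt <- tiers[[e$to[k]]]
      if (e$mark[k] == "directed" && tf > tt) {
        problems <- c(problems, sprintf("%s -> %s points back in time", e$from[k], e$to[k]))
      }
      if (e$mark[k] == "undirected" && tf != tt) {
        problems <- c(problems, sprintf("%s -- %s crosses tiers undirected", e$from[k], e$to[k]))
      }
    }
  }
  if (!is.null(schema) && nrow(schema$forbidden)) {
    for (k in seq_len(nrow(schema$forbidden))) {
      a <- schema$forbidden$from[k]; b <- schema$forbidden$to[k]
      if (g$amat[a, b] == 1L && g$amat[b, a] == 0L) {
        problems <- c(problems, sprintf("forbidden orientation %s -> %s present", a, b))
      }
    }
  }
  if (length(problems)) abort(paste(c("invalid mpdag:", problems), collapse = "\n  "))
  invisible(TRUE)
}

# cycle check on a logical directed adjacency matrix
has_directed_cycle <- function(d) {
  p <- nrow(d)
  if (p == 0 || !any(d)) return(FALSE)
  indeg <- colSums(d)
  alive <- rep(TRUE, p)
  repeat {
    src <- which(alive & indeg == 0)
    if (!length(src)) break
    for (v in src) {
      alive[v] <- FALSE
      indeg[d[v, ]] <- indeg[d[v, ]] - 1L
    }
  }
  any(alive)
}

as_igraph_skeleton <- function(g) {
  igraph::graph_from_adjacency_matrix(skeleton_amat(g) * 1, mode = "undirected")
}

#' Write / read an mpdag as GraphML
#'
#' Nodes carry a `name` attribute (and `tier` when known); every edge is
#' written as a GraphML edge with a `mark` attribute, `directed` or
#' `undirected`. `read_graphml()` restores the object exactly.
#'
#' @param g An `mpdag`.
#' @param path File path.
#' @export
write_graphml <- function(g, path) {
  e <- mpdag_edges(g)
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "mark", `for` = "edge",
                      attr.name = "mark", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "tier", `for` = "node",
                      attr.name = "tier", attr.type = "int")
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (nm in g$nodes) {
    nd <- xml2::xml_add_child(gr, "node", id = nm)
    if (!is.null(g$tiers)) {
      dt <- xml2::xml_add_child(nd, "data", key = "tier")
      xml2::xml_set_text(dt, as.character(g$tiers[[nm]]))
    }
  }
  for (k in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(gr, "edge", source = e$from[k], target = e$to[k])
    dm <- xml2::xml_add_child(ed, "data", key = "mark")
    xml2::xml_set_text(dm, e$mark[k])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- xml2::xml_attr(node_els, "id")
  tiers <- vapply(node_els, function(nd) {
    t <- xml2::xml_find_first(nd, ".//g:data[@key='tier']", ns)
    if (inherits(t, "xml_missing")) NA_integer_ else as.integer(xml2::xml_text(t))
  }, integer(1))
  tiers <- if (all(is.na(tiers))) NULL else setNames(tiers, nodes)
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- tibble(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    mark = vapply(edge_els, function(ed) {
      m <- xml2::xml_find_first(ed, ".//g:data[@key='mark']", ns)
      if (inherits(m, "xml_missing")) "directed" else xml2::xml_text(m)
    }, character(1))
  )
  mpdag(nodes, edges, tiers)
}

#' Write / read an mpdag in DOT format
#'
#' Directed edges are written `a -> b`; undirected edges `a -> b
#' [dir=none]`. The reader parses this dialect (as produced by the writer).
#'
#' @param g An `mpdag`.
#' @param path File path.
#' @export
write_dot <- function(g, path) {
  e <- mpdag_edges(g)
  lines <- c("digraph mpdag {",
             sprintf("  \"%s\";", g$nodes),
             if (nrow(e)) sprintf("  \"%s\" -> \"%s\"%s;", e$from, e$to,
                                  ifelse(e$mark == "undirected", " [dir=none]", "")),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dot
#' @export
read_dot <- function(path) {
  lines <- trimws(readLines(path))
  node_rx <- "^\"([^\"]+)\";$"
  edge_rx <- "^\"([^\"]+)\" -> \"([^\"]+)\"( \\[dir=none\\])?;$"
  nodes <- sub(node_rx, "\\1", grep(node_rx, lines, value = TRUE))
  el <- grep(edge_rx, lines, value = TRUE)
  edges <- tibble(
    from = sub(edge_rx, "\\1", el),
    to = sub(edge_rx, "\\2", el),
    mark = ifelse(grepl("dir=none", el), "undirected", "directed")
  )
  mpdag(nodes, edges)
}

#' Write / read an mpdag as a plain adjacency list
#'
#' One line per edge (`a -> b` or `a -- b`) plus `node a` lines for
#' isolated nodes; a `tier a k` header line per node when tiers are known.
#'
#' @param g An `mpdag`.
#' @param path File path.
#' @export
write_adjacency <- function(g, path) {
  e <- mpdag_edges(g)
  lines <- c(
    if (!is.null(g$tiers)) sprintf("tier %s %d", g$nodes, g$tiers[g$nodes]),
    sprintf("node %s", g$nodes),
    if (nrow(e)) sprintf("%s %s %s", e$from,
                         ifelse(e$mark == "directed", "->", "--"), e$to)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  tier_ln <- grep("^tier ", lines, value = TRUE)
  node_ln <- grep("^node ", lines, value = TRUE)
  edge_ln <- setdiff(lines, c(tier_ln, node_ln))
  nodes <- sub("^node ", "", node_ln)
  tiers <- NULL
  if (length(tier_ln)) {
    parts <- strsplit(sub("^tier ", "", tier_ln), " ")
    tiers <- setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                      vapply(parts, `[`, character(1), 1))
  }
  edges <- purrr::map_dfr(strsplit(edge_ln, " "), function(p) {
    tibble(from = p[1], to = p[3],
           mark = if (p[2] == "--") "undirected" else "directed")
  })
  mpdag(nodes, edges, tiers)
}
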