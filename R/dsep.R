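# d-separation on a DAG via reachability in the moralised ancestral graph.

# amat: integer/logical matrix, amat[a,b] != 0 means a -> b
d_separated <- function(amat, x, y, S = character()) {
  nodes <- rownames(amat)
  stopifnot(all(c(x, y, S) %in% nodes))
  a <- amat != 0
  # ancestors of {x, y} ∪ S (including themselves)
  frontier <- unique(c(x, y, S))
  anc <- rep(FALSE, length(nodes)); names(anc) <- nodes
  anc[frontier] <- TRUE
  repeat {
    new <- rownames(a)[rowSums(a[, anc, drop = FALSE]) > 0 & !anc]
    if (!length(new)) break
    anc[new] <- TRUE
  }
  keep <- nodes[anc]
  sub <- a[keep, keep, drop = FALSE]
  # moralise: undirect and marry parents of every common child
  und <- sub | t(sub)
  for (v in seq_along(keep)) {
    pa <- which(sub[, v])
    if (length(pa) >= 2) und[pa, pa] <- TRUE
  }
  diag(und) <- FALSE
  # remove conditioning nodes, test connectivity x ~ y
  live <- setdiff(keep, S)
  if (!(x %in% live) || !(y %in% live)) return(TRUE)
  und <- und[live, live, drop = FALSE]
  reach <- setNames(rep(FALSE, length(live)), live)
  reach[x] <- TRUE
  repeat {
    new <- live[rowSums(und[, reach, drop = FALSE]) > 0 & !reach]
    if (!length(new)) break
    reach[new] <- TRUE
  }
  !reach[[y]]
}
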