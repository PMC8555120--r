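# Independent oracles and fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pairwise-concordance AUROC (Mann-Whitney): fraction of
# (positive, negative) score pairs with pos > neg, ties counted 1/2.
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Random labeled graph in the generic form used by the fingerprint module.
rand_graph <- function(n_max = 8L, p_edge = 0.4,
                       vlabels = c("A", "B", "C"),
                       elabels = c("x", "y")) {
  n <- sample.int(n_max, 1L)
  labels <- sample(vlabels, n, replace = TRUE)
  edges <- data.frame(i = integer(), j = integer(), label = character())
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    keep <- runif(ncol(pairs)) < p_edge
    if (any(keep)) {
      edges <- data.frame(i = pairs[1L, keep], j = pairs[2L, keep],
                          label = sample(elabels, sum(keep), replace = TRUE),
                          stringsAsFactors = FALSE)
    }
  }
  list(labels = labels, edges = edges)
}

# Relabel the vertices of a generic labeled graph by permutation `perm`
# (vertex v becomes perm[v]).
permute_graph <- function(g, perm) {
  inv <- order(perm)
  e <- g$edges
  if (nrow(e)) {
    ni <- perm[e$i]
    nj <- perm[e$j]
    e$i <- pmin(ni, nj)
    e$j <- pmax(ni, nj)
    e <- e[order(e$i, e$j), , drop = FALSE]
    rownames(e) <- NULL
  }
  list(labels = g$labels[inv], edges = e)
}

# Induced subgraph of all vertices within r hops of v, vertex ids remapped
# to 1..k (BFS order). Used with igraph VF2 as the isomorphism oracle.
neighborhood_subgraph <- function(g, v, r) {
  n <- length(g$labels)
  dist <- rep(Inf, n)
  dist[v] <- 0
  frontier <- v
  for (step in seq_len(r)) {
    nxt <- integer()
    for (u in frontier) {
      nbr <- c(g$edges$j[g$edges$i == u], g$edges$i[g$edges$j == u])
      nxt <- c(nxt, nbr[dist[nbr] == Inf])
      dist[nbr[dist[nbr] == Inf]] <- step
    }
    frontier <- unique(nxt)
    if (!length(frontier)) break
  }
  keep <- which(is.finite(dist))
  remap <- match(seq_len(n), keep)
  e <- g$edges[g$edges$i %in% keep & g$edges$j %in% keep, , drop = FALSE]
  list(labels = g$labels[keep], center = remap[v],
       edges = data.frame(i = remap[e$i], j = remap[e$j], label = e$label,
                          stringsAsFactors = FALSE))
}

# Labeled-graph isomorphism (also matching the neighborhood center) via
# igraph VF2 with vertex/edge colors.
graphs_isomorphic <- function(g1, g2) {
  if (length(g1$labels) != length(g2$labels)) return(FALSE)
  lab_space <- union(g1$labels, g2$labels)
  elab_space <- union(g1$edges$label, g2$edges$label)
  build <- function(g) {
    ig <- igraph::make_empty_graph(n = length(g$labels), directed = FALSE)
    if (nrow(g$edges)) {
      ig <- igraph::add_edges(ig, rbind(g$edges$i, g$edges$j))
    }
    ig
  }
  vc <- function(g) {
    col <- match(g$labels, lab_space)
    col[g$center] <- col[g$center] + length(lab_space)  # pin the center
    col
  }
  igraph::isomorphic(build(g1), build(g2), method = "vf2",
                     vertex.color1 = vc(g1), vertex.color2 = vc(g2),
                     edge.color1 = match(g1$edges$label, elab_space),
                     edge.color2 = match(g2$edges$label, elab_space))
}

# Random rigid motion (proper rotation + translation) applied to an
# n x 3 coordinate matrix.
rigid_transform <- function(xyz) {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  t(q %*% t(xyz)) + matrix(rnorm(3L, sd = 5), nrow(xyz), 3L, byrow = TRUE)
}

# Minimal pocket residue record for building pocket graphs directly.
mk_residue <- function(resno, aa3, ca) {
  list(chain = "A", resno = resno, insert = "", aa3 = aa3, ca = ca,
       xyz = matrix(ca, 1L, 3L))
}

# Small trained-model fixture shared by training/prediction tests.
small_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_split(60, 20, planted_rule(), seed = 4242,
                               n_pockets = 12L, n_compounds = 24L)
    }
    cache
  }
})
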