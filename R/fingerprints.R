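# r-radius subgraph fingerprints and vocabularies.
#
# A vertex fingerprint at radius r canonically identifies the subgraph of
# all vertices/edges within r hops, computed by iterative sorted-multiset
# neighborhood relabeling (Weisfeiler-Lehman refinement): isomorphic
# neighborhoods get identical fingerprints, and the partition at radius r+1
# refines the one at radius r. Fingerprints are stable readable strings,
# never platform-dependent hashes.

#' Convert a graph to the generic labeled-graph form
#'
#' Internal bridge used by the fingerprint machinery: a list with `labels`
#' (character per vertex) and `edges` (data frame `i`, `j`, `label`).
#'
#' @param x a [molecular_graph()] or a `pocket_graph`.
#' @return plain labeled-graph list.
#' @export
as_labeled_graph <- function(x) UseMethod("as_labeled_graph")

#' @export
as_labeled_graph.molecular_graph <- function(x) {
  e <- x$edges
  list(labels = x$vertex_labels,
       edges = data.frame(i = e$i, j = e$j, label = e$bond,
                          stringsAsFactors = FALSE))
}

#' @export
as_labeled_graph.pocket_graph <- function(x) {
  e <- x$edges
  list(labels = x$residues$aa3,
       edges = data.frame(i = e$i, j = e$j, label = e$class,
                          stringsAsFactors = FALSE))
}

#' @export
as_labeled_graph.default <- function(x) {
  stopifnot(is.list(x), !is.null(x$labels), !is.null(x$edges))
  x
}

.adjacency_lists <- function(n, edges) {
  nbr <- vector("list", n)
  elab <- vector("list", n)
  if (nrow(edges)) {
    di <- c(edges$i, edges$j)
    dj <- c(edges$j, edges$i)
    dl <- c(edges$label, edges$label)
    o <- order(di)
    di <- di[o]; dj <- dj[o]; dl <- dl[o]
    runs <- split(seq_along(di), factor(di, levels = seq_len(n)))
    for (v in seq_len(n)) {
      nbr[[v]] <- dj[runs[[v]]]
      elab[[v]] <- dl[runs[[v]]]
    }
  }
  list(nbr = nbr, elab = elab)
}

#' Vertex fingerprints at radius r for every vertex
#'
#' Radius 0 is the vertex's own label; each refinement step extends a
#' fingerprint with the lexicographically sorted multiset of
#' (incident edge label, neighbor's previous fingerprint) pairs.
#'
#' @param graph a graph accepted by [as_labeled_graph()].
#' @param r non-negative integer radius (number of hops).
#' @return character vector, one fingerprint per vertex.
#' @export
vertex_fingerprints <- function(graph, r) {
  stopifnot(length(r) == 1L, r >= 0)
  g <- as_labeled_graph(graph)
  n <- length(g$labels)
  fp <- paste0("{", g$labels, "}")
  if (r == 0L || n == 0L) return(fp)
  adj <- .adjacency_lists(n, g$edges)
  for (step in seq_len(r)) {
    fp <- vapply(seq_len(n), function(v) {
      if (length(adj$nbr[[v]]) == 0L) return(paste0(fp[v], "|()"))
      items <- sort(paste0(adj$elab[[v]], ":", fp[adj$nbr[[v]]]))
      paste0(fp[v], "|(", paste(items, collapse = ","), ")")
    }, character(1L))
  }
  fp
}

#' Fingerprint of a single vertex neighborhood
#'
#' @inheritParams vertex_fingerprints
#' @param v vertex index.
#' @return canonical fingerprint string of the radius-`r` neighborhood of `v`.
#' @export
vertex_fingerprint <- function(graph, v, r) {
  fps <- vertex_fingerprints(graph, r)
  stopifnot(v >= 1L, v <= length(fps))
  fps[[v]]
}

#' Edge fingerprints at radius r for every edge
#'
#' An edge fingerprint combines the edge's own label with the unordered pair
#' of its endpoints' radius-`r` vertex fingerprints; it is symmetric in the
#' endpoints by construction.
#'
#' @inheritParams vertex_fingerprints
#' @return character vector, one fingerprint per edge row of the graph.
#' @export
edge_fingerprints <- function(graph, r) {
  g <- as_labeled_graph(graph)
  if (nrow(g$edges) == 0L) return(character())
  vfp <- vertex_fingerprints(graph, r)
  ends <- cbind(vfp[g$edges$i], vfp[g$edges$j])
  lo <- pmin(ends[, 1L], ends[, 2L])
  hi <- pmax(ends[, 1L], ends[, 2L])
  paste0("E{", g$edges$label, "}[", lo, "~", hi, "]")
}

#' Fingerprint of a single edge
#'
#' @inheritParams vertex_fingerprints
#' @param edge length-2 vector `c(i, j)`; must be an edge of the graph.
#' @return canonical fingerprint string.
#' @export
edge_fingerprint <- function(graph, edge, r) {
  g <- as_labeled_graph(graph)
  i <- min(edge); j <- max(edge)
  row <- which(g$edges$i == i & g$edges$j == j)
  if (length(row) == 0L) {
    stop("(", edge[1L], ",", edge[2L], ") is not an edge of the graph")
  }
  edge_fingerprints(graph, r)[row[1L]]
}

#' Build a subgraph vocabulary from a training collection
#'
#' Collects every distinct radius-`r` vertex and edge fingerprint over the
#' collection, assigning dense indices in first-seen order, and reserves a
#' final UNK index in each map for fingerprints unseen at fit time. The
#' vocabulary is frozen once built.
#'
#' @param graphs non-empty list of graphs (all convertible by
#'   [as_labeled_graph()]).
#' @param r radius.
#' @return object of class `subgraph_vocabulary`: `radius`, `vertex` and
#'   `edge` (named integer maps fingerprint -> index, 1-based),
#'   `vertex_unk` / `edge_unk` (the reserved indices), and the table sizes
#'   `n_vertex` / `n_edge` (fingerprints + UNK).
#' @export
build_vocabulary <- function(graphs, r) {
  if (!is.list(graphs) || length(graphs) == 0L ||
      inherits(graphs, c("molecular_graph", "pocket_graph"))) {
    if (inherits(graphs, c("molecular_graph", "pocket_graph"))) {
      graphs <- list(graphs)
    } else {
      stop("graphs must be a non-empty list of graphs")
    }
  }
  vfps <- unlist(lapply(graphs, vertex_fingerprints, r = r))
  efps <- unlist(lapply(graphs, edge_fingerprints, r = r))
  vkeys <- unique(vfps)
  ekeys <- unique(efps)
  structure(list(
    radius = as.integer(r),
    vertex = stats::setNames(seq_along(vkeys), vkeys),
    edge = stats::setNames(seq_along(ekeys), ekeys),
    vertex_unk = length(vkeys) + 1L,
    edge_unk = length(ekeys) + 1L,
    n_vertex = length(vkeys) + 1L,
    n_edge = length(ekeys) + 1L),
    class = "subgraph_vocabulary")
}

#' @export
print.subgraph_vocabulary <- function(x, ...) {
  cat(sprintf(
    "Subgraph vocabulary (radius %d): %d vertex + %d edge fingerprints (+UNK)\n",
    x$radius, length(x$vertex), length(x$edge)))
  invisible(x)
}

#' Index a graph through a frozen vocabulary
#'
#' Maps every radius-`r` fingerprint of the graph through the vocabulary;
#' fingerprints unseen at fit time map to the reserved UNK index (counts
#' reported in the result).
#'
#' @param graph a graph accepted by [as_labeled_graph()].
#' @param vocab a [build_vocabulary()] result.
#' @return object of class `indexed_graph`: `vertex_idx`, `edges`
#'   (data frame `i`, `j`, `edge_idx`), `n_vertices`, adjacency arrays used
#'   by the network forward pass (`di`, `dj`, `de`: directed endpoint and
#'   edge-slot indices), and `n_unk_vertices` / `n_unk_edges`.
#' @export
index_graph <- function(graph, vocab) {
  stopifnot(inherits(vocab, "subgraph_vocabulary"))
  g <- as_labeled_graph(graph)
  vfp <- vertex_fingerprints(graph, vocab$radius)
  efp <- edge_fingerprints(graph, vocab$radius)
  vidx <- unname(vocab$vertex[vfp])
  vidx[is.na(vidx)] <- vocab$vertex_unk
  eidx <- unname(vocab$edge[efp])
  eidx[is.na(eidx)] <- vocab$edge_unk
  m <- nrow(g$edges)
  vidx <- as.integer(vidx)
  eidx <- as.integer(eidx)
  structure(list(
    vertex_idx = vidx,
    edges = data.frame(i = g$edges$i, j = g$edges$j, edge_idx = eidx),
    eidx = eidx,
    n_vertices = length(vidx),
    di = as.integer(c(g$edges$i, g$edges$j)),
    dj = as.integer(c(g$edges$j, g$edges$i)),
    de = rep.int(seq_len(m), 2L),
    touch_v = sort(unique(vidx)),
    touch_e = sort(unique(eidx)),
    n_unk_vertices = sum(vidx == vocab$vertex_unk &
                           !(vfp %in% names(vocab$vertex))),
    n_unk_edges = sum(eidx == vocab$edge_unk &
                        !(efp %in% names(vocab$edge)))),
    class = "indexed_graph")
}

#' Write a vocabulary to a versioned key-value text file
#'
#' @param vocab a `subgraph_vocabulary`.
#' @param path output file.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "subgraph_vocabulary"))
  lines <- c("# pocketgnn subgraph-vocabulary v1",
             sprintf("radius\t%d", vocab$radius),
             sprintf("V\t%d\t%s", unname(vocab$vertex), names(vocab$vertex)),
             sprintf("E\t%d\t%s", unname(vocab$edge), names(vocab$edge)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' @param path file path.
#' @return a `subgraph_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("subgraph-vocabulary v1", lines[1L],
                               fixed = TRUE)) {
    stop("not a pocketgnn vocabulary file: ", path)
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  kinds <- vapply(parts, `[`, "", 1L)
  r <- as.integer(parts[[which(kinds == "radius")[1L]]][2L])
  grab <- function(kind) {
    p <- parts[kinds == kind]
    stats::setNames(vapply(p, function(x) as.integer(x[2L]), 0L),
                    vapply(p, `[`, "", 3L))
  }
  v <- grab("V"); e <- grab("E")
  v <- sort(v); e <- sort(e)
  structure(list(radius = r, vertex = v, edge = e,
                 vertex_unk = length(v) + 1L, edge_unk = length(e) + 1L,
                 n_vertex = length(v) + 1L, n_edge = length(e) + 1L),
            class = "subgraph_vocabulary")
}
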