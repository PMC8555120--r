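# Graph neural network forward pass and analytic gradients.
#
# Each branch (compound, pocket) is embed -> L transition steps -> average.
# Transition (per vertex i, per layer l, ReLU nonlinearity):
#   h_i' = relu( h_i + sum_{j in N(i)} W_l (h_j + e_ij) )
# Edge vectors are looked up once and stay fixed across layers. The two
# branch vectors are concatenated as [y_molecule; y_protein] and classified:
#   z = W_output [y_molecule; y_protein] + b_output,  p = softmax(z)
# with class index 1 (second logit) = active. Gradients are hand-derived and
# verified against central finite differences in the test suite.

#' Initialize GNN parameters
#'
#' Embedding tables, per-layer transition weights for both branches and the
#' output head, drawn from a scaled uniform distribution
#' `U(-1/sqrt(d), 1/sqrt(d))` (head bias starts at zero) under a recorded
#' seed.
#'
#' @param vocab_compound,vocab_pocket [build_vocabulary()] results for the
#'   two branches (sizes include the UNK slot).
#' @param d embedding dimension (default 10).
#' @param layers_compound,layers_pocket number of transition layers per
#'   branch (default 3 and 3).
#' @param seed RNG seed for the draw.
#' @return object of class `gnn_parameters`: per-branch lists
#'   (`vertex_emb`, `edge_emb`, `W` list of d x d matrices), `W_out`
#'   (2 x 2d), `b_out` (length 2), plus `d` and the layer counts.
#' @export
init_gnn_params <- function(vocab_compound, vocab_pocket, d = 10L,
                            layers_compound = 3L, layers_pocket = 3L,
                            seed = 1L) {
  stopifnot(d >= 1L, layers_compound >= 0L, layers_pocket >= 0L)
  s <- 1 / sqrt(d)
  with_seed(seed, {
    branch <- function(nv, ne, L) {
      list(vertex_emb = matrix(runif(nv * d, -s, s), nv, d),
           edge_emb = matrix(runif(ne * d, -s, s), ne, d),
           W = lapply(seq_len(L), function(l) matrix(runif(d * d, -s, s), d, d)))
    }
    structure(list(
      compound = branch(vocab_compound$n_vertex, vocab_compound$n_edge,
                        layers_compound),
      pocket = branch(vocab_pocket$n_vertex, vocab_pocket$n_edge,
                      layers_pocket),
      W_out = matrix(runif(2L * 2L * d, -1 / sqrt(2 * d), 1 / sqrt(2 * d)),
                     2L, 2L * d),
      b_out = c(0, 0),
      d = as.integer(d),
      layers_compound = as.integer(layers_compound),
      layers_pocket = as.integer(layers_pocket)),
      class = "gnn_parameters")
  })
}

#' Look up embeddings for an indexed graph
#'
#' Pure row lookup from the branch embedding tables; parameters are never
#' mutated.
#'
#' @param indexed_graph an [index_graph()] result.
#' @param branch_params one branch of a [init_gnn_params()] object
#'   (`$compound` or `$pocket`).
#' @return list with `H` (n x d vertex vectors) and `Ev` (m x d edge
#'   vectors; zero-row matrix for an edgeless graph).
#' @export
embed_graph <- function(indexed_graph, branch_params) {
  vt <- branch_params$vertex_emb
  et <- branch_params$edge_emb
  if (any(indexed_graph$vertex_idx > nrow(vt)) ||
      (nrow(indexed_graph$edges) &&
       any(indexed_graph$edges$edge_idx > nrow(et)))) {
    stop("embedding index out of bounds: vocabulary/parameter mismatch")
  }
  eidx <- indexed_graph$eidx %||% indexed_graph$edges$edge_idx
  list(H = cpp_gather(vt, indexed_graph$vertex_idx),
       Ev = cpp_gather(et, eidx))
}

# One transition layer, keeping the intermediates needed for backprop
# (S and the post-ReLU output, whose positivity pattern is the mask).
.transition_forward <- function(H, Ev, adj, W) {
  n <- nrow(H)
  S <- matrix(0, n, ncol(H))
  if (length(adj$di)) {
    Msg <- cpp_gather2_sum(H, adj$dj, Ev, adj$de)
    cpp_add_rows(S, adj$di, Msg)
  }
  Z <- H + S %*% t(W)
  list(H = pmax(Z, 0), S = S)
}

#' One message-passing transition step
#'
#' Updates every vertex vector as
#' `h_i' = relu(h_i + sum_{j in N(i)} W (h_j + e_ij))`; an isolated vertex
#' gets `relu(h_i)`. Edge vectors are not modified.
#'
#' @param vertex_vecs n x d matrix of vertex vectors.
#' @param edge_vecs m x d matrix of edge vectors (row per edge).
#' @param adjacency list with directed incidence arrays `di`, `dj`, `de`
#'   (as built by [index_graph()]); `de` indexes rows of `edge_vecs`.
#' @param W d x d transition weight matrix.
#' @return updated n x d matrix of vertex vectors.
#' @export
transition_step <- function(vertex_vecs, edge_vecs, adjacency, W) {
  d <- ncol(vertex_vecs)
  stopifnot(nrow(W) == d, ncol(W) == d)
  if (length(adjacency$di) && nrow(edge_vecs) > 0L &&
      ncol(edge_vecs) != d) {
    stop("edge/vertex vector dimension mismatch")
  }
  .transition_forward(vertex_vecs, edge_vecs, adjacency, W)$H
}

#' Averaging readout
#'
#' The branch output vector: arithmetic mean of the vertex vectors.
#'
#' @param vertex_vecs n x d matrix, n >= 1.
#' @return numeric vector of length d.
#' @export
readout_average <- function(vertex_vecs) {
  if (is.null(dim(vertex_vecs)) || nrow(vertex_vecs) == 0L) {
    stop("readout of an empty graph is undefined")
  }
  colMeans(vertex_vecs)
}

#' Encode a graph into its branch vector
#'
#' Full branch pass: embedding lookup, `L` transition steps with
#' layer-specific weights, then averaging readout.
#'
#' @inheritParams embed_graph
#' @param L number of transition layers; must not exceed the layers held in
#'   `branch_params` (`L = 0` returns the mean raw embedding).
#' @return numeric d-vector (`y_molecule` / `y_protein`).
#' @export
encode_graph <- function(indexed_graph, branch_params,
                         L = length(branch_params$W)) {
  stopifnot(L >= 0L, L <= length(branch_params$W))
  e <- embed_graph(indexed_graph, branch_params)
  H <- e$H
  adj <- indexed_graph
  for (l in seq_len(L)) {
    H <- .transition_forward(H, e$Ev, adj, branch_params$W[[l]])$H
  }
  readout_average(H)
}

.softmax <- function(z) {
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

#' Classify a compound/pocket vector pair
#'
#' Concatenates the two branch vectors in the fixed order
#' `[y_molecule; y_protein]`, applies the linear head
#' `z = W_output %*% concat + b_output` and a softmax. The second logit
#' (class index 1) is the active class.
#'
#' @param y_molecule,y_protein numeric d-vectors from [encode_graph()].
#' @param params a [init_gnn_params()] object.
#' @return list with `z` (two logits), `p` (softmax probabilities) and
#'   `p_active` (probability of the active class).
#' @export
classify_pair <- function(y_molecule, y_protein, params) {
  d <- params$d
  if (length(y_molecule) != d || length(y_protein) != d) {
    stop("branch vector dimension mismatch (expected d = ", d, ")")
  }
  z <- drop(params$W_out %*% c(y_molecule, y_protein) + params$b_out)
  p <- .softmax(z)
  list(z = z, p = p, p_active = p[2L])
}

#' Forward pass for one labeled pair
#'
#' @param ig_compound,ig_pocket indexed graphs for the two branches.
#' @param params a [init_gnn_params()] object.
#' @return as [classify_pair()].
#' @export
forward_pair <- function(ig_compound, ig_pocket, params) {
  ym <- encode_graph(ig_compound, params$compound, params$layers_compound)
  yp <- encode_graph(ig_pocket, params$pocket, params$layers_pocket)
  classify_pair(ym, yp, params)
}

# --- training internals -----------------------------------------------------

# Deep copy of the parameter arrays. The optimizer updates arrays in place,
# so training must own unique storage: without this, arrays shared with the
# caller (or with byte-compiled constants) would be silently corrupted.
.copy_params <- function(params) {
  cp <- function(x) x + 0
  for (br in c("compound", "pocket")) {
    params[[br]]$vertex_emb <- cp(params[[br]]$vertex_emb)
    params[[br]]$edge_emb <- cp(params[[br]]$edge_emb)
    params[[br]]$W <- lapply(params[[br]]$W, cp)
  }
  params$W_out <- cp(params$W_out)
  params$b_out <- cp(params$b_out)
  params
}

.zero_like <- function(params) {
  zb <- function(b) list(
    vertex_emb = matrix(0, nrow(b$vertex_emb), ncol(b$vertex_emb)),
    edge_emb = matrix(0, nrow(b$edge_emb), ncol(b$edge_emb)),
    W = lapply(b$W, function(w) matrix(0, nrow(w), ncol(w))))
  list(compound = zb(params$compound), pocket = zb(params$pocket),
       W_out = matrix(0, nrow(params$W_out), ncol(params$W_out)),
       b_out = numeric(length(params$b_out)))
}

# Branch forward keeping the per-layer cache needed for backprop.
.branch_forward <- function(ig, branch, L) {
  e <- embed_graph(ig, branch)
  cache <- vector("list", L)
  H <- e$H
  for (l in seq_len(L)) {
    step <- .transition_forward(H, e$Ev, ig, branch$W[[l]])
    cache[[l]] <- list(S = step$S, H_out = step$H)
    H <- step$H
  }
  list(H = H, Ev = e$Ev, cache = cache, y = readout_average(H))
}

# Backprop one branch given d(loss)/d(y). Embedding-row gradients are
# accumulated into `grad` IN PLACE (C kernel); transition-weight gradients
# by ordinary assignment. Returns the grad branch plus the touched
# embedding rows (so the caller can zero them cheaply after the step).
.branch_backward <- function(dy, fwd, ig, branch, grad) {
  n <- nrow(fwd$H)
  L <- length(fwd$cache)
  dH <- matrix(rep(dy / n, each = n), n, length(dy))
  m <- length(ig$eidx)
  dEv <- matrix(0, m, length(dy))
  for (l in rev(seq_len(L))) {
    cc <- fwd$cache[[l]]
    dZ <- cpp_mask_mul(dH, cc$H_out)
    grad$W[[l]] <- grad$W[[l]] + crossprod(dZ, cc$S)
    if (length(ig$di)) {
      dS <- dZ %*% branch$W[[l]]
      dMsg <- cpp_gather(dS, ig$di)
      cpp_add_rows(dZ, ig$dj, dMsg)      # dZ becomes dH for the layer below
      cpp_add_rows(dEv, ig$de, dMsg)
    }
    dH <- dZ
  }
  cpp_add_rows(grad$vertex_emb, ig$vertex_idx, dH)
  if (m) cpp_add_rows(grad$edge_emb, ig$eidx, dEv)
  list(grad = grad, touched_v = ig$touch_v, touched_e = ig$touch_e)
}

# Cross-entropy loss and full analytic gradient for one labeled pair.
# Embedding gradients accumulate into `grad` in place; returns the grad
# (with updated W/head slots) and the touched embedding rows per branch.
pair_loss_grad <- function(ig_compound, ig_pocket, label, params,
                           grad = .zero_like(params)) {
  fc <- .branch_forward(ig_compound, params$compound, params$layers_compound)
  fp <- .branch_forward(ig_pocket, params$pocket, params$layers_pocket)
  cls <- classify_pair(fc$y, fp$y, params)
  target <- c(1 - label, label)
  loss <- -sum(target * log(pmax(cls$p, 1e-300)))
  dz <- cls$p - target
  d <- params$d
  conc <- c(fc$y, fp$y)
  grad$W_out <- grad$W_out + dz %o% conc
  grad$b_out <- grad$b_out + dz
  dconc <- drop(t(params$W_out) %*% dz)
  bc <- .branch_backward(dconc[seq_len(d)], fc, ig_compound,
                         params$compound, grad$compound)
  grad$compound <- bc$grad
  bp <- .branch_backward(dconc[d + seq_len(d)], fp, ig_pocket,
                         params$pocket, grad$pocket)
  grad$pocket <- bp$grad
  list(loss = loss, p_active = cls$p_active, grad = grad,
       touched = list(c_v = bc$touched_v, c_e = bc$touched_e,
                      p_v = bp$touched_v, p_e = bp$touched_e))
}

# Zero a gradient structure in place, given the touched embedding rows.
.reset_grad <- function(grad, touched) {
  cpp_zero_rows(grad$compound$vertex_emb, touched$c_v)
  cpp_zero_rows(grad$compound$edge_emb, touched$c_e)
  cpp_zero_rows(grad$pocket$vertex_emb, touched$p_v)
  cpp_zero_rows(grad$pocket$edge_emb, touched$p_e)
  for (br in c("compound", "pocket")) {
    for (l in seq_along(grad[[br]]$W)) cpp_fill_zero(grad[[br]]$W[[l]])
  }
  cpp_fill_zero(grad$W_out)
  cpp_fill_zero(grad$b_out)
  invisible(grad)
}

# --- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = .zero_like(params), v = .zero_like(params), t = 0L)
}

# Apply one Adam update with gradient `grad` at learning rate `lr`.
# Parameter and moment arrays are updated IN PLACE (C kernel); the returned
# structures share storage with the inputs. Dense update: every parameter
# moves every step, as standard Adam prescribes.
.adam_step <- function(params, grad, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    cpp_adam_update(p, g, m, v, lr, beta1, beta2, eps, bc1, bc2)
  }
  for (br in c("compound", "pocket")) {
    for (nm in c("vertex_emb", "edge_emb")) {
      upd(params[[br]][[nm]], grad[[br]][[nm]],
          state$m[[br]][[nm]], state$v[[br]][[nm]])
    }
    for (l in seq_along(params[[br]]$W)) {
      upd(params[[br]]$W[[l]], grad[[br]]$W[[l]],
          state$m[[br]]$W[[l]], state$v[[br]]$W[[l]])
    }
  }
  upd(params$W_out, grad$W_out, state$m$W_out, state$v$W_out)
  upd(params$b_out, grad$b_out, state$m$b_out, state$v$b_out)
  list(params = params, state = state)
}
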