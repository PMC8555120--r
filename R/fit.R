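# End-to-end model fitting and prediction.

#' Stepwise learning-rate schedule
#'
#' `lr = learning_rate * lr_decay ^ floor(epoch / decay_interval)`, i.e. the
#' rate is multiplied by `lr_decay` at every `decay_interval` epoch
#' boundary. Defaults: initial rate 0.001 halved every 10 epochs.
#'
#' @param epoch 0-based epoch number.
#' @param learning_rate initial learning rate.
#' @param lr_decay multiplicative decay factor in (0, 1].
#' @param decay_interval epochs between decays.
#' @return the learning rate for that epoch.
#' @examples
#' lr_schedule(0)   # 0.001
#' lr_schedule(10)  # 0.0005
#' lr_schedule(25)  # 0.00025
#' @export
lr_schedule <- function(epoch, learning_rate = 0.001, lr_decay = 0.5,
                        decay_interval = 10L) {
  stopifnot(all(epoch >= 0), learning_rate > 0, lr_decay > 0, lr_decay <= 1,
            decay_interval >= 1)
  learning_rate * lr_decay^(epoch %/% decay_interval)
}

#' Down-sample decoys to a 1:1 active:decoy ratio
#'
#' Keeps every active pair and a uniformly random, seed-determined subset of
#' decoys of the same size; the combined list is then shuffled
#' deterministically by the same seed.
#'
#' @param actives,decoys lists of labeled pairs (see [pocketgnn()]).
#' @param seed integer seed controlling selection and shuffle.
#' @return balanced, shuffled list of length `2 * length(actives)`.
#' @export
downsample_1to1 <- function(actives, decoys, seed = 1L) {
  if (length(decoys) < length(actives)) {
    stop("fewer decoys (", length(decoys), ") than actives (",
         length(actives), "): 1:1 ratio unreachable")
  }
  with_seed(seed, {
    keep <- sample.int(length(decoys), length(actives))
    out <- c(actives, decoys[keep])
    out[sample.int(length(out))]
  })
}

.pair_label <- function(p) as.integer(p$label)

# Index the graphs of a pair list through the two vocabularies, computing
# fingerprints once per distinct graph (graphs carry a "graph_id" attribute
# when they come from the generators; anonymous graphs are indexed afresh).
.index_pairs <- function(pairs, vocab_c, vocab_p) {
  cache <- new.env(parent = emptyenv())
  idx1 <- function(g, vocab, kind) {
    id <- attr(g, "graph_id", exact = TRUE)
    if (is.null(id)) return(index_graph(g, vocab))
    key <- paste0(kind, "::", id)
    if (is.null(cache[[key]])) cache[[key]] <- index_graph(g, vocab)
    cache[[key]]
  }
  lapply(pairs, function(p) {
    list(compound = idx1(p$compound, vocab_c, "c"),
         pocket = idx1(p$pocket, vocab_p, "p"),
         label = .pair_label(p))
  })
}

.unique_graphs <- function(pairs, field) {
  seen <- character()
  out <- list()
  for (p in pairs) {
    g <- p[[field]]
    id <- attr(g, "graph_id", exact = TRUE) %||%
      paste0("anon-", length(out) + 1L)
    if (!(id %in% seen)) {
      seen <- c(seen, id)
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

#' Fit a compound-pocket activity GNN
#'
#' Trains the two-branch r-radius subgraph neural network end to end:
#' fingerprint vocabularies are built from the training pairs at the given
#' radii, all parameters (embedding tables, per-layer transition weights,
#' output head) are optimized jointly by Adam on the mean softmax
#' cross-entropy, with the stepwise [lr_schedule()] and a fresh data order
#' drawn each epoch from the run seed. Hyperparameter defaults are the
#' reference configuration: d = 10, radii 2 (compound) / 1 (pocket), 3
#' transition layers per branch, learning rate 0.001 halved every 10
#' epochs, Adam, 100 epochs, batch size 1.
#'
#' @param pairs non-empty list of labeled pairs; each a list with
#'   `compound` (a [molecular_graph()]), `pocket` (a `pocket_graph`) and
#'   `label` (1 = active, 0 = inactive/decoy).
#' @param dim embedding dimension d.
#' @param r_compound,r_pocket fingerprint radii for the two branches.
#' @param layers_compound,layers_pocket transition layers per branch.
#' @param learning_rate,lr_decay,decay_interval see [lr_schedule()].
#' @param epochs number of passes over the data (0 returns the
#'   initialization untouched).
#' @param batch_size examples per optimizer step.
#' @param seed seed for initialization and epoch shuffling; fitting is fully
#'   reproducible given the seed.
#' @param verbose print per-epoch progress.
#' @return an object of class `pocketgnn` with components `params`
#'   (trained [init_gnn_params()] object), `vocab_compound`,
#'   `vocab_pocket`, `config` (resolved hyperparameters), `loss_history`
#'   (mean training cross-entropy per epoch) and `n_pairs`.
#' @seealso [predict.pocketgnn()], [downsample_1to1()]
#' @export
pocketgnn <- function(pairs, dim = 10L, r_compound = 2L, r_pocket = 1L,
                      layers_compound = 3L, layers_pocket = 3L,
                      learning_rate = 0.001, lr_decay = 0.5,
                      decay_interval = 10L, epochs = 100L, batch_size = 1L,
                      seed = 1L, verbose = FALSE) {
  stopifnot(is.list(pairs), length(pairs) >= 1L, epochs >= 0L,
            batch_size >= 1L)
  labels <- vapply(pairs, .pair_label, 0L)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    warning("training labels are single-class; ",
            "downstream AUROC will be undefined")
  }
  config <- list(dim = as.integer(dim), r_compound = as.integer(r_compound),
                 r_pocket = as.integer(r_pocket),
                 layers_compound = as.integer(layers_compound),
                 layers_pocket = as.integer(layers_pocket),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 decay_interval = as.integer(decay_interval),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", seed = as.integer(seed))

  vocab_c <- build_vocabulary(.unique_graphs(pairs, "compound"), r_compound)
  vocab_p <- build_vocabulary(.unique_graphs(pairs, "pocket"), r_pocket)
  indexed <- .index_pairs(pairs, vocab_c, vocab_p)
  n <- length(indexed)

  params <- .copy_params(init_gnn_params(
    vocab_c, vocab_p, d = dim, layers_compound = layers_compound,
    layers_pocket = layers_pocket, seed = seed))
  state <- .adam_init(params)
  grad <- .zero_like(params)     # reused across steps, zeroed in place
  loss_history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (epoch in seq_len(epochs) - 1L) {
      lr <- lr_schedule(epoch, learning_rate, lr_decay, decay_interval)
      ord <- sample.int(n)
      total <- 0
      b <- 1L
      while (b <= n) {
        take <- ord[b:min(b + batch_size - 1L, n)]
        bloss <- 0
        touched <- list(c_v = integer(), c_e = integer(),
                        p_v = integer(), p_e = integer())
        for (k in take) {
          pr <- indexed[[k]]
          res <- pair_loss_grad(pr$compound, pr$pocket, pr$label, params,
                                grad)
          grad <- res$grad
          bloss <- bloss + res$loss
          touched <- Map(c, touched, res$touched)
        }
        nb <- length(take)
        if (nb > 1L) grad <- .scale_grad(grad, 1 / nb)
        st <- .adam_step(params, grad, state, lr)
        params <- st$params
        state <- st$state
        .reset_grad(grad, touched)
        total <- total + bloss
        b <- b + batch_size
      }
      loss_history[epoch + 1L] <- total / n
      if (!is.finite(loss_history[epoch + 1L])) {
        stop("non-finite training loss at epoch ", epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.5f", epoch, lr,
                        total / n))
      }
    }
  })
  structure(list(params = params, vocab_compound = vocab_c,
                 vocab_pocket = vocab_p, config = config,
                 loss_history = loss_history, n_pairs = n,
                 call = match.call()),
            class = "pocketgnn")
}

.scale_grad <- function(grad, s) {
  for (br in c("compound", "pocket")) {
    grad[[br]]$vertex_emb <- grad[[br]]$vertex_emb * s
    grad[[br]]$edge_emb <- grad[[br]]$edge_emb * s
    grad[[br]]$W <- lapply(grad[[br]]$W, `*`, s)
  }
  grad$W_out <- grad$W_out * s
  grad$b_out <- grad$b_out * s
  grad
}

#' Predict activity probabilities for compound/pocket pairs
#'
#' Scores each pair with the trained model; fingerprints unseen at training
#' time map to the UNK embedding. A pair whose compound is an excluded
#' record (dot-disconnected SMILES, see [parse_smiles()]) gets no score and
#' is flagged in the `excluded` column.
#'
#' @param object a fitted [pocketgnn()] model.
#' @param pairs list of pairs, each a list with `compound` (a
#'   [molecular_graph()] or a `smiles_exclusion`) and `pocket` (a
#'   `pocket_graph`); labels, if present, are ignored.
#' @param ... unused.
#' @return data frame with one row per input pair: `p_active` (probability
#'   of the active class, `NA` for excluded records) and `excluded`
#'   (logical).
#' @export
predict.pocketgnn <- function(object, pairs, ...) {
  stopifnot(inherits(object, "pocketgnn"), is.list(pairs))
  score <- rep(NA_real_, length(pairs))
  excl <- vapply(pairs, function(p) is_excluded(p$compound), logical(1L))
  keep <- which(!excl)
  if (length(keep)) {
    idx <- .index_pairs(lapply(pairs[keep], function(p) {
      list(compound = p$compound, pocket = p$pocket, label = 0L)
    }), object$vocab_compound, object$vocab_pocket)
    score[keep] <- vapply(idx, function(pr) {
      forward_pair(pr$compound, pr$pocket, object$params)$p_active
    }, numeric(1L))
  }
  data.frame(p_active = score, excluded = excl)
}

#' @export
print.pocketgnn <- function(x, ...) {
  cfg <- x$config
  cat("Compound-pocket activity GNN (pocketgnn)\n")
  cat(sprintf("  d = %d, radii = %d (compound) / %d (pocket), layers = %d/%d\n",
              cfg$dim, cfg$r_compound, cfg$r_pocket, cfg$layers_compound,
              cfg$layers_pocket))
  cat(sprintf("  vocab: %d vertex / %d edge fingerprints (compound), %d / %d (pocket), +UNK each\n",
              length(x$vocab_compound$vertex), length(x$vocab_compound$edge),
              length(x$vocab_pocket$vertex), length(x$vocab_pocket$edge)))
  cat(sprintf("  trained on %d pairs for %d epochs (Adam, lr %.4g halved every %d); final loss %.4f\n",
              x$n_pairs, cfg$epochs, cfg$learning_rate, cfg$decay_interval,
              if (length(x$loss_history)) tail(x$loss_history, 1L) else NA))
  invisible(x)
}

#' @export
summary.pocketgnn <- function(object, ...) {
  n_par <- function(b) {
    length(b$vertex_emb) + length(b$edge_emb) + sum(lengths(b$W))
  }
  out <- list(
    config = object$config,
    n_pairs = object$n_pairs,
    n_parameters = n_par(object$params$compound) +
      n_par(object$params$pocket) + length(object$params$W_out) +
      length(object$params$b_out),
    loss_first = if (length(object$loss_history)) object$loss_history[1L] else NA,
    loss_final = if (length(object$loss_history)) tail(object$loss_history, 1L) else NA,
    vocab_sizes = c(compound_vertex = length(object$vocab_compound$vertex),
                    compound_edge = length(object$vocab_compound$edge),
                    pocket_vertex = length(object$vocab_pocket$vertex),
                    pocket_edge = length(object$vocab_pocket$edge)))
  class(out) <- "summary.pocketgnn"
  out
}

#' @export
print.summary.pocketgnn <- function(x, ...) {
  cat("pocketgnn model summary\n")
  cat(sprintf("  pairs: %d   trainable parameters: %d\n", x$n_pairs,
              x$n_parameters))
  cat(sprintf("  training loss: %.4f -> %.4f over %d epochs\n",
              x$loss_first, x$loss_final, x$config$epochs))
  cat("  fingerprint vocabulary sizes:\n")
  print(x$vocab_sizes)
  invisible(x)
}

#' @export
coef.pocketgnn <- function(object, ...) object$params

#' Plot the training loss trajectory
#'
#' @param x a fitted [pocketgnn()] model.
#' @param ... passed to [plot()].
#' @export
plot.pocketgnn <- function(x, ...) {
  plot(seq_along(x$loss_history) - 1L, x$loss_history, type = "l",
       xlab = "epoch", ylab = "mean cross-entropy",
       main = "pocketgnn training loss", ...)
  invisible(x)
}
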