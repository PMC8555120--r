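# Fixtures: tiny vocabularies/graphs so parameter tables are small.
tiny_setup <- function(d = 2L, L = 1L, seed = 9L) {
  gc <- parse_smiles("CCO")
  gp <- build_pocket_graph(list(mk_residue(1, "TRP", c(0, 0, 0)),
                                mk_residue(2, "ALA", c(4, 0, 0)),
                                mk_residue(3, "GLY", c(8, 0, 0))))
  vc <- build_vocabulary(list(gc), 1)
  vp <- build_vocabulary(list(gp), 1)
  params <- init_gnn_params(vc, vp, d = d, layers_compound = L,
                            layers_pocket = L, seed = seed)
  list(gc = gc, gp = gp, vc = vc, vp = vp, params = params,
       ic = index_graph(gc, vc), ip = index_graph(gp, vp))
}

# Permute the vertices of an indexed graph (vertex v becomes perm[v]).
permute_indexed <- function(ig, perm) {
  inv <- order(perm)
  ig$vertex_idx <- ig$vertex_idx[inv]
  ig$edges$i <- perm[ig$edges$i]
  ig$edges$j <- perm[ig$edges$j]
  ig$di <- as.integer(perm[ig$di])
  ig$dj <- as.integer(perm[ig$dj])
  ig
}

test_that("embedding is a pure row lookup", {
  s <- tiny_setup()
  e <- embed_graph(s$ic, s$params$compound)
  for (k in seq_along(s$ic$vertex_idx)) {
    expect_identical(e$H[k, ], s$params$compound$vertex_emb[
      s$ic$vertex_idx[k], ])
  }
  # equal indices give equal vectors (the two carbons differ at r=1 here,
  # so check via a repeated index directly)
  ig <- s$ic
  ig$vertex_idx <- c(1L, 1L, 2L)
  e2 <- embed_graph(ig, s$params$compound)
  expect_identical(e2$H[1L, ], e2$H[2L, ])
  # out-of-bounds index is a vocabulary/parameter mismatch
  ig$vertex_idx <- c(1L, 2L, 99L)
  expect_error(embed_graph(ig, s$params$compound), "out of bounds")
})

test_that("transition step reproduces the hand-computed d=1 example", {
  # 2 vertices, h = (1, 2), one edge with e = 0.5, W = (1):
  # h0' = relu(1 + 1 * (2 + 0.5)) = 3.5 ; h1' = relu(2 + 1 * (1 + 0.5)) = 3.5
  H <- matrix(c(1, 2), 2L, 1L)
  Ev <- matrix(0.5, 1L, 1L)
  adj <- list(di = c(1L, 2L), dj = c(2L, 1L), de = c(1L, 1L))
  out <- transition_step(H, Ev, adj, matrix(1, 1L, 1L))
  expect_equal(out, matrix(c(3.5, 3.5), 2L, 1L))
})

test_that("zero transition weights leave nonnegative vertex vectors fixed", {
  H <- matrix(c(0.3, 1.2, 0, 2), 2L, 2L)
  Ev <- matrix(rnorm(2L), 1L, 2L)
  adj <- list(di = c(1L, 2L), dj = c(2L, 1L), de = c(1L, 1L))
  expect_equal(transition_step(H, Ev, adj, matrix(0, 2L, 2L)), H)
  # isolated vertex: empty neighbor sum, relu passes nonnegatives
  lone <- list(di = integer(), dj = integer(), de = integer())
  expect_equal(transition_step(H, matrix(0, 0L, 2L), lone,
                               matrix(rnorm(4L), 2L)), H)
})

test_that("averaging readout is the arithmetic mean and order-free", {
  expect_equal(readout_average(matrix(c(1, 2, 3), 1L)), c(1, 2, 3))
  m <- rbind(rep(0, 3), rep(2, 3))
  expect_equal(readout_average(m), rep(1, 3))
  set.seed(5)
  m <- matrix(rnorm(20L), 5L)
  expect_equal(readout_average(m), readout_average(m[sample(5L), ]))
  expect_error(readout_average(matrix(0, 0L, 3L)), "empty")
})

test_that("encode_graph with L = 0 is the mean raw embedding, and zero embeddings give zero", {
  s <- tiny_setup(d = 3L, L = 2L)
  y0 <- encode_graph(s$ic, s$params$compound, L = 0L)
  expect_equal(y0, colMeans(s$params$compound$vertex_emb[s$ic$vertex_idx, ]))
  p0 <- s$params
  p0$compound$vertex_emb[] <- 0
  p0$compound$edge_emb[] <- 0
  expect_equal(encode_graph(s$ic, p0$compound, L = 2L), rep(0, 3L))
})

test_that("encode_graph is invariant under vertex relabeling", {
  set.seed(17)
  s <- tiny_setup(d = 4L, L = 3L, seed = 3L)
  for (rep in 1:25) {
    perm <- sample.int(s$ic$n_vertices)
    y1 <- encode_graph(s$ic, s$params$compound)
    y2 <- encode_graph(permute_indexed(s$ic, perm), s$params$compound)
    expect_lt(max(abs(y1 - y2)), 1e-12)
    permp <- sample.int(s$ip$n_vertices)
    z1 <- encode_graph(s$ip, s$params$pocket)
    z2 <- encode_graph(permute_indexed(s$ip, permp), s$params$pocket)
    expect_lt(max(abs(z1 - z2)), 1e-12)
  }
})

test_that("classifier head follows the concatenation + softmax contract", {
  s <- tiny_setup(d = 2L)
  p <- s$params
  p$W_out[] <- 0
  p$b_out <- c(0, 0)
  cls <- classify_pair(c(1, 2), c(3, 4), p)
  expect_equal(cls$p, c(0.5, 0.5))
  # z = (0, ln 3) -> softmax (0.25, 0.75)
  p$b_out <- c(0, log(3))
  cls <- classify_pair(c(1, 2), c(3, 4), p)
  expect_equal(cls$p, c(0.25, 0.75))
  expect_equal(cls$p_active, 0.75)
  # concatenation is ordered: swapping the inputs changes z
  set.seed(8)
  p$W_out <- matrix(rnorm(8L), 2L, 4L)
  z1 <- classify_pair(c(1, 2), c(3, 4), p)$z
  z2 <- classify_pair(c(3, 4), c(1, 2), p)$z
  expect_false(isTRUE(all.equal(z1, z2)))
  expect_error(classify_pair(c(1, 2, 3), c(1, 2), p), "dimension")
})

test_that("softmax output is a probability vector for random logits", {
  s <- tiny_setup()
  set.seed(99)
  for (rep in 1:50) {
    p <- s$params
    p$b_out <- rnorm(2L, sd = 5)
    cls <- classify_pair(rnorm(2L), rnorm(2L), p)
    expect_equal(sum(cls$p), 1)
    expect_true(all(cls$p > 0 & cls$p < 1))
  }
})

test_that("analytic gradients match central finite differences", {
  s <- tiny_setup(d = 2L, L = 1L, seed = 9L)
  paths <- list(c("compound", "vertex_emb"), c("compound", "edge_emb"),
                c("compound", "W", 1L), c("pocket", "vertex_emb"),
                c("pocket", "edge_emb"), c("pocket", "W", 1L),
                "W_out", "b_out")
  getp <- function(p, pa) {
    if (length(pa) == 3L) p[[pa[[1L]]]][[pa[[2L]]]][[as.integer(pa[[3L]])]]
    else if (length(pa) == 2L) p[[pa[[1L]]]][[pa[[2L]]]]
    else p[[pa]]
  }
  setp <- function(p, pa, v) {
    if (length(pa) == 3L) p[[pa[[1L]]]][[pa[[2L]]]][[as.integer(pa[[3L]])]] <- v
    else if (length(pa) == 2L) p[[pa[[1L]]]][[pa[[2L]]]] <- v
    else p[[pa]] <- v
    p
  }
  loss_of <- function(p, label) {
    pocketgnn:::pair_loss_grad(s$ic, s$ip, label, p)$loss
  }
  for (label in c(0L, 1L)) {
    analytic <- pocketgnn:::pair_loss_grad(s$ic, s$ip, label, s$params)$grad
    max_rel <- 0
    for (pa in paths) {
      arr <- getp(s$params, pa)
      gan <- getp(analytic, pa)
      for (k in seq_along(arr)) {
        eps <- 1e-5
        up <- arr; up[k] <- up[k] + eps
        dn <- arr; dn[k] <- dn[k] - eps
        fd <- (loss_of(setp(s$params, pa, up), label) -
                 loss_of(setp(s$params, pa, dn), label)) / (2 * eps)
        denom <- max(abs(fd), abs(gan[k]), 1e-8)
        if (denom > 1e-8) {
          max_rel <- max(max_rel, abs(fd - gan[k]) / denom)
        }
      }
    }
    expect_lt(max_rel, 1e-4)
  }
})
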