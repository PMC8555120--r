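# Synthetic data: toy protein-ligand complexes with known contact geometry,
# pocket populations, and planted-rule compound x pocket datasets.
#
# The planted rule is conjunctive: a pair is active iff the pocket carries a
# residue motif (>= k residues of one type) AND the compound contains a
# substructure motif (an ether oxygen: O bonded to two carbons), optionally
# label-flipped at a noise rate. Pockets are drawn from a finite panel of
# structures reused across pairs, emulating screening a compound library
# against a fixed target panel.

#' Define a planted compound x pocket interaction rule
#'
#' @param pocket_motif_aa residue type of the pocket motif (default `"TRP"`).
#' @param pocket_motif_k minimum count of motif residues (default 3).
#' @param compound_motif `"ether"` (an oxygen bonded to two carbons) or
#'   `NULL` for a rule depending on the pocket only.
#' @param noise_rate label-flip probability in `[0, 0.5)`.
#' @return object of class `planted_rule`.
#' @export
planted_rule <- function(pocket_motif_aa = "TRP", pocket_motif_k = 3L,
                         compound_motif = "ether", noise_rate = 0) {
  stopifnot(pocket_motif_aa %in% AA20, pocket_motif_k >= 1L,
            noise_rate >= 0, noise_rate < 0.5,
            is.null(compound_motif) || identical(compound_motif, "ether"))
  structure(list(pocket_motif_aa = pocket_motif_aa,
                 pocket_motif_k = as.integer(pocket_motif_k),
                 compound_motif = compound_motif,
                 noise_rate = noise_rate),
            class = "planted_rule")
}

#' Does a compound contain the rule's substructure motif?
#'
#' For the `"ether"` motif: any non-aromatic oxygen vertex with at least two
#' carbon neighbors. A rule without a compound motif is satisfied by every
#' compound.
#'
#' @param graph a [molecular_graph()].
#' @param rule a [planted_rule()].
#' @return logical.
#' @export
compound_has_motif <- function(graph, rule) {
  if (is.null(rule$compound_motif)) return(TRUE)
  labs <- graph$vertex_labels
  ox <- which(labs == "O")
  if (!length(ox)) return(FALSE)
  elem <- sub(":.*$", "", labs)
  e <- graph$edges
  any(vapply(ox, function(v) {
    nbr <- c(e$j[e$i == v], e$i[e$j == v])
    sum(elem[nbr] == "C") >= 2L
  }, logical(1L)))
}

#' Does a pocket satisfy the rule's residue motif?
#'
#' @param pocket a `pocket_graph`.
#' @param rule a [planted_rule()].
#' @return logical: at least `pocket_motif_k` residues of the motif type.
#' @export
pocket_has_motif <- function(pocket, rule) {
  sum(pocket$residues$aa3 == rule$pocket_motif_aa) >= rule$pocket_motif_k
}

#' Score pairs with the planted rule itself
#'
#' The Bayes-optimal reference classifier for generated data: 1 when the
#' rule's motif condition holds, 0 otherwise. At noise rate 0 its AUROC
#' against the generated labels is exactly 1.
#'
#' @param pairs list of pairs with `compound` and `pocket` graphs.
#' @param rule the [planted_rule()] that generated them.
#' @return numeric 0/1 vector.
#' @export
oracle_rule_score <- function(pairs, rule) {
  vapply(pairs, function(p) {
    as.numeric(compound_has_motif(p$compound, rule) &&
                 pocket_has_motif(p$pocket, rule))
  }, numeric(1L))
}

# --- compounds --------------------------------------------------------------

# Random small drug-like SMILES: a linear heavy-atom chain of 4-9 atoms of
# C (with occasional N). Motif version inserts an ether O between two
# adjacent carbons; motif-free versions may carry a terminal hydroxyl (an
# oxygen with only one carbon neighbor), so motif detection requires the
# neighborhood, not mere oxygen presence. Uses the current RNG stream.
.gen_smiles <- function(with_motif) {
  len <- sample(4:9, 1L)
  atoms <- sample(c("C", "N"), len, replace = TRUE, prob = c(0.85, 0.15))
  if (with_motif) {
    # ensure an adjacent C-C pair, then splice the O between them
    cc <- which(atoms[-len] == "C" & atoms[-1L] == "C")
    if (!length(cc)) {
      pos <- sample.int(len - 1L, 1L)
      atoms[pos] <- atoms[pos + 1L] <- "C"
      cc <- pos
    }
    at <- if (length(cc) == 1L) cc else sample(cc, 1L)
    atoms <- append(atoms, "O", after = at)
  } else if (runif(1L) < 0.3) {
    atoms[len] <- "C"                     # hydroxyl needs a carbon carrier
    atoms <- c(atoms, "O")
  }
  paste(atoms, collapse = "")
}

#' Generate random small-compound SMILES
#'
#' @param n number of compounds.
#' @param with_motif logical (recycled): include the ether motif?
#' @param seed RNG seed.
#' @return character vector of SMILES; every string parses without
#'   exclusion.
#' @export
generate_compound_smiles <- function(n, with_motif = FALSE, seed = 1L) {
  with_motif <- rep_len(with_motif, n)
  with_seed(seed, vapply(with_motif, .gen_smiles, character(1L)))
}

# --- pockets ----------------------------------------------------------------

# Compact 3D point process: sequential rejection sampling inside a sphere
# (radius 8.5 A) with a 3.8 A minimum separation, the typical Calpha
# packing distance. Uses the current RNG stream.
.gen_pocket_coords <- function(n, radius = 8.5, min_sep = 3.8) {
  pts <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    for (try in 1:500) {
      p <- runif(3L, -radius, radius)
      if (sum(p^2) > radius^2) next
      if (k == 1L || min(rowSums((pts[seq_len(k - 1L), , drop = FALSE] -
                                  matrix(p, k - 1L, 3L, byrow = TRUE))^2)) >=
          min_sep^2) {
        pts[k, ] <- p
        break
      }
    }
    if (anyNA(pts[k, ])) stop("could not place pocket residue ", k)
  }
  pts
}

.gen_pocket <- function(size, n_motif, motif_aa) {
  ca <- .gen_pocket_coords(size)
  aa <- sample(setdiff(AA20, motif_aa), size, replace = TRUE)
  if (n_motif > 0L) {
    aa[sample.int(size, n_motif)] <- motif_aa
  }
  residues <- lapply(seq_len(size), function(k) {
    .residue(chain = "A", resno = k, insert = "", aa3 = aa[k],
             ca = ca[k, ], xyz = matrix(ca[k, ], 1L, 3L))
  })
  build_pocket_graph(residues)
}

.gen_population <- function(n_pockets, size_range, rule) {
  half <- ceiling(n_pockets / 2)
  lapply(seq_len(n_pockets), function(p) {
    motif <- p <= half
    n_motif <- if (motif) rule$pocket_motif_k + sample(0:1, 1L) else 0L
    size <- sample(size_range[1L]:size_range[2L], 1L)
    g <- .gen_pocket(size, n_motif, rule$pocket_motif_aa)
    attr(g, "graph_id") <- sprintf("pocket-%03d", p)
    list(graph = g, motif = motif)
  })
}

#' Generate a population of synthetic pocket graphs
#'
#' Residues are placed by a compact random 3D point process and converted
#' through the real distance-binning code, so the population exercises all
#' five edge classes. Roughly half the pockets carry the rule's residue
#' motif (injected motif residues); the rest contain none.
#'
#' @param n_pockets population size.
#' @param size_range length-2 integer range of residues per pocket (within
#'   3..50).
#' @param rule a [planted_rule()].
#' @param seed RNG seed.
#' @return list of `list(graph = pocket_graph, motif = logical)`.
#' @export
generate_pocket_population <- function(n_pockets, size_range = c(8L, 16L),
                                       rule = planted_rule(), seed = 1L) {
  stopifnot(size_range[1L] >= 3L, size_range[2L] <= 50L,
            size_range[1L] <= size_range[2L])
  with_seed(seed, .gen_population(n_pockets, size_range, rule))
}

# --- labeled pairs ----------------------------------------------------------

#' Generate a planted-rule labeled pair dataset
#'
#' Draws both sides from finite populations reused across pairs — a panel
#' of pocket structures and a library of compounds — emulating a screening
#' campaign of a fixed compound library against a fixed target panel; a
#' pair is a (compound, pocket) combination, and distinct draws of the
#' generator yield disjoint combinations rather than disjoint molecules.
#' Reuse is also what makes the planted rule identifiable by a two-branch
#' model whose head is additive across branches: every library compound
#' (and every panel pocket) occurs with both labels, so no single branch
#' can interpolate the labels and the fit must recover the motif rule.
#'
#' Under the conjunctive rule, motif presence is sampled at rate
#' `1/sqrt(2)` per branch so actives and decoys are balanced (~50%) at
#' noise 0 while neither motif alone determines the label. For a
#' pocket-only rule (`compound_motif = NULL`) the pocket motif is drawn at
#' rate 1/2.
#'
#' @param n_pairs number of pairs (>= 20).
#' @param rule a [planted_rule()].
#' @param seed RNG seed; generation is bit-reproducible.
#' @param n_pockets size of the pocket panel.
#' @param n_compounds size of the compound library (half with the motif).
#' @param size_range residues per pocket.
#' @return list of pairs: `compound` ([molecular_graph()]), `pocket`
#'   (`pocket_graph`), `label` (post-noise 0/1), plus bookkeeping fields
#'   `smiles`, `compound_motif`, `pocket_motif`, `label_preflip`. The
#'   pocket panel and rule are attached as attributes `pockets` and `rule`.
#' @export
generate_labeled_pairs <- function(n_pairs, rule = planted_rule(),
                                   seed = 1L, n_pockets = 40L,
                                   n_compounds = 80L,
                                   size_range = c(8L, 16L)) {
  stopifnot(n_pairs >= 20L, n_compounds >= 4L)
  with_seed(seed, {
    panel <- .gen_population(n_pockets, size_range, rule)
    motif_ids <- which(vapply(panel, `[[`, logical(1L), "motif"))
    plain_ids <- setdiff(seq_along(panel), motif_ids)
    half <- ceiling(n_compounds / 2)
    library_flags <- seq_len(n_compounds) <= half
    compounds <- lapply(seq_len(n_compounds), function(k) {
      smiles <- .gen_smiles(library_flags[k])
      g <- parse_smiles(smiles)
      attr(g, "graph_id") <- sprintf("cmpd-lib-%04d", k)
      list(graph = g, smiles = smiles, motif = library_flags[k])
    })
    cmpd_motif_ids <- which(library_flags)
    cmpd_plain_ids <- which(!library_flags)
    conj <- !is.null(rule$compound_motif)
    p_motif <- if (conj) 1 / sqrt(2) else 0.5
    pairs <- lapply(seq_len(n_pairs), function(k) {
      pflag <- runif(1L) < p_motif
      cflag <- if (conj) runif(1L) < 1 / sqrt(2) else runif(1L) < 0.5
      pocket_id <- if (pflag) sample(motif_ids, 1L) else sample(plain_ids, 1L)
      cmpd_id <- if (cflag) sample(cmpd_motif_ids, 1L) else {
        sample(cmpd_plain_ids, 1L)
      }
      pre <- as.integer(pflag && (!conj || cflag))
      lab <- if (runif(1L) < rule$noise_rate) 1L - pre else pre
      list(compound = compounds[[cmpd_id]]$graph,
           pocket = panel[[pocket_id]]$graph, label = lab,
           smiles = compounds[[cmpd_id]]$smiles, compound_motif = cflag,
           pocket_motif = pflag, label_preflip = pre,
           compound_id = cmpd_id, pocket_id = pocket_id)
    })
    attr(pairs, "pockets") <- panel
    attr(pairs, "compounds") <- compounds
    attr(pairs, "rule") <- rule
    pairs
  })
}

#' Generate a train/test split of planted-rule pairs
#'
#' Draws one pocket panel and one compound library, then a training set and
#' a test set of (compound, pocket) combinations from them, rejecting any
#' test combination already present in training: the held-out pairs are
#' unseen combinations of seen molecules and seen pockets, the screening
#' analogue of predicting untested compound-target pairs.
#'
#' @inheritParams generate_labeled_pairs
#' @param n_train,n_test sizes of the two sets.
#' @return list with `train` and `test` pair lists (the shared populations
#'   attached to both as attributes).
#' @export
generate_split <- function(n_train, n_test, rule = planted_rule(),
                           seed = 1L, n_pockets = 40L, n_compounds = 80L,
                           size_range = c(8L, 16L)) {
  both <- generate_labeled_pairs(n_train + 4L * n_test, rule, seed,
                                 n_pockets, n_compounds, size_range)
  combo <- vapply(both, function(p) {
    paste0(p$compound_id, ":", p$pocket_id)
  }, character(1L))
  train <- both[seq_len(n_train)]
  rest <- setdiff(seq_along(both), seq_len(n_train))
  fresh <- rest[!(combo[rest] %in% combo[seq_len(n_train)]) &
                  !duplicated(combo[rest])]
  if (length(fresh) < n_test) {
    stop("could not assemble ", n_test, " held-out combinations; ",
         "increase the panel or library size")
  }
  test <- both[fresh[seq_len(n_test)]]
  for (a in c("pockets", "compounds", "rule")) {
    attr(train, a) <- attr(both, a)
    attr(test, a) <- attr(both, a)
  }
  list(train = train, test = test)
}

# --- toy complexes ----------------------------------------------------------

.pdb_atom_line <- function(record, serial, name, resn, chain, resno, xyz,
                           element) {
  sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resn, chain, resno, xyz[1L], xyz[2L],
          xyz[3L], 1, 0, element)
}

#' Generate a toy protein-ligand complex PDB with planted contact geometry
#'
#' Emits a syntactically valid PDB text in which each residue's nearest
#' heavy atom sits at a planned minimum distance from the ligand. The
#' expected contact set at any cutoff is then exactly the residues whose
#' planned distance is at or below it, which the generator verifies
#' internally against the emitted coordinates.
#'
#' Geometry: ligand heavy atoms form a tight cluster at the origin;
#' residue `k` lies along its own ray, with its CB placed (by root finding)
#' so its minimum distance to the ligand equals `contact_plan[k]`, and CA
#' and N further out along the same ray.
#'
#' @param n_residues number of residues.
#' @param n_ligand_atoms number of ligand heavy atoms.
#' @param contact_plan numeric vector (length `n_residues`) of planned
#'   minimum residue-ligand distances in Angstrom, all positive.
#' @param seed RNG seed; identical seeds give identical file bytes.
#' @param ligand_code HETATM residue code for the ligand.
#' @return list with `pdb` (the PDB text, one string),
#'   `planned_distances`, and `ligand_code`.
#' @export
generate_toy_complex_pdb <- function(n_residues, n_ligand_atoms,
                                     contact_plan, seed = 1L,
                                     ligand_code = "LIG") {
  stopifnot(length(contact_plan) == n_residues, all(contact_plan > 0),
            n_ligand_atoms >= 1L, n_residues >= 1L)
  with_seed(seed, {
    lig <- matrix(0, n_ligand_atoms, 3L)
    if (n_ligand_atoms > 1L) {
      for (a in 2:n_ligand_atoms) {
        repeat {
          p <- runif(3L, -0.7, 0.7)
          if (sum(p^2) <= 0.7^2) break
        }
        lig[a, ] <- p
      }
    }
    lig <- round(lig, 3)                         # match PDB coordinate precision
    # well-separated ray directions so residues do not crowd each other
    dirs <- matrix(NA_real_, n_residues, 3L)
    for (k in seq_len(n_residues)) {
      placed <- FALSE
      for (try in 1:2000) {
        u <- rnorm(3L)
        u <- u / sqrt(sum(u^2))
        if (k == 1L ||
            max(dirs[seq_len(k - 1L), , drop = FALSE] %*% u) < cos(pi / 7)) {
          dirs[k, ] <- u
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible geometry: too many residues to separate")
    }
    min_lig_dist <- function(p) {
      sqrt(min(rowSums((lig - matrix(p, nrow(lig), 3L, byrow = TRUE))^2)))
    }
    lines <- character()
    serial <- 0L
    aa_pool <- setdiff(AA20, "GLY")
    achieved <- numeric(n_residues)
    for (k in seq_len(n_residues)) {
      dk <- contact_plan[k]
      u <- dirs[k, ]
      f <- function(t) min_lig_dist(t * u) - dk
      t0 <- if (abs(f(dk)) < 1e-12) dk else {
        stats::uniroot(f, c(dk, dk + 0.71), tol = 1e-12)$root
      }
      cb <- round(t0 * u, 3)                     # PDB precision is 0.001 A
      ca <- round((t0 + 1.53) * u, 3)
      nn <- round((t0 + 2.5) * u, 3)
      achieved[k] <- min(min_lig_dist(cb), min_lig_dist(ca),
                         min_lig_dist(nn))
      aa <- sample(aa_pool, 1L)
      for (atom in list(list("N", nn, "N"), list("CA", ca, "C"),
                        list("CB", cb, "C"))) {
        serial <- serial + 1L
        lines <- c(lines, .pdb_atom_line("ATOM", serial, atom[[1L]], aa,
                                         "A", k, atom[[2L]], atom[[3L]]))
      }
    }
    for (a in seq_len(n_ligand_atoms)) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line("HETATM", serial,
                                       sprintf("C%d", a), ligand_code, "L",
                                       900L, lig[a, ], "C"))
    }
    lines <- c(lines, "END")
    if (any(abs(achieved - contact_plan) > 5e-3)) {
      stop("internal error: emitted geometry misses the contact plan")
    }
    list(pdb = paste(lines, collapse = "\n"),
         planned_distances = contact_plan, ligand_code = ligand_code)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Generates a planted-rule pair dataset and writes the same formats the
#' pipeline consumes: one pocket-graph text file per panel pocket, a
#' tab-separated pair list (`compound_id`, `smiles`, `pocket_file`,
#' `label`), and a manifest recording the seed and rule parameters.
#'
#' @inheritParams generate_labeled_pairs
#' @param out_dir output directory (created if missing).
#' @return invisibly, the path of the pair list file.
#' @export
simulate_dataset <- function(out_dir, n_pairs, rule = planted_rule(),
                             seed = 1L, n_pockets = 40L) {
  dir.create(file.path(out_dir, "pockets"), recursive = TRUE,
             showWarnings = FALSE)
  pairs <- generate_labeled_pairs(n_pairs, rule, seed, n_pockets)
  panel <- attr(pairs, "pockets")
  for (p in panel) {
    id <- attr(p$graph, "graph_id")
    write_pocket_graph(p$graph, file.path(out_dir, "pockets",
                                          paste0(id, ".txt")))
  }
  rows <- vapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    pid <- attr(p$pocket, "graph_id")
    sprintf("%s\t%s\tpockets/%s.txt\t%d", attr(p$compound, "graph_id"),
            p$smiles, pid, p$label)
  }, character(1L))
  pairs_path <- file.path(out_dir, "pairs.tsv")
  writeLines(c("compound_id\tsmiles\tpocket_file\tlabel", rows), pairs_path)
  writeLines(c(
    "# pocketgnn synthetic dataset manifest",
    paste0("seed\t", seed),
    paste0("n_pairs\t", n_pairs),
    paste0("n_pockets\t", n_pockets),
    paste0("pocket_motif\t", rule$pocket_motif_aa, " x", rule$pocket_motif_k),
    paste0("compound_motif\t", rule$compound_motif %||% "none"),
    paste0("noise_rate\t", rule$noise_rate),
    paste0("n_active\t", sum(vapply(pairs, `[[`, 0L, "label")))),
    file.path(out_dir, "manifest.txt"))
  invisible(pairs_path)
}
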