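test_that("toy complexes realize their contact plans exactly", {
  toy <- generate_toy_complex_pdb(4, 3, c(2, 4, 5, 8), seed = 12)
  pk <- parse_pdb_complex(toy$pdb, toy$ligand_code)
  got <- vapply(
    extract_contact_residues(pk$residues, pk$ligand_xyz, 4.5),
    function(r) r$resno, 0L)
  expect_identical(got, c(1L, 2L))
  # nothing within cutoff
  toy2 <- generate_toy_complex_pdb(3, 1, c(6, 7, 8), seed = 12)
  pk2 <- parse_pdb_complex(toy2$pdb, "LIG")
  expect_warning(
    none <- extract_contact_residues(pk2$residues, pk2$ligand_xyz, 4.5),
    "empty")
  expect_length(none, 0L)
  # byte-identical regeneration
  expect_identical(toy$pdb,
                   generate_toy_complex_pdb(4, 3, c(2, 4, 5, 8),
                                            seed = 12)$pdb)
  expect_error(generate_toy_complex_pdb(2, 1, c(-1, 3), seed = 1))
})

test_that("pocket populations carry the motif and exercise all edge classes", {
  rule <- planted_rule(pocket_motif_aa = "TRP", pocket_motif_k = 3L)
  pop <- generate_pocket_population(200, rule = rule, seed = 6)
  motif <- vapply(pop, `[[`, logical(1L), "motif")
  expect_equal(sum(motif), 100L)
  for (p in pop) {
    n_trp <- sum(p$graph$residues$aa3 == "TRP")
    if (p$motif) expect_gte(n_trp, 3L) else expect_equal(n_trp, 0L)
    expect_gte(nrow(p$graph$edges), 1L)
  }
  classes <- unlist(lapply(pop, function(p) p$graph$edges$class))
  expect_setequal(unique(classes), c("I", "II", "III", "IV", "V"))
  # determinism
  pop2 <- generate_pocket_population(200, rule = rule, seed = 6)
  expect_identical(lapply(pop, `[[`, "graph"), lapply(pop2, `[[`, "graph"))
})

test_that("labeled pairs follow the conjunctive rule with balanced classes", {
  rule <- planted_rule(noise_rate = 0)
  pairs <- generate_labeled_pairs(1000, rule, seed = 8)
  labs <- vapply(pairs, `[[`, 0L, "label")
  expect_gte(mean(labs), 0.45)
  expect_lte(mean(labs), 0.55)
  for (p in pairs[1:50]) {
    expect_s3_class(p$compound, "molecular_graph")
    expect_identical(p$label_preflip,
                     as.integer(p$compound_motif && p$pocket_motif))
    expect_identical(p$label, p$label_preflip)   # noise 0
    # recorded flags agree with direct motif checks on the graphs
    expect_identical(compound_has_motif(p$compound, rule), p$compound_motif)
    expect_identical(pocket_has_motif(p$pocket, rule), p$pocket_motif)
  }
  # neither motif alone determines the label
  cm <- vapply(pairs, `[[`, logical(1L), "compound_motif")
  pm <- vapply(pairs, `[[`, logical(1L), "pocket_motif")
  expect_gt(mean(labs[cm]), 0)
  expect_lt(mean(labs[cm]), 1)
  expect_gt(mean(labs[pm]), 0)
  expect_lt(mean(labs[pm]), 1)
})

test_that("generated SMILES always parse and noise flips at the stated rate", {
  smis <- generate_compound_smiles(200, with_motif = c(TRUE, FALSE),
                                   seed = 3)
  for (s in smis) expect_false(is_excluded(parse_smiles(s)))
  rule <- planted_rule(noise_rate = 0.2)
  pairs <- generate_labeled_pairs(1500, rule, seed = 9)
  flipped <- vapply(pairs, function(p) p$label != p$label_preflip, logical(1L))
  # binomial(1500, 0.2): 4 sigma is about 0.041
  expect_gt(mean(flipped), 0.2 - 0.045)
  expect_lt(mean(flipped), 0.2 + 0.045)
})

test_that("the rule oracle achieves AUROC 1 at noise 0", {
  rule <- planted_rule(noise_rate = 0)
  pairs <- generate_labeled_pairs(300, rule, seed = 5)
  labs <- vapply(pairs, `[[`, 0L, "label")
  expect_equal(auroc(oracle_rule_score(pairs, rule), labs), 1.0)
})

test_that("pair generation is bit-reproducible and split combos are disjoint", {
  rule <- planted_rule()
  p1 <- generate_labeled_pairs(50, rule, seed = 77)
  p2 <- generate_labeled_pairs(50, rule, seed = 77)
  expect_identical(p1, p2)
  sp <- generate_split(120, 60, rule, seed = 13, n_pockets = 15L,
                       n_compounds = 30L)
  expect_length(sp$train, 120L)
  expect_length(sp$test, 60L)
  combo <- function(ps) vapply(ps, function(p) {
    paste0(p$compound_id, ":", p$pocket_id)
  }, character(1L))
  expect_length(intersect(combo(sp$train), combo(sp$test)), 0L)
  # populations are shared between the two sides
  expect_identical(attr(sp$train, "pockets"), attr(sp$test, "pockets"))
})

test_that("pocket-only rules need no compound motif", {
  rule <- planted_rule(compound_motif = NULL)
  pairs <- generate_labeled_pairs(200, rule, seed = 4)
  labs <- vapply(pairs, `[[`, 0L, "label")
  pm <- vapply(pairs, `[[`, logical(1L), "pocket_motif")
  expect_identical(labs, as.integer(pm))
  expect_gte(mean(labs), 0.4)
  expect_lte(mean(labs), 0.6)
})

test_that("simulated datasets round-trip through the pair-list reader", {
  out <- withr::local_tempdir()
  simulate_dataset(out, 40, planted_rule(), seed = 21, n_pockets = 10L)
  expect_true(file.exists(file.path(out, "manifest.txt")))
  loaded <- read_pair_list(file.path(out, "pairs.tsv"))
  expect_length(loaded$pairs, 40L)
  orig <- generate_labeled_pairs(40, planted_rule(), seed = 21,
                                 n_pockets = 10L)
  for (k in c(1L, 7L, 40L)) {
    expect_identical(loaded$pairs[[k]]$label, orig[[k]]$label)
    expect_identical(loaded$pairs[[k]]$compound$vertex_labels,
                     orig[[k]]$compound$vertex_labels)
    expect_identical(loaded$pairs[[k]]$pocket$edges, orig[[k]]$pocket$edges)
  }
})
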