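test_that("Calpha distance binning follows the five half-open intervals", {
  expect_identical(bin_ca_distance(c(3, 8, 12)), c("I", "III", "V"))
  # shared boundaries go to the upper bin
  expect_identical(bin_ca_distance(c(1.0, 4.8, 7.0, 9.2, 11.4)),
                   c("I", "II", "III", "IV", "V"))
  expect_identical(bin_ca_distance(c(0.5, 13.6, 14.0)),
                   rep(NA_character_, 3L))
  expect_error(bin_ca_distance(-1), "negative")
})

test_that("amino-acid one-hot encoding uses the fixed alphabetical order", {
  a <- residue_one_hot("ALA")
  expect_equal(unname(a[1L]), 1)
  expect_equal(sum(a), 1)
  v <- residue_one_hot("VAL")
  expect_equal(unname(v[20L]), 1)
  expect_error(residue_one_hot("MSE"),
               class = "pocketgnn_nonstandard_residue")
})

test_that("toy complex round-trips through the PDB parser", {
  toy <- generate_toy_complex_pdb(3, 2, c(2, 3, 4), seed = 11)
  parsed <- parse_pdb_complex(toy$pdb, "LIG")
  expect_length(parsed$residues, 3L)
  expect_equal(nrow(parsed$ligand_xyz), 2L)
  expect_true(all(vapply(parsed$residues, function(r) r$aa3 %in% AA20,
                         logical(1L))))
})

test_that("missing ligand code and missing ATOM records are explicit errors", {
  toy <- generate_toy_complex_pdb(2, 1, c(3, 5), seed = 2)
  expect_error(parse_pdb_complex(toy$pdb, "XYZ"),
               class = "pocketgnn_ligand_not_found")
  expect_error(parse_pdb_complex(toy$pdb, "HOH"),
               class = "pocketgnn_ligand_not_found")
  hetatm_only <- paste(grep("^HETATM", strsplit(toy$pdb, "\n")[[1L]],
                            value = TRUE), collapse = "\n")
  expect_error(parse_pdb_complex(paste0(hetatm_only, "\nEND\n"), "LIG"),
               class = "pocketgnn_bad_pdb")
})

test_that("residues lacking a CA atom are dropped with a warning", {
  toy <- generate_toy_complex_pdb(3, 1, c(2, 3, 4), seed = 5)
  lines <- strsplit(toy$pdb, "\n")[[1L]]
  # strip the CA line of residue 2
  drop <- grepl("^ATOM", lines) & grepl(" CA ", lines) &
    substr(lines, 23, 26) == "   2"
  expect_true(any(drop))
  expect_warning(parsed <- parse_pdb_complex(
    paste(lines[!drop], collapse = "\n"), "LIG"), "CA")
  expect_length(parsed$residues, 2L)
})

test_that("contact extraction matches the planted distances and nests monotonically", {
  toy <- generate_toy_complex_pdb(4, 3, c(2, 4, 5, 8), seed = 21)
  parsed <- parse_pdb_complex(toy$pdb, "LIG")
  contacts <- extract_contact_residues(parsed$residues, parsed$ligand_xyz,
                                       4.5)
  expect_identical(vapply(contacts, function(r) r$resno, 0L), c(1L, 2L))
  # monotone nesting in the cutoff
  prev <- character()
  for (cutoff in c(1, 2.5, 4.5, 6, 9)) {
    cur <- vapply(
      suppressWarnings(extract_contact_residues(parsed$residues,
                                                parsed$ligand_xyz, cutoff)),
      function(r) paste(r$chain, r$resno), character(1L))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_warning(extract_contact_residues(parsed$residues,
                                          parsed$ligand_xyz, 0.5),
                 "empty pocket")
})

test_that("pocket graphs connect residue pairs exactly by their distance bin", {
  r2 <- list(mk_residue(1, "ALA", c(0, 0, 0)),
             mk_residue(2, "TRP", c(3.8, 0, 0)))
  g <- build_pocket_graph(r2)
  expect_equal(nrow(g$edges), 1L)
  expect_identical(g$edges$class, "I")

  far <- list(mk_residue(1, "ALA", c(0, 0, 0)),
              mk_residue(2, "TRP", c(20, 0, 0)))
  expect_equal(nrow(build_pocket_graph(far)$edges), 0L)

  # four residues on a line at 0, 5, 10, 15 Angstrom
  line <- lapply(1:4, function(k) {
    mk_residue(k, "GLY", c(5 * (k - 1), 0, 0))
  })
  g4 <- build_pocket_graph(line)
  got <- g4$edges[order(g4$edges$i, g4$edges$j), ]
  expect_equal(nrow(got), 5L)             # (1,4) at 15 A is beyond the bins
  expect_identical(
    paste(got$i, got$j, got$class),
    c("1 2 II", "1 3 IV", "2 3 II", "2 4 IV", "3 4 II"))
})

test_that("one-hot rows are exact indicators and non-admissible residues drop", {
  res <- list(mk_residue(1, "ALA", c(0, 0, 0)),
              mk_residue(2, "MSE", c(4, 0, 0)),
              mk_residue(3, "VAL", c(8, 0, 0)))
  expect_warning(g <- build_pocket_graph(res), "MSE")
  expect_equal(nrow(g$residues), 2L)
  expect_true(all(rowSums(g$onehot) == 1))
  expect_true(all(g$onehot %in% c(0, 1)))
  expect_equal(unname(which(g$onehot[1L, ] == 1)), 1L)    # ALA
  expect_equal(unname(which(g$onehot[2L, ] == 1)), 20L)   # VAL
  expect_error(build_pocket_graph(list(mk_residue(1, "MSE", c(0, 0, 0)))) |>
                 suppressWarnings(),
               class = "pocketgnn_empty_pocket")
})

test_that("pocket edges match a brute-force double loop and survive rigid motion", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:30, 1L)
    ca <- matrix(rnorm(n * 3L, sd = 6), n, 3L)
    res <- lapply(seq_len(n), function(k) {
      mk_residue(k, sample(AA20, 1L), ca[k, ])
    })
    g <- build_pocket_graph(res)
    # independent double loop over all pairs
    expected <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      cls <- if (d >= 1.0 && d < 4.8) "I" else if (d < 7.0 && d >= 4.8) "II"
        else if (d >= 7.0 && d < 9.2) "III" else if (d >= 9.2 && d < 11.4) "IV"
        else if (d >= 11.4 && d < 13.6) "V" else NA_character_
      if (!is.na(cls)) expected[[length(expected) + 1L]] <- c(i, j, cls)
    }
    exp_df <- if (length(expected)) {
      as.data.frame(do.call(rbind, expected), stringsAsFactors = FALSE)
    } else data.frame(V1 = character(), V2 = character(), V3 = character())
    expect_equal(nrow(g$edges), nrow(exp_df))
    if (nrow(exp_df)) {
      expect_identical(paste(g$edges$i, g$edges$j, g$edges$class),
                       paste(exp_df$V1, exp_df$V2, exp_df$V3))
    }
    # rigid motion leaves the graph unchanged
    ca2 <- rigid_transform(ca)
    res2 <- lapply(seq_len(n), function(k) {
      mk_residue(k, res[[k]]$aa3, ca2[k, ])
    })
    g2 <- build_pocket_graph(res2)
    expect_identical(g$edges, g2$edges)
  }
})

test_that("pocket graph text format round-trips losslessly", {
  toy <- generate_toy_complex_pdb(5, 2, c(2, 3, 4, 4.2, 6), seed = 31)
  pocket <- extract_pocket(toy$pdb, "LIG", 4.5)
  expect_equal(nrow(pocket$residues), 4L)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_pocket_graph(pocket, tf)
  back <- read_pocket_graph(tf)
  expect_identical(back$residues, pocket$residues)
  expect_identical(back$edges, pocket$edges)
  expect_equal(back$ca, pocket$ca, tolerance = 1e-5)
})
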