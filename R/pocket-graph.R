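# Binding-pocket residue graphs from PDB complex structures.
#
# A pocket is the set of residues in contact with a co-crystallized ligand.
# Vertices carry 20-dimensional amino-acid one-hot labels; an edge joins two
# residues when their Calpha-Calpha distance falls in one of five bins.

#' The 20 standard amino acids, alphabetical by three-letter code
#'
#' Fixed ordering used for the one-hot encoding: `ALA` is index 1 (slot 0 of
#' the vector) through `VAL` at index 20.
#' @export
AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Calpha-Calpha distance bin boundaries (Angstrom)
#'
#' Five half-open intervals `[lo, hi)`: I `[1.0, 4.8)`, II `[4.8, 7.0)`,
#' III `[7.0, 9.2)`, IV `[9.2, 11.4)`, V `[11.4, 13.6)`. Distances outside
#' `[1.0, 13.6)` produce no edge.
#' @export
CA_DISTANCE_BREAKS <- c(1.0, 4.8, 7.0, 9.2, 11.4, 13.6)

EDGE_CLASSES <- c("I", "II", "III", "IV", "V")

#' Bin a Calpha-Calpha distance into an edge class
#'
#' Half-open convention: a boundary value belongs to the upper bin (4.8 is
#' class II). Distances below 1.0 (a clash, a data-quality issue) or at or
#' above 13.6 Angstrom yield no edge, encoded `NA`.
#'
#' @param d numeric vector of non-negative distances in Angstrom.
#' @return character vector in `c("I","II","III","IV","V")`, `NA` = no edge.
#' @examples
#' bin_ca_distance(c(3, 4.8, 8, 12, 14))  # "I" "II" "III" "V" NA
#' @export
bin_ca_distance <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0, na.rm = TRUE)) stop("negative distance")
  idx <- findInterval(d, CA_DISTANCE_BREAKS)      # 0 below 1.0, 6 at/above 13.6
  out <- rep(NA_character_, length(d))
  inband <- idx >= 1L & idx <= 5L & !is.na(idx)
  out[inband] <- EDGE_CLASSES[idx[inband]]
  out
}

#' One-hot encode an amino-acid type
#'
#' @param aa3 a standard three-letter amino-acid code (see [AA20]).
#' @return named 0/1 vector of length 20 with a single 1 at the position of
#'   `aa3` in the fixed alphabetical ordering.
#' @export
residue_one_hot <- function(aa3) {
  stopifnot(is.character(aa3), length(aa3) == 1L)
  k <- match(aa3, AA20)
  if (is.na(k)) {
    stop_classed("pocketgnn_nonstandard_residue",
                 paste0("non-standard residue type: ", aa3))
  }
  v <- stats::setNames(numeric(20L), AA20)
  v[k] <- 1
  v
}

.residue <- function(chain, resno, insert, aa3, ca, xyz) {
  list(chain = chain, resno = resno, insert = insert, aa3 = aa3,
       ca = ca, xyz = xyz)
}

#' Parse a protein-ligand complex from PDB text
#'
#' Reads fixed-column PDB (via bio3d), groups protein `ATOM` records into
#' residues by (chain, residue number, insertion code), and collects the
#' heavy atoms of the named `HETATM` ligand. Waters are never treated as
#' ligand. Only the first copy of the ligand is used when several share the
#' code. Residues lacking a Calpha record are dropped with a warning (they
#' cannot enter a pocket graph). Alternate locations: first kept.
#'
#' @param pdb PDB file path, or the PDB text itself (anything containing a
#'   newline is treated as text).
#' @param ligand_code three-letter HETATM residue code of the ligand.
#' @return list with `residues` (list of residue records: `chain`, `resno`,
#'   `insert`, `aa3`, `ca` 3-vector, `xyz` heavy-atom coordinate matrix) and
#'   `ligand_xyz` (matrix of ligand heavy-atom coordinates).
#' @export
parse_pdb_complex <- function(pdb, ligand_code) {
  stopifnot(is.character(pdb), length(pdb) == 1L,
            is.character(ligand_code), length(ligand_code) == 1L)
  if (identical(toupper(ligand_code), "HOH")) {
    stop_classed("pocketgnn_ligand_not_found", "water cannot be the ligand")
  }
  if (grepl("\n", pdb, fixed = TRUE)) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1L]], tf)
    pdb <- tf
  }
  parsed <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- parsed$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) {
    stop_classed("pocketgnn_bad_pdb", "no ATOM records in PDB input")
  }
  heavy <- function(df) {
    el <- df$elesy
    miss <- is.na(el) | !nzchar(el)
    el[miss] <- substr(trimws(df$elety[miss]), 1L, 1L)
    df[toupper(el) != "H", , drop = FALSE]
  }
  prot <- heavy(prot)
  lig <- at[at$type == "HETATM" & at$resid == ligand_code, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop_classed("pocketgnn_ligand_not_found",
                 paste0("ligand code not found in PDB: ", ligand_code))
  }
  lig <- heavy(lig)
  lig_key <- paste(lig$chain, lig$resno, lig$insert)
  lig <- lig[lig_key == lig_key[1L], , drop = FALSE]   # first copy only
  ligand_xyz <- as.matrix(lig[, c("x", "y", "z")])

  key <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  groups <- split(seq_len(nrow(prot)), factor(key, levels = unique(key)))
  residues <- vector("list", length(groups))
  dropped <- character()
  for (g in seq_along(groups)) {
    rows <- prot[groups[[g]], , drop = FALSE]
    ca_row <- which(trimws(rows$elety) == "CA")
    if (length(ca_row) == 0L) {
      dropped <- c(dropped,
                   sprintf("%s%d %s", rows$chain[1L], rows$resno[1L],
                           rows$resid[1L]))
      next
    }
    residues[[g]] <- .residue(
      chain = rows$chain[1L], resno = rows$resno[1L],
      insert = if (is.na(rows$insert[1L])) "" else rows$insert[1L],
      aa3 = rows$resid[1L],
      ca = as.numeric(rows[ca_row[1L], c("x", "y", "z")]),
      xyz = as.matrix(rows[, c("x", "y", "z")]))
  }
  residues <- residues[!vapply(residues, is.null, logical(1L))]
  if (length(dropped)) {
    warning("dropped residue(s) lacking a CA atom: ",
            paste(dropped, collapse = ", "))
  }
  list(residues = residues, ligand_xyz = ligand_xyz)
}

#' Identify ligand-contact residues
#'
#' A residue is in contact when at least one of its heavy atoms lies within
#' `contact_cutoff` of any ligand heavy atom (minimum atom-atom distance
#' criterion; an explicit, reproducible stand-in for contact-surface
#' software). Output preserves the input residue order.
#'
#' @param residues residue list from [parse_pdb_complex()].
#' @param ligand_xyz matrix of ligand heavy-atom coordinates.
#' @param contact_cutoff contact distance threshold in Angstrom (default 4.5).
#' @return the contacting subset of `residues`.
#' @export
extract_contact_residues <- function(residues, ligand_xyz,
                                     contact_cutoff = 4.5) {
  stopifnot(contact_cutoff > 0)
  ligand_xyz <- as.matrix(ligand_xyz)
  if (nrow(ligand_xyz) == 0L) {
    stop_classed("pocketgnn_empty_ligand", "ligand has no heavy atoms")
  }
  hit <- vapply(residues, function(res) {
    xyz <- res$xyz
    d2min <- min(vapply(seq_len(nrow(ligand_xyz)), function(a) {
      min(rowSums((xyz - matrix(ligand_xyz[a, ], nrow(xyz), 3,
                                byrow = TRUE))^2))
    }, numeric(1L)))
    sqrt(d2min) <= contact_cutoff
  }, logical(1L))
  out <- residues[hit]
  if (length(out) == 0L) {
    warning("no residues within ", contact_cutoff,
            " Angstrom of the ligand (empty pocket)")
  }
  out
}

#' Build a pocket residue-interaction graph
#'
#' Vertices are the admitted contact residues (standard amino-acid type and
#' a Calpha coordinate required; others are dropped with a warning), labeled
#' by 20-dimensional one-hot vectors. For every residue pair an edge exists
#' iff the Calpha-Calpha distance falls into one of the five bins of
#' [bin_ca_distance()], and carries that class. Bonded and non-bonded
#' residue interactions are represented solely through these distance bins.
#'
#' @param contact_residues residue list (see [extract_contact_residues()]).
#' @return an object of class `pocket_graph`: `residues` (data frame with
#'   `chain`, `resno`, `insert`, `aa3`), `ca` (n x 3 matrix),
#'   `onehot` (n x 20 matrix), `edges` (data frame `i`, `j`, `class`).
#' @export
build_pocket_graph <- function(contact_residues) {
  ok <- vapply(contact_residues, function(r) {
    r$aa3 %in% AA20 && !is.null(r$ca) && all(is.finite(r$ca))
  }, logical(1L))
  if (any(!ok)) {
    bad <- vapply(contact_residues[!ok], function(r) {
      sprintf("%s%s %s", r$chain, r$resno, r$aa3)
    }, character(1L))
    warning("dropped non-admissible residue(s): ", paste(bad, collapse = ", "))
  }
  contact_residues <- contact_residues[ok]
  n <- length(contact_residues)
  if (n == 0L) {
    stop_classed("pocketgnn_empty_pocket", "no admissible pocket residues")
  }
  res_df <- data.frame(
    chain = vapply(contact_residues, `[[`, "", "chain"),
    resno = vapply(contact_residues, function(r) as.integer(r$resno), 0L),
    insert = vapply(contact_residues, function(r) r$insert %||% "", ""),
    aa3 = vapply(contact_residues, `[[`, "", "aa3"),
    stringsAsFactors = FALSE)
  ca <- do.call(rbind, lapply(contact_residues, `[[`, "ca"))
  onehot <- do.call(rbind, lapply(res_df$aa3, residue_one_hot))
  rownames(onehot) <- NULL
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    d <- sqrt(colSums((t(ca[pairs[1L, ], , drop = FALSE]) -
                       t(ca[pairs[2L, ], , drop = FALSE]))^2))
    cls <- bin_ca_distance(d)
    keep <- !is.na(cls)
    edges <- data.frame(i = pairs[1L, keep], j = pairs[2L, keep],
                        class = cls[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(i = integer(), j = integer(), class = character())
  }
  structure(list(residues = res_df, ca = ca, onehot = onehot, edges = edges),
            class = "pocket_graph")
}

#' Extract a pocket graph from a PDB complex in one call
#'
#' Convenience pipeline: [parse_pdb_complex()] then
#' [extract_contact_residues()] then [build_pocket_graph()].
#'
#' @inheritParams parse_pdb_complex
#' @inheritParams extract_contact_residues
#' @return a `pocket_graph`.
#' @export
extract_pocket <- function(pdb, ligand_code, contact_cutoff = 4.5) {
  parsed <- parse_pdb_complex(pdb, ligand_code)
  contacts <- extract_contact_residues(parsed$residues, parsed$ligand_xyz,
                                       contact_cutoff)
  build_pocket_graph(contacts)
}

#' @export
print.pocket_graph <- function(x, ...) {
  cat(sprintf("Pocket graph: %d residues, %d edges\n",
              nrow(x$residues), nrow(x$edges)))
  tab <- table(factor(x$edges$class, levels = EDGE_CLASSES))
  cat("  edge classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Write a pocket graph to its text format
#'
#' Versioned, lossless plain-text format: a header, one residue line per
#' vertex (`res<TAB>chain<TAB>resno<TAB>insert<TAB>aa3<TAB>x<TAB>y<TAB>z`),
#' then one `edge<TAB>i<TAB>j<TAB>class` line per edge.
#'
#' @param pocket a `pocket_graph`.
#' @param path output file.
#' @export
write_pocket_graph <- function(pocket, path) {
  stopifnot(inherits(pocket, "pocket_graph"))
  r <- pocket$residues
  lines <- c(
    "# pocketgnn pocket-graph v1",
    sprintf("res\t%s\t%d\t%s\t%s\t%.6f\t%.6f\t%.6f",
            r$chain, r$resno, r$insert, r$aa3,
            pocket$ca[, 1L], pocket$ca[, 2L], pocket$ca[, 3L]),
    if (nrow(pocket$edges)) {
      sprintf("edge\t%d\t%d\t%s", pocket$edges$i, pocket$edges$j,
              pocket$edges$class)
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a pocket graph written by [write_pocket_graph()]
#'
#' @param path file path.
#' @return a `pocket_graph`.
#' @export
read_pocket_graph <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("pocket-graph v1", lines[1L], fixed = TRUE)) {
    stop("not a pocketgnn pocket-graph v1 file: ", path)
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  kinds <- vapply(parts, `[`, "", 1L)
  res <- parts[kinds == "res"]
  if (!length(res)) stop("pocket file has no residues: ", path)
  residues <- lapply(res, function(p) {
    .residue(chain = p[2L], resno = as.integer(p[3L]), insert = p[4L],
             aa3 = p[5L], ca = as.numeric(p[6:8]),
             xyz = matrix(as.numeric(p[6:8]), 1L, 3L))
  })
  g <- build_pocket_graph(residues)
  # sanity: edges recomputed from coordinates must match the stored lines
  ed <- parts[kinds == "edge"]
  stored <- if (length(ed)) {
    df <- data.frame(i = vapply(ed, function(p) as.integer(p[2L]), 0L),
                     j = vapply(ed, function(p) as.integer(p[3L]), 0L),
                     class = vapply(ed, `[`, "", 4L),
                     stringsAsFactors = FALSE)
    df[order(df$i, df$j), ]
  } else {
    data.frame(i = integer(), j = integer(), class = character())
  }
  got <- g$edges[order(g$edges$i, g$edges$j), ]
  if (!isTRUE(all.equal(unname(as.matrix(stored[1:2])),
                        unname(as.matrix(got[1:2])))) ||
      !identical(unname(stored$class), unname(got$class))) {
    warning("stored edges disagree with coordinates; using recomputed edges")
  }
  g
}
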