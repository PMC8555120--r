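# Molecular graphs from SMILES.
#
# Parsing is delegated to OpenBabel (via ChemmineOB): SMILES -> MOL2, which
# preserves aromaticity as ".ar" atom types and "ar" bond records, then read
# with bio3d::read.mol2. Hydrogens are implicit and never appear as vertices.

BOND_TYPES <- c("single", "double", "triple", "aromatic")

# MOL2 bond orders -> bond classes. Amide bonds are treated as single;
# OpenBabel emits "ar" for delocalized systems (rings, carboxylates alike).
.mol2_bond_map <- c("1" = "single", "2" = "double", "3" = "triple",
                    "am" = "single", "ar" = "aromatic")

#' Construct a molecular graph
#'
#' Low-level constructor validating the graph invariants: at least one
#' vertex, undirected edges stored once with `i < j`, no self loops, no
#' duplicate edges, bond types among single/double/triple/aromatic.
#'
#' @param vertex_labels character vector of atom labels; an aromatic atom is
#'   suffixed `":ar"` (e.g. `"C:ar"`), so aromatic and aliphatic carbons are
#'   distinct labels.
#' @param edges data frame with integer columns `i`, `j` (1-based vertex
#'   indices) and character column `bond`.
#' @param source_smiles the SMILES string the graph came from.
#' @return an object of class `molecular_graph`.
#' @export
molecular_graph <- function(vertex_labels, edges, source_smiles = NA_character_) {
  stopifnot(is.character(vertex_labels), length(vertex_labels) >= 1L)
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(i = integer(), j = integer(), bond = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("i", "j", "bond") %in% names(edges)))
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  if (nrow(edges)) {
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    if (any(edges$i == edges$j)) stop("self-loops are not allowed")
    n <- length(vertex_labels)
    if (any(edges$i < 1L) || any(edges$j > n)) {
      stop("edge endpoint outside vertex range")
    }
    key <- paste(edges$i, edges$j)
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    if (!all(edges$bond %in% BOND_TYPES)) {
      stop("unknown bond type: ", paste(setdiff(edges$bond, BOND_TYPES),
                                        collapse = ", "))
    }
    edges <- edges[order(edges$i, edges$j), c("i", "j", "bond")]
    rownames(edges) <- NULL
  }
  structure(list(vertex_labels = vertex_labels, edges = edges,
                 source_smiles = source_smiles),
            class = "molecular_graph")
}

#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string to a labeled heavy-atom graph. Vertices are atom
#' types (element symbol, with aromatic atoms carrying a distinct `":ar"`
#' suffix); edges are bonds classed as single, double, triple or aromatic.
#' Hydrogens are implicit and omitted; charges, isotopes and stereochemistry
#' are ignored.
#'
#' A SMILES containing a dot (a disconnected, multi-component structure)
#' cannot give a single connected graph and is excluded: the function then
#' returns an exclusion mark (class `smiles_exclusion`) rather than a graph,
#' so callers can log and skip the record. An unparsable SMILES, by
#' contrast, raises an error of class `pocketgnn_parse_error`.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a [molecular_graph()] object, or an object of class
#'   `smiles_exclusion` (fields `smiles`, `reason`) for dot-disconnected
#'   input.
#' @examples
#' g <- parse_smiles("CCO")
#' g$vertex_labels          # "C" "C" "O"
#' is_excluded(parse_smiles("C.C"))
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) {
    stop_classed("pocketgnn_parse_error", "empty SMILES string")
  }
  if (grepl(".", smiles, fixed = TRUE)) {
    return(structure(list(smiles = smiles, reason = "dot-disconnected"),
                     class = "smiles_exclusion"))
  }
  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", source = smiles),
    error = function(e) "")
  if (!is.character(mol2) || length(mol2) != 1L ||
      !grepl("@<TRIPOS>ATOM", mol2, fixed = TRUE)) {
    stop_classed("pocketgnn_parse_error",
                 paste0("unparsable SMILES: ", smiles))
  }
  mol <- .read_mol2_text(mol2)
  atoms <- mol$atom
  if (is.null(atoms) || nrow(atoms) == 0L) {
    stop_classed("pocketgnn_parse_error",
                 paste0("unparsable SMILES: ", smiles))
  }
  elem <- sub("\\..*$", "", atoms$elety)
  aromatic <- grepl("\\.ar$", atoms$elety)
  keep <- elem != "H"
  if (!any(keep)) {
    stop_classed("pocketgnn_parse_error",
                 paste0("no heavy atoms in SMILES: ", smiles))
  }
  newidx <- cumsum(keep)
  labels <- paste0(elem[keep], ifelse(aromatic[keep], ":ar", ""))
  bonds <- mol$bond
  if (!is.null(bonds) && nrow(bonds)) {
    bkeep <- keep[bonds$origin] & keep[bonds$target]
    bonds <- bonds[bkeep, , drop = FALSE]
  }
  if (is.null(bonds) || nrow(bonds) == 0L) {
    edges <- data.frame(i = integer(), j = integer(), bond = character())
  } else {
    btype <- .mol2_bond_map[as.character(bonds$type)]
    if (anyNA(btype)) {
      stop_classed("pocketgnn_parse_error",
                   paste0("unsupported bond type in SMILES: ", smiles))
    }
    edges <- data.frame(i = newidx[bonds$origin], j = newidx[bonds$target],
                        bond = unname(btype), stringsAsFactors = FALSE)
  }
  molecular_graph(labels, edges, source_smiles = smiles)
}

# Read a MOL2 text block. bio3d::read.mol2 handles the general case but
# fails on bond-less molecules (a single heavy atom), which are parsed
# directly from the ATOM section here.
.read_mol2_text <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1L]]
  counts <- strsplit(trimws(lines[which(lines == "@<TRIPOS>MOLECULE") + 2L]),
                     "[[:space:]]+")[[1L]]
  n_bonds <- suppressWarnings(as.integer(counts[2L]))
  if (is.na(n_bonds) || n_bonds > 0L) {
    tf <- tempfile(fileext = ".mol2")
    on.exit(unlink(tf), add = TRUE)
    writeLines(lines, tf)
    return(bio3d::read.mol2(tf))
  }
  a0 <- which(lines == "@<TRIPOS>ATOM")
  n_atoms <- as.integer(counts[1L])
  fields <- strsplit(trimws(lines[a0 + seq_len(n_atoms)]), "[[:space:]]+")
  list(atom = data.frame(
    eleno = vapply(fields, function(f) as.integer(f[1L]), 0L),
    elena = vapply(fields, `[`, "", 2L),
    elety = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE),
    bond = NULL)
}

#' Is a parse result an exclusion mark?
#'
#' @param x result of [parse_smiles()].
#' @return `TRUE` for an excluded (dot-disconnected) record.
#' @export
is_excluded <- function(x) inherits(x, "smiles_exclusion")

#' Read a SMILES list file
#'
#' One record per line: either a bare SMILES, or `id<TAB>smiles`.
#'
#' @param path file path.
#' @return data frame with columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  has_id <- lengths(parts) >= 2L
  data.frame(
    id = ifelse(has_id, vapply(parts, `[`, "", 1L),
                paste0("cmpd", seq_along(lines))),
    smiles = ifelse(has_id, vapply(parts, `[`, "", 2L),
                    vapply(parts, `[`, "", 1L)),
    stringsAsFactors = FALSE)
}

#' Export a molecular graph as an edge-list text block
#'
#' Debug format: a vertex block (`v<TAB>index<TAB>label`) followed by one
#' `i<TAB>j<TAB>bond_type` line per edge.
#'
#' @param graph a [molecular_graph()].
#' @param path optional file; when `NULL` the lines are returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_molecular_graph <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "molecular_graph"))
  lines <- c(
    sprintf("v\t%d\t%s", seq_along(graph$vertex_labels), graph$vertex_labels),
    sprintf("%d\t%d\t%s", graph$edges$i, graph$edges$j, graph$edges$bond))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("Molecular graph: %d heavy atoms, %d bonds (%s)\n",
              length(x$vertex_labels), nrow(x$edges),
              x$source_smiles %||% "?"))
  tab <- table(x$vertex_labels)
  cat("  atoms:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.smiles_exclusion <- function(x, ...) {
  cat(sprintf("Excluded SMILES record (%s): %s\n", x$reason, x$smiles))
  invisible(x)
}
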