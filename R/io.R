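# Plain-text, versioned file formats: pair lists, score files, model files.
# Everything is diffable text; matrices are serialized at full double
# precision (%.17g) so a round trip is bit-exact.

#' Read a tab-separated pair list
#'
#' Expected columns: `compound_id`, `smiles`, `pocket_file`, `label`
#' (header optional). Pocket files are resolved relative to the pair-list
#' directory. SMILES are parsed on the fly: dot-disconnected records are
#' kept with an exclusion flag instead of a graph; rows that fail to parse
#' raise an error naming the row.
#'
#' @param path pair-list file.
#' @param parse parse SMILES and load pocket files (default); when `FALSE`
#'   only the table is returned.
#' @return when `parse = TRUE`, a list with `pairs` (list of
#'   compound/pocket/label records, excluded compounds carried as
#'   `smiles_exclusion` objects) and `table` (the raw data frame).
#' @export
read_pair_list <- function(path, parse = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^compound_id\t", lines[1L])) {
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("empty pair list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) {
    stop("malformed pair list row(s): ", paste(bad, collapse = ", "))
  }
  tab <- data.frame(
    compound_id = vapply(parts, `[`, "", 1L),
    smiles = vapply(parts, `[`, "", 2L),
    pocket_file = vapply(parts, `[`, "", 3L),
    label = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(tab$label) || !all(tab$label %in% 0:1)) {
    stop("labels must be 0/1 in ", path)
  }
  if (!parse) return(list(table = tab))
  base <- dirname(path)
  pocket_cache <- new.env(parent = emptyenv())
  pairs <- lapply(seq_len(nrow(tab)), function(k) {
    g <- tryCatch(parse_smiles(tab$smiles[k]), error = function(e) {
      stop("row ", k, " of ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (!is_excluded(g)) attr(g, "graph_id") <- tab$compound_id[k]
    pf <- tab$pocket_file[k]
    if (is.null(pocket_cache[[pf]])) {
      full <- if (grepl("^(/|[A-Za-z]:)", pf)) pf else file.path(base, pf)
      pg <- read_pocket_graph(full)
      attr(pg, "graph_id") <- pf
      pocket_cache[[pf]] <- pg
    }
    list(compound = g, pocket = pocket_cache[[pf]], label = tab$label[k])
  })
  list(pairs = pairs, table = tab)
}

#' Write a score file
#'
#' Tab-separated: `pair_id`, `score` (empty for excluded records),
#' `label`, `excluded`.
#'
#' @param ids record identifiers.
#' @param scores numeric scores (`NA` = excluded).
#' @param labels 0/1 labels (may be `NA` at pure prediction time).
#' @param path output file.
#' @export
write_scores <- function(ids, scores, labels, path) {
  writeLines(c("pair_id\tscore\tlabel\texcluded",
               sprintf("%s\t%s\t%s\t%s", ids,
                       ifelse(is.na(scores), "",
                              sprintf("%.10f", scores)),
                       ifelse(is.na(labels), "", labels),
                       ifelse(is.na(scores), "1", "0"))), path)
  invisible(path)
}

#' Read a score file written by [write_scores()]
#'
#' @param path file path.
#' @return data frame with `pair_id`, `score`, `label`, `excluded`.
#' @export
read_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "integer",
                                          "integer"), fill = TRUE,
                           na.strings = "")
  tab$excluded <- tab$excluded == 1L
  tab
}

.fmt_matrix <- function(name, m) {
  m <- as.matrix(m)
  c(sprintf("matrix\t%s\t%d\t%d", name, nrow(m), ncol(m)),
    apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")))
}

#' Save a fitted model to a versioned text file
#'
#' Bundles the resolved configuration, both fingerprint vocabularies and
#' every parameter table in one plain-text file; doubles are written at
#' full precision, so save/load round trips exactly. The file header
#' records the class-index convention (second logit = active).
#'
#' @param model a fitted [pocketgnn()] object.
#' @param path output file.
#' @export
write_pocketgnn <- function(model, path) {
  stopifnot(inherits(model, "pocketgnn"))
  cfg <- model$config
  vocab_lines <- function(tag, vocab) {
    c(sprintf("%s_radius\t%d", tag, vocab$radius),
      sprintf("%s_V\t%d\t%s", tag, unname(vocab$vertex),
              names(vocab$vertex)),
      sprintf("%s_E\t%d\t%s", tag, unname(vocab$edge), names(vocab$edge)))
  }
  p <- model$params
  lines <- c(
    "# pocketgnn model v1 (class index 1, the second logit, = active)",
    sprintf("config\t%s\t%s", names(cfg), vapply(cfg, as.character, "")),
    vocab_lines("vc", model$vocab_compound),
    vocab_lines("vp", model$vocab_pocket),
    sprintf("loss_history\t%s",
            paste(sprintf("%.17g", model$loss_history), collapse = " ")),
    .fmt_matrix("c_vertex_emb", p$compound$vertex_emb),
    .fmt_matrix("c_edge_emb", p$compound$edge_emb),
    unlist(lapply(seq_along(p$compound$W), function(l) {
      .fmt_matrix(paste0("c_W", l), p$compound$W[[l]])
    })),
    .fmt_matrix("p_vertex_emb", p$pocket$vertex_emb),
    .fmt_matrix("p_edge_emb", p$pocket$edge_emb),
    unlist(lapply(seq_along(p$pocket$W), function(l) {
      .fmt_matrix(paste0("p_W", l), p$pocket$W[[l]])
    })),
    .fmt_matrix("W_out", p$W_out),
    .fmt_matrix("b_out", matrix(p$b_out, nrow = 1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Load a model written by [write_pocketgnn()]
#'
#' Validates the shape invariants (table sizes against vocabulary sizes,
#' head dimensions against d) on load.
#'
#' @param path model file.
#' @return a `pocketgnn` object.
#' @export
read_pocketgnn <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("pocketgnn model v1", lines[1L],
                               fixed = TRUE)) {
    stop("not a pocketgnn model v1 file: ", path)
  }
  lines <- lines[-1L]
  first <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)

  cfg_rows <- strsplit(lines[first == "config"], "\t", fixed = TRUE)
  cfg <- stats::setNames(lapply(cfg_rows, `[`, 3L),
                         vapply(cfg_rows, `[`, "", 2L))
  num_keys <- c("learning_rate", "lr_decay")
  int_keys <- c("dim", "r_compound", "r_pocket", "layers_compound",
                "layers_pocket", "decay_interval", "epochs", "batch_size",
                "seed")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])

  read_vocab <- function(tag) {
    r <- as.integer(strsplit(lines[first == paste0(tag, "_radius")][1L],
                             "\t")[[1L]][2L])
    grab <- function(kind) {
      rows <- strsplit(lines[first == paste0(tag, "_", kind)], "\t",
                       fixed = TRUE)
      stats::setNames(vapply(rows, function(x) as.integer(x[2L]), 0L),
                      vapply(rows, `[`, "", 3L))
    }
    v <- grab("V"); e <- grab("E")
    structure(list(radius = r, vertex = v, edge = e,
                   vertex_unk = length(v) + 1L, edge_unk = length(e) + 1L,
                   n_vertex = length(v) + 1L, n_edge = length(e) + 1L),
              class = "subgraph_vocabulary")
  }
  vc <- read_vocab("vc")
  vp <- read_vocab("vp")

  mat_heads <- which(first == "matrix")
  mats <- list()
  for (h in mat_heads) {
    hd <- strsplit(lines[h], "\t", fixed = TRUE)[[1L]]
    nr <- as.integer(hd[3L]); nc <- as.integer(hd[4L])
    block <- lines[(h + 1L):(h + nr)]
    mats[[hd[2L]]] <- matrix(as.numeric(unlist(
      strsplit(block, " ", fixed = TRUE))), nr, nc, byrow = TRUE)
  }
  branch <- function(prefix, L) {
    list(vertex_emb = mats[[paste0(prefix, "_vertex_emb")]],
         edge_emb = mats[[paste0(prefix, "_edge_emb")]],
         W = lapply(seq_len(L), function(l) mats[[paste0(prefix, "_W", l)]]))
  }
  params <- structure(list(
    compound = branch("c", cfg$layers_compound),
    pocket = branch("p", cfg$layers_pocket),
    W_out = mats[["W_out"]], b_out = drop(mats[["b_out"]]),
    d = cfg$dim, layers_compound = cfg$layers_compound,
    layers_pocket = cfg$layers_pocket), class = "gnn_parameters")

  stopifnot(nrow(params$compound$vertex_emb) == vc$n_vertex,
            nrow(params$compound$edge_emb) == vc$n_edge,
            nrow(params$pocket$vertex_emb) == vp$n_vertex,
            nrow(params$pocket$edge_emb) == vp$n_edge,
            ncol(params$W_out) == 2L * cfg$dim,
            nrow(params$W_out) == 2L, length(params$b_out) == 2L)

  lh_row <- lines[first == "loss_history"]
  loss_history <- if (length(lh_row)) {
    as.numeric(strsplit(strsplit(lh_row[1L], "\t")[[1L]][2L], " ")[[1L]])
  } else numeric()

  structure(list(params = params, vocab_compound = vc, vocab_pocket = vp,
                 config = cfg, loss_history = loss_history,
                 n_pairs = NA_integer_, call = NULL),
            class = "pocketgnn")
}

#' Write a resolved-configuration snapshot
#'
#' One `key<TAB>value` line per setting; written next to every CLI output
#' so runs are auditable and reproducible.
#'
#' @param config named list.
#' @param path output file.
#' @export
write_config_snapshot <- function(config, path) {
  writeLines(sprintf("%s\t%s", names(config),
                     vapply(config, function(v) paste(as.character(v),
                                                      collapse = ","), "")),
             path)
  invisible(path)
}
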