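#' Coerce and validate an OTU count table
#'
#' The canonical community container is an integer matrix with samples as rows
#' and OTUs as columns, both axes labelled. Data frames are accepted with
#' sample identifiers either as row names or in a leading `sample_id` column.
#'
#' @param x matrix or data frame of non-negative integer counts.
#' @param samples_as_rows are rows samples (`TRUE`, default) or OTUs?
#' @return validated integer matrix, samples x OTUs.
#' @export
as_otu_table <- function(x, samples_as_rows = TRUE) {
  if (is.data.frame(x)) {
    if (ncol(x) >= 1 && (names(x)[1] %in% c("sample_id", "otu_id"))) {
      ids <- as.character(x[[1]])
      x <- as.matrix(x[-1])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!samples_as_rows) x <- t(x)
  storage.mode(x) <- "double"
  validate_otu_table(x)
  storage.mode(x) <- "integer"
  x
}

#' Validate OTU table invariants
#'
#' Checks unique row/column identifiers, non-negative integer counts, and a
#' positive total per sample.
#'
#' @param x samples x OTUs count matrix.
#' @return `x`, invisibly.
#' @export
validate_otu_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    abort("OTU table must be a numeric matrix", class = "pelagos_validation_error")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort("OTU table must have sample and OTU identifiers", class = "pelagos_id_error")
  if (anyDuplicated(rownames(x)))
    abort("duplicate sample identifiers", class = "pelagos_id_error")
  if (anyDuplicated(colnames(x)))
    abort("duplicate OTU identifiers", class = "pelagos_id_error")
  if (anyNA(x) || any(x < 0))
    abort("counts must be non-negative", class = "pelagos_validation_error")
  if (any(abs(x - round(x)) > 1e-8))
    abort("counts must be integers", class = "pelagos_validation_error")
  if (any(rowSums(x) == 0))
    abort(paste0("samples with zero total counts: ",
                 paste(rownames(x)[rowSums(x) == 0], collapse = ", ")),
          class = "pelagos_validation_error")
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' Reads a tab-separated table with one labelled axis per margin and returns
#' it in the canonical samples x OTUs orientation.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows are samples, `"otus"` if rows are
#'   OTUs, or `"auto"` to take the longer margin as the OTU axis.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, orientation = c("samples", "otus", "auto")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    abort("OTU table body must be numeric", class = "pelagos_validation_error")
  rows_are_samples <- switch(orientation,
    samples = TRUE,
    otus = FALSE,
    auto = nrow(m) <= ncol(m))
  as_otu_table(m, samples_as_rows = rows_are_samples)
}

#' Write an OTU table (or any labelled matrix) as TSV
#'
#' @param x labelled matrix.
#' @param path file path.
#' @param id_header header for the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_header = "sample_id") {
  df <- data.frame(row = rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_tsv()]
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read a rooted phylogenetic tree in newick format
#'
#' Branch lengths are required; internal node labels (e.g. bootstrap values)
#' are tolerated and ignored.
#'
#' @param path newick file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylo_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0("malformed newick: ", conditionMessage(e)),
                                             class = "pelagos_parse_error"))
  if (is.null(tree))
    abort("malformed newick", class = "pelagos_parse_error")
  if (is.null(tree$edge.length))
    abort("tree has no branch lengths", class = "pelagos_parse_error")
  if (any(tree$edge.length < 0))
    abort("negative branch lengths", class = "pelagos_validation_error")
  if (anyDuplicated(tree$tip.label))
    abort("duplicate tip labels", class = "pelagos_id_error")
  tree
}

#' Compare OTU table and tree labels
#'
#' @param tree `phylo` object.
#' @param table OTU count matrix.
#' @return list with `missing` (OTUs in the table absent from the tree) and
#'   `extra` (tips absent from the table).
#' @export
check_tree_coverage <- function(tree, table) {
  list(missing = setdiff(colnames(table), tree$tip.label),
       extra = setdiff(tree$tip.label, colnames(table)))
}

#' Reconcile an OTU table with a tree
#'
#' OTUs present in the table but absent from the tree are an error by default
#' (the caller decides whether to drop them); extra tips are always pruned.
#'
#' @param table OTU count matrix.
#' @param tree `phylo` object.
#' @param action `"error"` to fail on uncovered OTUs, `"prune"` to drop them
#'   from the table.
#' @return list with aligned `table` and `tree`.
#' @export
align_tree_table <- function(table, tree, action = c("error", "prune")) {
  action <- match.arg(action)
  cov <- check_tree_coverage(tree, table)
  if (length(cov$missing) > 0) {
    if (action == "error")
      abort(paste0("OTUs absent from the tree: ",
                   paste(cov$missing, collapse = ", ")),
            class = "pelagos_coverage_error")
    table <- table[, setdiff(colnames(table), cov$missing), drop = FALSE]
  }
  if (length(cov$extra) > 0)
    tree <- ape::drop.tip(tree, cov$extra)
  list(table = table, tree = tree)
}

#' Bundle heterogeneous results for serialization
#'
#' A result bundle is a named list of labelled matrices, data frames, igraph
#' graphs, and list summaries, plus run metadata (seed, parameters).
#'
#' @param ... named results.
#' @param metadata named list of run metadata.
#' @return object of class `result_bundle`.
#' @export
result_bundle <- function(..., metadata = list()) {
  items <- list(...)
  if (length(items) == 1 && is.null(names(items)) && is.list(items[[1]]) &&
      !is.data.frame(items[[1]]))
    items <- items[[1]]
  if (length(items) > 0 && (is.null(names(items)) || any(names(items) == "")))
    abort("all bundle items must be named", class = "pelagos_validation_error")
  structure(list(items = items, metadata = metadata), class = "result_bundle")
}

#' Write a result bundle to disk
#'
#' Matrices become labelled TSV, data frames TSV, igraph graphs GraphML plus
#' an edge-list TSV, everything else JSON. A `manifest.json` listing every
#' file with its MD5 checksum is written last.
#'
#' @param bundle a [result_bundle()].
#' @param out_dir output directory, created if needed.
#' @return tibble manifest (file, bytes, md5), invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(paste0("cannot create output directory ", out_dir),
          class = "pelagos_io_error")
  files <- character(0)
  for (nm in names(bundle$items)) {
    obj <- bundle$items[[nm]]
    if (inherits(obj, "igraph")) {
      f1 <- file.path(out_dir, paste0(nm, ".graphml"))
      igraph::write_graph(obj, f1, format = "graphml")
      el <- network_edges(obj)
      f2 <- file.path(out_dir, paste0(nm, "_edges.tsv"))
      write.table(el, f2, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f1, f2)
    } else if (is.matrix(obj)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_matrix_tsv(obj, f)
      files <- c(files, f)
    } else if (inherits(obj, "dist")) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_matrix_tsv(as.matrix(obj), f)
      files <- c(files, f)
    } else if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           force = TRUE, pretty = TRUE)
      files <- c(files, f)
    }
  }
  if (length(bundle$metadata) > 0) {
    f <- file.path(out_dir, "run_metadata.json")
    jsonlite::write_json(bundle$metadata, f, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    files <- c(files, f)
  }
  manifest <- tibble(
    file = basename(files),
    bytes = as.integer(file.size(files)),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
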