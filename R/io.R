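#' Read and write the pipeline's plain-text formats
#'
#' Expression matrices are tab-separated with genes as rows, a `gene_id`
#' first column, sample IDs in the header, and the empty string marking
#' non-assessable entries. Sample annotation is a two-column TSV
#' (`sample`, `arm`). Header comment lines start with `#` and record
#' the seed/thresholds of the producing run; they are ignored on read.
#' Write-then-read reproduces the in-memory object exactly, including
#' missingness.
#'
#' @param study An `expression_study`.
#' @param path Output TSV path for the matrix.
#' @param annotation_path Output TSV path for the sample annotation.
#' @param header Optional character vector of header comment lines
#'   (written prefixed with `"# "`).
#' @return `write_expression()`: the paths, invisibly.
#' @name expression_io
#' @export
write_expression <- function(study, path, annotation_path, header = NULL) {
  stopifnot(inherits(study, "expression_study"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(header)) writeLines(paste("#", header), con)
  x <- study$intensities
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(row) {
    v <- formatC(row, format = "g", digits = 15)
    v[is.na(row)] <- ""
    paste(v, collapse = "\t")
  })
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  acon <- file(annotation_path, "w")
  on.exit(close(acon), add = TRUE)
  if (!is.null(header)) writeLines(paste("#", header), acon)
  writeLines(c("sample\tarm",
               paste(colnames(x), as.character(study$arms), sep = "\t")),
             acon)
  invisible(c(path, annotation_path))
}

#' @rdname expression_io
#' @param design Optional [study_design()]; if omitted, a minimal design is
#'   reconstructed from the annotation with every non-control arm treated
#'   by its label (`control`/`EndoRT` map to their categories, labels
#'   containing `EBRT` to `EBRT`, the rest to `combined`).
#' @return `read_expression()`: an `expression_study`.
#' @export
read_expression <- function(path, annotation_path, design = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("malformed expression table: ", path)
  if (anyDuplicated(tab[[1]])) stop("duplicate gene_ids in ", path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mat[mat == ""] <- NA
  storage.mode(mat) <- "double"
  rownames(mat) <- tab[[1]]
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           comment.char = "#",
                           colClasses = "character")
  if (!all(c("sample", "arm") %in% names(ann)))
    stop("annotation must have columns 'sample' and 'arm'")
  unknown <- setdiff(colnames(mat), ann$sample)
  if (length(unknown) > 0)
    stop("samples missing from the annotation: ",
         paste(unknown, collapse = ", "))
  arm <- ann$arm[match(colnames(mat), ann$sample)]
  if (is.null(design)) {
    arms <- unique(ann$arm)
    cat_of <- function(a) {
      if (tolower(a) == "control") "control"
      else if (grepl("endo", a, ignore.case = TRUE)) "endoRT"
      else if (grepl("EBRT", a)) "EBRT"
      else "combined"
    }
    design <- study_design(
      arms = arms,
      replicates = as.integer(table(factor(ann$arm, levels = arms))),
      categories = vapply(arms, cat_of, character(1)))
  }
  study <- structure(list(intensities = mat,
                          arms = factor(arm, levels = design$arms),
                          design = design),
                     class = "expression_study")
  names(study$arms) <- colnames(mat)
  study
}

#' Gene-list files: one identifier per line
#'
#' @param genes Character vector.
#' @param path File path.
#' @param header Optional header comment lines.
#' @return `read_gene_list()`: character vector.
#' @name gene_list_io
#' @export
write_gene_list <- function(genes, path, header = NULL) {
  lines <- c(if (!is.null(header)) paste("#", header), genes)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gene_list_io
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Gene-set collections in GMT format
#'
#' GMT per the Broad convention: one set per line,
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param collection A `gene_set_collection`.
#' @param path File path.
#' @return `read_gmt()`: a `gene_set_collection`.
#' @name gmt_io
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id)
    paste(c(id, "na", collection$sets[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gmt_io
#' @param universe Optional universe; defaults to the union of all sets.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  structure(list(sets = sets, universe = universe, planted_set_id = NULL),
            class = "gene_set_collection")
}

#' Interaction edge lists as two-column TSV
#'
#' Undirected, unweighted edges; duplicate undirected edges and self-loops
#' are removed on read with a warning.
#'
#' @param graph An [igraph::graph].
#' @param path File path.
#' @return `read_edges()`: an [igraph::graph].
#' @name edges_io
#' @export
write_edges <- function(graph, path) {
  stopifnot(igraph::is_igraph(graph))
  el <- igraph::as_edgelist(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("from\tto", con)
  if (nrow(el) > 0)
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  invisible(path)
}

#' @rdname edges_io
#' @param vertices Optional full vertex set (keeps isolated nodes).
#' @export
read_edges <- function(path, vertices = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("edge list must have two columns: ", path)
  bad <- !stats::complete.cases(tab[, 1:2]) | tab[[1]] == "" | tab[[2]] == ""
  if (any(bad))
    stop("malformed edge row(s) at line(s): ",
         paste(which(bad) + 1L, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    tab[, 1:2], directed = FALSE,
    vertices = if (is.null(vertices)) NULL
               else data.frame(name = vertices))
  simplified <- igraph::simplify(g)
  if (igraph::ecount(simplified) < igraph::ecount(g))
    warning(igraph::ecount(g) - igraph::ecount(simplified),
            " duplicate or self-loop edge(s) removed")
  simplified
}

#' Read a tidy observation table with a required schema
#'
#' Thin wrapper over `read.csv` that verifies required columns are present
#' and reports missing ones by name.
#'
#' @param path CSV path (one row per observation; `#` comments allowed).
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_tidy <- function(path, required = character(0)) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' @rdname read_tidy
#' @param x Data frame to write.
#' @param header Optional header comment lines.
#' @export
write_tidy <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}
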