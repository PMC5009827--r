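# Readers and writers for the delimited-text dialects the tool speaks.
# Matrix files: first row feature names, first column sample IDs, tab or
# comma delimited (sniffed from the header); values written back with 17
# significant digits so write -> read round trips are lossless in double
# precision. Edge lists: two tab-separated feature NAMES per line, '#'
# comments allowed; an absent file means the complete graph.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop(sprintf("'%s' is empty", path))
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read one labelled numeric matrix
#'
#' @param path delimited text file: header row of feature names, first
#'   column of sample IDs, tab or comma separated (auto-detected).
#' @return numeric matrix with sample IDs as rownames.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", colClasses = "character",
                          quote = "\"")
  if (ncol(df) < 2L) stop(sprintf("'%s' has no feature columns", path))
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw),
                                dimnames = dimnames(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing cell in '%s' at row %d (sample '%s'), column '%s'",
                 path, bad[1L, 1L], ids[bad[1L, 1L]],
                 colnames(raw)[bad[1L, 2L]]))
  }
  rownames(num) <- ids
  num
}

#' Read and join two paired matrix files
#'
#' Inner join on sample IDs; the joined sample order follows the X file.
#' Duplicate IDs within a file and joins with fewer than three common
#' samples are rejected.
#'
#' @param x_path,y_path matrix files (see [read_matrix_file()]).
#' @return an unstandardized [paired_data()].
#' @export
read_paired_matrices <- function(x_path, y_path) {
  X <- read_matrix_file(x_path)
  Y <- read_matrix_file(y_path)
  if (anyDuplicated(rownames(X))) {
    stop(sprintf("duplicate sample IDs in '%s'", x_path))
  }
  if (anyDuplicated(rownames(Y))) {
    stop(sprintf("duplicate sample IDs in '%s'", y_path))
  }
  common <- rownames(X)[rownames(X) %in% rownames(Y)]
  if (length(common) < 3L) {
    stop(sprintf("only %d overlapping sample IDs between '%s' and '%s' (need >= 3)",
                 length(common), x_path, y_path))
  }
  paired_data(X[common, , drop = FALSE], Y[common, , drop = FALSE],
              sample_ids = common)
}

fmt_full <- function(x) {
  # shortest representation that round-trips doubles exactly
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a labelled matrix as TSV
#'
#' @param M numeric matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(M, path) {
  rn <- rownames(M)
  if (is.null(rn)) rn <- paste0("s", seq_len(nrow(M)))
  cn <- colnames(M)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(M)))
  lines <- c(paste(c("sample_id", cn), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i) {
               paste(c(rn[i], fmt_full(M[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a loading vector as TSV (feature, weight)
#'
#' @param loadings named numeric vector.
#' @param path output file.
#' @export
write_loadings_tsv <- function(loadings, path) {
  nm <- names(loadings)
  if (is.null(nm)) nm <- paste0("f", seq_along(loadings))
  lines <- c("feature\tweight",
             paste(nm, fmt_full(as.numeric(loadings)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a loading TSV written by [write_loadings_tsv()]
#' @param path input file.
#' @return named numeric vector.
#' @export
read_loadings_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stats::setNames(as.numeric(df$weight), df$feature)
}

#' Read a feature-graph edge list
#'
#' Two tab-separated feature names per line; lines starting with '#' are
#' ignored; edges are undirected and de-duplicated. A missing file (or
#' `NULL` path) yields the complete graph over `feature_names`
#' (group-pursuit mode).
#'
#' @param path edge-list file, or `NULL`/nonexistent for the complete graph.
#' @param feature_names character vector the names must resolve against.
#' @return a [feature_graph()].
#' @export
read_edge_list <- function(path, feature_names) {
  p <- length(feature_names)
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    return(complete_graph(p))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(feature_graph(p))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop(sprintf("edge list '%s': every line must have exactly two tab-separated names",
                 path))
  }
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  ia <- match(a, feature_names)
  ib <- match(b, feature_names)
  unknown <- unique(c(a[is.na(ia)], b[is.na(ib)]))
  if (length(unknown) > 0L) {
    stop(sprintf("edge list '%s': unknown feature name(s): %s",
                 path, paste(unknown, collapse = ", ")))
  }
  if (any(ia == ib)) {
    stop(sprintf("edge list '%s': self-loop on '%s'", path, a[which(ia == ib)[1L]]))
  }
  feature_graph(p, cbind(ia, ib))
}

#' Assemble run metadata
#'
#' One metadata record per CLI run: command, configuration snapshot, seed,
#' package version, md5 digests of the input files, wall time and a
#' convergence summary. Written as JSON.
#'
#' @param command subcommand name.
#' @param config configuration object (coerced to a plain list).
#' @param seed integer seed.
#' @param inputs named character vector of input file paths (digested).
#' @param extra named list of additional fields (timings, convergence, ...).
#' @return a list of class `run_metadata`.
#' @export
run_metadata <- function(command, config = NULL, seed = NULL,
                         inputs = character(0), extra = list()) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  structure(c(list(
    command = command,
    package = "goscca",
    version = as.character(utils::packageVersion("goscca")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    input_digests = digests
  ), extra), class = "run_metadata")
}

#' Write run metadata as JSON
#' @param meta a [run_metadata()] list.
#' @param path output file.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
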