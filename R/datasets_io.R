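# On-disk formats: 2-column TSV edge lists (no header), labelled TSV matrices
# (first row / first column = labels, "NA" for undefined entries), DAG files
# as child<TAB>parent lines.

#' Read a bipartite edge list into a binary association matrix
#'
#' Each line names one observed pair (row-entity, column-entity); an entry of
#' the returned matrix is 1 iff the pair appears at least once.  Labels are
#' the union of observed identifiers and any supplied universe, sorted
#' lexicographically so that matrix orientation is deterministic across runs.
#' Pairs falling outside a supplied universe are filtered out silently (they
#' belong to entities the model does not track), with a message counting them.
#'
#' @param path TSV file with at least two tab-separated columns; extra
#'   columns are ignored.  No header.
#' @param row_universe,col_universe optional duplicate-free identifier lists
#'   defining the full entity sets (entities with no observed edge then get
#'   all-zero profiles).
#' @return A [bipartite_assoc] matrix.
#' @export
read_bipartite_edges <- function(path, row_universe = NULL, col_universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected >= 2 tab-separated fields",
                 bad[1], path))
  rw <- vapply(parts, `[[`, "", 1L)
  cl <- vapply(parts, `[[`, "", 2L)
  if (!is.null(row_universe) && anyDuplicated(row_universe))
    stop("row_universe has duplicates")
  if (!is.null(col_universe) && anyDuplicated(col_universe))
    stop("col_universe has duplicates")
  keep <- rep(TRUE, length(rw))
  if (!is.null(row_universe)) keep <- keep & rw %in% row_universe
  if (!is.null(col_universe)) keep <- keep & cl %in% col_universe
  if (any(!keep))
    message(sum(!keep), " edge(s) outside the supplied universe dropped")
  rw <- rw[keep]; cl <- cl[keep]
  rows <- sort(unique(c(rw, row_universe)))
  cols <- sort(unique(c(cl, col_universe)))
  if (!length(rows) || !length(cols))
    stop("no row/column entities: empty file and no universe supplied")
  mat <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (length(rw)) {
    dup <- duplicated(paste(rw, cl, sep = "\r"))
    if (any(dup)) message(sum(dup), " duplicated edge(s) collapsed")
    mat[cbind(rw, cl)] <- 1
  }
  bipartite_assoc(mat)
}

#' Restrict the miRNA-lncRNA layer to miRNAs of the disease layer
#'
#' miRNAs that interact with lncRNAs but have no known disease association
#' cannot be coupled into the propagation and are removed from the
#' interaction matrix, mirroring the harmonization applied to the public
#' starBase/HMDD pair (which reduced 10112 raw interactions to 9088).
#' lncRNAs left with zero interactions are retained by default: the Gaussian
#' kernel handles all-zero profiles.
#'
#' @param B_raw miRNA-by-lncRNA [bipartite_assoc] (rows = miRNAs).
#' @param A disease-by-miRNA [bipartite_assoc] (columns = miRNAs).
#' @param drop_isolated drop lncRNA columns whose degree becomes zero.
#' @param pad if `TRUE`, additionally give every miRNA of `A` that has no
#'   known lncRNA interaction an all-zero row, so that the result conforms
#'   with `A` for the propagation algebra.
#' @return [bipartite_assoc] whose rows are the miRNAs shared with `A`
#'   (or all of `colnames(A)` when `pad = TRUE`).
#' @export
harmonize_lncrna_layer <- function(B_raw, A, drop_isolated = FALSE, pad = FALSE) {
  mirnas <- colnames(A)
  common <- intersect(rownames(B_raw), mirnas)
  if (!length(common))
    stop("no miRNA shared between the disease and lncRNA layers; ",
         "the layers cannot be coupled")
  keep_rows <- sort(if (pad) mirnas else common)
  out <- matrix(0, length(keep_rows), ncol(B_raw),
                dimnames = list(keep_rows, colnames(B_raw)))
  out[common, ] <- unclass(B_raw)[common, , drop = FALSE]
  if (drop_isolated) {
    keep <- colSums(out) > 0
    if (!any(keep)) stop("all lncRNAs isolated after harmonization")
    out <- out[, keep, drop = FALSE]
  }
  bipartite_assoc(out)
}

#' Read a MeSH-style disease DAG from a child/parent edge list
#'
#' @param path TSV file of `child<TAB>parent` lines; a node may have several
#'   parents.  Cycles and self-edges are rejected.
#' @return A [disease_dag].
#' @export
read_disease_dag <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected child<TAB>parent",
                 bad[1], path))
  edges <- data.frame(child = vapply(parts, `[[`, "", 1L),
                      parent = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  disease_dag(nodes = character(0), edges = edges)
}

#' Write a disease DAG as a child/parent edge list
#' @param dag a [disease_dag].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_disease_dag <- function(dag, path) {
  writeLines(paste(dag$edges$child, dag$edges$parent, sep = "\t"), path)
  invisible(path)
}

#' Write a labelled matrix as TSV
#'
#' First row and first column carry labels; undefined similarity entries are
#' serialized as `NA`.  Values are written with 17 significant digits so the
#' round-trip is lossless well beyond 12 significant digits.
#'
#' @param m a [similarity_matrix] or [bipartite_assoc] (or plain labelled
#'   matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  x <- unclass(as.matrix(m))
  attr(x, "coverage") <- NULL
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  header <- paste(c("", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt(x[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labelled TSV matrix
#'
#' @param path file written by [write_matrix()].
#' @param type `"similarity"` validates squareness/symmetry and rebuilds the
#'   coverage mask from `NA` cells; `"bipartite"` validates binary entries;
#'   `"plain"` returns the raw labelled matrix.
#' @return [similarity_matrix], [bipartite_assoc], or matrix.
#' @export
read_matrix <- function(path, type = c("similarity", "bipartite", "plain")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cols <- header[-1]
  rows <- character(length(lines) - 1)
  mat <- matrix(NA_real_, length(lines) - 1, length(cols))
  for (i in seq_along(rows)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols) + 1)
      stop(sprintf("shape mismatch at line %d of %s: %d fields, expected %d",
                   i + 1, path, length(f), length(cols) + 1))
    rows[i] <- f[1]
    mat[i, ] <- suppressWarnings(as.numeric(f[-1]))
  }
  dimnames(mat) <- list(rows, cols)
  switch(type,
         similarity = {
           if (nrow(mat) != ncol(mat))
             stop("similarity matrix file is not square: ", path)
           similarity_matrix(mat)
         },
         bipartite = bipartite_assoc(mat),
         plain = mat)
}
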