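#' Labelled binary bipartite association matrix
#'
#' Container for a binary adjacency matrix between two entity types, e.g. the
#' disease-by-miRNA association matrix `A` or the miRNA-by-lncRNA interaction
#' matrix `B`.  Rows and columns carry duplicate-free labels and every entry
#' is 0 or 1.
#'
#' @param mat numeric matrix of 0/1 entries with complete `dimnames`.
#' @return An object of class `bipartite_assoc` (a matrix).
#' @export
bipartite_assoc <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("bipartite_assoc: matrix must have row and column labels")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("bipartite_assoc: duplicate labels")
  if (any(is.na(mat)) || !all(mat %in% c(0, 1)))
    stop("bipartite_assoc: entries must be 0 or 1")
  storage.mode(mat) <- "double"
  class(mat) <- c("bipartite_assoc", class(matrix()))
  mat
}

#' @export
print.bipartite_assoc <- function(x, ...) {
  cat(sprintf("bipartite_assoc: %d x %d, %d positive entries\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Labelled square similarity matrix with coverage mask
#'
#' Square nonnegative matrix over one entity type.  Entries where the
#' similarity is undefined (e.g. miRNA pairs whose disease sets are empty)
#' are stored as `NA` and marked `FALSE` in the coverage mask.
#'
#' @param mat square numeric matrix with identical row/column labels;
#'   defined entries in `[0, 1]`, symmetric within `1e-10`.
#' @param coverage optional logical matrix marking defined pairs; defaults to
#'   `!is.na(mat)`.
#' @param kernel if `TRUE` the diagonal is required to be exactly 1.
#' @return An object of class `similarity_matrix` (a matrix with a
#'   `coverage` attribute).
#' @export
similarity_matrix <- function(mat, coverage = NULL, kernel = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat))
    stop("similarity_matrix: matrix must be square")
  if (is.null(rownames(mat))) rownames(mat) <- colnames(mat)
  if (is.null(colnames(mat))) colnames(mat) <- rownames(mat)
  if (is.null(rownames(mat)))
    stop("similarity_matrix: matrix must be labelled")
  if (!identical(rownames(mat), colnames(mat)))
    stop("similarity_matrix: row and column labels differ")
  if (is.null(coverage)) coverage <- !is.na(mat)
  coverage <- as.matrix(coverage)
  if (!identical(dim(coverage), dim(mat)))
    stop("similarity_matrix: coverage shape mismatch")
  if (!isTRUE(all.equal(coverage, t(coverage), check.attributes = FALSE)))
    stop("similarity_matrix: coverage mask must be symmetric")
  vals <- mat[coverage]
  if (any(is.na(vals)))
    stop("similarity_matrix: NA entry inside declared coverage")
  if (any(vals < 0 | vals > 1))
    stop("similarity_matrix: defined entries must lie in [0, 1]")
  sym <- mat
  sym[!coverage] <- 0
  if (max(abs(sym - t(sym))) > 1e-10)
    stop("similarity_matrix: matrix not symmetric within 1e-10")
  if (kernel && any(diag(mat) != 1))
    stop("similarity_matrix: kernel diagonal must be exactly 1")
  mat[!coverage] <- NA_real_
  structure(mat, coverage = coverage,
            class = c("similarity_matrix", class(matrix())))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cov <- attr(x, "coverage")
  cat(sprintf("similarity_matrix: %d x %d, %.1f%% covered\n",
              nrow(x), ncol(x), 100 * mean(cov)))
  invisible(x)
}

#' Coverage mask of a similarity matrix
#' @param m a `similarity_matrix`.
#' @return logical matrix marking defined pairs.
#' @export
sim_coverage <- function(m) {
  cov <- attr(m, "coverage")
  if (is.null(cov)) cov <- !is.na(unclass(m))
  cov
}

# Strip class/attributes for plain linear algebra; NA outside coverage -> 0.
sim_values <- function(m, fill = 0) {
  x <- unclass(as.matrix(m))
  attr(x, "coverage") <- NULL
  x[is.na(x)] <- fill
  x
}

#' Rooted disease DAG with ancestor sets
#'
#' A MeSH-style directed acyclic graph of disease terms stored as
#' child -> parent edges.  For every disease `D` the ancestor closure
#' `T(D)` (the node itself plus all ancestors) is precomputed, as is the
#' membership count used by semantic similarity model 2: the number of
#' disease DAGs that contain a given term.
#'
#' @param nodes character vector of disease identifiers.
#' @param edges data frame (or 2-column matrix) of child/parent pairs.
#' @return Object of class `disease_dag` with fields `nodes`, `edges`,
#'   `ancestors` (named list of `T(D)`), `membership` (named integer vector).
#' @export
disease_dag <- function(nodes, edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("disease_dag: edges need child and parent columns")
  names(edges)[1:2] <- c("child", "parent")
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  nodes <- sort(unique(c(as.character(nodes), edges$child, edges$parent)))
  if (any(edges$child == edges$parent))
    stop("disease_dag: self-edge on ",
         edges$child[edges$child == edges$parent][1])
  edges <- unique(edges[, c("child", "parent")])
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = nodes)
    if (!igraph::is_dag(g))
      stop("disease_dag: cycle detected: ",
           paste(find_cycle(edges), collapse = " -> "))
    anc <- lapply(nodes, function(v) {
      sort(names(igraph::subcomponent(g, v, mode = "out")))
    })
  } else {
    anc <- as.list(nodes)
  }
  names(anc) <- nodes
  membership <- setNames(as.integer(table(factor(unlist(anc), levels = nodes))),
                         nodes)
  structure(list(nodes = nodes, edges = edges, ancestors = anc,
                 membership = membership),
            class = "disease_dag")
}

# Walk child -> parent links until a node repeats; only called when a cycle
# is known to exist so the walk must close.
find_cycle <- function(edges) {
  nxt <- split(edges$parent, edges$child)
  start <- edges$child[1]
  seen <- character(0)
  v <- start
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    cand <- nxt[[v]]
    cand_in <- cand[cand %in% names(nxt)]
    v <- if (length(cand_in)) cand_in[1] else cand[1]
    if (is.null(v)) return(seen)  # defensive; should not happen
  }
  c(seen[which(seen == v):length(seen)], v)
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Ancestor closure T(D) of a disease
#' @param dag a `disease_dag`.
#' @param D disease identifier.
#' @return character vector: `D` plus all its ancestors.
#' @export
dag_ancestors <- function(dag, D) {
  if (!D %in% dag$nodes) stop("disease not in DAG: ", D)
  dag$ancestors[[D]]
}
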