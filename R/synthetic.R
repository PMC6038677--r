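# Synthetic triple-layer datasets with planted cluster structure: diseases,
# miRNAs and lncRNAs are assigned to matched clusters; associations are
# Bernoulli(p_in) within matched clusters and Bernoulli(p_out) across; the
# disease DAG is a rooted tree whose subtrees follow the disease clusters,
# so cluster-mates share deep ancestors and are semantically similar.

#' Specification of a synthetic triple-layer dataset
#'
#' @param nd,nm,nl numbers of diseases, miRNAs, lncRNAs.
#' @param n_clusters number of planted clusters
#'   (`<= min(nd, nm, nl)`).
#' @param p_in,p_out association probability inside matched clusters vs.
#'   outside, for both bipartite layers; `p_in >= p_out`.  The defaults
#'   (0.3 / 0.02) give a desk-scale network whose in-cluster signal is
#'   clearly detectable but far from deterministic.
#' @param dag_branching branching factor of the within-cluster subtrees of
#'   the disease DAG.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(nd = 30, nm = 40, nl = 25, n_clusters = 4,
                           p_in = 0.3, p_out = 0.02, dag_branching = 2,
                           seed = 1L) {
  if (any(c(nd, nm, nl, n_clusters, dag_branching) < 1))
    stop("sizes, n_clusters and dag_branching must be positive integers")
  if (n_clusters > min(nd, nm, nl))
    stop("n_clusters must not exceed min(nd, nm, nl)")
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1))
    stop("p_in and p_out must be probabilities")
  if (p_in < p_out) stop("p_in must be >= p_out")
  structure(list(nd = nd, nm = nm, nl = nl, n_clusters = n_clusters,
                 p_in = p_in, p_out = p_out, dag_branching = dag_branching,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

make_labels <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# Round-robin cluster assignment over lexicographically sorted labels:
# cluster sizes as equal as possible.
assign_clusters <- function(n, k) rep(seq_len(k), length.out = n)

# Rooted tree: the first disease of cluster 1 is the global root; each
# cluster's first member heads its subtree and hangs off the root; within a
# cluster the remaining members fill a `branching`-ary tree under the head.
cluster_tree_edges <- function(labels, clusters, branching) {
  edges <- NULL
  heads <- character(max(clusters))
  for (c in sort(unique(clusters))) {
    members <- labels[clusters == c]
    heads[c] <- members[1]
    if (length(members) > 1) {
      parent_idx <- (seq_along(members)[-1] - 2L) %/% branching + 1L
      edges <- rbind(edges, cbind(members[-1], members[parent_idx]))
    }
  }
  root <- heads[1]
  if (length(heads) > 1)
    edges <- rbind(edges, cbind(heads[-1], root))
  data.frame(child = edges[, 1], parent = edges[, 2],
             stringsAsFactors = FALSE)
}

draw_layer <- function(row_clusters, col_clusters, p_in, p_out, row_lab,
                       col_lab) {
  pm <- ifelse(outer(row_clusters, col_clusters, "=="), p_in, p_out)
  m <- matrix(rbinom(length(pm), 1, pm), nrow(pm), ncol(pm),
              dimnames = list(row_lab, col_lab))
  list(m = m, pm = pm)
}

# Redraw all-zero rows/columns until every entity has at least one positive.
ensure_degree <- function(m, pm, max_tries = 1000) {
  resamples <- 0L
  for (tries in seq_len(max_tries)) {
    zr <- which(rowSums(m) == 0)
    zc <- which(colSums(m) == 0)
    if (!length(zr) && !length(zc)) {
      if (resamples > 0)
        message(resamples, " row/column redraw(s) to guarantee >= 1 positive")
      return(m)
    }
    for (i in zr) m[i, ] <- rbinom(ncol(m), 1, pm[i, ])
    for (j in zc) m[, j] <- rbinom(nrow(m), 1, pm[, j])
    resamples <- resamples + length(zr) + length(zc)
  }
  stop("could not guarantee >= 1 positive per row/column after ",
       max_tries, " resampling rounds; increase p_in/p_out")
}

#' Generate a synthetic triple-layer dataset
#'
#' @param spec a [synthetic_spec()].
#' @return List of class `trilayer_sim` with elements `dag`
#'   ([disease_dag]), `A` (disease-by-miRNA [bipartite_assoc]), `B`
#'   (miRNA-by-lncRNA [bipartite_assoc]), `disease_sets` (miRNA ->
#'   associated diseases), `truth` (planted cluster labels per layer) and
#'   the `spec`.
#' @export
generate_trilayer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  d_lab <- make_labels("d", spec$nd)
  m_lab <- make_labels("m", spec$nm)
  l_lab <- make_labels("l", spec$nl)
  d_cl <- assign_clusters(spec$nd, spec$n_clusters)
  m_cl <- assign_clusters(spec$nm, spec$n_clusters)
  l_cl <- assign_clusters(spec$nl, spec$n_clusters)
  dag <- disease_dag(d_lab,
                     cluster_tree_edges(d_lab, d_cl, spec$dag_branching))
  la <- draw_layer(d_cl, m_cl, spec$p_in, spec$p_out, d_lab, m_lab)
  A <- bipartite_assoc(ensure_degree(la$m, la$pm))
  lb <- draw_layer(m_cl, l_cl, spec$p_in, spec$p_out, m_lab, l_lab)
  B <- bipartite_assoc(ensure_degree(lb$m, lb$pm))
  structure(list(dag = dag, A = A, B = B,
                 disease_sets = disease_sets_from_assoc(A),
                 truth = list(disease = setNames(d_cl, d_lab),
                              mirna = setNames(m_cl, m_lab),
                              lncrna = setNames(l_cl, l_lab)),
                 spec = spec),
            class = "trilayer_sim")
}

#' @export
print.trilayer_sim <- function(x, ...) {
  cat(sprintf(paste0("trilayer_sim: %d diseases x %d miRNAs x %d lncRNAs, ",
                     "%d clusters, %d + %d positives\n"),
              x$spec$nd, x$spec$nm, x$spec$nl, x$spec$n_clusters,
              sum(x$A), sum(x$B)))
  invisible(x)
}

#' Randomly flip association entries
#'
#' Flips each entry of a binary matrix independently with probability
#' `flip_rate`; used for robustness experiments.
#'
#' @param A a [bipartite_assoc].
#' @param flip_rate flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return Perturbed [bipartite_assoc].
#' @export
perturb_associations <- function(A, flip_rate, seed = 1L) {
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  set.seed(seed)
  m <- unclass(as.matrix(A))
  flips <- matrix(rbinom(length(m), 1, flip_rate), nrow(m), ncol(m))
  bipartite_assoc((m + flips) %% 2)
}
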