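# Similarity layer: disease semantic similarity from the DAG (two models and
# their average), MISIM-style miRNA functional similarity from associated
# disease sets, Gaussian interaction-profile kernels, and the integrated
# SM / SD matrices the propagation engine consumes.

#' Configuration for disease semantic similarity
#'
#' @param delta semantic contribution factor in (0,1): each step from a
#'   disease to its parent multiplies the ancestor's contribution by `delta`.
#'   Default 0.5, the conventional choice for MeSH-based semantic similarity.
#' @param log_base base of the logarithm in model 2's information-content
#'   weight: `"natural"` (default) or `"10"`.
#' @param selfsim_degenerate self-similarity assigned in model 2 to diseases
#'   whose every ancestor (including themselves) appears in all DAGs, making
#'   both semantic values zero.  Self-similarity must be maximal, so 1.
#' @return A `semantic_config` list.
#' @export
semantic_config <- function(delta = 0.5, log_base = c("natural", "10"),
                            selfsim_degenerate = 1) {
  log_base <- match.arg(log_base)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1)
    stop("delta must lie strictly in (0, 1)")
  structure(list(delta = delta, log_base = log_base,
                 selfsim_degenerate = selfsim_degenerate),
            class = "semantic_config")
}

#' Configuration for Gaussian interaction-profile kernels
#'
#' @param gamma_prime_d,gamma_prime_m,gamma_prime_l raw bandwidths for the
#'   disease, miRNA and lncRNA kernels; each is divided by the mean squared
#'   profile norm of its own entity set to give the effective bandwidth.
#'   Default 1 for all three (the usual interaction-profile convention).
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(gamma_prime_d = 1, gamma_prime_m = 1,
                          gamma_prime_l = 1) {
  g <- c(gamma_prime_d, gamma_prime_m, gamma_prime_l)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("all gamma_prime values must be strictly positive")
  structure(list(gamma_prime_d = gamma_prime_d, gamma_prime_m = gamma_prime_m,
                 gamma_prime_l = gamma_prime_l), class = "kernel_config")
}

#' Model-1 semantic contributions of a disease's ancestors
#'
#' The disease contributes 1 to its own semantic value; every ancestor `d`
#' contributes `delta` times the largest contribution among its children
#' inside `T(D)`, so contributions decay geometrically with distance from
#' `D` and merge by maximum where ancestry paths rejoin.
#'
#' @param dag a [disease_dag].
#' @param D disease identifier; must be in the DAG.
#' @param cfg a [semantic_config()].
#' @return Named numeric vector over `T(D)`.
#' @export
semantic_contribution_m1 <- function(dag, D, cfg = semantic_config()) {
  tset <- dag_ancestors(dag, D)
  children <- split(dag$edges$child, dag$edges$parent)
  memo <- new.env(parent = emptyenv())
  assign(D, 1, envir = memo)
  contrib <- function(d) {
    if (!is.null(v <- get0(d, envir = memo, inherits = FALSE))) return(v)
    kids <- intersect(children[[d]], tset)
    v <- cfg$delta * max(vapply(kids, contrib, 0))
    assign(d, v, envir = memo)
    v
  }
  setNames(vapply(tset, contrib, 0), tset)
}

#' Semantic value of a disease
#'
#' Sum of the contributions of all terms in `T(D)`; at least 1, since the
#' disease always contributes 1 to itself.
#'
#' @param contributions named vector from [semantic_contribution_m1()] (or
#'   the model-2 analogue).
#' @return A scalar.
#' @export
semantic_value <- function(contributions) {
  if (!length(contributions)) stop("empty contribution map")
  sum(contributions)
}

#' Disease semantic similarity, model 1
#'
#' For each pair the contributions of shared DAG terms, measured in each
#' disease's own DAG, are summed and normalized by the two semantic values:
#' `SS1(i,j) = sum_{t in T(i) ^ T(j)} (DD1_i(t) + DD1_j(t)) / (DV1(i) + DV1(j))`.
#'
#' @inheritParams semantic_contribution_m1
#' @return A [similarity_matrix] over all DAG nodes (full coverage,
#'   unit diagonal).
#' @export
semantic_similarity_m1 <- function(dag, cfg = semantic_config()) {
  contribs <- lapply(dag$nodes, function(d) semantic_contribution_m1(dag, d, cfg))
  names(contribs) <- dag$nodes
  dv <- vapply(contribs, semantic_value, 0)
  pairwise_semantic(dag$nodes, contribs, dv, degenerate_self = NULL)
}

#' Model-2 semantic contributions (information content weights)
#'
#' Each DAG term `d` is weighted by how specific it is:
#' `DD2(d) = -log(n_DAGs_containing_d / n_diseases)`, so terms appearing in
#' every disease's DAG (e.g. the root of a connected DAG) contribute 0 and
#' rare, specific terms contribute most.  Unlike model 1 the weight does not
#' depend on which disease's DAG it is evaluated in.
#'
#' @inheritParams semantic_contribution_m1
#' @return Named numeric vector over all DAG nodes.
#' @export
semantic_contribution_m2 <- function(dag, cfg = semantic_config()) {
  frac <- dag$membership / length(dag$nodes)
  w <- if (cfg$log_base == "10") -log10(frac) else -log(frac)
  setNames(w, dag$nodes)
}

#' Disease semantic similarity, model 2
#'
#' Same combination rule as model 1 but with the information-content weights
#' of [semantic_contribution_m2()].  When both semantic values are zero the
#' pair is degenerate: the diagonal receives `cfg$selfsim_degenerate`
#' (default 1) and off-diagonal degenerate pairs receive 0.
#'
#' @inheritParams semantic_contribution_m1
#' @return A [similarity_matrix] over all DAG nodes.
#' @export
semantic_similarity_m2 <- function(dag, cfg = semantic_config()) {
  dd2 <- semantic_contribution_m2(dag, cfg)
  contribs <- lapply(dag$nodes, function(d) dd2[dag$ancestors[[d]]])
  names(contribs) <- dag$nodes
  dv <- vapply(contribs, sum, 0)
  n_degen <- sum(dv == 0)
  if (n_degen > 0)
    message(n_degen, " disease(s) with zero model-2 semantic value; ",
            "using degenerate self-similarity ", cfg$selfsim_degenerate)
  pairwise_semantic(dag$nodes, contribs, dv,
                    degenerate_self = cfg$selfsim_degenerate)
}

# Shared pairwise combination rule for both semantic models.
pairwise_semantic <- function(nodes, contribs, dv, degenerate_self) {
  n <- length(nodes)
  ss <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    ci <- contribs[[i]]
    for (j in i:n) {
      denom <- dv[i] + dv[j]
      if (denom == 0) {
        # only possible in model 2
        ss[i, j] <- ss[j, i] <- if (i == j) degenerate_self else 0
        next
      }
      cj <- contribs[[j]]
      common <- intersect(names(ci), names(cj))
      ss[i, j] <- ss[j, i] <- (sum(ci[common]) + sum(cj[common])) / denom
    }
  }
  similarity_matrix(ss)
}

#' Average of the two semantic similarity models
#'
#' @param SS1,SS2 [similarity_matrix] objects over the same diseases.
#' @return Entrywise mean; coverage is the intersection of the coverages.
#' @export
combined_semantic_similarity <- function(SS1, SS2) {
  stopifnot(identical(rownames(SS1), rownames(SS2)))
  cov <- sim_coverage(SS1) & sim_coverage(SS2)
  m <- (sim_values(SS1) + sim_values(SS2)) / 2
  m[!cov] <- NA_real_
  similarity_matrix(m, coverage = cov)
}

#' Disease sets of each miRNA
#'
#' @param A disease-by-miRNA [bipartite_assoc].
#' @return Named list mapping each miRNA to the character vector of diseases
#'   it is associated with (possibly empty).
#' @export
disease_sets_from_assoc <- function(A) {
  ds <- apply(unclass(A), 2, function(col) rownames(A)[col == 1],
              simplify = FALSE)
  names(ds) <- colnames(A)
  ds
}

#' MISIM-style miRNA functional similarity
#'
#' Functional similarity of two miRNAs is derived from the semantic
#' similarity of their associated disease sets in four steps: identify the
#' two disease sets, take the semantic values of their diseases from the
#' DAG, score every disease of one set by its best match in the other set
#' (`S(d, Dset) = max_{d'} SS(d, d')`), and combine:
#' `FS(i,j) = (sum_{d in D(i)} S(d, D(j)) + sum_{d in D(j)} S(d, D(i))) /
#' (|D(i)| + |D(j)|)`.
#'
#' Pairs where either disease set is empty are left uncovered (the score is
#' undefined, not zero); the integration step then falls back to the
#' Gaussian kernel for those pairs.
#'
#' @param disease_sets named list, miRNA -> character vector of diseases; all
#'   diseases must be covered by `SS`.
#' @param SS disease [similarity_matrix] (typically
#'   [combined_semantic_similarity()]).
#' @return miRNA [similarity_matrix] with coverage mask.
#' @export
mirna_functional_similarity <- function(disease_sets, SS) {
  mirnas <- names(disease_sets)
  if (is.null(mirnas)) stop("disease_sets must be a named list")
  alld <- unique(unlist(disease_sets))
  missing <- setdiff(alld, rownames(SS))
  if (length(missing))
    stop("disease(s) not covered by SS: ", paste(head(missing, 3), collapse = ", "))
  ssv <- sim_values(SS)
  n <- length(mirnas)
  fs <- matrix(NA_real_, n, n, dimnames = list(mirnas, mirnas))
  nonempty <- lengths(disease_sets) > 0
  best <- function(d, set) max(ssv[d, set])
  for (i in seq_len(n)) {
    if (!nonempty[i]) next
    di <- disease_sets[[i]]
    for (j in i:n) {
      if (!nonempty[j]) next
      dj <- disease_sets[[j]]
      s_ij <- sum(vapply(di, best, 0, set = dj))
      s_ji <- sum(vapply(dj, best, 0, set = di))
      fs[i, j] <- fs[j, i] <- (s_ij + s_ji) / (length(di) + length(dj))
    }
  }
  similarity_matrix(fs, coverage = !is.na(fs))
}

#' Gaussian interaction-profile kernel similarity
#'
#' Each entity's binary association profile `IP(x)` (its row or column of
#' the bipartite matrix) is compared by a Gaussian kernel
#' `K(u,v) = exp(-gamma * ||IP(u) - IP(v)||^2)` whose bandwidth is the raw
#' `gamma_prime` normalized by the mean squared profile norm over all
#' entities of the chosen axis.  Entities with all-zero profiles are allowed
#' (the formula applies unchanged); the kernel is only undefined when every
#' profile is empty.
#'
#' @param profiles a [bipartite_assoc] (or binary labelled matrix).
#' @param axis `"rows"` or `"cols"`: which margin holds the entities to
#'   compare.
#' @param gamma_prime raw bandwidth, strictly positive.
#' @return A [similarity_matrix] with diagonal exactly 1.
#' @export
gaussian_profile_kernel <- function(profiles, axis = c("rows", "cols"),
                                    gamma_prime = 1) {
  axis <- match.arg(axis)
  if (!is.numeric(gamma_prime) || gamma_prime <= 0)
    stop("gamma_prime must be strictly positive")
  x <- unclass(as.matrix(profiles))
  if (axis == "cols") x <- t(x)
  norms2 <- rowSums(x^2)
  msn <- mean(norms2)
  if (msn == 0) stop("all profiles empty; kernel undefined")
  gamma <- gamma_prime / msn
  # ||u - v||^2 = |u| + |v| - 2 u.v  for binary profiles
  g <- tcrossprod(x)
  d2 <- outer(norms2, norms2, "+") - 2 * g
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  diag(k) <- 1
  similarity_matrix(k, kernel = TRUE)
}

#' Integrated miRNA similarity
#'
#' Where a pair's functional similarity is defined, average it with the
#' kernel similarity; elsewhere use the kernel alone.  Full coverage.
#'
#' @param KM miRNA Gaussian kernel [similarity_matrix].
#' @param FS miRNA functional [similarity_matrix] with coverage mask.
#' @return [similarity_matrix] `SM`.
#' @export
integrate_mirna_similarity <- function(KM, FS) {
  integrate_pair(KM, FS)
}

#' Integrated disease similarity
#'
#' Same branch rule as [integrate_mirna_similarity()], with the disease
#' semantic similarity in place of the functional similarity.
#'
#' @param KD disease Gaussian kernel [similarity_matrix].
#' @param SS disease semantic [similarity_matrix].
#' @return [similarity_matrix] `SD`.
#' @export
integrate_disease_similarity <- function(KD, SS) {
  integrate_pair(KD, SS)
}

integrate_pair <- function(K, S) {
  if (!identical(rownames(K), rownames(S)))
    stop("label mismatch between kernel and similarity matrices")
  cov <- sim_coverage(S)
  out <- sim_values(K)
  sv <- sim_values(S)
  out[cov] <- (out[cov] + sv[cov]) / 2
  similarity_matrix(out)
}
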