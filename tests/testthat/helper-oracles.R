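# Independent brute-force oracles, written against the model definitions
# directly (explicit loops, naive recursion), never calling the package's
# fast paths.

# --- disease semantic similarity, model 1 -----------------------------------

oracle_ancestors <- function(edges, d) {
  tset <- d
  repeat {
    parents <- unique(edges$parent[edges$child %in% tset])
    new <- setdiff(parents, tset)
    if (!length(new)) return(sort(tset))
    tset <- c(tset, new)
  }
}

oracle_dd1 <- function(edges, D, delta) {
  tset <- oracle_ancestors(edges, D)
  dd <- function(d) {
    if (d == D) return(1)
    kids <- edges$child[edges$parent == d]
    kids <- kids[kids %in% tset]
    delta * max(vapply(kids, dd, 0))
  }
  setNames(vapply(tset, dd, 0), tset)
}

oracle_ss1 <- function(edges, di, dj, delta) {
  ci <- oracle_dd1(edges, di, delta)
  cj <- oracle_dd1(edges, dj, delta)
  common <- intersect(names(ci), names(cj))
  (sum(ci[common]) + sum(cj[common])) / (sum(ci) + sum(cj))
}

# --- miRNA functional similarity (explicit loops over set pairs) ------------

oracle_fs <- function(set_i, set_j, ss) {
  best <- function(d, set) {
    m <- -Inf
    for (dd in set) m <- max(m, ss[d, dd])
    m
  }
  tot <- 0
  for (d in set_i) tot <- tot + best(d, set_j)
  for (d in set_j) tot <- tot + best(d, set_i)
  tot / (length(set_i) + length(set_j))
}

# --- propagation: literal loop-based recurrences ----------------------------

oracle_propagate <- function(A, B, SM, SD, KL, alpha, iters, variant) {
  nd <- nrow(A); nm <- ncol(A); nl <- ncol(B)
  W <- A; V <- B
  norm1 <- function(M) {
    n <- nrow(M)
    rs <- numeric(n)
    for (i in 1:n) rs[i] <- sum(M[i, ])
    N <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      den <- if (variant == "symmetric_sqrt") sqrt(rs[i] * rs[j]) else rs[i] * rs[j]
      N[i, j] <- if (den == 0) 0 else M[i, j] / den
    }
    N
  }
  for (k in seq_len(iters)) {
    IM <- matrix(0, nm, nm)
    for (i in 1:nm) for (j in 1:nm) {
      s <- 0
      for (a in 1:nm) for (b in 1:nl) for (cc in 1:nl)
        s <- s + SM[i, a] * V[a, b] * KL[b, cc] * V[j, cc]
      IM[i, j] <- s
    }
    ID <- matrix(0, nm, nm)
    for (i in 1:nm) for (j in 1:nm) {
      s <- 0
      for (u in 1:nd) for (v in 1:nd) for (a in 1:nm)
        s <- s + W[u, i] * SD[u, v] * W[v, a] * SM[a, j]
      ID[i, j] <- s
    }
    NIM <- norm1(IM); NID <- norm1(ID)
    Wn <- matrix(0, nd, nm)
    for (u in 1:nd) for (j in 1:nm) {
      s <- 0
      for (i in 1:nm) s <- s + W[u, i] * NIM[i, j]
      Wn[u, j] <- alpha * s + (1 - alpha) * A[u, j]
    }
    Vn <- matrix(0, nm, nl)
    for (i in 1:nm) for (b in 1:nl) {
      s <- 0
      for (j in 1:nm) s <- s + NID[i, j] * V[j, b]
      Vn[i, b] <- alpha * s + (1 - alpha) * B[i, b]
    }
    W <- Wn; V <- Vn
  }
  list(W = W, V = V)
}

# --- AUC: brute-force pairwise Mann-Whitney ---------------------------------

oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# --- shared random fixtures -------------------------------------------------

random_symmetric <- function(n, labels = NULL, unit_diag = TRUE) {
  x <- matrix(runif(n * n), n)
  x <- (x + t(x)) / 2
  if (unit_diag) diag(x) <- 1
  if (!is.null(labels)) dimnames(x) <- list(labels, labels)
  x
}

random_instance <- function(nd = 3, nm = 4, nl = 5) {
  dl <- sprintf("d%d", 1:nd); ml <- sprintf("m%d", 1:nm); ll <- sprintf("l%d", 1:nl)
  A <- matrix(rbinom(nd * nm, 1, 0.5), nd, nm, dimnames = list(dl, ml))
  B <- matrix(rbinom(nm * nl, 1, 0.5), nm, nl, dimnames = list(ml, ll))
  list(A = A, B = B,
       SM = random_symmetric(nm, ml), SD = random_symmetric(nd, dl),
       KL = random_symmetric(nl, ll))
}

# Random rooted DAG as a child -> parent edge frame: node 1 is the root,
# every later node gets 1-2 parents among earlier nodes.
random_rooted_dag_edges <- function(n) {
  labels <- sprintf("D%02d", 1:n)
  edges <- NULL
  for (i in 2:n) {
    np <- sample(1:min(2, i - 1), 1)
    parents <- sample(labels[seq_len(i - 1)], np)
    edges <- rbind(edges, data.frame(child = labels[i], parent = parents,
                                     stringsAsFactors = FALSE))
  }
  edges
}

# Small toy DAG used across tests: D2 -> D1, D3 -> D1.
toy_dag <- function() disease_dag(c("D1", "D2", "D3"),
                                  data.frame(child = c("D2", "D3"),
                                             parent = c("D1", "D1")))

# Default similarity stack for a synthetic dataset.
build_similarities <- function(sim, scfg = semantic_config(),
                               kcfg = kernel_config()) {
  SS <- suppressMessages(combined_semantic_similarity(
    semantic_similarity_m1(sim$dag, scfg),
    semantic_similarity_m2(sim$dag, scfg)))
  FS <- mirna_functional_similarity(sim$disease_sets, SS)
  KD <- gaussian_profile_kernel(sim$A, "rows", kcfg$gamma_prime_d)
  KM <- gaussian_profile_kernel(sim$A, "cols", kcfg$gamma_prime_m)
  KL <- gaussian_profile_kernel(sim$B, "cols", kcfg$gamma_prime_l)
  list(SS = SS, FS = FS, KD = KD, KM = KM, KL = KL,
       SM = integrate_mirna_similarity(KM, FS),
       SD = integrate_disease_similarity(KD, SS))
}
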