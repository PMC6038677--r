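test_that("model-1 semantic contributions decay geometrically and merge by max", {
  chain <- disease_dag(character(0),
                       data.frame(child = c("D3", "D2"), parent = c("D2", "D1")))
  cfg <- semantic_config(delta = 0.5)
  expect_equal(semantic_contribution_m1(chain, "D3", cfg),
               c(D1 = 0.25, D2 = 0.5, D3 = 1))
  expect_equal(semantic_contribution_m1(chain, "D1", cfg), c(D1 = 1))
  expect_equal(semantic_value(semantic_contribution_m1(chain, "D3", cfg)), 1.75)

  # diamond: two length-2 paths merge by max, no double counting
  diamond <- disease_dag(character(0),
                         data.frame(child = c("D4", "D4", "D2", "D3"),
                                    parent = c("D2", "D3", "D1", "D1")))
  cd <- semantic_contribution_m1(diamond, "D4", cfg)
  expect_equal(unname(cd["D1"]), 0.25)
  expect_equal(semantic_value(cd), 2.25)

  expect_error(semantic_contribution_m1(chain, "DX", cfg), "not in DAG")
})

test_that("SS1 matches hand-computed values on the toy DAG", {
  ss1 <- semantic_similarity_m1(toy_dag(), semantic_config(delta = 0.5))
  expect_equal(ss1["D2", "D3"], 1 / 3, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ss1["D1", "D2"], 0.6, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(unclass(ss1))), rep(1, 3))
})

test_that("model-2 uses DAG-membership information content", {
  dag <- toy_dag()
  cfg <- semantic_config()
  dd2 <- semantic_contribution_m2(dag, cfg)
  expect_equal(unname(dd2["D1"]), 0)
  expect_equal(unname(dd2["D2"]), -log(1 / 3))
  dd2_10 <- semantic_contribution_m2(dag, semantic_config(log_base = "10"))
  expect_equal(unname(dd2_10["D2"]), -log10(1 / 3))

  ss2 <- suppressMessages(semantic_similarity_m2(dag, cfg))
  expect_equal(ss2["D2", "D3"], 0, ignore_attr = TRUE)
  expect_equal(ss2["D2", "D2"], 1, ignore_attr = TRUE)
  # root-only disease has zero semantic value -> degenerate convention
  expect_equal(ss2["D1", "D1"], 1, ignore_attr = TRUE)
  # shared root has weight 0, denominator positive -> similarity 0
  expect_equal(ss2["D1", "D2"], 0, ignore_attr = TRUE)
})

test_that("combined semantic similarity is the entrywise mean", {
  dag <- toy_dag()
  ss1 <- semantic_similarity_m1(dag)
  ss2 <- suppressMessages(semantic_similarity_m2(dag))
  ss <- combined_semantic_similarity(ss1, ss2)
  expect_equal(ss["D2", "D3"], 1 / 6, ignore_attr = TRUE)
  expect_equal(unname(diag(unclass(ss))), rep(1, 3))
  same <- combined_semantic_similarity(ss1, ss1)
  expect_equal(unclass(same), unclass(ss1), ignore_attr = TRUE)
})

test_that("miRNA functional similarity matches hand-computed examples", {
  dag <- toy_dag()
  ss <- semantic_similarity_m1(dag)
  fs <- mirna_functional_similarity(list(m1 = "DA", m2 = "DA"),
                                    similarity_matrix(matrix(1, 1, 1,
                                      dimnames = list("DA", "DA"))))
  expect_equal(fs["m1", "m2"], 1, ignore_attr = TRUE)

  fs2 <- mirna_functional_similarity(list(m1 = "D2", m2 = "D3"), ss)
  expect_equal(fs2["m1", "m2"], 1 / 3, ignore_attr = TRUE)

  fs3 <- mirna_functional_similarity(list(m1 = c("D2", "D3"), m2 = "D2"), ss)
  expect_equal(fs3["m1", "m2"], (1 + 1 / 3 + 1) / 3, ignore_attr = TRUE)

  # empty disease set -> uncovered, not an error
  fs4 <- mirna_functional_similarity(list(m1 = "D2", m2 = character(0)), ss)
  expect_false(sim_coverage(fs4)["m1", "m2"])
  expect_true(is.na(fs4["m2", "m2"]))
})

test_that("functional similarity agrees with brute-force loops on random instances", {
  set.seed(31)
  for (rep in 1:10) {
    nd <- sample(4:8, 1)
    labs <- sprintf("D%d", 1:nd)
    ss <- similarity_matrix(random_symmetric(nd, labs))
    sets <- lapply(1:4, function(i) sample(labs, sample(1:min(8, nd), 1)))
    names(sets) <- sprintf("m%d", 1:4)
    fs <- mirna_functional_similarity(sets, ss)
    for (i in 1:4) for (j in 1:4)
      expect_equal(fs[i, j], oracle_fs(sets[[i]], sets[[j]], unclass(ss)),
                   ignore_attr = TRUE)
  }
})

test_that("Gaussian kernel matches the hand-computed 2x2 case", {
  A <- bipartite_assoc(matrix(c(1, 0, 0, 1), 2, 2,
                              dimnames = list(c("d1", "d2"), c("m1", "m2"))))
  kd <- gaussian_profile_kernel(A, "rows", gamma_prime = 1)
  expect_equal(kd["d1", "d2"], exp(-2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(unclass(kd))), c(1, 1))

  # identical profiles -> similarity 1
  A2 <- bipartite_assoc(matrix(c(1, 1, 0, 0), 2, 2,
                               dimnames = list(c("d1", "d2"), c("m1", "m2"))))
  expect_equal(gaussian_profile_kernel(A2, "rows")["d1", "d2"], 1,
               ignore_attr = TRUE)

  # zero profile among nonzero ones is fine; all-zero matrix is not
  A3 <- bipartite_assoc(matrix(c(1, 0, 1, 0), 2, 2,
                               dimnames = list(c("d1", "d2"), c("m1", "m2"))))
  k3 <- gaussian_profile_kernel(A3, "rows")
  expect_gt(k3["d1", "d2"], 0)
  expect_equal(unname(diag(unclass(k3))), c(1, 1))
  A0 <- bipartite_assoc(matrix(0, 2, 2,
                               dimnames = list(c("d1", "d2"), c("m1", "m2"))))
  expect_error(gaussian_profile_kernel(A0, "rows"), "kernel undefined")
})

test_that("kernel is equivariant under simultaneous permutation", {
  set.seed(5)
  A <- matrix(rbinom(30, 1, 0.4), 5, 6,
              dimnames = list(sprintf("d%d", 1:5), sprintf("m%d", 1:6)))
  A[1, 1] <- 1  # ensure nonzero
  k <- unclass(gaussian_profile_kernel(bipartite_assoc(A), "rows"))
  p <- sample(5)
  kp <- unclass(gaussian_profile_kernel(bipartite_assoc(A[p, ]), "rows"))
  expect_equal(kp, k[p, p], ignore_attr = TRUE)
})

test_that("integration averages where covered and falls back to the kernel", {
  lab <- c("m1", "m2")
  KM <- similarity_matrix(matrix(c(1, 0.2, 0.2, 1), 2, 2,
                                 dimnames = list(lab, lab)), kernel = TRUE)
  FS <- similarity_matrix(matrix(c(1, 0.6, 0.6, 1), 2, 2,
                                 dimnames = list(lab, lab)))
  expect_equal(integrate_mirna_similarity(KM, FS)["m1", "m2"], 0.4,
               ignore_attr = TRUE)

  FSna <- similarity_matrix(matrix(c(1, NA, NA, 1), 2, 2,
                                   dimnames = list(lab, lab)))
  expect_equal(integrate_mirna_similarity(KM, FSna)["m1", "m2"], 0.2,
               ignore_attr = TRUE)
  expect_equal(unclass(integrate_disease_similarity(KM, KM)),
               unclass(KM), ignore_attr = TRUE)
})

test_that("similarity outputs are symmetric, in [0,1], with unit kernel diagonals", {
  sim <- generate_trilayer(synthetic_spec(nd = 12, nm = 14, nl = 10,
                                          n_clusters = 3, seed = 4))
  sims <- build_similarities(sim)
  for (nm_ in names(sims)) {
    m <- sim_values(sims[[nm_]])
    expect_lt(max(abs(m - t(m))), 1e-10)
    vals <- unclass(sims[[nm_]])[sim_coverage(sims[[nm_]])]
    expect_true(all(vals >= 0 & vals <= 1))
  }
  for (nm_ in c("KD", "KM", "KL"))
    expect_equal(unname(diag(unclass(sims[[nm_]]))),
                 rep(1, nrow(sims[[nm_]])))
})

test_that("SS1 agrees with the brute-force oracle and never decreases when a shared ancestor is added", {
  set.seed(17)
  for (rep in 1:5) {
    edges <- random_rooted_dag_edges(sample(5:8, 1))
    dag <- disease_dag(character(0), edges)
    delta <- 0.5
    ss1 <- semantic_similarity_m1(dag, semantic_config(delta = delta))
    picks <- utils::combn(dag$nodes, 2)[, sample(choose(length(dag$nodes), 2), 4)]
    for (c_ in seq_len(ncol(picks))) {
      di <- picks[1, c_]; dj <- picks[2, c_]
      expect_equal(ss1[di, dj], oracle_ss1(edges, di, dj, delta),
                   ignore_attr = TRUE)
    }
    # add a new ancestor above the current root: shared by every pair
    root <- setdiff(dag$nodes, dag$edges$child)[1]
    edges2 <- rbind(edges, data.frame(child = root, parent = "ZZtop"))
    ss1b <- semantic_similarity_m1(disease_dag(character(0), edges2),
                                   semantic_config(delta = delta))
    for (c_ in seq_len(ncol(picks))) {
      di <- picks[1, c_]; dj <- picks[2, c_]
      expect_gte(ss1b[di, dj], ss1[di, dj] - 1e-12)
    }
  }
})
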