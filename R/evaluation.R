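# Cross-validation harness: global leave-one-out, repeated k-fold, ROC/AUC.
#
# Each held-out known association is zeroed in A, the model is rerun
# (optionally refitting the A-derived kernels so nothing leaks), and the
# held-out pair's score is compared with the scores of all candidate pairs
# (pairs with no known association in the full A).  The AUC is the
# rank-statistic (Mann-Whitney) form of the ROC area.

#' ROC curve and AUC from positive and negative score lists
#'
#' The AUC is computed exactly in the rank (Mann-Whitney) form
#' `P(pos > neg) + 0.5 P(pos = neg)`, which equals the trapezoidal area
#' under the ROC curve obtained by sweeping a threshold over the scores.
#' ROC points are also emitted for plotting.
#'
#' @param pos_scores,neg_scores nonempty numeric vectors.
#' @return List with `auc` and `roc_points` (`data.frame` of `fpr`, `tpr`
#'   from (0,0) to (1,1)).
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("both score lists must be nonempty")
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), 0)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- roc[!duplicated(roc), , drop = FALSE]
  list(auc = auc, roc_points = roc)
}

# Random balanced fold assignment: sizes differ by at most 1.
make_folds <- function(n, k) {
  rep(seq_len(k), length.out = n)[sample.int(n)]
}

# Fraction of candidate scores a test score beats (ties count half).
score_percentile <- function(s, cand) {
  (sum(cand < s) + 0.5 * sum(cand == s)) / length(cand)
}

# Refit the A-derived similarity matrices after masking test entries.
# FS and SS come from external knowledge and are never refit.
refit_similarities <- function(A_masked, FS, SS, kcfg) {
  KD <- gaussian_profile_kernel(A_masked, "rows", kcfg$gamma_prime_d)
  KM <- gaussian_profile_kernel(A_masked, "cols", kcfg$gamma_prime_m)
  list(SM = integrate_mirna_similarity(KM, FS),
       SD = integrate_disease_similarity(KD, SS))
}

default_score_fn <- function(B, KL, prop_cfg) {
  function(A_masked, sims) {
    fit <- trilayer_propagate(A_masked, B, sims$SM, sims$SD, KL,
                              config = prop_cfg)
    fit$dm_scores
  }
}

# ROC points from per-test percentiles: candidates define the score scale,
# so at percentile threshold u the FPR is 1 - u and the TPR is the fraction
# of test pairs at or above u.
percentile_roc <- function(p) {
  u <- sort(unique(c(0, p, 1)), decreasing = TRUE)
  roc <- data.frame(fpr = 1 - u, tpr = vapply(u, function(t) mean(p >= t), 0))
  roc <- rbind(data.frame(fpr = 0, tpr = 0), roc,
               data.frame(fpr = 1, tpr = 1))
  roc[!duplicated(roc), , drop = FALSE]
}

cv_result <- function(auc_per_run, roc_points, n_test, n_candidate, seed,
                      degenerate = FALSE, percentiles = NULL) {
  structure(list(auc_per_run = auc_per_run,
                 mean_auc = mean(auc_per_run),
                 sd_auc = if (length(auc_per_run) > 1) sd(auc_per_run) else NA_real_,
                 roc_points = roc_points, n_test = n_test,
                 n_candidate = n_candidate, seed = seed,
                 degenerate = degenerate, percentiles = percentiles),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean AUC = %.4f%s over %d run(s), %d test pair(s)\n",
              x$mean_auc,
              if (is.na(x$sd_auc)) "" else sprintf(" +/- %.4f", x$sd_auc),
              length(x$auc_per_run), x$n_test))
  invisible(x)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is zeroed in turn, the model is rerun, and the
#' held-out score is ranked against the scores of all candidate pairs (pairs
#' unobserved in the full `A`).  The AUC pools these comparisons: it is the
#' mean over test pairs of the fraction of candidates they outscore (ties
#' half), i.e. the Mann-Whitney probability that a held-out positive
#' outranks a random candidate.
#'
#' @param A disease-by-miRNA [bipartite_assoc] with at least 2 positives.
#' @param B miRNA-by-lncRNA [bipartite_assoc] conformable with `A`.
#' @param SS disease semantic [similarity_matrix] (external knowledge, never
#'   refit).
#' @param FS miRNA functional [similarity_matrix]; if `NULL`, computed once
#'   from the disease sets of the full `A` (it plays the role of the
#'   externally downloaded functional-similarity matrix).
#' @param kernel_cfg a [kernel_config()].
#' @param prop_cfg a [propagation_config()].
#' @param refit recompute the Gaussian kernels (and hence `SM`, `SD`) after
#'   masking each test entry (default; no leakage through the kernels), or
#'   reuse matrices fitted once on the full `A` (`refit = FALSE`, faster and
#'   closer to a static setup).
#' @param candidate_scores `"per_fold"` takes candidate scores from each
#'   masked rerun; `"full_model"` takes them from a single run on the full
#'   `A`.
#' @param per_disease restrict each test pair's candidate pool to its own
#'   disease's unobserved miRNAs (diagnostic mode); default is the global
#'   pool.
#' @param score_fn optional scoring function `function(A_masked, sims)`
#'   returning a disease-by-miRNA score matrix; defaults to the propagation
#'   engine.  Exposed for diagnostics such as leakage guards.
#' @return A `cv_result`.
#' @export
global_loocv <- function(A, B, SS, FS = NULL,
                         kernel_cfg = kernel_config(),
                         prop_cfg = propagation_config(),
                         refit = TRUE,
                         candidate_scores = c("per_fold", "full_model"),
                         per_disease = FALSE, score_fn = NULL) {
  candidate_scores <- match.arg(candidate_scores)
  Am <- unclass(as.matrix(A))
  pos <- which(Am == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("need at least 2 known associations for LOOCV")
  if (is.null(FS)) FS <- mirna_functional_similarity(disease_sets_from_assoc(A), SS)
  KL <- gaussian_profile_kernel(B, "cols", kernel_cfg$gamma_prime_l)
  if (is.null(score_fn)) score_fn <- default_score_fn(B, KL, prop_cfg)
  static_sims <- if (!refit) refit_similarities(A, FS, SS, kernel_cfg)
  full_scores <- if (candidate_scores == "full_model") {
    sims <- static_sims %||% refit_similarities(A, FS, SS, kernel_cfg)
    score_fn(Am, sims)
  }
  cand_mask <- Am == 0
  p <- numeric(nrow(pos))
  n_tied <- 0L
  for (i in seq_len(nrow(pos))) {
    Ai <- Am
    Ai[pos[i, 1], pos[i, 2]] <- 0
    sims <- static_sims %||% refit_similarities(Ai, FS, SS, kernel_cfg)
    S <- tryCatch(score_fn(Ai, sims),
                  error = function(e)
                    stop("scoring failed for held-out pair (",
                         rownames(Am)[pos[i, 1]], ", ",
                         colnames(Am)[pos[i, 2]], "): ", conditionMessage(e)))
    s_test <- S[pos[i, 1], pos[i, 2]]
    Sc <- if (is.null(full_scores)) S else full_scores
    cand <- if (per_disease) {
      Sc[pos[i, 1], cand_mask[pos[i, 1], ]]
    } else {
      Sc[cand_mask]
    }
    if (all(cand == s_test)) n_tied <- n_tied + 1L
    p[i] <- score_percentile(s_test, cand)
  }
  degenerate <- n_tied == nrow(pos)
  if (degenerate)
    warning("every held-out score ties all candidate scores; ",
            "AUC is degenerate (0.5)")
  cv_result(auc_per_run = mean(p), roc_points = percentile_roc(p),
            n_test = nrow(pos), n_candidate = sum(cand_mask),
            seed = NA_integer_, degenerate = degenerate, percentiles = p)
}

#' Repeated k-fold cross-validation
#'
#' The known associations are randomly split into `k` disjoint folds of
#' near-equal size (sizes differ by at most 1).  Each fold is zeroed in
#' turn, the model is rerun, and each held-out pair is ranked against the
#' candidate scores of that rerun; folds are pooled within a repeat to give
#' one AUC per repeat.  The RNG is fully determined by `seed`.
#'
#' @inheritParams global_loocv
#' @param k number of folds (>= 2, <= number of positives).
#' @param repeats number of random re-partitions (the reference protocol
#'   uses 100; tests use fewer).
#' @param seed integer seed controlling the fold assignments.
#' @return A `cv_result` with one AUC per repeat.
#' @export
kfold_cv <- function(A, B, SS, FS = NULL, k = 5, repeats = 100, seed = 1,
                     kernel_cfg = kernel_config(),
                     prop_cfg = propagation_config(),
                     refit = TRUE, per_disease = FALSE, score_fn = NULL) {
  Am <- unclass(as.matrix(A))
  pos <- which(Am == 1, arr.ind = TRUE)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(pos)) stop("k exceeds the number of known associations")
  if (is.null(FS)) FS <- mirna_functional_similarity(disease_sets_from_assoc(A), SS)
  KL <- gaussian_profile_kernel(B, "cols", kernel_cfg$gamma_prime_l)
  if (is.null(score_fn)) score_fn <- default_score_fn(B, KL, prop_cfg)
  static_sims <- if (!refit) refit_similarities(A, FS, SS, kernel_cfg)
  cand_mask <- Am == 0
  set.seed(seed)
  aucs <- numeric(repeats)
  all_p <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_id <- make_folds(nrow(pos), k)
    p <- numeric(nrow(pos))
    for (f in seq_len(k)) {
      idx <- which(fold_id == f)
      Af <- Am
      Af[pos[idx, , drop = FALSE]] <- 0
      sims <- static_sims %||% refit_similarities(Af, FS, SS, kernel_cfg)
      S <- score_fn(Af, sims)
      cand <- if (per_disease) NULL else S[cand_mask]
      for (i in idx) {
        ci <- if (per_disease) S[pos[i, 1], cand_mask[pos[i, 1], ]] else cand
        p[i] <- score_percentile(S[pos[i, 1], pos[i, 2]], ci)
      }
    }
    aucs[r] <- mean(p)
    all_p <- c(all_p, p)
  }
  cv_result(auc_per_run = aucs, roc_points = percentile_roc(all_p),
            n_test = nrow(pos), n_candidate = sum(cand_mask), seed = seed)
}
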