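# Coupled propagation over the triple-layer network.  Starting from the
# observed binary layers W_dm^0 = A and W_ml^0 = B, each synchronous step
# rebuilds two miRNA-by-miRNA coupling matrices from the current iterates,
#
#   IM = SM . W_ml . KL . W_ml^T        (lncRNA-layer coupling)
#   ID = W_dm^T . SD . W_dm . SM        (disease-layer coupling)
#
# normalizes them, and mixes one propagation step with a restart on the
# observed layer:
#
#   W_dm <- alpha * W_dm . N(IM) + (1 - alpha) A
#   W_ml <- alpha * N(ID) . W_ml + (1 - alpha) B
#
# until the L1 change of W_dm (optionally also W_ml) drops below the cutoff.

#' Propagation configuration
#'
#' @param alpha decay factor strictly in (0,1): weight of the propagated
#'   term against the restart on the observed associations.  Default 0.4.
#' @param cutoff positive L1 stopping threshold on the change of the
#'   disease-miRNA iterate between consecutive steps.  Default `1e-6`.
#' @param max_iter iteration cap; hitting it returns a result flagged
#'   `converged = FALSE` with a warning.
#' @param normalization `"symmetric_sqrt"` divides each coupling entry by the
#'   square root of the product of its two row sums, which bounds the
#'   spectral radius by 1 and guarantees contraction for `alpha < 1`;
#'   `"row_product_literal"` divides by the plain product of the two row
#'   sums (a much stronger damping, kept for fidelity experiments).
#' @param track `"dm_only"` checks convergence on the disease-miRNA iterate;
#'   `"both"` additionally requires the miRNA-lncRNA iterate to settle.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.4, cutoff = 1e-6, max_iter = 1000,
                               normalization = c("symmetric_sqrt",
                                                 "row_product_literal"),
                               track = c("dm_only", "both")) {
  normalization <- match.arg(normalization)
  track <- match.arg(track)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (max_iter < 1) stop("max_iter must be a positive integer")
  structure(list(alpha = alpha, cutoff = cutoff,
                 max_iter = as.integer(max_iter),
                 normalization = normalization, track = track),
            class = "propagation_config")
}

#' lncRNA-layer coupling matrix IM
#'
#' @param SM miRNA integrated similarity (nm x nm).
#' @param W_ml current miRNA-lncRNA iterate (nm x nl).
#' @param KL lncRNA Gaussian kernel (nl x nl).
#' @return nm x nm nonnegative matrix `SM . W_ml . KL . W_ml^T`.
#' @export
coupling_im <- function(SM, W_ml, KL) {
  SM <- sim_values(SM); KL <- sim_values(KL); W <- unclass(as.matrix(W_ml))
  if (ncol(SM) != nrow(W) || ncol(W) != nrow(KL))
    stop("coupling_im: non-conformable shapes")
  SM %*% W %*% KL %*% t(W)
}

#' Disease-layer coupling matrix ID
#'
#' By dimension analysis this is a miRNA-by-miRNA matrix
#' (`W_dm^T . SD . W_dm . SM`), and it is normalized over that dimension.
#'
#' @param SD disease integrated similarity (nd x nd).
#' @param W_dm current disease-miRNA iterate (nd x nm).
#' @param SM miRNA integrated similarity (nm x nm).
#' @return nm x nm nonnegative matrix.
#' @export
coupling_id <- function(SD, W_dm, SM) {
  SD <- sim_values(SD); SM <- sim_values(SM); W <- unclass(as.matrix(W_dm))
  if (nrow(W) != nrow(SD) || ncol(W) != nrow(SM))
    stop("coupling_id: non-conformable shapes")
  crossprod(W, SD %*% W) %*% SM
}

#' Normalize a coupling matrix
#'
#' `symmetric_sqrt` divides entry (i,j) by `sqrt(rowsum_i * rowsum_j)`; the
#' result is similar to a row-stochastic matrix, so its spectral radius is
#' at most 1.  `row_product_literal` divides by `rowsum_i * rowsum_j`.
#' Rows with zero sum map to zero rows (`0/0 := 0`: isolated nodes
#' propagate nothing).
#'
#' @param M square nonnegative matrix.
#' @param variant `"symmetric_sqrt"` or `"row_product_literal"`.
#' @return Normalized matrix of the same shape.
#' @export
normalize_coupling <- function(M, variant = c("symmetric_sqrt",
                                              "row_product_literal")) {
  variant <- match.arg(variant)
  M <- unclass(as.matrix(M))
  if (any(M < 0)) stop("normalize_coupling: negative entry")
  rs <- rowSums(M)
  denom <- outer(rs, rs)
  if (variant == "symmetric_sqrt") denom <- sqrt(denom)
  out <- M / denom
  out[denom == 0] <- 0
  out
}

#' Run the coupled triple-layer propagation
#'
#' @param A disease-by-miRNA binary [bipartite_assoc].
#' @param B miRNA-by-lncRNA binary [bipartite_assoc]; its rows must match
#'   `A`'s columns (see [harmonize_lncrna_layer()] with `pad = TRUE`).
#' @param SM,SD,KL integrated miRNA similarity, integrated disease
#'   similarity, and lncRNA kernel, with labels matching `A`/`B`.
#' @param config a [propagation_config()].
#' @return Object of class `trilayer_scores`: list with `dm_scores`
#'   (nd x nm), `ml_scores` (nm x nl), `iteration`, `delta_dm`, `delta_ml`,
#'   `converged`, and the `config` used.
#' @export
trilayer_propagate <- function(A, B, SM, SD, KL, config = propagation_config()) {
  Am <- unclass(as.matrix(A)); Bm <- unclass(as.matrix(B))
  SMv <- sim_values(SM); SDv <- sim_values(SD); KLv <- sim_values(KL)
  if (!is.null(rownames(Bm)) && !is.null(colnames(Am)) &&
      !identical(colnames(Am), rownames(Bm)))
    stop("miRNA labels of A (columns) and B (rows) do not match")
  if (ncol(Am) != nrow(Bm) || ncol(Am) != nrow(SMv) ||
      nrow(Am) != nrow(SDv) || ncol(Bm) != nrow(KLv))
    stop("non-conformable layer shapes")
  check_labels <- function(lbl, m, what) {
    if (!is.null(lbl) && !is.null(rownames(m)) && !identical(lbl, rownames(m)))
      stop("label mismatch for ", what)
  }
  check_labels(colnames(Am), SMv, "SM")
  check_labels(rownames(Am), SDv, "SD")
  check_labels(colnames(Bm), KLv, "KL")

  alpha <- config$alpha
  W_dm <- Am; W_ml <- Bm
  delta_dm <- delta_ml <- Inf
  converged <- FALSE
  iter <- 0L
  for (k in seq_len(config$max_iter)) {
    IM <- SMv %*% W_ml %*% KLv %*% t(W_ml)
    ID <- crossprod(W_dm, SDv %*% W_dm) %*% SMv
    NIM <- normalize_coupling(IM, config$normalization)
    NID <- normalize_coupling(ID, config$normalization)
    W_dm_new <- alpha * W_dm %*% NIM + (1 - alpha) * Am
    W_ml_new <- alpha * NID %*% W_ml + (1 - alpha) * Bm
    if (!all(is.finite(W_dm_new)) || !all(is.finite(W_ml_new)))
      stop("non-finite value during propagation at iteration ", k)
    delta_dm <- sum(abs(W_dm_new - W_dm))
    delta_ml <- sum(abs(W_ml_new - W_ml))
    W_dm <- W_dm_new; W_ml <- W_ml_new
    iter <- k
    done <- delta_dm < config$cutoff &&
      (config$track != "both" || delta_ml < config$cutoff)
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warning("propagation did not converge within ", config$max_iter,
            " iterations (last delta_dm = ", signif(delta_dm, 4), ")")
  dimnames(W_dm) <- dimnames(Am)
  dimnames(W_ml) <- dimnames(Bm)
  structure(list(dm_scores = W_dm, ml_scores = W_ml, iteration = iter,
                 delta_dm = delta_dm, delta_ml = delta_ml,
                 converged = converged, config = config),
            class = "trilayer_scores")
}

#' @export
print.trilayer_scores <- function(x, ...) {
  cat(sprintf("trilayer_scores: %d x %d disease-miRNA, %d x %d miRNA-lncRNA\n",
              nrow(x$dm_scores), ncol(x$dm_scores),
              nrow(x$ml_scores), ncol(x$ml_scores)))
  cat(sprintf("  %s after %d iterations (delta_dm = %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iteration, x$delta_dm))
  invisible(x)
}

#' One-shot disease-lncRNA inference
#'
#' The intermediate disease-by-lncRNA association inference
#' `W_dl = W_dm . SM . W_ml`, exposed as a diagnostic by-product of the
#' model derivation.
#'
#' @param W_dm disease-miRNA matrix (nd x nm).
#' @param SM miRNA similarity (nm x nm).
#' @param W_ml miRNA-lncRNA matrix (nm x nl).
#' @return nd x nl matrix.
#' @export
one_shot_disease_lncrna <- function(W_dm, SM, W_ml) {
  unclass(as.matrix(W_dm)) %*% sim_values(SM) %*% unclass(as.matrix(W_ml))
}

#' Rank candidate miRNAs for a disease
#'
#' Lists only miRNAs with no known association to the disease, sorted by
#' predicted score descending, ties broken by miRNA label ascending.
#'
#' @param scores a `trilayer_scores` object or a disease-by-miRNA score
#'   matrix.
#' @param A the known disease-by-miRNA [bipartite_assoc].
#' @param disease disease identifier (must be a row label of `A`).
#' @param top optionally truncate to the top `top` candidates.
#' @return `data.frame` with columns `mirna` and `score`.
#' @export
rank_candidates <- function(scores, A, disease, top = NULL) {
  S <- if (inherits(scores, "trilayer_scores")) scores$dm_scores else
    unclass(as.matrix(scores))
  if (!disease %in% rownames(A)) stop("unknown disease: ", disease)
  cand <- colnames(A)[unclass(A)[disease, ] == 0]
  s <- S[disease, cand]
  ord <- order(-s, cand)
  out <- data.frame(mirna = cand[ord], score = unname(s[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(top)) out <- head(out, top)
  out
}
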