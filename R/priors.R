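#' Assemble prior networks on one shared gene/TF index
#'
#' Converts one or more prior edge lists (or matrices) to dense
#' genes-by-TFs matrices on a single shared index: the sorted union of all
#' ids observed across the inputs (optionally extended by `genes`/`tfs`).
#' Each prior is rescaled so its maximum entry is 1, making heterogeneous
#' score scales (peak scores, motif scores, correlations) comparable before
#' summation.
#'
#' @param priors A list of `grncf_edge_list` objects and/or numeric matrices
#'   with gene rownames and TF colnames.
#' @param genes,tfs Optional character vectors forced into the index.
#' @return A `grncf_prior_set`: list with `P` (list of n-by-m matrices),
#'   `genes`, `tfs`.
#' @export
prior_set <- function(priors, genes = NULL, tfs = NULL) {
  if (!is.list(priors) || length(priors) == 0L) stop("need at least one prior network")
  if (inherits(priors, "grncf_edge_list")) priors <- list(priors)
  g <- as.character(genes); t <- as.character(tfs)
  for (p in priors) {
    if (is.matrix(p)) {
      g <- c(g, rownames(p)); t <- c(t, colnames(p))
    } else {
      g <- c(g, p$gene); t <- c(t, p$tf)
    }
  }
  g <- sort(unique(g)); t <- sort(unique(t))
  if (length(g) == 0L || length(t) == 0L) stop("prior set has an empty gene or TF index")
  P <- lapply(priors, function(p) {
    M <- matrix(0, length(g), length(t), dimnames = list(g, t))
    if (is.matrix(p)) {
      if (any(!is.finite(p)) || any(p < 0)) stop("prior matrices must be finite and >= 0")
      M[rownames(p), colnames(p)] <- p
    } else if (nrow(p) > 0L) {
      M[cbind(match(p$gene, g), match(p$tf, t))] <- p$weight
    }
    mx <- max(M)
    if (mx > 0) M <- M / mx
    M
  })
  structure(list(P = P, genes = g, tfs = t), class = "grncf_prior_set")
}

prior_sum <- function(priors) Reduce(`+`, priors$P)

#' Build the CF penalty and observation matrices from priors
#'
#' From the summed prior evidence `Psum = sum_k P^k` the collaborative
#' filtering term derives its confidence weights: `C = 1 + a * Psum`, the
#' binary support indicator `B = (Psum != 0)`, and the confirmed-edge
#' penalty `Cbar = 1 + a * cbar_scale * max(Psum, 1/d)` where `d` is the
#' number of priors. The floor `1/d` guarantees `Cbar > 1` even for pairs
#' with no prior support, so edges newly confirmed by the expression model
#' always carry an above-baseline confidence.
#'
#' @param priors A `grncf_prior_set`.
#' @param a Confidence scale (> 0), default 60.
#' @param cbar_scale Scale of the confirmed-edge penalty (> 0), default 1.
#' @return A `grncf_penalties`: list with matrices `C`, `Cbar`, `B` and the
#'   shared `genes`/`tfs` index.
#' @export
build_penalties <- function(priors, a = 60, cbar_scale = 1) {
  stopifnot(inherits(priors, "grncf_prior_set"))
  if (length(priors$P) == 0L) stop("empty prior set")
  if (a <= 0) stop("a must be > 0")
  if (cbar_scale <= 0) stop("cbar_scale must be > 0")
  Psum <- prior_sum(priors)
  d <- length(priors$P)
  C <- 1 + a * Psum
  B <- (Psum != 0) * 1
  Cbar <- 1 + a * cbar_scale * pmax(Psum, 1 / d)
  structure(list(C = C, Cbar = Cbar, B = B,
                 genes = priors$genes, tfs = priors$tfs),
            class = "grncf_penalties")
}

#' PriorSum baseline ranking
#'
#' Ranks each (gene, TF) pair by the summed weight across all priors; pairs
#' with zero summed weight receive no prediction.
#'
#' @param priors A `grncf_prior_set`.
#' @return A `grncf_edge_ranking`.
#' @export
priorsum_baseline <- function(priors) {
  stopifnot(inherits(priors, "grncf_prior_set"))
  Psum <- prior_sum(priors)
  idx <- which(Psum > 0, arr.ind = TRUE)
  edge_ranking(priors$genes[idx[, 1L]], priors$tfs[idx[, 2L]], Psum[idx])
}

#' Build a co-expression prior from TF-gene Pearson correlation
#'
#' Computes the Pearson correlation between each TF's expression row and
#' every gene's expression row and keeps the pairs whose correlation is at
#' least `threshold` (pairs below it are removed). A TF paired with itself
#' is excluded; pairs involving a constant (zero-variance) row are skipped
#' with a message.
#'
#' @param expr Numeric genes-by-samples matrix; every `tf_ids` entry must be
#'   one of its rownames, and at least 3 samples are required.
#' @param tf_ids Character vector of TF gene ids.
#' @param threshold Retention cutoff in (0, 1]; default 0.7.
#' @return A `grncf_edge_list` with role `"prior"`, weights = correlations.
#' @export
build_coexpression_prior <- function(expr, tf_ids, threshold = 0.7) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  tf_ids <- as.character(tf_ids)
  missing_tf <- setdiff(tf_ids, rownames(expr))
  if (length(missing_tf) > 0L) {
    stop("TF id(s) not in expression matrix: ", paste(missing_tf, collapse = ", "))
  }
  sds <- apply(expr, 1L, stats::sd)
  const <- rownames(expr)[sds == 0]
  if (length(const) > 0L) {
    message("skipping ", length(const), " constant expression row(s)")
  }
  ok_genes <- setdiff(rownames(expr), const)
  ok_tfs <- setdiff(tf_ids, const)
  if (length(ok_tfs) == 0L || length(ok_genes) == 0L) {
    return(edge_list(character(), character(), numeric(), role = "prior"))
  }
  R <- stats::cor(t(expr[ok_genes, , drop = FALSE]),
                  t(expr[ok_tfs, , drop = FALSE]))
  keep <- which(R >= threshold, arr.ind = TRUE)
  if (nrow(keep) > 0L) {
    gi <- ok_genes[keep[, 1L]]; tj <- ok_tfs[keep[, 2L]]
    self <- gi == tj
    gi <- gi[!self]; tj <- tj[!self]
    w <- R[keep][!self]
  } else {
    gi <- character(); tj <- character(); w <- numeric()
  }
  edge_list(gi, tj, w, role = "prior")
}
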