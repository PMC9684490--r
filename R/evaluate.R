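#' Percentile rankings of predicted regulators (or targets)
#'
#' For `axis = "gene"`, each gene's predicted TFs are ordered by descending
#' confidence and TF at (1-based) position `p` among `m` TFs gets the
#' percentile `100 * (p - 1) / (m - 1)`; tied scores receive the mean of
#' their positions. A TF with no prediction for that gene gets 100%. The
#' top prediction therefore scores 0% and the bottom (or absent) one 100%.
#' `axis = "tf"` is the transpose: genes ranked within each TF's list.
#'
#' @param prediction A `grncf_edge_ranking`.
#' @param axis `"gene"` (rank TFs per gene) or `"tf"` (rank genes per TF).
#' @param genes,tfs Character vectors fixing the evaluation universe; by
#'   default the union of ids seen in the prediction.
#' @return An n-by-m matrix of percentiles in [0, 100] with dimnames.
#' @export
percentile_ranks <- function(prediction, axis = c("gene", "tf"),
                             genes = NULL, tfs = NULL) {
  axis <- match.arg(axis)
  genes <- sort(unique(c(as.character(genes), prediction$gene)))
  tfs <- sort(unique(c(as.character(tfs), prediction$tf)))
  n <- length(genes); m <- length(tfs)
  if ((axis == "gene" && m < 2L) || (axis == "tf" && n < 2L)) {
    stop("need at least 2 candidates along the ranked axis")
  }
  R <- matrix(100, n, m, dimnames = list(genes, tfs))
  if (nrow(prediction) == 0L) return(R)
  gi <- match(prediction$gene, genes)
  tj <- match(prediction$tf, tfs)
  if (axis == "gene") {
    denom <- m - 1L
    for (i in unique(gi)) {
      sel <- gi == i
      pos <- rank(-prediction$score[sel], ties.method = "average")
      R[i, tj[sel]] <- 100 * (pos - 1) / denom
    }
  } else {
    denom <- n - 1L
    for (j in unique(tj)) {
      sel <- tj == j
      pos <- rank(-prediction$score[sel], ties.method = "average")
      R[gi[sel], j] <- 100 * (pos - 1) / denom
    }
  }
  R
}

#' Average Rank Score of a prediction against a gold standard
#'
#' Gene-centric: for gene `i`, `rank_i = sum_j r_ij I_ij / sum_j I_ij`, the
#' mean percentile of its gold-standard TFs; the overall score averages
#' `rank_i` over the genes possessing at least one gold edge. Lower is
#' better; a uniformly random ranking sits at 50%. The TF-centric score is
#' the transpose.
#'
#' @param percentiles Percentile matrix from [percentile_ranks()].
#' @param gold Binary gold-standard indicator matrix with dimnames, or a
#'   `grncf_edge_list`; ids missing from the percentile matrix are treated
#'   as unpredicted (100%).
#' @param axis `"gene"` or `"tf"`: which entities the averages run over.
#' @return A `grncf_rank_report`: list with `per_entity` (named vector of
#'   per-gene or per-TF averages, %), `overall` (%), `axis`, `n_entities`.
#' @export
ars <- function(percentiles, gold, axis = c("gene", "tf")) {
  axis <- match.arg(axis)
  I <- as_gold_matrix(gold, rownames(percentiles), colnames(percentiles))
  if (sum(I) == 0) stop("gold standard has no edges inside the universe")
  R <- matrix(100, nrow(I), ncol(I), dimnames = dimnames(I))
  cg <- intersect(rownames(I), rownames(percentiles))
  ct <- intersect(colnames(I), colnames(percentiles))
  R[cg, ct] <- percentiles[cg, ct]
  if (axis == "gene") {
    counts <- rowSums(I)
    keep <- counts > 0
    per <- rowSums(R * I)[keep] / counts[keep]
  } else {
    counts <- colSums(I)
    keep <- counts > 0
    per <- colSums(R * I)[keep] / counts[keep]
  }
  structure(list(per_entity = per, overall = mean(per), axis = axis,
                 n_entities = length(per)),
            class = "grncf_rank_report")
}

as_gold_matrix <- function(gold, genes = NULL, tfs = NULL) {
  if (is.matrix(gold)) {
    if (is.null(rownames(gold)) || is.null(colnames(gold))) {
      stop("gold matrix needs dimnames")
    }
    return((gold != 0) * 1)
  }
  g <- sort(unique(c(genes, gold$gene)))
  t <- sort(unique(c(tfs, gold$tf)))
  I <- matrix(0, length(g), length(t), dimnames = list(g, t))
  if (nrow(gold) > 0L) I[cbind(match(gold$gene, g), match(gold$tf, t))] <- 1
  I
}

#' @export
print.grncf_rank_report <- function(x, ...) {
  cat(sprintf("%s-centric Average Rank Score over %d entities: %.2f%%\n",
              x$axis, x$n_entities, x$overall))
  invisible(x)
}

#' Evaluate a ranked prediction against a gold standard
#'
#' Convenience wrapper: fixes the evaluation universe to the union of the
#' gold standard's and the prediction's ids (so a method is not rewarded
#' for omitting hard TFs), computes percentile ranks, and averages them.
#'
#' @param prediction A `grncf_edge_ranking`.
#' @param gold Gold-standard edge list or binary matrix.
#' @param axis `"gene"` or `"tf"`.
#' @return A `grncf_rank_report`.
#' @export
evaluate_ranking <- function(prediction, gold, axis = c("gene", "tf")) {
  axis <- match.arg(axis)
  I <- as_gold_matrix(gold)
  genes <- sort(unique(c(rownames(I), prediction$gene)))
  tfs <- sort(unique(c(colnames(I), prediction$tf)))
  R <- percentile_ranks(prediction, axis = axis, genes = genes, tfs = tfs)
  ars(R, I, axis = axis)
}

#' Random-confidence baseline ranking
#'
#' Assigns every (gene, TF) pair an independent uniform(0, 1) confidence
#' score drawn from `seed`.
#'
#' @param genes,tfs Character vectors defining the universe.
#' @param seed Integer seed.
#' @return A `grncf_edge_ranking` covering all pairs.
#' @export
random_baseline <- function(genes, tfs, seed = 1L) {
  genes <- as.character(genes); tfs <- as.character(tfs)
  set.seed(as.integer(seed))
  idx <- expand.grid(g = genes, t = tfs, stringsAsFactors = FALSE)
  edge_ranking(idx$g, idx$t, stats::runif(nrow(idx)))
}

#' Gold-standard edges from a differential-expression table
#'
#' A knockdown-derived (TF, gene) pair becomes a gold-standard edge when the
#' gene responds to the TF's depletion: `|log2fc| > lfc_cut` OR
#' `padj < padj_cut`. A row with missing `padj` is kept only if the fold
#' change condition holds (reported via a message).
#'
#' @param de data.frame with columns `gene`, `tf`, `log2fc`, `padj`.
#' @param lfc_cut Absolute log2 fold-change cutoff, default 1.
#' @param padj_cut Adjusted p-value cutoff, default 0.05.
#' @return A `grncf_edge_list` with role `"gold_standard"`, weights 1.
#' @export
gold_from_de <- function(de, lfc_cut = 1, padj_cut = 0.05) {
  stopifnot(all(c("gene", "tf", "log2fc", "padj") %in% names(de)))
  napad <- is.na(de$padj)
  if (any(napad)) {
    message(sum(napad), " row(s) with missing padj: log2fc condition only")
  }
  keep <- abs(de$log2fc) > lfc_cut
  keep[!napad] <- keep[!napad] | (de$padj[!napad] < padj_cut)
  edge_list(de$gene[keep], de$tf[keep], rep(1, sum(keep)),
            role = "gold_standard")
}
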