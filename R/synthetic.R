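#' Specification of a planted-network simulation
#'
#' Defaults define the package's reference study conditions: a 60-gene,
#' 10-TF, 30-sample system with 15% edge density, moderate expression noise
#' (sd 0.5 against unit-variance activities), and two degraded priors that
#' each see 70% of the true edges plus a 2% spurious-pair rate.
#'
#' @param n_genes,m_tfs,l_samples Problem dimensions (>= 1).
#' @param density Planted edge probability per pair, in (0, 1].
#' @param noise_sd Gaussian expression noise standard deviation (>= 0).
#' @param prior_recall Probability a true edge enters each prior, in [0, 1].
#' @param prior_fpr Probability a non-edge enters each prior, in [0, 1).
#' @param n_priors Number of independently degraded priors (>= 1).
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A `grncf_sim_spec` list.
#' @export
sim_spec <- function(n_genes = 60L, m_tfs = 10L, l_samples = 30L,
                     density = 0.15, noise_sd = 0.5, prior_recall = 0.7,
                     prior_fpr = 0.02, n_priors = 2L, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), m_tfs = as.integer(m_tfs),
               l_samples = as.integer(l_samples), density = as.numeric(density),
               noise_sd = as.numeric(noise_sd),
               prior_recall = as.numeric(prior_recall),
               prior_fpr = as.numeric(prior_fpr),
               n_priors = as.integer(n_priors), seed = as.integer(seed))
  stopifnot(spec$n_genes >= 1L, spec$m_tfs >= 1L, spec$l_samples >= 1L,
            spec$density > 0, spec$density <= 1, spec$noise_sd >= 0,
            spec$prior_recall >= 0, spec$prior_recall <= 1,
            spec$prior_fpr >= 0, spec$prior_fpr < 1, spec$n_priors >= 1L)
  if (spec$density * spec$n_genes * spec$m_tfs < 1) {
    stop("expected planted network is empty (density * n * m < 1)")
  }
  class(spec) <- "grncf_sim_spec"
  spec
}

#' Simulate a planted network, activities, expression, and degraded priors
#'
#' Draws a ground-truth network `S_true` with Bernoulli(`density`) support
#' and signed weights uniform on +/-[0.5, 2] (bounded away from zero so the
#' support is unambiguous under noise), standard-normal TF activities
#' `A_true`, and expression `E = S_true A_true + N(0, noise_sd)`. Each
#' prior keeps every true edge independently with probability
#' `prior_recall` and adds each non-edge with probability `prior_fpr`, with
#' uniform(0, 1] weights. The gold standard is the support of `S_true`.
#'
#' The base RNG stream (from `spec$seed`) draws the ground truth and
#' expression; each prior uses its own derived sub-seed, so changing
#' `n_priors` never perturbs `E`.
#'
#' @param spec A `grncf_sim_spec`.
#' @return A `grncf_sim_bundle`: list with `S_true`, `A_true`, `E`,
#'   `priors` (a `grncf_prior_set`), `gold` (a `grncf_edge_list`), `spec`.
#' @export
simulate_grn <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "grncf_sim_spec"))
  n <- spec$n_genes; m <- spec$m_tfs; l <- spec$l_samples
  genes <- sprintf("g%03d", seq_len(n))
  tfs <- sprintf("tf%02d", seq_len(m))
  samples <- sprintf("s%03d", seq_len(l))

  set.seed(spec$seed)
  supp <- matrix(stats::rbinom(n * m, 1L, spec$density), n, m)
  mag <- matrix(stats::runif(n * m, 0.5, 2), n, m)
  sgn <- matrix(sign(stats::runif(n * m) - 0.5), n, m)
  sgn[sgn == 0] <- 1
  S_true <- supp * mag * sgn
  dimnames(S_true) <- list(genes, tfs)
  A_true <- matrix(stats::rnorm(m * l), m, l, dimnames = list(tfs, samples))
  E <- S_true %*% A_true
  if (spec$noise_sd > 0) {
    E <- E + matrix(stats::rnorm(n * l, sd = spec$noise_sd), n, l)
  }
  dimnames(E) <- list(genes, samples)

  priors <- vector("list", spec$n_priors)
  for (k in seq_len(spec$n_priors)) {
    set.seed((spec$seed * 1009L + 7919L * k) %% .Machine$integer.max)
    keep <- matrix(stats::rbinom(n * m, 1L, spec$prior_recall), n, m) * supp
    fp <- matrix(stats::rbinom(n * m, 1L, spec$prior_fpr), n, m) * (1 - supp)
    Pk <- (keep + fp) * matrix(stats::runif(n * m, .Machine$double.eps, 1), n, m)
    dimnames(Pk) <- list(genes, tfs)
    priors[[k]] <- Pk
  }
  pset <- prior_set(priors, genes = genes, tfs = tfs)

  gi <- which(supp == 1, arr.ind = TRUE)
  gold <- edge_list(genes[gi[, 1L]], tfs[gi[, 2L]], rep(1, nrow(gi)),
                    role = "gold_standard")
  structure(list(S_true = S_true, A_true = A_true, E = E, priors = pset,
                 gold = gold, spec = spec),
            class = "grncf_sim_bundle")
}

#' Write a simulated bundle as the standard TSV exchange files
#'
#' Writes `expression.tsv`, `prior_<k>.tsv` for each prior, `gold.tsv`, and
#' `truth.tsv` (the signed planted network) into `outdir`.
#'
#' @param bundle A `grncf_sim_bundle`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_sim_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(outdir, "expression.tsv")
  write_expression(bundle$E, p); paths <- c(paths, p)
  for (k in seq_along(bundle$priors$P)) {
    Pk <- bundle$priors$P[[k]]
    idx <- which(Pk > 0, arr.ind = TRUE)
    el <- edge_list(rownames(Pk)[idx[, 1L]], colnames(Pk)[idx[, 2L]], Pk[idx],
                    role = "prior")
    p <- file.path(outdir, sprintf("prior_%d.tsv", k))
    write_edge_list(el, p); paths <- c(paths, p)
  }
  p <- file.path(outdir, "gold.tsv")
  write_edge_list(bundle$gold, p); paths <- c(paths, p)
  idx <- which(bundle$S_true != 0, arr.ind = TRUE)
  tr <- data.frame(gene = rownames(bundle$S_true)[idx[, 1L]],
                   tf = colnames(bundle$S_true)[idx[, 2L]],
                   weight = bundle$S_true[idx], stringsAsFactors = FALSE)
  p <- file.path(outdir, "truth.tsv")
  utils::write.table(tr, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
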