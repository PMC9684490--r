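#' Run configuration for a network fit
#'
#' Collects every tunable of the joint collaborative-filtering / sparse-NCA
#' model and its solver. All fields are validated; the object serializes to
#' and from YAML without loss.
#'
#' @param a Confidence scale of the prior-derived penalty matrix
#'   (`C = 1 + a * sum_k P^k`); default 60.
#' @param h Latent feature dimension of the factorization; default 50.
#' @param lambda Balance between the CF term and the NCA term; default 1.
#' @param lambda_A,lambda_S Ridge penalties on TF activities and on the
#'   network weights; default 0.1 each.
#' @param eta Scalar l0 edge-penalty scale, expanded to a constant matrix
#'   eta_ij. It prices edge retention: a prior-supported edge survives the
#'   hard threshold only if its refit weight exceeds `sqrt(2 * eta / mu_S)`.
#'   With unit-variance activities `mu_S ~ l * sqrt(m)`, the default 5
#'   corresponds to pruning edges below roughly 0.3 at the package's
#'   reference problem scale.
#' @param cbar_scale Scale of the confirmed-edge penalty matrix Cbar;
#'   default 1.
#' @param max_iter Maximum outer iterations of the alternating scheme.
#' @param tol Relative objective-decrease threshold for convergence.
#' @param warm_start Number of CF-only alternating sweeps (targets taken from
#'   the priors alone) before the joint loop; default 10.
#' @param seed Integer seed for factor initialization.
#' @param center_expression Whether [read_expression()] centers gene rows.
#' @param mu_min Lower guard on prox step constants; default 1e-6.
#' @return A `grncf_config` list.
#' @export
run_config <- function(a = 60, h = 50, lambda = 1, lambda_A = 0.1,
                       lambda_S = 0.1, eta = 5, cbar_scale = 1,
                       max_iter = 500L, tol = 1e-5, warm_start = 10L,
                       seed = 1L, center_expression = TRUE, mu_min = 1e-6) {
  cfg <- list(a = as.numeric(a), h = as.integer(h), lambda = as.numeric(lambda),
              lambda_A = as.numeric(lambda_A), lambda_S = as.numeric(lambda_S),
              eta = as.numeric(eta), cbar_scale = as.numeric(cbar_scale),
              max_iter = as.integer(max_iter), tol = as.numeric(tol),
              warm_start = as.integer(warm_start), seed = as.integer(seed),
              center_expression = isTRUE(center_expression),
              mu_min = as.numeric(mu_min))
  validate_config(cfg)
  class(cfg) <- "grncf_config"
  cfg
}

validate_config <- function(cfg) {
  num <- c("a", "lambda", "lambda_A", "lambda_S", "eta", "cbar_scale",
           "tol", "mu_min")
  for (f in num) {
    if (!is.finite(cfg[[f]])) stop("config field '", f, "' must be finite")
  }
  if (cfg$a <= 0) stop("a must be > 0")
  if (cfg$h < 1L) stop("h must be >= 1")
  if (cfg$lambda < 0) stop("lambda must be >= 0")
  if (cfg$lambda_A < 0 || cfg$lambda_S < 0) stop("ridge penalties must be >= 0")
  if (cfg$eta < 0) stop("eta must be >= 0")
  if (cfg$cbar_scale <= 0) stop("cbar_scale must be > 0")
  if (cfg$max_iter < 1L) stop("max_iter must be >= 1")
  if (cfg$tol <= 0) stop("tol must be > 0")
  if (cfg$warm_start < 0L) stop("warm_start must be >= 0")
  if (cfg$mu_min <= 0) stop("mu_min must be > 0")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to [run_config()]
#' defaults. Reading the same file twice yields identical configurations.
#'
#' @param path Path to a YAML key-value file.
#' @return A `grncf_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `grncf_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
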