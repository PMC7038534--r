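#' Fit a hierarchical structural component model
#'
#' Fits the joint pathway model
#' \deqn{g(E[y_j]) = \beta_0 + \sum_{k=1}^{K}\Big[\sum_{t=1}^{T_k}
#'   \sum_{i=1}^{N_{kt}} g_{ktij} w_{kti}\Big]\beta_k + x_j^\top\gamma}
#' where \eqn{g_{kti}} are the selected per-gene PC scores, \eqn{w_{kti}} are
#' gene-PC weights and \eqn{\beta_k} pathway coefficients, by maximizing the
#' ridge-penalized log-likelihood
#' \deqn{\phi = \sum_j \log p(y_j;\gamma_j,\delta)
#'   - \tfrac12\lambda_g\sum w_{kti}^2 - \tfrac12\lambda_p\sum\beta_k^2.}
#' Estimation alternates two penalized least-squares half-steps until
#' convergence: with the weights fixed, the pathway coefficients (plus
#' intercept and covariate effects, both unpenalized) are updated by a ridge
#' GLM on the latent pathway scores; with the pathway coefficients fixed, the
#' weights are updated by a ridge GLM on the \eqn{\beta_k}-scaled PC columns.
#' The binomial family uses iteratively reweighted least squares with
#' step-halving so the objective never decreases; the gaussian half-steps are
#' exact solves (dispersion held at 1 inside the iteration, estimated by the
#' residual mean square afterwards).
#'
#' After convergence the per-pathway sign indeterminacy of \eqn{(w,\beta)} is
#' resolved by making the largest-magnitude weight in each pathway block
#' positive.
#'
#' @param design a `hiscom_design` from [build_design()].
#' @param y numeric phenotype vector (0/1 for binomial), or a
#'   [phenotype_data] object (its family is then used).
#' @param family `"gaussian"` or `"binomial"`.
#' @param lambda_g,lambda_p nonnegative ridge penalties on the gene-weight
#'   and pathway-effect layers.
#' @param tol convergence tolerance: stop when the largest absolute parameter
#'   change over a full iteration, or the change in \eqn{\phi}, falls below
#'   `tol` (default 1e-5).
#' @param max_iter iteration cap (default 100); hitting it returns
#'   `converged = FALSE` with a warning.
#' @param init `"equal"` (deterministic: each block's weights equal with unit
#'   block norm) or `"random"` (seeded standard normal, block-normalized).
#' @param seed seed for `init = "random"`.
#' @return An object of class `hiscom` with elements `beta0`, `beta` (named
#'   by pathway), `weights` (per PC column), `covariate_coefs`, `family`,
#'   `lambda_g`, `lambda_p`, `dispersion`, `objective_trace` (phi after every
#'   half-step), `converged`, `n_iter`, `design`, `y`.
#' @examples
#' sim <- simulate_study(sim_config(n_samples = 120, n_pathways = 3,
#'                                  genes_per_pathway = 2, n_causal_genes = 2,
#'                                  snps_per_gene = 3), seed = 7)
#' des <- design_from_study(sim)
#' fit <- hiscom(des, sim$phenotype$y, "gaussian", lambda_g = 1, lambda_p = 1)
#' fit
#' @export
hiscom <- function(design, y, family = c("gaussian", "binomial"),
                   lambda_g = 1, lambda_p = 1, tol = 1e-5, max_iter = 100L,
                   init = c("equal", "random"), seed = NULL) {
  stopifnot(inherits(design, "hiscom_design"))
  if (inherits(y, "phenotype_data")) {
    family <- y$family
    y <- y$y
  } else {
    family <- match.arg(family)
  }
  init <- match.arg(init)
  y <- as.numeric(y)
  if (length(y) != nrow(design$Z))
    stop("phenotype length does not match the design", call. = FALSE)
  if (lambda_g < 0 || lambda_p < 0)
    stop("ridge penalties must be nonnegative", call. = FALSE)

  ini <- hiscom_init(design, y, family, init = init, seed = seed)
  fam_code <- if (family == "gaussian") 0L else 1L
  res <- .als_fit_cpp(design$Z, design$covariates, y,
                      as.integer(design$index$k), fam_code,
                      lambda_g, lambda_p, ini$w, ini$beta0,
                      tol, as.integer(max_iter))
  if (!res$converged)
    warning("ALS did not converge in ", max_iter, " iterations",
            call. = FALSE)

  beta <- as.numeric(res$beta)
  w <- as.numeric(res$w)
  # per-block sign convention: largest-|w| entry positive
  for (k in seq_along(beta)) {
    sel <- design$index$k == k
    lead <- which(sel)[which.max(abs(w[sel]))]
    if (length(lead) && w[lead] < 0) {
      w[sel] <- -w[sel]
      beta[k] <- -beta[k]
    }
  }
  names(beta) <- design$pathway_ids
  names(w) <- colnames(design$Z)
  gamma <- as.numeric(res$gamma)
  if (ncol(design$covariates))
    names(gamma) <- colnames(design$covariates)

  structure(list(beta0 = res$beta0, beta = beta, weights = w,
                 covariate_coefs = gamma, family = family,
                 lambda_g = lambda_g, lambda_p = lambda_p,
                 dispersion = if (family == "gaussian") res$dispersion else 1,
                 objective_trace = as.numeric(res$phi_trace),
                 converged = res$converged, n_iter = res$n_iter,
                 design = design, y = y,
                 call = match.call()),
            class = "hiscom")
}

#' Deterministic or seeded-random starting values
#'
#' The default start sets every weight within a pathway block to the same
#' value with unit block norm (`1/sqrt(P_k)` for a block of `P_k` PC
#' columns), all pathway coefficients to zero, covariate effects to zero, and
#' the intercept to the null-model value (mean for gaussian, logit of the
#' mean for binomial). The random start draws weights from a seeded standard
#' normal and block-normalizes them.
#'
#' @inheritParams hiscom
#' @return list with `w`, `beta`, `beta0`, `covariate_coefs`.
#' @export
hiscom_init <- function(design, y, family = c("gaussian", "binomial"),
                        init = c("equal", "random"), seed = NULL) {
  family <- match.arg(family)
  init <- match.arg(init)
  kidx <- design$index$k
  P <- length(kidx)
  if (init == "equal") {
    blk <- table(kidx)
    w <- 1 / sqrt(as.numeric(blk)[kidx])
  } else {
    if (!is.null(seed)) set.seed(seed)
    w <- stats::rnorm(P)
    for (k in unique(kidx)) {
      sel <- kidx == k
      w[sel] <- w[sel] / sqrt(sum(w[sel]^2))
    }
  }
  ybar <- mean(y)
  beta0 <- if (family == "gaussian") ybar else {
    ybar <- min(max(ybar, 1e-8), 1 - 1e-8)
    stats::qlogis(ybar)
  }
  list(w = w, beta = numeric(max(kidx)), beta0 = beta0,
       covariate_coefs = numeric(ncol(design$covariates)))
}

#' Penalized log-likelihood of a fitted or hypothetical parameter set
#'
#' Computes \eqn{\phi}: the model log-likelihood minus the two ridge
#' penalties (no penalty on the intercept or covariate effects). For the
#' gaussian family the log-density uses variance `dispersion` (default 1,
#' matching the value traced during fitting).
#'
#' @param design a `hiscom_design`.
#' @param fit a `hiscom` object, or any list with elements `beta0`, `beta`,
#'   `weights`, `covariate_coefs`, `family`, `lambda_g`, `lambda_p`.
#' @param y phenotype vector (defaults to the fit's own).
#' @param dispersion gaussian variance \eqn{\delta} (default 1).
#' @return scalar \eqn{\phi}.
#' @export
penalized_loglik <- function(design, fit, y = fit$y, dispersion = 1) {
  eta <- hiscom_eta(design, fit)
  if (!all(is.finite(eta)))
    stop("nonfinite linear predictor", call. = FALSE)
  n <- length(y)
  ll <- if (fit$family == "gaussian") {
    -n / 2 * log(2 * pi * dispersion) - sum((y - eta)^2) / (2 * dispersion)
  } else {
    sum(y * eta - log1p(exp(pmin(eta, 700))) - pmax(eta - 700, 0))
  }
  ll - 0.5 * fit$lambda_g * sum(fit$weights^2) -
    0.5 * fit$lambda_p * sum(fit$beta^2)
}

# linear predictor eta for parameter set `fit` on `design`
hiscom_eta <- function(design, fit) {
  kidx <- design$index$k
  if (length(fit$weights) != ncol(design$Z) ||
      length(fit$beta) != max(kidx))
    stop("parameter dimensions do not match the design", call. = FALSE)
  scale <- fit$weights * fit$beta[kidx]
  eta <- fit$beta0 + drop(design$Z %*% scale)
  if (ncol(design$covariates))
    eta <- eta + drop(design$covariates %*% fit$covariate_coefs)
  eta
}

#' Latent pathway component scores
#'
#' Column k holds \eqn{\sum_t\sum_i g_{kti} w_{kti}} for each subject: the
#' weighted gene-PC combination representing pathway k.
#'
#' @param object a fitted `hiscom` model.
#' @param design optionally, a different `hiscom_design` with the same
#'   column layout.
#' @return numeric matrix, samples x pathways.
#' @export
pathway_scores <- function(object, design = object$design) {
  kidx <- design$index$k
  K <- max(kidx)
  S <- matrix(0, nrow(design$Z), K,
              dimnames = list(design$sample_ids, design$pathway_ids))
  for (k in seq_len(K)) {
    sel <- kidx == k
    S[, k] <- design$Z[, sel, drop = FALSE] %*% object$weights[sel]
  }
  S
}
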