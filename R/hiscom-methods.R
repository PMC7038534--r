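#' @export
print.hiscom <- function(x, ...) {
  cat("Hierarchical structural component model (", x$family, ")\n", sep = "")
  cat(length(x$beta), " pathways, ", length(x$weights), " gene-PC columns, ",
      length(x$y), " samples\n", sep = "")
  cat("lambda_g = ", format(x$lambda_g), ", lambda_p = ", format(x$lambda_p),
      "\n", sep = "")
  cat(if (x$converged) "converged" else "NOT converged",
      " after ", x$n_iter, " iterations; phi = ",
      format(utils::tail(x$objective_trace, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted hierarchical pathway model
#'
#' @param object a `hiscom` fit.
#' @param ... unused.
#' @return A `summary.hiscom` object: the pathway coefficient table (with
#'   block sizes and latent-score standard deviations) and the largest gene
#'   contributions `|w * beta|`.
#' @export
summary.hiscom <- function(object, ...) {
  idx <- object$design$index
  K <- length(object$beta)
  S <- pathway_scores(object)
  tab <- data.frame(
    pathway_id = names(object$beta),
    n_genes = as.integer(tapply(idx$gene, idx$k,
                                function(g) length(unique(g)))),
    n_pcs = as.integer(table(idx$k)),
    beta = as.numeric(object$beta),
    score_sd = apply(S, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  contrib <- abs(object$weights * object$beta[idx$k])
  genes <- stats::aggregate(contrib,
                            by = list(pathway_id = idx$pathway_id,
                                      gene = idx$gene),
                            FUN = max)
  names(genes)[3] <- "statistic"
  genes <- genes[order(-genes$statistic), ]
  structure(list(pathways = tab, genes = genes, family = object$family,
                 lambda_g = object$lambda_g, lambda_p = object$lambda_p,
                 converged = object$converged, n_iter = object$n_iter,
                 phi = utils::tail(object$objective_trace, 1)),
            class = "summary.hiscom")
}

#' @export
print.summary.hiscom <- function(x, ...) {
  cat("HisCoM fit (", x$family, "), lambda_g = ", format(x$lambda_g),
      ", lambda_p = ", format(x$lambda_p), ", phi = ",
      format(x$phi, digits = 6), "\n\nPathway coefficients:\n", sep = "")
  print(x$pathways, digits = 4)
  cat("\nTop gene contributions |w * beta|:\n")
  print(utils::head(x$genes, 10), digits = 4)
  invisible(x)
}

#' Extract coefficients from a hiscom fit
#'
#' @param object a `hiscom` fit.
#' @param type which layer: pathway coefficients `beta_k`, gene-PC
#'   `weights` `w_kti`, unpenalized `covariates`, or `all` (named list
#'   including the intercept).
#' @param ... unused.
#' @export
coef.hiscom <- function(object, type = c("pathways", "weights",
                                         "covariates", "all"), ...) {
  type <- match.arg(type)
  switch(type,
         pathways = object$beta,
         weights = object$weights,
         covariates = object$covariate_coefs,
         all = list(beta0 = object$beta0, beta = object$beta,
                    weights = object$weights,
                    covariate_coefs = object$covariate_coefs))
}

#' Predict from a hiscom fit
#'
#' @param object a `hiscom` fit.
#' @param design optionally a new `hiscom_design` with the same column
#'   layout (e.g. held-out samples).
#' @param type `"link"` (linear predictor) or `"response"` (mean scale:
#'   identity for gaussian, logistic for binomial).
#' @param ... unused.
#' @export
predict.hiscom <- function(object, design = object$design,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- hiscom_eta(design, object)
  if (type == "response" && object$family == "binomial")
    eta <- stats::plogis(eta)
  eta
}

#' @export
fitted.hiscom <- function(object, ...)
  predict(object, type = "response")

#' Residuals of a hiscom fit
#'
#' @param object a `hiscom` fit.
#' @param type `"response"` (y minus fitted mean), `"pearson"`, or
#'   `"deviance"`.
#' @param ... unused.
#' @export
residuals.hiscom <- function(object,
                             type = c("response", "pearson", "deviance"),
                             ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  y <- object$y
  r <- y - mu
  if (type == "response") return(r)
  if (object$family == "gaussian") {
    v <- object$dispersion
    return(r / sqrt(v))                       # pearson == deviance here
  }
  if (type == "pearson") return(r / sqrt(pmax(mu * (1 - mu), 1e-12)))
  d <- -2 * (y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  sign(r) * sqrt(pmax(d, 0))
}

#' @export
logLik.hiscom <- function(object, ...) {
  eta <- hiscom_eta(object$design, object)
  y <- object$y
  n <- length(y)
  ll <- if (object$family == "gaussian") {
    v <- object$dispersion
    -n / 2 * log(2 * pi * v) - sum((y - eta)^2) / (2 * v)
  } else {
    sum(y * eta - log1p(exp(pmin(eta, 700))) - pmax(eta - 700, 0))
  }
  structure(ll, nobs = n,
            df = 1 + length(object$beta) + length(object$weights) +
              length(object$covariate_coefs),
            class = "logLik")
}

#' Simulate responses from a fitted hiscom model
#'
#' @param object a `hiscom` fit.
#' @param nsim number of response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.hiscom <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  n <- length(mu)
  sims <- replicate(nsim, {
    if (object$family == "gaussian")
      stats::rnorm(n, mu, sqrt(object$dispersion))
    else
      stats::rbinom(n, 1, mu)
  })
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot the ALS objective trace
#'
#' Shows the penalized log-likelihood \eqn{\phi} after every half-step; a
#' monotone non-decreasing trace is the expected behaviour.
#'
#' @param x a `hiscom` fit.
#' @param ... passed to [plot.default()].
#' @export
plot.hiscom <- function(x, ...) {
  phi <- x$objective_trace
  plot(seq_along(phi) - 1, phi, type = "b", pch = 20,
       xlab = "half-step", ylab = expression(phi),
       main = "ALS objective trace", ...)
  invisible(x)
}
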