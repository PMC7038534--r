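#' Cross-validated selection of the ridge penalties
#'
#' Partitions the samples into `k` folds by a seeded shuffle (stratified by
#' outcome class for the binomial family), fits the model on each training
#' set for every `(lambda_g, lambda_p)` pair, and scores the held-out
#' negative log-likelihood (deviance/2; gaussian with unit dispersion). The
#' loss is the fold-size-weighted mean; the best pair attains the minimum,
#' with ties broken toward the larger `lambda_g + lambda_p` and then the
#' larger `lambda_p`.
#'
#' @inheritParams hiscom
#' @param grid_g,grid_p candidate penalty values (default
#'   `c(0.01, 0.1, 1, 10, 100, 1000)` each).
#' @param k number of folds (default 5).
#' @param seed seed for the fold shuffle (default 1).
#' @return An object of class `hiscom_cv`: list with `grid` (one row per
#'   pair: `lambda_g`, `lambda_p`, `loss`, per-fold losses), `best`
#'   (named vector), `folds`, `k`, `seed`.
#' @export
hiscom_cv <- function(design, y, family = c("gaussian", "binomial"),
                      grid_g = c(0.01, 0.1, 1, 10, 100, 1000),
                      grid_p = c(0.01, 0.1, 1, 10, 100, 1000),
                      k = 5, seed = 1, tol = 1e-5, max_iter = 500L) {
  if (inherits(y, "phenotype_data")) {
    family <- y$family
    y <- y$y
  } else {
    family <- match.arg(family)
  }
  n <- length(y)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k samples", call. = FALSE)
  if (!length(grid_g) || !length(grid_p))
    stop("penalty grids must be non-empty", call. = FALSE)

  folds <- cv_folds(y, family, k, seed)
  grid <- expand.grid(lambda_g = grid_g, lambda_p = grid_p,
                      KEEP.OUT.ATTRS = FALSE)
  fold_loss <- matrix(NA_real_, nrow(grid), k)
  fold_n <- tabulate(folds, k)

  for (f in seq_len(k)) {
    test <- folds == f
    if (family == "binomial" && length(unique(y[!test])) < 2)
      stop("training fold with a single outcome class; reduce k",
           call. = FALSE)
    d_tr <- design_subset(design, which(!test))
    d_te <- design_subset(design, which(test))
    for (i in seq_len(nrow(grid))) {
      fit <- suppressWarnings(
        hiscom(d_tr, y[!test], family, lambda_g = grid$lambda_g[i],
               lambda_p = grid$lambda_p[i], tol = tol, max_iter = max_iter))
      eta <- predict(fit, d_te, type = "link")
      fold_loss[i, f] <- heldout_nll(y[test], eta, family)
    }
  }
  grid$loss <- as.numeric(fold_loss %*% fold_n) / n
  colnames(fold_loss) <- paste0("fold", seq_len(k))

  best_loss <- min(grid$loss)
  cand <- which(grid$loss <= best_loss + 1e-12)
  ord <- order(-(grid$lambda_g[cand] + grid$lambda_p[cand]),
               -grid$lambda_p[cand])
  best_i <- cand[ord[1]]

  structure(list(grid = cbind(grid, fold_loss),
                 best = c(lambda_g = grid$lambda_g[best_i],
                          lambda_p = grid$lambda_p[best_i]),
                 best_loss = grid$loss[best_i],
                 folds = folds, k = k, seed = seed, family = family),
            class = "hiscom_cv")
}

# seeded, outcome-stratified fold assignment; sizes differ by at most one
cv_folds <- function(y, family, k, seed) {
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(n)
  if (family == "binomial") {
    # round-robin continues across classes so overall fold sizes stay
    # within one of each other while classes spread evenly
    counter <- 0L
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
  } else {
    ord <- sample.int(n)
    folds[ord] <- rep_len(seq_len(k), n)
  }
  folds
}

# held-out negative log-likelihood per observation set (deviance/2 scale;
# gaussian uses unit dispersion)
heldout_nll <- function(y, eta, family) {
  if (family == "gaussian") {
    sum((y - eta)^2) / 2
  } else {
    sum(log1p(exp(pmin(eta, 700))) + pmax(eta - 700, 0) - y * eta)
  }
}

#' @export
print.hiscom_cv <- function(x, ...) {
  cat("hiscom_cv: ", x$k, "-fold CV over ", nrow(x$grid), " penalty pairs (",
      x$family, ")\n", sep = "")
  cat("best: lambda_g = ", format(x$best["lambda_g"]), ", lambda_p = ",
      format(x$best["lambda_p"]), " (mean held-out NLL ",
      format(x$best_loss, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.hiscom_cv <- function(x, ...) {
  g <- x$grid
  lg <- sort(unique(g$lambda_g))
  lp <- sort(unique(g$lambda_p))
  z <- matrix(NA_real_, length(lg), length(lp))
  for (i in seq_len(nrow(g)))
    z[match(g$lambda_g[i], lg), match(g$lambda_p[i], lp)] <- g$loss[i]
  graphics::image(log10(lg), log10(lp), z,
                  xlab = expression(log[10](lambda[g])),
                  ylab = expression(log[10](lambda[p])),
                  main = "CV held-out loss", ...)
  graphics::points(log10(x$best["lambda_g"]), log10(x$best["lambda_p"]),
                   pch = 4, cex = 2, lwd = 2)
  invisible(x)
}
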