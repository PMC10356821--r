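# Environmental covariate preparation: variable transforms, multivariate-
# normal EM imputation of missing cells, and PCA on the correlation matrix
# whose component z-scores serve as PERMANCOVA covariates.

#' Normalize environmental variables before EM imputation
#'
#' Right-skewed, strictly positive variables (age, depth, EC, ice content,
#' total C, total N, organic C) are transformed by `ln(x + c)` with `c` half
#' the smallest positive observed value of that variable; the remaining
#' variables are left on their original scale.  Every variable is then
#' centered and scaled to mean 0, SD 1 over its observed cells.  All
#' parameters are recorded so the transform is exactly invertible with
#' [denormalize_env()].
#'
#' @param meta Metadata tibble (or any data frame containing the
#'   environmental columns); missing cells allowed.
#' @param variables Character vector of columns to use (default: the twelve
#'   continuous environmental variables present in `meta`).
#' @return A list of class `"env_normalized"`: `x` (samples x variables
#'   numeric matrix, NAs preserved), `transform_record` (tibble with
#'   per-variable transform, offset, center, scale), `sample_ids`.
#' @export
normalize_env <- function(meta, variables = intersect(ENV_VARS, names(meta))) {
  X <- as.matrix(as.data.frame(meta)[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- meta$sample_id
  rec <- purrr::map_dfr(variables, function(v) {
    x <- X[, v]
    obs <- x[!is.na(x)]
    if (length(obs) < 3) abort(sprintf("variable '%s' has < 3 observed values", v))
    if (v %in% LOG_VARS) {
      offset <- min(obs[obs > 0]) / 2
      x <- log(x + offset)
      tr <- "log"
    } else {
      offset <- 0
      tr <- "identity"
    }
    ctr <- mean(x, na.rm = TRUE)
    scl <- sd(x, na.rm = TRUE)
    if (!is.finite(scl) || scl == 0) {
      abort(sprintf("variable '%s' has zero SD among observed values", v))
    }
    X[, v] <<- (x - ctr) / scl
    tibble::tibble(variable = v, transform = tr, offset = offset,
                   center = ctr, scale = scl)
  })
  structure(list(x = X, transform_record = rec, sample_ids = meta$sample_id),
            class = "env_normalized")
}

#' Invert the normalization transform
#'
#' @param x Matrix on the normalized scale (columns named as in the record).
#' @param transform_record The record from [normalize_env()].
#' @return Matrix on the original measurement scale.
#' @export
denormalize_env <- function(x, transform_record) {
  out <- x
  for (i in seq_len(nrow(transform_record))) {
    v <- transform_record$variable[i]
    y <- x[, v] * transform_record$scale[i] + transform_record$center[i]
    if (transform_record$transform[i] == "log") {
      y <- exp(y) - transform_record$offset[i]
    }
    out[, v] <- y
  }
  out
}

# observed-data log-likelihood of a MVN model with per-row missingness
mvn_obs_loglik <- function(X, mu, Sigma) {
  ll <- 0
  for (i in seq_len(nrow(X))) {
    o <- which(!is.na(X[i, ]))
    S <- Sigma[o, o, drop = FALSE]
    d <- X[i, o] - mu[o]
    ch <- chol(S)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, d, transpose = TRUE)^2))
  }
  ll
}

#' Impute missing environmental values by multivariate-normal EM
#'
#' Classic EM for a multivariate normal with ignorable (MCAR/MAR)
#' missingness.  The E-step fills each missing block with its conditional
#' mean given the observed cells and the current `(mu, Sigma)` and
#' accumulates the conditional covariance correction; the M-step updates
#' `(mu, Sigma)`.  Iteration stops when the maximum absolute change in the
#' parameters falls below `tol` or at `max_iter` (an error carrying the last
#' delta).  The observed-data log-likelihood is checked to be non-decreasing
#' at every iteration.  Observed cells are returned bit-for-bit unchanged.
#'
#' @param x Either an `env_normalized` object or a numeric matrix (samples x
#'   variables) with NAs; each variable needs >= 3 observed values and each
#'   sample >= 1.
#' @param tol Convergence threshold on the max parameter delta (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A list of class `"env_imputed"`: `x` (complete matrix on the input
#'   scale), `x_original_scale` (back-transformed when a transform record is
#'   available), `imputation_mask` (TRUE where imputed), `mu`, `sigma`,
#'   `n_iter`, `loglik` (per-iteration trace), `transform_record`.
#' @export
em_impute <- function(x, tol = 1e-6, max_iter = 500) {
  rec <- NULL
  if (inherits(x, "env_normalized")) {
    rec <- x$transform_record
    X <- x$x
  } else {
    X <- as.matrix(x)
  }
  p <- ncol(X)
  if (any(colSums(!is.na(X)) < 3)) abort("each variable needs >= 3 observed values")
  if (any(rowSums(!is.na(X)) < 1)) abort("each sample needs >= 1 observed variable")
  mask <- is.na(X)

  mu <- colMeans(X, na.rm = TRUE)
  Sigma <- cov(X, use = "pairwise.complete.obs")
  Sigma[is.na(Sigma)] <- 0
  diag(Sigma)[diag(Sigma) <= 0] <- 1
  Sigma <- ridge_pd(Sigma)

  ll_trace <- numeric(0)
  n <- nrow(X)
  Xc <- X
  iter <- 0
  repeat {
    iter <- iter + 1
    # E-step
    Cc <- matrix(0, p, p)       # accumulated conditional covariance
    for (i in seq_len(n)) {
      m <- which(mask[i, ])
      if (length(m) == 0) next
      o <- which(!mask[i, ])
      Soo_inv <- solve(Sigma[o, o, drop = FALSE])
      B <- Sigma[m, o, drop = FALSE] %*% Soo_inv
      Xc[i, m] <- mu[m] + B %*% (X[i, o] - mu[o])
      Cc[m, m] <- Cc[m, m] + Sigma[m, m, drop = FALSE] -
        B %*% Sigma[o, m, drop = FALSE]
    }
    # M-step
    mu_new <- colMeans(Xc)
    Xd <- sweep(Xc, 2, mu_new)
    Sigma_new <- (crossprod(Xd) + Cc) / n
    Sigma_new <- ridge_pd(Sigma_new)

    ll <- mvn_obs_loglik(X, mu_new, Sigma_new)
    if (length(ll_trace) > 0 && ll < tail(ll_trace, 1) - 1e-6) {
      warn(sprintf("EM log-likelihood decreased at iteration %d", iter))
    }
    ll_trace <- c(ll_trace, ll)

    delta <- max(abs(mu_new - mu), abs(Sigma_new - Sigma))
    mu <- mu_new
    Sigma <- Sigma_new
    if (!any(mask)) break                       # complete data: single pass
    if (delta < tol) break
    if (iter >= max_iter) {
      abort(sprintf("EM did not converge in %d iterations (last delta %.3g)",
                    max_iter, delta))
    }
  }
  stopifnot(identical(Xc[!mask], X[!mask]))     # observed cells untouched
  orig <- if (!is.null(rec)) denormalize_env(Xc, rec) else NULL
  structure(list(x = Xc, x_original_scale = orig, imputation_mask = mask,
                 mu = mu, sigma = Sigma, n_iter = iter, loglik = ll_trace,
                 transform_record = rec),
            class = "env_imputed")
}

# add a tiny ridge if a covariance update loses positive-definiteness
ridge_pd <- function(S, eps = 1e-8) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) S <- S + diag(eps - min(ev), ncol(S))
  S
}

#' PCA of environmental variables on the correlation matrix
#'
#' Eigen-decomposition of the Pearson correlation matrix of a complete
#' environmental matrix.  Components are ordered by decreasing eigenvalue;
#' each loading column is sign-oriented so the variable with the largest
#' absolute loading has a positive loading (a deterministic convention, since
#' eigenvectors are sign-ambiguous).  Scores are the standardized data
#' projected on the loadings and then re-standardized to unit variance, i.e.
#' per-component z-scores, ready for use as PERMANCOVA covariates.
#'
#' @param x An `env_imputed` object or a complete numeric matrix (samples x
#'   variables, >= 2 variables).
#' @return An object of class `"env_pca"` with elements `loadings`
#'   (variables x components), `eigenvalues`, `pct_variance`, `scores`
#'   (samples x components z-scores).  `tidy()` returns the loadings in long
#'   form; `glance()` the variance decomposition; `autoplot()` a score plot.
#' @export
pca_correlation <- function(x) {
  X <- if (inherits(x, "env_imputed")) x$x else as.matrix(x)
  if (anyNA(X)) abort("pca_correlation requires a complete matrix; impute first")
  if (ncol(X) < 2) abort("need at least 2 variables")
  R <- cor(X)
  ee <- eigen(R, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  V <- ee$vectors
  dimnames(V) <- list(colnames(X), sprintf("PC%d", seq_len(ncol(V))))
  # deterministic sign: largest-|loading| variable positive in each column
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Z <- scale(X)
  scores <- Z %*% V
  score_sd <- apply(scores, 2, sd)
  score_sd[score_sd == 0] <- 1
  scores <- sweep(scores, 2, score_sd, `/`)
  structure(list(loadings = V, eigenvalues = lam,
                 pct_variance = 100 * lam / sum(lam),
                 scores = scores, n = nrow(X)),
            class = "env_pca")
}

#' @method tidy env_pca
#' @export
tidy.env_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") %>%
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @method glance env_pca
#' @export
glance.env_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 eigenvalue = x$eigenvalues,
                 pct_variance = x$pct_variance,
                 cum_pct_variance = cumsum(x$pct_variance))
}

#' Extract PC z-scores as a covariate tibble
#'
#' @param pca An `env_pca` object.
#' @param components Which components to keep (default PC1 and PC2, the
#'   covariates used in the PERMANCOVA stage).
#' @return Tibble `sample_id` + one column per component.
#' @export
pc_scores <- function(pca, components = c("PC1", "PC2")) {
  stopifnot(inherits(pca, "env_pca"))
  tibble::as_tibble(pca$scores[, components, drop = FALSE],
                    rownames = "sample_id")
}
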