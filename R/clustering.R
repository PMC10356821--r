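# Sample clustering on highly-variable-gene (or taxa) abundances: Johnson
# normalization, k-means with k-means++ seeding and elbow-based k selection,
# environmental characterization of clusters by ANOVA/Tukey, and Cohen's
# kappa agreement between two clusterings.

#' Johnson transformation toward normality
#'
#' Fits the Johnson S_U / S_B / S_L families by the percentile method over a
#' small grid of selection constants `z`, transforms with each valid fit,
#' and keeps the candidate whose transformed data maximize the Shapiro-Wilk
#' W.  With fewer than 20 observations, or when no family fit is valid, a
#' rank-based inverse-normal transform (Blom scores) is used instead and
#' recorded as the fallback.
#'
#' @param x Numeric vector (non-constant).
#' @return List of class `"johnson_fit"`: `y` (transformed values),
#'   `family` (`"SU"`, `"SB"`, `"SL"`, `"identity"` or `"rank_normal"`),
#'   `params` (gamma, delta, xi, lambda, z), `shapiro_w`.  Parametric fits
#'   are exactly invertible with [johnson_inverse()].  The affine
#'   standardization (`"identity"`) is always a candidate, so the chosen
#'   transform never has a lower Shapiro-Wilk W than the input
#'   (location-scale changes leave W untouched).
#' @export
johnson_transform <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2) abort("constant vector")
  x <- as.numeric(x)
  mu <- mean(x, na.rm = TRUE)
  sdv <- sd(x, na.rm = TRUE)
  y0 <- (x - mu) / sdv
  w0 <- suppressWarnings(tryCatch(
    shapiro.test(sample_for_shapiro(y0))$statistic, error = function(e) NA_real_))
  best <- if (is.finite(w0)) {
    list(y = y0, family = "identity",
         params = list(gamma = -mu / sdv, delta = 1 / sdv, xi = 0, lambda = 1),
         shapiro_w = unname(w0))
  }
  if (sum(!is.na(x)) >= 20) {
    cands <- list()
    for (z in c(0.25, 0.39, 0.524, 0.75, 1.0)) {
      for (fam in c("SU", "SB", "SL")) {
        cands[[length(cands) + 1]] <- try_johnson_fit(x, z, fam)
      }
    }
    cands[[length(cands) + 1]] <- fit_sl_profile(x)
    for (fit in cands) {
      if (is.null(fit)) next
      w <- suppressWarnings(tryCatch(
        shapiro.test(sample_for_shapiro(fit$y))$statistic,
        error = function(e) NA_real_))
      if (is.finite(w) && (is.null(best) || w > best$shapiro_w)) {
        best <- c(fit, list(shapiro_w = unname(w)))
      }
    }
  }
  if (is.null(best)) {
    r <- rank(x, na.last = "keep")
    n <- sum(!is.na(x))
    y <- qnorm((r - 0.375) / (n + 0.25))
    w <- suppressWarnings(tryCatch(
      shapiro.test(sample_for_shapiro(y))$statistic, error = function(e) NA_real_))
    best <- list(y = y, family = "rank_normal", params = NULL,
                 shapiro_w = unname(w))
  }
  structure(best, class = "johnson_fit")
}

# shapiro.test caps n at 5000
sample_for_shapiro <- function(y) {
  y <- y[is.finite(y)]
  if (length(y) > 5000) y[seq(1, length(y), length.out = 5000)] else y
}

# percentile-method fit (Slifker & Shapiro) at selection constant z;
# invalid-domain NaNs just mean the family does not fit at this z
try_johnson_fit <- function(x, z, family) suppressWarnings(
  try_johnson_fit_(x, z, family))

try_johnson_fit_ <- function(x, z, family) {
  q <- quantile(x, pnorm(c(-3, -1, 1, 3) * z), na.rm = TRUE, names = FALSE,
                type = 8)
  x3z <- q[4]; xz <- q[3]; xmz <- q[2]; xm3z <- q[1]
  m <- x3z - xz; nn <- xmz - xm3z; p <- xz - xmz
  if (p <= 0 || m <= 0 || nn <= 0) return(NULL)
  tol <- 1e-8
  fit <- switch(family,
    SU = {
      ratio <- m * nn / p^2
      if (ratio <= 1 + tol) return(NULL)
      mp <- m / p; np <- nn / p
      delta <- 2 * z / acosh(0.5 * (mp + np))
      gamma <- delta * asinh((np - mp) / (2 * sqrt(mp * np - 1)))
      lambda <- 2 * p * sqrt(mp * np - 1) /
        ((mp + np - 2) * sqrt(mp + np + 2))
      xi <- (xz + xmz) / 2 + p * (np - mp) / (2 * (mp + np - 2))
      list(gamma = gamma, delta = delta, xi = xi, lambda = lambda)
    },
    SB = {
      pm <- p / m; pn <- p / nn
      if (pm * pn >= 1 - tol) return(NULL)
      delta <- z / acosh(0.5 * sqrt((1 + pm) * (1 + pn)))
      gamma <- delta * asinh((pn - pm) * sqrt((1 + pm) * (1 + pn) - 4) /
                               (2 * (pm * pn - 1)))
      lambda <- p * sqrt(((1 + pm) * (1 + pn) - 2)^2 - 4) / (1 - pm * pn)
      xi <- (xz + xmz) / 2 - lambda / 2 + p * (pn - pm) / (2 * (1 - pm * pn))
      list(gamma = gamma, delta = delta, xi = xi, lambda = lambda)
    },
    SL = {
      if (m / p <= 1 + tol) return(NULL)
      delta <- 2 * z / log(m / p)
      ratio <- m / p
      xi <- (xz + xmz) / 2 - p / 2 * (ratio + 1) / (ratio - 1)
      gamma <- -delta * log((xz - xi))
      list(gamma = gamma, delta = delta, xi = xi, lambda = 1)
    })
  if (any(!is.finite(unlist(fit))) || fit$delta <= 0) return(NULL)
  y <- johnson_forward(x, family, fit)
  if (any(!is.finite(y[!is.na(x)]))) return(NULL)
  list(y = y, family = family, params = c(fit, list(z = z)))
}

# S_L fit with the threshold xi chosen to maximize Shapiro W of log(x - xi);
# gamma/delta then standardize exactly (W is affine-invariant)
fit_sl_profile <- function(x) {
  obs <- x[is.na(x) == FALSE]
  lo <- min(obs)
  span <- diff(range(obs))
  if (span <= 0) return(NULL)
  wfun <- function(xi) {
    y <- log(obs - xi)
    suppressWarnings(tryCatch(shapiro.test(sample_for_shapiro(y))$statistic,
                              error = function(e) -Inf))
  }
  opt <- tryCatch(optimize(wfun, c(lo - 5 * span, lo - 1e-9 * span),
                           maximum = TRUE),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) return(NULL)
  xi <- opt$maximum
  y <- log(x - xi)
  mu <- mean(y, na.rm = TRUE)
  sdy <- sd(y, na.rm = TRUE)
  if (!is.finite(sdy) || sdy == 0) return(NULL)
  delta <- 1 / sdy
  gamma <- -mu / sdy
  list(y = gamma + delta * log(x - xi), family = "SL",
       params = list(gamma = gamma, delta = delta, xi = xi, lambda = 1,
                     z = NA_real_))
}

johnson_forward <- function(x, family, pr) {
  u <- (x - pr$xi) / pr$lambda
  switch(family,
    SU = pr$gamma + pr$delta * asinh(u),
    SB = pr$gamma + pr$delta * log(u / (1 - u)),
    SL = pr$gamma + pr$delta * log(x - pr$xi))
}

#' Invert a parametric Johnson transform
#'
#' @param y Values on the transformed (normal) scale.
#' @param fit A `johnson_fit` with a parametric family (not the rank-based
#'   fallback, which has no closed-form inverse).
#' @return Values on the original scale.
#' @export
johnson_inverse <- function(y, fit) {
  if (fit$family == "rank_normal") {
    abort("rank-based fallback transform has no parametric inverse")
  }
  pr <- fit$params
  w <- (y - pr$gamma) / pr$delta
  switch(fit$family,
    identity = w,
    SU = pr$xi + pr$lambda * sinh(w),
    SB = pr$xi + pr$lambda / (1 + exp(-w)),
    SL = pr$xi + exp(w))
}

# k-means++ seeding
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - X[rep(centers[1], n), , drop = FALSE])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = prob)
    }
    d2 <- pmin(d2, rowSums((X - X[rep(centers[j], n), , drop = FALSE])^2))
  }
  X[centers, , drop = FALSE] + 1e-10 * matrix(rnorm(k * ncol(X)), k)
}

#' k-means clustering with elbow-based selection of k
#'
#' For each `k` in `k_range`, runs `restarts` k-means++ seeded Lloyd
#' clusterings and keeps the best total within-cluster sum of squares.  The
#' chosen `k` maximizes the second difference of the within-SS curve (the
#' elbow); when the strongest elbow is weak relative to the total drop of
#' the curve a warning is emitted.  Features are expected already normalized
#' (e.g. Johnson-transformed); with `standardize = TRUE` (default) they are
#' additionally scaled by the pooled within-cluster SD from a pilot k-means
#' at the midpoint of `k_range` (a two-pass scheme approximating JMP's
#' "within cluster standard deviations" option).  Clusters with four or
#' fewer samples are flagged for removal from downstream ANOVA.
#'
#' @param x Samples x features data frame (`sample_id` first column) or
#'   numeric matrix with rownames.
#' @param k_range Candidate k values (default 2:8).
#' @param restarts k-means++ restarts per k (default 50).
#' @param seed Integer seed.
#' @param standardize Apply the pooled within-cluster SD standardization.
#' @return Object of class `"cluster_result"`: `assignments` (tibble
#'   `sample_id`, `cluster`, `retained`), `k`, `elbow` (tibble `k`,
#'   `within_ss`, `second_difference`), `within_ss`, `retained_clusters`,
#'   `standardization` (per-feature divisor).  `tidy()` returns the
#'   assignments; `autoplot()` the elbow curve.
#' @export
kmeans_elbow <- function(x, k_range = 2:8, restarts = 50, seed = 1L,
                         standardize = TRUE) {
  X <- if (is.data.frame(x)) counts_to_matrix(x) else as.matrix(x)
  if (max(k_range) >= nrow(X)) abort("k_max must be below the number of samples")
  scl <- rep(1, ncol(X))
  fits <- with_seed(seed, {
    if (standardize) {
      k_mid <- round(median(k_range))
      pilot <- best_kmeans(X, k_mid, restarts = max(10, restarts %/% 5))
      scl <- pooled_within_sd(X, pilot$cluster)
      scl[scl <= 1e-12] <- 1
      X <- sweep(X, 2, scl, `/`)
    }
    lapply(k_range, function(k) best_kmeans(X, k, restarts))
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  if (any(diff(wss) > 1e-8)) {
    warn("within-SS curve not monotone non-increasing in k (local optima)")
  }
  d2 <- rep(NA_real_, length(k_range))
  if (length(k_range) >= 3) {
    inner <- 2:(length(k_range) - 1)
    d2[inner] <- wss[inner - 1] - 2 * wss[inner] + wss[inner + 1]
  }
  if (all(is.na(d2))) {
    pick <- 1L
  } else {
    pick <- which.max(d2)
  }
  total_drop <- max(wss) - min(wss)
  curvature <- if (is.na(d2[pick])) 0 else d2[pick]
  if (total_drop <= 0 || curvature < 0.4 * total_drop) {
    warn(sprintf("no pronounced elbow (curvature %.3g vs curve drop %.3g); chosen k = %d",
                 curvature, total_drop, k_range[pick]))
  }
  k <- k_range[pick]
  fit <- fits[[pick]]
  sizes <- table(fit$cluster)
  retained <- names(sizes)[sizes > 4]
  assignments <- tibble::tibble(sample_id = rownames(X),
                                cluster = as.character(fit$cluster),
                                retained = as.character(fit$cluster) %in% retained)
  structure(list(assignments = assignments, k = k,
                 elbow = tibble::tibble(k = k_range, within_ss = wss,
                                        second_difference = d2),
                 within_ss = fit$tot.withinss,
                 retained_clusters = retained,
                 standardization = scl, seed = seed),
            class = "cluster_result")
}

best_kmeans <- function(X, k, restarts) {
  best <- NULL
  for (r in seq_len(restarts)) {
    ctrs <- kmeanspp_centers(X, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(X, centers = ctrs, iter.max = 100,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed for every restart")
  best
}

pooled_within_sd <- function(X, cluster) {
  vapply(seq_len(ncol(X)), function(j) {
    ssw <- sum(tapply(X[, j], cluster, function(v) sum((v - mean(v))^2)))
    dfw <- nrow(X) - length(unique(cluster))
    sqrt(ssw / max(dfw, 1))
  }, numeric(1))
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$assignments

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(k = x$k, within_ss = x$within_ss,
                 n_retained_clusters = length(x$retained_clusters))
}

#' One-way ANOVA of an environmental variable across clusters
#'
#' Residual normality is checked with Shapiro-Wilk; when rejected at 0.05
#' the variable is Johnson-transformed and the model refit.  Reports F, p,
#' `R^2 = SS_between / SS_total`, and, when the ANOVA is significant at
#' 0.05, Tukey-Kramer HSD pairwise comparisons (valid for unequal group
#' sizes) at family level 0.05.  Only retained clusters (> 4 samples) enter;
#' a cluster with fewer than 2 observed values for the variable is dropped
#' from this variable's ANOVA.
#'
#' @param assignments Tibble from `tidy(cluster_result)` (columns
#'   `sample_id`, `cluster`, optionally `retained`), or any data frame with
#'   sample-to-group labels in a `cluster` column.
#' @param meta Metadata tibble.
#' @param variable Name of the environmental variable.
#' @param normalize_if_needed Apply the Johnson normalization step when
#'   residuals fail Shapiro-Wilk (default TRUE; FALSE tests on the
#'   measurement scale).
#' @return Object of class `"anova_summary"` (one-row tibble with `variable`,
#'   `f`, `df_between`, `df_within`, `p`, `r_squared`, `shapiro_w_p`,
#'   `normalized`, and attribute `"tukey"` with the pairwise table).
#' @export
cluster_anova <- function(assignments, meta, variable,
                          normalize_if_needed = TRUE) {
  df <- as.data.frame(assignments)
  if ("retained" %in% names(df)) df <- df[df$retained, , drop = FALSE]
  all_clusters <- unique(df$cluster)
  df$value <- meta[[variable]][match(df$sample_id, meta$sample_id)]
  df <- df[!is.na(df$value), , drop = FALSE]
  ok_clusters <- names(which(table(df$cluster) >= 2))
  dropped <- setdiff(all_clusters, ok_clusters)
  if (length(dropped) > 0) {
    inform(sprintf("cluster(s) dropped for '%s' (<2 observed values): %s",
                   variable, paste(dropped, collapse = ", ")))
  }
  df <- df[df$cluster %in% ok_clusters, , drop = FALSE]
  if (length(ok_clusters) < 2) abort("need at least 2 clusters with data")
  anova_one_way(df$value, factor(df$cluster), variable,
                normalize_if_needed = normalize_if_needed)
}

# shared one-way ANOVA machinery (cluster and age-class characterizations)
anova_one_way <- function(value, group, variable, normalize_if_needed = TRUE) {
  fit <- aov(value ~ group)
  res <- stats::residuals(fit)
  sw <- tryCatch(shapiro.test(sample_for_shapiro(res))$p.value,
                 error = function(e) NA_real_)
  normalized <- FALSE
  if (normalize_if_needed && is.finite(sw) && sw < 0.05 &&
      length(unique(value)) > 2) {
    jt <- tryCatch(johnson_transform(value), error = function(e) NULL)
    if (!is.null(jt)) {
      value <- jt$y
      fit <- aov(value ~ group)
      res <- stats::residuals(fit)
      sw <- tryCatch(shapiro.test(sample_for_shapiro(res))$p.value,
                     error = function(e) sw)
      normalized <- TRUE
    }
  }
  an <- suppressWarnings(anova(fit))   # perfect separation is guarded below
  ssb <- an[["Sum Sq"]][1]
  ssw <- an[["Sum Sq"]][2]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (ssw == 0) {                       # perfect separation guard
    f <- Inf
    p <- 1e-15
  }
  r2 <- ssb / (ssb + ssw)
  tukey <- NULL
  if (is.finite(p) && p < 0.05 || ssw == 0) {
    tk <- tryCatch(TukeyHSD(fit, conf.level = 0.95)$group, error = function(e) NULL)
    if (!is.null(tk)) {
      tukey <- tibble::as_tibble(tk, rownames = "pair") %>%
        rename(mean_difference = "diff", adjusted_p = "p adj") %>%
        mutate(significant = .data$adjusted_p < 0.05) %>%
        select("pair", "mean_difference", "adjusted_p", "significant")
    }
  }
  out <- tibble::tibble(variable = variable, f = f,
                        df_between = an$Df[1], df_within = an$Df[2],
                        p = p, r_squared = r2, shapiro_w_p = sw,
                        normalized = normalized)
  attr(out, "tukey") <- tukey
  class(out) <- c("anova_summary", class(out))
  out
}

#' One-way ANOVA of a variable by age class
#'
#' Contrasts Holocene vs Pleistocene samples for one biophysical variable,
#' with the same Shapiro/normalization/Tukey machinery as [cluster_anova()].
#'
#' @param meta Metadata with `age_class`.
#' @param variable Variable name.
#' @param normalize_if_needed Apply the Johnson normalization step when
#'   residuals fail Shapiro-Wilk (default TRUE; set FALSE to test on the
#'   measurement scale).
#' @return An `anova_summary` tibble.
#' @export
age_class_anova <- function(meta, variable, normalize_if_needed = TRUE) {
  df <- data.frame(value = meta[[variable]], group = meta$age_class)
  df <- df[!is.na(df$value) & !is.na(df$group), ]
  if (length(unique(df$group)) < 2) abort("need both age classes present")
  anova_one_way(df$value, factor(df$group), variable,
                normalize_if_needed = normalize_if_needed)
}

#' Cohen's kappa agreement between two clusterings
#'
#' Builds the contingency table of the two labelings, aligns cluster labels
#' by the one-to-one matching that maximizes the diagonal sum (labels are
#' arbitrary, so alignment is required before agreement can be measured),
#' computes Cohen's kappa `(p_o - p_e) / (1 - p_e)` on the aligned table,
#' and obtains a permutation p-value by reshuffling one labeling.
#'
#' @param labels_a,labels_b Named vectors (names = sample ids) or vectors in
#'   matching sample order; the two labelings must cover the same samples.
#' @param B Number of label permutations for the p-value (default 9999).
#' @param seed Integer seed.
#' @return Object of class `"agreement_result"`: `kappa`,
#'   `observed_agreement`, `expected_agreement`, `permutation_p`,
#'   `contingency` (aligned square table).
#' @export
kappa_agreement <- function(labels_a, labels_b, B = 9999, seed = 1L) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      abort("the two labelings cover different sample sets")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    abort("the two labelings cover different sample sets")
  }
  kap <- aligned_kappa(labels_a, labels_b)
  perm <- with_seed(seed,
    replicate(B, aligned_kappa(labels_a, sample(labels_b))$kappa))
  if (B == 0) perm <- numeric(0)
  p <- (1 + sum(perm >= kap$kappa)) / (B + 1)
  structure(list(kappa = kap$kappa, observed_agreement = kap$po,
                 expected_agreement = kap$pe, permutation_p = p,
                 contingency = kap$table, n_permutations = B),
            class = "agreement_result")
}

aligned_kappa <- function(a, b) {
  tab <- table(a, b)
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  # align columns to rows by the permutation maximizing the diagonal;
  # exhaustive for small k, greedy otherwise
  if (k <= 7) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) sum(sq[cbind(seq_len(k), p)]), numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k)
    used <- rep(FALSE, k)
    for (i in order(-apply(sq, 1, max))) {
      j <- order(-sq[i, ])
      j <- j[!used[j]][1]
      best[i] <- j
      used[j] <- TRUE
    }
  }
  al <- sq[, best, drop = FALSE]
  n <- sum(al)
  po <- sum(diag(al)) / n
  pe <- sum(rowSums(al) * colSums(al)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, po = po, pe = pe, table = al)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, observed_agreement = x$observed_agreement,
                 expected_agreement = x$expected_agreement,
                 permutation_p = x$permutation_p)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (observed %.3f, expected %.3f), permutation p = %.4g\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$permutation_p))
  invisible(x)
}
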