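# Bray-Curtis dissimilarity construction and permutational ANOVA/ANCOVA for
# a 3-factor nested mixed design (continent fixed; region within continent
# and site within region random) with continuous covariates such as
# environmental PC z-scores or latitude polynomial contrasts.

#' Abundance filter on a count table
#'
#' Keeps feature `g` iff the number of samples with `count(g) > min_count` is
#' at least `ceiling(min_fraction * n_samples)`: strictly "more than"
#' `min_count` on counts, "at least" on the sample fraction.
#'
#' @param counts Count tibble (`sample_id` + features).
#' @param min_count Count a sample must strictly exceed (default 10).
#' @param min_fraction Minimum fraction of samples (default 0.10).
#' @return Filtered count tibble; attribute `"filter_report"` records feature
#'   counts in and out.
#' @export
abundance_filter <- function(counts, min_count = 10, min_fraction = 0.10) {
  m <- counts_to_matrix(counts)
  need <- ceiling(min_fraction * nrow(m))
  keep <- colSums(m > min_count) >= need
  if (!any(keep)) abort("abundance filter removed every feature")
  out <- counts[, c(TRUE, keep), drop = FALSE]
  attr(out, "filter_report") <- tibble::tibble(
    n_features_in = ncol(m), n_features_out = sum(keep),
    min_count = min_count, min_fraction = min_fraction)
  out
}

#' Abundance filter for the highly-variable-gene stage
#'
#' The HVG stage uses a stricter filter: genes observed more than 100 times
#' in at least 10% of samples are retained.
#'
#' @inheritParams abundance_filter
#' @export
hvg_filter <- function(counts) abundance_filter(counts, min_count = 100,
                                                min_fraction = 0.10)

#' Bray-Curtis dissimilarities of square-root relative abundances
#'
#' Counts are converted to per-sample relative abundances, square-root
#' transformed, and the Bray-Curtis dissimilarity
#' `d(i,j) = sum |x_i - x_j| / sum (x_i + x_j)` is computed on the
#' transformed values.
#'
#' @param counts Count tibble; rows with all-zero counts are an error naming
#'   the sample.
#' @param transform `"sqrt_relabund"` (default: relative abundance then
#'   square root) or `"none"` (use values as given).
#' @return A list of class `"bc_dist"`: `sample_ids` and the symmetric
#'   dissimilarity matrix `d` with zero diagonal and entries in \[0, 1\].
#' @export
bray_curtis <- function(counts, transform = c("sqrt_relabund", "none")) {
  transform <- match.arg(transform)
  m <- counts_to_matrix(counts)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(rownames(m)[rs == 0], collapse = ", ")))
  }
  if (transform == "sqrt_relabund") m <- sqrt(m / rs)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  structure(list(sample_ids = rownames(m), d = d), class = "bc_dist")
}

#' Orthogonal polynomial contrasts
#'
#' Columns span the same space as `(x, x^2, ..., x^degree)`, are orthonormal
#' and orthogonal to the intercept — the classical a-priori contrasts used to
#' test linear, quadratic and cubic trends.
#'
#' @param x Numeric vector with at least `degree + 1` distinct values.
#' @param degree Polynomial degree, 1 to 3.
#' @return Matrix with `degree` columns named `linear`, `quadratic`, `cubic`.
#' @export
orthogonal_polynomials <- function(x, degree = 3) {
  stopifnot(degree >= 1, degree <= 3)
  if (length(unique(x)) < degree + 1) {
    abort(sprintf("need at least %d distinct values for degree %d",
                  degree + 1, degree))
  }
  P <- stats::poly(x, degree = degree)
  colnames(P) <- c("linear", "quadratic", "cubic")[seq_len(degree)]
  unclass(P)[, , drop = FALSE]
}

# --- internal machinery -----------------------------------------------------

# Gower-centered inner-product matrix from a dissimilarity matrix:
# G = -1/2 C D^2 C, whose trace is the total sum of squares.
gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

# trace(H G) where H projects onto the column space of Q (orthonormal)
trace_hg <- function(Q, G) if (is.null(Q)) 0 else sum(Q * (G %*% Q))

# orthonormal basis of the column space of M
ortho_basis <- function(M) {
  qrm <- qr(M)
  r <- qrm$rank
  if (r == 0) return(NULL)
  qr.Q(qrm)[, seq_len(r), drop = FALSE]
}

# restricted permutation of sample indices
perm_indices <- function(scheme, design) {
  n <- nrow(design)
  switch(scheme,
    free = sample.int(n),
    within_region = {
      idx <- seq_len(n)
      for (r in unique(design$region)) {
        pos <- which(design$region == r)
        idx[pos] <- pos[sample.int(length(pos))]
      }
      idx
    },
    sites_within_continent = {
      idx <- seq_len(n)
      for (cc in unique(design$continent)) {
        pos <- which(design$continent == cc)
        blocks <- split(pos, design$site[pos])
        idx[pos] <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
      }
      idx
    },
    within_continent = {
      idx <- seq_len(n)
      for (cc in unique(design$continent)) {
        pos <- which(design$continent == cc)
        idx[pos] <- pos[sample.int(length(pos))]
      }
      idx
    },
    region_blocks = {
      blocks <- split(seq_len(n), design$region)
      unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
    },
    abort(sprintf("unknown permutation scheme '%s'", scheme)))
}

#' Nested mixed-model PERMANCOVA on a dissimilarity matrix
#'
#' Partitions a (Bray-Curtis) dissimilarity matrix by sequential (Type-I)
#' sums of squares over the ordered terms *covariates, continent,
#' region(continent), site(region), covariate x site(region)* via projection
#' matrices applied to the Gower-centered inner-product matrix
#' `G = -1/2 C D^2 C`.  Pseudo-F ratios follow the expected-mean-square rules
#' for a fixed factor above nested random factors: continent is tested over
#' the region mean square, region over the site mean square, and site,
#' covariates and interactions over the residual.  P-values come from
#' permutation of residuals under the reduced model, permuting at the
#' exchangeable-unit level of each term (samples freely for covariates;
#' samples within regions for site-level terms; whole sites within continents
#' for the region term; whole regions for the continent term).
#'
#' @param d A `bc_dist` object or a symmetric dissimilarity matrix with
#'   sample ids as dimnames.
#' @param design Data frame with `sample_id` and any of `continent`,
#'   `region`, `site` (region nested in continent, site in region).
#' @param covariates Optional data frame (`sample_id` + numeric columns) or
#'   numeric matrix of covariate values aligned to `d`, e.g. PC z-scores from
#'   [pc_scores()] or contrasts from [orthogonal_polynomials()].
#' @param include_interaction Add the covariate x site(region) interaction
#'   term (default TRUE when covariates and a site factor are both present).
#' @param B Number of permutations (default 999).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `"permancova"`; `tidy()` gives the table with
#'   columns `term`, `df`, `ss`, `ms`, `pseudo_f`, `p_perm`,
#'   `pct_variation` (= 100 SS / total SS), `denominator`.
#' @export
permancova <- function(d, design, covariates = NULL,
                       include_interaction = !is.null(covariates),
                       B = 999, seed = 1L) {
  if (inherits(d, "bc_dist")) {
    ids <- d$sample_ids
    D <- d$d
  } else {
    D <- as.matrix(d)
    ids <- rownames(D)
  }
  design <- as.data.frame(design)
  stopifnot(!is.null(ids), all(ids %in% design$sample_id))
  design <- design[match(ids, design$sample_id), , drop = FALSE]
  n <- length(ids)

  cov_mat <- NULL
  if (!is.null(covariates)) {
    if (is.data.frame(covariates)) {
      stopifnot("sample_id" %in% names(covariates))
      cov_mat <- as.matrix(covariates[match(ids, covariates$sample_id),
                                      setdiff(names(covariates), "sample_id"),
                                      drop = FALSE])
    } else {
      cov_mat <- as.matrix(covariates)
    }
    if (anyNA(cov_mat)) abort("covariates must be complete (impute first)")
  }

  # term model matrices, in sequential order
  terms <- list()
  schemes <- character()
  den_pref <- list()
  if (!is.null(cov_mat)) {
    terms[[length(terms) + 1]] <- list(name = "covariate", M = cov_mat)
    schemes <- c(schemes, "free")
    den_pref[["covariate"]] <- "Residual"
  }
  has <- function(v) v %in% names(design) && length(unique(design[[v]])) > 1
  if (has("continent")) {
    terms[[length(terms) + 1]] <- list(
      name = "continent", M = model.matrix(~ factor(design$continent))[, -1, drop = FALSE])
    schemes <- c(schemes, if (has("region")) "region_blocks" else "free")
    den_pref[["continent"]] <- c("region(continent)", "site(region)", "Residual")
  }
  if (has("region")) {
    terms[[length(terms) + 1]] <- list(
      name = "region(continent)", M = model.matrix(~ factor(design$region))[, -1, drop = FALSE])
    schemes <- c(schemes,
                 if (has("site")) "sites_within_continent" else "within_continent")
    den_pref[["region(continent)"]] <- c("site(region)", "Residual")
  }
  if (has("site")) {
    terms[[length(terms) + 1]] <- list(
      name = "site(region)", M = model.matrix(~ factor(design$site))[, -1, drop = FALSE])
    schemes <- c(schemes, "within_region")
    den_pref[["site(region)"]] <- "Residual"
  }
  if (!is.null(cov_mat) && include_interaction && has("site")) {
    S <- model.matrix(~ factor(design$site))[, , drop = FALSE]
    Mint <- do.call(cbind, lapply(seq_len(ncol(cov_mat)),
                                  function(j) S * cov_mat[, j]))
    terms[[length(terms) + 1]] <- list(name = "covariate:site(region)", M = Mint)
    schemes <- c(schemes, "within_region")
    den_pref[["covariate:site(region)"]] <- "Residual"
  }
  if (length(terms) == 0) abort("design yields no testable terms")

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # cumulative orthonormal bases and sequential traces
  Mcum <- matrix(1, n, 1)
  Qs <- vector("list", length(terms))
  tr_prev <- trace_hg(ortho_basis(Mcum), G)   # intercept removes nothing (G centered)
  ss <- df <- numeric(length(terms))
  rank_prev <- 1
  for (k in seq_along(terms)) {
    Mcum <- cbind(Mcum, terms[[k]]$M)
    Q <- ortho_basis(Mcum)
    Qs[[k]] <- Q
    tr_k <- trace_hg(Q, G)
    ss[k] <- tr_k - tr_prev
    df[k] <- ncol(Q) - rank_prev
    rank_prev <- ncol(Q)
    tr_prev <- tr_k
  }
  names(ss) <- names(df) <- vapply(terms, `[[`, "", "name")

  dropped <- names(df)[df == 0]
  if (length(dropped) > 0) {
    inform(sprintf("term(s) with 0 df dropped: %s", paste(dropped, collapse = ", ")))
  }
  keep <- df > 0
  df_res <- n - rank_prev
  ss_res <- ss_total - sum(ss)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_

  denom_of <- function(nm) {
    for (cand in den_pref[[nm]]) {
      if (cand == "Residual" && df_res > 0) return("Residual")
      if (cand %in% names(df) && isTRUE(df[cand] > 0)) return(cand)
    }
    "Residual"
  }
  denoms <- vapply(names(df), denom_of, "")
  ms_of <- function(nm, ms_vec, msr) if (nm == "Residual") msr else ms_vec[nm]
  f_obs <- vapply(names(df), function(nm) {
    dn <- ms_of(denoms[nm], ms, ms_res)
    if (!is.finite(dn) || dn == 0) Inf else ms[nm] / dn
  }, numeric(1))

  # permutation p-values: residuals under the reduced model per term
  p_perm <- rep(NA_real_, length(terms))
  names(p_perm) <- names(df)
  Q1 <- ortho_basis(matrix(1, n, 1))
  with_seed(seed, for (k in seq_along(terms)) {
    if (!keep[k]) next
    nm <- names(df)[k]
    Q_red <- if (k == 1) Q1 else Qs[[k - 1]]
    R <- diag(n) - tcrossprod(Q_red)
    Gr <- R %*% G %*% R
    exceed <- 0
    for (b in seq_len(B)) {
      pi_ <- perm_indices(schemes[k], design)
      Gp <- Gr[pi_, pi_]
      trp <- vapply(Qs, trace_hg, numeric(1), G = Gp)
      ssp <- diff(c(trace_hg(Q1, Gp), trp))
      names(ssp) <- names(df)
      ssp_res <- sum(diag(Gp)) - trp[length(trp)]
      msp <- ifelse(df > 0, ssp / df, NA_real_)
      msp_res <- if (df_res > 0) ssp_res / df_res else NA_real_
      dnp <- ms_of(denoms[nm], msp, msp_res)
      fp <- if (!is.finite(dnp) || dnp <= 0) Inf else msp[nm] / dnp
      if (fp >= f_obs[nm] - 1e-12) exceed <- exceed + 1
    }
    p_perm[k] <- (1 + exceed) / (B + 1)
  })

  ss_col <- unname(c(ss[keep], ss_res, ss_total))
  tab <- tibble::tibble(
    term = c(names(df)[keep], "Residual", "Total"),
    df = unname(c(df[keep], df_res, n - 1)),
    ss = ss_col,
    ms = unname(c(ms[keep], ms_res, NA_real_)),
    pseudo_f = unname(c(f_obs[keep], NA_real_, NA_real_)),
    p_perm = unname(c(p_perm[keep], NA_real_, NA_real_)),
    pct_variation = 100 * ss_col / ss_total,
    denominator = unname(c(denoms[keep], NA_character_, NA_character_)))
  structure(list(table = tab, n = n, n_permutations = B, seed = seed,
                 ss_total = ss_total, dropped_terms = dropped),
            class = "permancova")
}

#' @method tidy permancova
#' @export
tidy.permancova <- function(x, ...) x$table

#' @method glance permancova
#' @export
glance.permancova <- function(x, ...) {
  tibble::tibble(n = x$n, n_terms = nrow(x$table) - 2,
                 ss_total = x$ss_total, n_permutations = x$n_permutations)
}

#' @export
print.permancova <- function(x, ...) {
  cat(sprintf("PERMANCOVA (%d samples, %d permutations)\n", x$n, x$n_permutations))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}
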