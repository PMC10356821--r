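# Highly-variable-gene identification: median-of-ratios size factors, a
# negative-binomial Wald test between site pairs (vectorized IRLS across
# genes with method-of-moments dispersions shrunk toward a fitted
# mean-dispersion trend), counting of significant site pairs per gene,
# top-5% selection, Ward.D2 clustering of the selected genes, and
# hypergeometric set enrichment of the resulting gene groups.

#' Median-of-ratios size factors
#'
#' `s_j` is the median across reference genes of `count_gj / geomean_g`,
#' where reference genes are those with a positive count in every sample;
#' factors are rescaled to geometric mean 1.  When no gene is positive in
#' all samples, the ratios are taken per sample over that sample's positive
#' genes (logged fallback).
#'
#' @param counts Count tibble.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  all_pos <- colSums(m == 0) == 0
  if (any(all_pos)) {
    log_gm <- colMeans(log(m[, all_pos, drop = FALSE]))
    ratios <- log(m[, all_pos, drop = FALSE]) - rep(log_gm, each = nrow(m))
    s <- exp(apply(ratios, 1, median))
  } else {
    inform("no gene positive in all samples; using per-sample positive genes")
    log_gm <- colSums(log(m + (m == 0))) / pmax(colSums(m > 0), 1)
    s <- exp(vapply(seq_len(nrow(m)), function(i) {
      pos <- m[i, ] > 0
      median(log(m[i, pos]) - log_gm[pos])
    }, numeric(1)))
  }
  s <- s / exp(mean(log(s)))
  setNames(s, rownames(m))
}

# method-of-moments NB dispersion per gene on normalized counts pooled over
# both groups, shrunk 0.5/0.5 toward the trend a0 + a1/mean, floored at 1e-8
mom_dispersion <- function(norm_counts, group) {
  mu_by_g <- apply(norm_counts, 2, function(x) ave(x, group))
  resid2 <- (norm_counts - mu_by_g)^2
  ngrp <- length(unique(group))
  v <- colSums(resid2) / pmax(nrow(norm_counts) - ngrp, 1)
  mu <- colMeans(norm_counts)
  raw <- (v - mu) / mu^2
  raw[!is.finite(raw)] <- 0
  raw <- pmax(raw, 1e-8)
  # parametric trend alpha(mu) = a0 + a1/mu fitted by least squares on the
  # gene-wise estimates (robust enough for the 0.5-weight shrinkage)
  ok <- mu > 0 & is.finite(raw)
  trend <- raw
  if (sum(ok) >= 10) {
    fit <- tryCatch(lm(raw[ok] ~ I(1 / mu[ok])), error = function(e) NULL)
    if (!is.null(fit)) {
      a <- coef(fit)
      trend <- pmax(a[1] + a[2] / mu, 1e-8)
    }
  }
  pmax(0.5 * raw + 0.5 * trend, 1e-8)
}

#' Negative-binomial Wald test between two sites
#'
#' Per gene, fits the model `mu_gj = s_j q_g 2^(beta_g x_j)` with `x_j` the
#' site indicator and a fixed per-gene dispersion `alpha_g` (variance
#' `mu + alpha mu^2`).  Dispersions are method-of-moments estimates on
#' normalized counts pooled across both sites, shrunk with weight 0.5 toward
#' a fitted mean-dispersion trend and floored at 1e-8.  `beta_g` (log2 fold
#' change) and its standard error come from iteratively reweighted least
#' squares, vectorized across genes; the two-sided Wald p uses the normal
#' reference, and BH adjustment is applied across the genes of this pair.
#' Genes with all-zero counts in both sites are excluded from testing and
#' from the BH family.
#'
#' @param counts Filtered count tibble (see [hvg_filter()]).
#' @param meta Metadata with `sample_id` and `site`.
#' @param site_a,site_b Site labels; each must have >= 2 samples.
#' @param sf Optional precomputed size factors for all samples in `counts`.
#' @return Tibble with `gene_id`, `site_a`, `site_b`, `log2_fc`, `se`,
#'   `wald_p`, `bh_adjusted_p`, `dispersion`.
#' @export
nb_pairwise_test <- function(counts, meta, site_a, site_b, sf = NULL) {
  samples_a <- meta$sample_id[meta$site == site_a]
  samples_b <- meta$sample_id[meta$site == site_b]
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    abort("both sites need at least 2 samples")
  }
  m <- counts_to_matrix(counts)
  sel <- c(samples_a, samples_b)
  stopifnot(all(sel %in% rownames(m)))
  if (is.null(sf)) sf <- size_factors(counts)
  s <- sf[sel]
  y <- m[sel, , drop = FALSE]
  x <- as.numeric(sel %in% samples_b)

  nz <- colSums(y) > 0
  excluded <- colnames(y)[!nz]
  y <- y[, nz, drop = FALSE]

  alpha <- mom_dispersion(sweep(y, 1, s, `/`), x)
  fit <- nb_irls(y, x, s, alpha)
  beta2 <- fit$beta / log(2)
  se2 <- fit$se / log(2)
  z <- ifelse(se2 > 0, beta2 / se2, 0)
  p <- 2 * pnorm(-abs(z))
  p[se2 == 0] <- 1
  out <- tibble::tibble(gene_id = colnames(y),
                        site_a = site_a, site_b = site_b,
                        log2_fc = beta2, se = se2, wald_p = p,
                        bh_adjusted_p = benjamini_hochberg(p),
                        dispersion = alpha)
  attr(out, "excluded_genes") <- excluded
  attr(out, "size_factors") <- s
  out
}

# vectorized IRLS for the two-group NB GLM with log link and offset log(s):
# log mu_gj = log s_j + b0_g + b1_g x_j.  Returns b1 (natural log) and SE.
nb_irls <- function(y, x, s, alpha, max_iter = 50, tol = 1e-8) {
  G <- ncol(y)
  n <- nrow(y)
  off <- log(s)
  # init from group means of normalized counts
  yn <- sweep(y, 1, s, `/`)
  m0 <- colMeans(yn[x == 0, , drop = FALSE])
  m1 <- colMeans(yn[x == 1, , drop = FALSE])
  eps <- 0.5
  b0 <- log(m0 + eps)
  b1 <- log(m1 + eps) - log(m0 + eps)
  for (it in seq_len(max_iter)) {
    eta <- outer(off, rep(1, G)) + rep(b0, each = n) + outer(x, b1)
    mu <- exp(eta)
    mu <- pmin(mu, 1e12)
    w <- mu / (1 + rep(alpha, each = n) * mu)      # IRLS weight for NB, log link
    zres <- (y - mu) / mu                           # working residual (z - eta)
    # per-gene 2x2 weighted least squares with design [1, x]
    sw   <- colSums(w)
    swx  <- colSums(w * x)
    swxx <- colSums(w * x^2)
    u0 <- colSums(w * zres)
    u1 <- colSums(w * x * zres)
    det <- sw * swxx - swx^2
    det[det <= 0] <- NA
    d0 <- ( swxx * u0 - swx * u1) / det
    d1 <- (-swx  * u0 + sw  * u1) / det
    d0[is.na(d0)] <- 0
    d1[is.na(d1)] <- 0
    d0 <- pmin(pmax(d0, -5), 5)
    d1 <- pmin(pmax(d1, -5), 5)
    b0 <- b0 + d0
    b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  eta <- outer(off, rep(1, G)) + rep(b0, each = n) + outer(x, b1)
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + rep(alpha, each = n) * mu)
  sw   <- colSums(w)
  swx  <- colSums(w * x)
  swxx <- colSums(w * x^2)
  det <- sw * swxx - swx^2
  se1 <- sqrt(ifelse(det > 0, sw / det, Inf))
  list(beta = b1, se = se1)
}

#' All pairwise site tests
#'
#' Runs [nb_pairwise_test()] for every unordered pair of replicated sites
#' (sites with >= 2 samples); singleton sites are excluded from testing.
#'
#' @param counts Filtered count tibble.
#' @param meta Metadata with `sample_id` and `site`.
#' @return Tibble of stacked per-pair results; attribute `"n_pairs"`.
#' @export
nb_all_pairs <- function(counts, meta) {
  meta <- meta[match(counts$sample_id, meta$sample_id), ]
  tab <- table(meta$site)
  sites <- sort(names(tab)[tab >= 2])
  if (length(sites) < 2) abort("need at least two replicated sites")
  sf <- size_factors(counts)
  pairs <- utils::combn(sites, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    nb_pairwise_test(counts, meta, pr[1], pr[2], sf = sf)
  })
  attr(res, "n_pairs") <- length(pairs)
  res
}

#' Count significant site pairs per gene
#'
#' `c_g` is the number of unordered site pairs in which the gene's
#' (BH-adjusted, by default) p-value is below `threshold`.  Genes absent
#' from a pair contribute 0 for that pair.
#'
#' @param results Stacked results from [nb_all_pairs()].
#' @param threshold Significance threshold (default 0.01).
#' @param use_adjusted Count on BH-adjusted p (default TRUE) or raw Wald p.
#' @return Tibble `gene_id`, `pair_count`, `n_pairs_tested`.
#' @export
pair_count_statistic <- function(results, threshold = 0.01, use_adjusted = TRUE) {
  pr <- distinct(results[, c("site_a", "site_b")])
  key <- paste(pmin(pr$site_a, pr$site_b), pmax(pr$site_a, pr$site_b))
  gkey <- paste(results$gene_id,
                pmin(results$site_a, results$site_b),
                pmax(results$site_a, results$site_b))
  if (anyDuplicated(key) || anyDuplicated(gkey)) {
    abort("duplicate site pair in results")
  }
  n_pairs <- nrow(pr)
  pcol <- if (use_adjusted) "bh_adjusted_p" else "wald_p"
  results %>%
    group_by(.data$gene_id) %>%
    summarise(pair_count = sum(.data[[pcol]] < threshold), .groups = "drop") %>%
    mutate(n_pairs_tested = n_pairs) %>%
    arrange(desc(.data$pair_count), .data$gene_id)
}

#' Select the top fraction of most variable genes
#'
#' Ranks genes by `pair_count` descending and takes the top
#' `ceiling(fraction * G)` where `G` is the number of scored genes.  Ties at
#' the cutoff are broken by larger total normalized abundance, then by
#' lexicographic gene id, so the selection is deterministic.
#'
#' @param scores Tibble from [pair_count_statistic()].
#' @param counts Count tibble used for the tie-breaking abundance.
#' @param fraction Fraction to select (default 0.05).
#' @return `scores` with added logical column `selected`.
#' @export
select_top_fraction <- function(scores, counts, fraction = 0.05) {
  G <- nrow(scores)
  if (G < 20) abort("need at least 20 scored genes")
  n_sel <- ceiling(fraction * G)
  sf <- size_factors(counts)
  m <- sweep(counts_to_matrix(counts), 1, sf, `/`)
  abund <- colSums(m)[scores$gene_id]
  ord <- order(-scores$pair_count, -abund, scores$gene_id)
  sel <- rep(FALSE, G)
  sel[ord[seq_len(n_sel)]] <- TRUE
  scores$selected <- sel
  scores
}

#' Ward.D2 clustering of selected genes
#'
#' Selected genes are represented by their per-sample relative abundances,
#' z-scaled across samples per gene, and clustered by Ward.D2 agglomeration
#' on Euclidean distances between genes.  The tree is cut at 2 to give
#' primary groups and each primary group is cut again at 2, yielding labels
#' A1/A2/B1/B2.  Group "A" is the larger primary cluster (a cosmetic
#' labeling convention); pass `archaea_reference` (a vector of gene ids) to
#' instead label "A" as the primary cluster with more reference genes.
#'
#' @param counts Count tibble covering the selected genes.
#' @param genes Character vector of selected gene ids.
#' @param archaea_reference Optional gene ids anchoring the "A" label.
#' @return List of class `"gene_clusters"`: `labels` (named vector with
#'   values A1/A2/B1/B2), `primary` (A/B), `hclust` (the dendrogram),
#'   `matrix` (the z-scaled gene x sample matrix).
#' @export
ward_cluster_genes <- function(counts, genes, archaea_reference = NULL) {
  if (length(genes) < 4) abort("need at least 4 selected genes")
  m <- counts_to_matrix(counts)
  rel <- m / rowSums(m)
  X <- t(rel[, genes, drop = FALSE])               # genes x samples
  mu <- rowMeans(X)
  sdv <- apply(X, 1, sd)
  sdv <- pmax(sdv, 1e-12)                          # guard constant genes
  Z <- (X - mu) / sdv
  hc <- hclust(dist(Z), method = "ward.D2")
  k2 <- cutree(hc, 2)
  lab_primary <- ifelse(k2 == 1, "g1", "g2")
  if (!is.null(archaea_reference)) {
    n1 <- sum(names(k2)[k2 == 1] %in% archaea_reference)
    n2 <- sum(names(k2)[k2 == 2] %in% archaea_reference)
    a_is_1 <- n1 >= n2
  } else {
    a_is_1 <- sum(k2 == 1) >= sum(k2 == 2)
  }
  primary <- ifelse((k2 == 1) == a_is_1, "A", "B")
  labels <- primary
  for (g in c("A", "B")) {
    idx <- which(primary == g)
    if (length(idx) >= 2) {
      sub <- cutree(hclust(dist(Z[idx, , drop = FALSE]), method = "ward.D2"), 2)
      labels[idx] <- paste0(g, sub)
    } else {
      labels[idx] <- paste0(g, "1")
    }
  }
  names(labels) <- names(primary) <- rownames(Z)
  structure(list(labels = labels, primary = primary, hclust = hc, matrix = Z),
            class = "gene_clusters")
}

#' Hypergeometric enrichment of gene groups
#'
#' For each annotation set within each gene group: `N` is the number of
#' highly variable genes (the universe), `n` the genes in the group, `K` the
#' variable genes in the set, `k` the in-group genes in the set.  The
#' enrichment p is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` (including `k`), BH-adjusted across the
#' sets tested within each group.  Sets with `K = 0` are skipped.
#'
#' @param groups Named vector of group labels (e.g. from
#'   [ward_cluster_genes()]`$labels` or `$primary`).
#' @param annotation Feature-to-set tibble ([read_annotation()] format).
#' @param universe Character vector of the highly variable gene ids.
#' @return Tibble `group`, `set_id`, `set_kind`, `N`, `n`, `K`, `k`,
#'   `p_hyper`, `bh_adjusted_p`.
#' @export
hypergeom_enrich <- function(groups, annotation, universe = names(groups)) {
  stopifnot(all(names(groups) %in% universe))
  N <- length(universe)
  ann <- annotation %>% filter(.data$feature_id %in% universe)
  sets <- ann %>% group_by(.data$set_id, .data$set_kind) %>%
    summarise(members = list(unique(.data$feature_id)), .groups = "drop") %>%
    mutate(K = lengths(.data$members)) %>% filter(.data$K > 0)
  out <- purrr::map_dfr(sort(unique(groups)), function(g) {
    in_group <- names(groups)[groups == g]
    n <- length(in_group)
    res <- sets %>%
      mutate(k = purrr::map_int(.data$members, ~ sum(in_group %in% .x))) %>%
      select(-"members")
    if (any(res$k > pmin(n, res$K))) abort("k exceeds min(n, K): bookkeeping bug")
    res$p_hyper <- phyper(res$k - 1, res$K, N - res$K, n, lower.tail = FALSE)
    res$bh_adjusted_p <- benjamini_hochberg(res$p_hyper)
    bind_cols(tibble::tibble(group = g, N = N, n = n), res)
  })
  out %>% select("group", "set_id", "set_kind", "N", "n", "K", "k",
                 "p_hyper", "bh_adjusted_p")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `adj_i = min_{j >= rank(i)} (m/j) p_(j)`, capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' End-to-end highly-variable-gene workflow
#'
#' Chains [hvg_filter()], [nb_all_pairs()], [pair_count_statistic()],
#' [select_top_fraction()] and [ward_cluster_genes()].
#'
#' @param counts Raw integer count tibble.
#' @param meta Metadata with `sample_id` and `site`.
#' @param fraction Selection fraction (default 0.05).
#' @param threshold Per-pair significance threshold (default 0.01).
#' @param use_adjusted Count BH-adjusted (default) or raw p-values.
#' @return List with `filtered`, `pair_results`, `scores`, `selected`
#'   (gene ids), `clusters` (a `gene_clusters` object, or NULL when fewer
#'   than 4 genes are selected).
#' @export
run_hvg <- function(counts, meta, fraction = 0.05, threshold = 0.01,
                    use_adjusted = TRUE) {
  filtered <- hvg_filter(counts)
  pair_results <- nb_all_pairs(filtered, meta)
  scores <- pair_count_statistic(pair_results, threshold = threshold,
                                 use_adjusted = use_adjusted)
  scores <- select_top_fraction(scores, filtered, fraction = fraction)
  selected <- scores$gene_id[scores$selected]
  clusters <- if (length(selected) >= 4) {
    ward_cluster_genes(filtered, selected)
  }
  list(filtered = filtered, pair_results = pair_results, scores = scores,
       selected = selected, clusters = clusters)
}
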