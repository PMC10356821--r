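# Size factors, the NB pairwise Wald test, pair counting, top-5% selection,
# Ward.D2 clustering, hypergeometric enrichment, and BH adjustment.

test_that("size factors: identical samples give 1, a doubled sample ratio 2", {
  m <- matrix(rep(c(10, 20, 30, 40), each = 3), 3, 4)
  expect_equal(unname(size_factors(as_counts(m))), rep(1, 3))

  m2 <- rbind(c(10, 20, 30), c(20, 40, 60), c(10, 20, 30))
  s <- unname(size_factors(as_counts(m2)))
  expect_equal(s[2] / s[1], 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)
  # scale invariance of normalized counts
  s5 <- size_factors(as_counts(5 * m2))
  n1 <- sweep(m2, 1, unname(size_factors(as_counts(m2))), `/`)
  n5 <- sweep(5 * m2, 1, unname(s5), `/`)
  expect_equal(n5 / n1, matrix(5, 3, 3), tolerance = 1e-12)
})

test_that("NB Wald estimates agree with a fixed-dispersion GLM fit per gene", {
  set.seed(41)
  d <- nb_null_data(n_per_site = 5, n_genes = 40)
  # plant one strong effect
  m <- permagrad:::counts_to_matrix(d$counts)
  m[d$meta$site == "B", 1] <- m[d$meta$site == "B", 1] * 4
  ct <- as_counts(m)
  res <- nb_pairwise_test(ct, d$meta, "A", "B")
  sf <- attr(res, "size_factors")
  x <- as.numeric(d$meta$site == "B")
  for (g in c(1, 7, 22)) {
    fit <- suppressWarnings(stats::glm(
      m[, g] ~ x + offset(log(sf)),
      family = MASS::negative.binomial(theta = 1 / res$dispersion[g])))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(unname(res$log2_fc[g]), unname(co["x", 1]) / log(2),
                 tolerance = 1e-4)
    expect_equal(unname(res$se[g]), unname(co["x", 2]) / log(2),
                 tolerance = 1e-3)
  }
  # the planted gene is detected with log2FC near 2
  expect_lt(res$bh_adjusted_p[1], 0.01)
  expect_equal(unname(res$log2_fc[1]), 2, tolerance = 0.6)
})

test_that("degenerate NB inputs are guarded", {
  # identical count vectors duplicated across both sites -> beta 0, p 1
  base <- matrix(rep(c(50, 80, 120), times = 4), 4, 3, byrow = TRUE,
                 dimnames = list(NULL, c("g1", "g2", "g3")))
  ct <- as_counts(base)
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         site = rep(c("A", "B"), each = 2))
  res <- nb_pairwise_test(ct, meta, "A", "B")
  expect_equal(unname(res$log2_fc), rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(res$wald_p), rep(1, 3), tolerance = 1e-4)
  # all-zero gene excluded from testing and BH
  m <- cbind(base, zero = 0)
  res2 <- nb_pairwise_test(as_counts(m), meta, "A", "B")
  expect_false("zero" %in% res2$gene_id)
  expect_equal(attr(res2, "excluded_genes"), "zero")
  expect_error(nb_pairwise_test(ct, tibble::tibble(sample_id = paste0("s", 1:4),
                                                   site = c("A", "B", "B", "B")),
                                "A", "B"), "at least 2")
})

test_that("planted fold changes are recovered without bias", {
  set.seed(42)
  betas <- replicate(30, {
    d <- nb_null_data(n_per_site = 4, n_genes = 60)
    m <- permagrad:::counts_to_matrix(d$counts)
    m[d$meta$site == "B", 1] <- rnbinom(4, mu = 4 * 200, size = 10)
    m[d$meta$site == "A", 1] <- rnbinom(4, mu = 200, size = 10)
    res <- nb_pairwise_test(as_counts(m), d$meta, "A", "B")
    res$log2_fc[res$gene_id == "g0001"]
  })
  expect_lt(abs(median(betas) - 2), 0.3)
})

test_that("pair counting tallies BH-significant pairs and is order-invariant", {
  # synthetic results table for 3 sites (3 pairs), 4 genes
  res <- tidyr::expand_grid(gene_id = paste0("g", 1:4),
                            pair = c("A|B", "A|C", "B|C")) |>
    tidyr::separate("pair", c("site_a", "site_b"), sep = "\\|") |>
    dplyr::mutate(bh_adjusted_p = c(0.001, 0.5, 0.002,   # g1: 2 pairs
                                    0.5, 0.5, 0.5,       # g2: 0
                                    0.009, 0.009, 0.009, # g3: 3
                                    0.011, 0.5, 0.5),    # g4: 0 (boundary)
                  wald_p = bh_adjusted_p)
  sc <- pair_count_statistic(res)
  expect_equal(sc$pair_count[match(paste0("g", 1:4), sc$gene_id)],
               c(2L, 0L, 3L, 0L))
  expect_equal(unique(sc$n_pairs_tested), 3L)
  # shuffling the rows leaves the counts unchanged
  sc2 <- pair_count_statistic(res[sample.int(nrow(res)), ])
  expect_equal(sc, sc2)
  expect_error(pair_count_statistic(dplyr::bind_rows(res, res[1, ])),
               "duplicate")
})

test_that("pair counts match a brute-force tally on a randomized fixture", {
  set.seed(43)
  sim <- simulate_dataset(sim_config(n_continents = 5,
                                     n_regions_per_continent = 1,
                                     n_sites_per_region = 1,
                                     n_samples_per_site = 3,
                                     n_genes = 60, n_planted_variable_genes = 6,
                                     seed = 43))
  filt <- hvg_filter(sim$genes)
  res <- nb_all_pairs(filt, sim$meta)
  sc <- pair_count_statistic(res)
  brute <- tapply(res$bh_adjusted_p < 0.01, res$gene_id, sum)
  expect_equal(sc$pair_count, as.vector(brute[sc$gene_id]))
})

test_that("top-fraction selection sizes and tie-breaks are deterministic", {
  set.seed(44)
  G <- 100
  m <- matrix(rpois(10 * G, 50), 10, G,
              dimnames = list(NULL, sprintf("g%03d", 1:G)))
  ct <- as_counts(m)
  scores <- tibble::tibble(gene_id = colnames(m)[order(colnames(m))],
                           pair_count = 0L, n_pairs_tested = 10L)
  out <- select_top_fraction(scores, ct, fraction = 0.05)
  expect_equal(sum(out$selected), 5)
  # all-tied counts: selection decided by abundance then id, stable on rerun
  expect_identical(out$selected, select_top_fraction(scores, ct, 0.05)$selected)
  abund <- colSums(sweep(m, 1, unname(size_factors(ct)), `/`))
  picked <- out$gene_id[out$selected]
  expect_true(min(abund[picked]) >= sort(abund, decreasing = TRUE)[6] - 1e-9)

  # the count rule at full scale: top 5% of 6540 genes is 327
  big <- tibble::tibble(gene_id = sprintf("g%05d", 1:6540),
                        pair_count = rpois(6540, 3), n_pairs_tested = 45L)
  bigct <- as_counts(matrix(rpois(2 * 6540, 20), 2, 6540,
                            dimnames = list(NULL, big$gene_id)))
  expect_equal(sum(select_top_fraction(big, bigct)$selected), ceiling(0.05 * 6540))
  expect_equal(ceiling(0.05 * 6540), 327)
})

test_that("Ward.D2 merge heights equal the brute-force Lance-Williams recursion", {
  set.seed(45)
  X <- matrix(rnorm(5 * 3), 5, 3)
  hc <- hclust(dist(X), method = "ward.D2")
  expect_equal(sort(hc$height), ward_d2_heights_brute(X), tolerance = 1e-10)
  # a second fixture with structure
  X2 <- rbind(matrix(rnorm(6, 0, 0.1), 2), matrix(rnorm(9, 5, 0.1), 3))
  hc2 <- hclust(dist(X2), method = "ward.D2")
  expect_equal(sort(hc2$height), ward_d2_heights_brute(X2), tolerance = 1e-10)
})

test_that("gene clustering recovers planted blocks and labels subgroups", {
  set.seed(46)
  n_s <- 12
  block1 <- matrix(rep(c(rep(400, 6), rep(50, 6)), 6), n_s, 6)
  block2 <- matrix(rep(c(rep(50, 6), rep(400, 6)), 6), n_s, 6)
  m <- cbind(block1, block2) + matrix(rpois(n_s * 12, 10), n_s)
  colnames(m) <- paste0("g", 1:12)
  ct <- as_counts(m)
  cl <- ward_cluster_genes(ct, paste0("g", 1:12))
  truth <- rep(c("x", "y"), each = 6)
  expect_equal(adjusted_rand(cl$primary, truth), 1)
  expect_true(all(cl$labels %in% c("A1", "A2", "B1", "B2")))
  # duplicated single gene: all in one primary group
  dup <- as_counts(matrix(rep(c(10, 30, 20, 40), 8), 4, 8) +
                     matrix(rpois(32, 2), 4))
  cl2 <- ward_cluster_genes(dup, paste0("g", 1:8))
  expect_error(ward_cluster_genes(dup, paste0("g", 1:3)), "at least 4")
  # reference anchoring controls which primary group is called A
  cl3 <- ward_cluster_genes(ct, paste0("g", 1:12),
                            archaea_reference = paste0("g", 1:6))
  expect_true(all(cl3$primary[paste0("g", 1:6)] == "A"))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # N = 10, K = 5, n = 5, k = 5: a single way out of C(10,5)
  groups <- setNames(rep(c("A", "B"), each = 5), paste0("g", 1:10))
  ann <- tibble::tibble(feature_id = paste0("g", 1:5), set_id = "s1",
                        set_kind = "pathway")
  en <- hypergeom_enrich(groups, ann)
  expect_equal(en$p_hyper[en$group == "A"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(en$k[en$group == "A"], 5L)
  # k = 0 has upper-tail probability 1
  expect_equal(en$p_hyper[en$group == "B"], 1)
  # random small cases vs brute-force sums
  set.seed(47)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    nn <- sample(1:N, 1)
    univ <- paste0("g", 1:N)
    grp <- setNames(ifelse(seq_len(N) <= nn, "A", "B"), univ)
    ann <- tibble::tibble(feature_id = paste0("g", sample.int(N, K)),
                          set_id = "s", set_kind = "pathway")
    en <- hypergeom_enrich(grp, ann, universe = univ)
    k <- en$k[en$group == "A"]
    expect_equal(en$p_hyper[en$group == "A"],
                 hyper_upper_brute(N, K, nn, k), tolerance = 1e-12)
  }
})

test_that("BH step-up matches hand computation and its monotonicity contract", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # hand step-up on an uneven vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  m <- length(p)
  adj_hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(benjamini_hochberg(p), pmin(adj_hand, 1))
  # monotone in raw p, adjusted >= raw
  set.seed(48)
  q <- runif(50)
  a <- benjamini_hochberg(q)
  expect_true(all(a >= q))
  expect_true(all(diff(a[order(q)]) >= -1e-12))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pair counts are invariant to sample and site relabeling order", {
  set.seed(49)
  sim <- simulate_dataset(sim_config(n_genes = 50, n_planted_variable_genes = 5,
                                     n_samples_per_site = 3, seed = 49))
  filt <- hvg_filter(sim$genes)
  sc1 <- pair_count_statistic(nb_all_pairs(filt, sim$meta))
  perm <- sample.int(nrow(filt))
  sc2 <- pair_count_statistic(nb_all_pairs(filt[perm, ], sim$meta))
  expect_equal(sc1, sc2)
})
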