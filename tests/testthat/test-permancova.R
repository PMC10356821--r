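# Abundance filtering, Bray-Curtis construction, orthogonal polynomial
# contrasts, and the nested PERMANCOVA machinery.

test_that("abundance filter applies strict > on counts, at-least on samples", {
  n <- 100
  m <- matrix(0, n, 3, dimnames = list(paste0("s", 1:n), c("keep", "drop", "edge")))
  m[1:10, "keep"] <- 11                 # count 11 in exactly 10% of samples
  m[, "drop"] <- 10                     # count 10 everywhere: > 10 fails
  m[1:9, "edge"] <- 100                 # one sample short of 10%
  out <- abundance_filter(as_counts(m), min_count = 10, min_fraction = 0.10)
  expect_equal(setdiff(names(out), "sample_id"), "keep")
  expect_error(abundance_filter(as_counts(m[, 2, drop = FALSE]), 10, 0.10),
               "every feature")
})

test_that("abundance filter agrees with brute-force recomputation", {
  set.seed(21)
  m <- matrix(rnbinom(60 * 500, mu = 30, size = 0.5), 60, 500,
              dimnames = list(paste0("s", 1:60), paste0("g", 1:500)))
  ct <- as_counts(m)
  out <- abundance_filter(ct, min_count = 10, min_fraction = 0.10)
  brute <- colnames(m)[vapply(seq_len(ncol(m)), function(j) {
    sum(m[, j] > 10) >= ceiling(0.10 * nrow(m))
  }, logical(1))]
  expect_equal(setdiff(names(out), "sample_id"), brute)
  # HVG variant is the same rule at 100 / 10%
  hv <- hvg_filter(ct)
  brute100 <- colnames(m)[colSums(m > 100) >= ceiling(0.10 * nrow(m))]
  expect_equal(setdiff(names(hv), "sample_id"), brute100)
})

test_that("Bray-Curtis matches the hand fixture and its boundary cases", {
  ct <- as_counts(matrix(c(1, 3, 2, 2), 2, byrow = TRUE))
  d <- bray_curtis(ct)
  # relative (0.25, 0.75) and (0.5, 0.5), sqrt, then sum|.|/sum(.)
  hand <- (abs(0.5 - sqrt(0.5)) + abs(sqrt(0.75) - sqrt(0.5))) /
    (0.5 + sqrt(0.75) + 2 * sqrt(0.5))
  expect_equal(d$d[1, 2], hand, tolerance = 1e-10)

  same <- as_counts(matrix(c(4, 6, 4, 6), 2, byrow = TRUE))
  expect_equal(bray_curtis(same)$d[1, 2], 0)
  disjoint <- as_counts(matrix(c(5, 0, 0, 7), 2, byrow = TRUE))
  expect_equal(bray_curtis(disjoint)$d[1, 2], 1)
  zero <- as_counts(matrix(c(1, 2, 0, 0), 2, byrow = TRUE))
  expect_error(bray_curtis(zero), "s2")
  # symmetry, zero diagonal, range
  set.seed(2)
  d2 <- bray_curtis(as_counts(matrix(rpois(50, 20), 5)))$d
  expect_equal(d2, t(d2))
  expect_equal(unname(diag(d2)), rep(0, 5))
  expect_true(all(d2 >= 0 & d2 <= 1))
})

test_that("orthogonal polynomial contrasts are orthonormal and span the trend space", {
  P <- orthogonal_polynomials(c(1, 2, 3), 1)
  expect_equal(abs(P[, 1]), c(1, 0, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(4)
  x <- rnorm(25)
  P3 <- orthogonal_polynomials(x, 3)
  G <- crossprod(cbind(1, P3))
  expect_equal(G[-1, -1], diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(colSums(P3)) < 1e-10))
  # spans (x, x^2, x^3): projection of x^2 onto [1, P3] is exact
  fit <- lm(I(x^2) ~ P3)
  expect_lt(sum(residuals(fit)^2), 1e-20)
  expect_error(orthogonal_polynomials(c(1, 1, 2), 2), "distinct")
})

test_that("pseudo-F for univariate Euclidean one-way design equals classical F", {
  set.seed(31)
  y <- c(rnorm(7), rnorm(8, 1.2))
  grp <- rep(c("A", "B"), c(7, 8))
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("s", 1:15), paste0("s", 1:15))
  des <- data.frame(sample_id = paste0("s", 1:15), continent = grp)
  pm <- permancova(D, des, B = 99, seed = 1)
  f_classic <- anova(lm(y ~ grp))[["F value"]][1]
  expect_equal(tidy(pm)$pseudo_f[1], f_classic, tolerance = 1e-10)
})

test_that("one-factor table matches vegan::adonis2 sums of squares and F", {
  set.seed(32)
  Y <- matrix(rpois(18 * 6, 25), 18)
  grp <- rep(c("A", "B", "C"), each = 6)
  D <- as.matrix(vegan::vegdist(Y, "bray"))
  dimnames(D) <- list(paste0("s", 1:18), paste0("s", 1:18))
  des <- data.frame(sample_id = paste0("s", 1:18), continent = grp)
  pm <- permancova(D, des, B = 49, seed = 1)
  av <- vegan::adonis2(vegan::vegdist(Y, "bray") ~ grp, permutations = 49)
  expect_equal(tidy(pm)$ss[1], av$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(tidy(pm)$ss[2], av$SumOfSqs[2], tolerance = 1e-8)
  expect_equal(tidy(pm)$pseudo_f[1], av$F[1], tolerance = 1e-8)
})

test_that("sequential SS partition is exact and matches tr(G) in the nested design", {
  sim <- simulate_dataset(sim_config(n_genes = 80, seed = 33))
  d <- bray_curtis(abundance_filter(sim$genes))
  covs <- tibble::tibble(sample_id = sim$meta$sample_id,
                         cov = rnorm(nrow(sim$meta)))
  pm <- permancova(d, sim$meta, covariates = covs, B = 19, seed = 2)
  tab <- tidy(pm)
  ss_terms <- sum(tab$ss[!(tab$term %in% c("Total"))])
  expect_equal(ss_terms, tab$ss[tab$term == "Total"], tolerance = 1e-8)
  # total SS equals the pairwise-dissimilarity identity (1/n) sum_{i<j} d^2
  n <- nrow(sim$meta)
  expect_equal(tab$ss[tab$term == "Total"],
               sum(d$d[upper.tri(d$d)]^2) / n, tolerance = 1e-8)
  # df partition
  expect_equal(sum(tab$df[tab$term != "Total"]), n - 1)
  # denominators follow the mixed-model rules
  expect_equal(tab$denominator[tab$term == "continent"], "region(continent)")
  expect_equal(tab$denominator[tab$term == "region(continent)"], "site(region)")
  expect_equal(tab$denominator[tab$term == "site(region)"], "Residual")
})

test_that("permutation p-values are reproducible and stable in B", {
  set.seed(34)
  y <- c(rnorm(8), rnorm(8, 0.8))
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("s", 1:16), paste0("s", 1:16))
  des <- data.frame(sample_id = paste0("s", 1:16),
                    continent = rep(c("A", "B"), each = 8))
  p1 <- tidy(permancova(D, des, B = 199, seed = 9))$p_perm[1]
  p2 <- tidy(permancova(D, des, B = 199, seed = 9))$p_perm[1]
  expect_identical(p1, p2)
  p_big <- tidy(permancova(D, des, B = 999, seed = 9))$p_perm[1]
  expect_lt(abs(p_big - p1), 0.05)
})

test_that("zero-df terms are dropped with a message", {
  # single region per continent: the region term adds no rank
  meta <- tiny_meta()
  sim <- simulate_dataset(sim_config(n_genes = 50, n_regions_per_continent = 1,
                                     seed = 35))
  d <- bray_curtis(abundance_filter(sim$genes))
  expect_message(pm <- permancova(d, sim$meta, B = 19, seed = 1), "0 df")
  expect_false("region(continent)" %in% tidy(pm)$term)
})

test_that("null covariate explains its df share of variation on average", {
  set.seed(36)
  pcts <- replicate(40, {
    n <- 24
    Y <- matrix(rnorm(n * 10), n)
    D <- as.matrix(dist(Y))
    ids <- paste0("s", seq_len(n))
    dimnames(D) <- list(ids, ids)
    des <- data.frame(sample_id = ids)
    covs <- tibble::tibble(sample_id = ids, z = rnorm(n))
    pm <- permancova(D, des, covariates = covs, B = 0, seed = 1)
    tidy(pm)$pct_variation[1]
  })
  expect_equal(mean(pcts), 100 / 23, tolerance = 0.35)
})
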