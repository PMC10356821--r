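# Johnson normalization, k-means with elbow selection, cluster/age-class
# ANOVA with Tukey-Kramer follow-up, and kappa agreement.

test_that("Johnson transform never worsens normality and inverts exactly", {
  set.seed(51)
  x <- rnorm(5000)
  jt <- johnson_transform(x)
  expect_gte(jt$shapiro_w, shapiro.test(x)$statistic)

  y <- rlnorm(800)
  jl <- johnson_transform(y)
  expect_gt(shapiro.test(jl$y)$p.value, 0.01)
  expect_true(jl$family %in% c("SU", "SB", "SL"))
  expect_equal(johnson_inverse(jl$y, jl), y, tolerance = 1e-8)

  expect_error(johnson_transform(rep(3, 50)), "constant")
  # small samples fall back to the rank-based transform
  js <- johnson_transform(c(1, 5, 2, 9, 3))
  expect_true(js$family %in% c("identity", "rank_normal"))
})

test_that("log-normal data are normalized in the large majority of draws", {
  set.seed(52)
  pvals <- replicate(40, {
    y <- rlnorm(300)
    shapiro.test(johnson_transform(y)$y)$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("elbow selection finds planted blobs and flags degenerate cases", {
  set.seed(53)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 7), 20),
             matrix(rnorm(40, -7), 20))
  rownames(X) <- paste0("s", 1:60)
  cl <- kmeans_elbow(X, k_range = 2:7, restarts = 15, seed = 3)
  expect_equal(cl$k, 3)
  truth <- rep(1:3, each = 20)
  expect_equal(adjusted_rand(cl$assignments$cluster, truth), 1)
  # within-SS non-increasing along the curve
  expect_true(all(diff(cl$elbow$within_ss) <= 1e-8))
  # determinism given seed
  cl2 <- kmeans_elbow(X, k_range = 2:7, restarts = 15, seed = 3)
  expect_identical(cl$assignments, cl2$assignments)

  # duplicated samples land in the same cluster
  Xd <- rbind(X, X[1:5, ])
  rownames(Xd) <- c(rownames(X), paste0("dup", 1:5))
  cld <- kmeans_elbow(Xd, k_range = 2:7, restarts = 15, seed = 3)
  a <- cld$assignments
  expect_equal(a$cluster[match(paste0("dup", 1:5), a$sample_id)],
               a$cluster[match(paste0("s", 1:5), a$sample_id)])

  # single blob: warning about a weak elbow
  set.seed(54)
  X1 <- matrix(rnorm(120), 40, 3, dimnames = list(paste0("s", 1:40), NULL))
  expect_warning(kmeans_elbow(X1, k_range = 2:6, restarts = 5, seed = 1),
                 "elbow|monotone")
  expect_error(kmeans_elbow(X1, k_range = 2:40), "k_max")
})

test_that("small clusters are flagged for removal from downstream ANOVA", {
  set.seed(55)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 8, 0.3), 20),
             matrix(rnorm(6, -8, 0.3), 3))
  rownames(X) <- paste0("s", 1:43)
  cl <- kmeans_elbow(X, k_range = 2:6, restarts = 15, seed = 2)
  sizes <- table(cl$assignments$cluster)
  expect_setequal(cl$retained_clusters, names(sizes)[sizes > 4])
  expect_equal(cl$assignments$retained,
               cl$assignments$cluster %in% cl$retained_clusters)
})

test_that("cluster ANOVA matches hand-computed F and guards separation", {
  # worked 3-group fixture
  vals <- c(1, 2, 3, 6, 7, 8, 11, 12, 13)
  grp <- rep(c("a", "b", "c"), each = 3)
  meta <- tibble::tibble(sample_id = paste0("s", 1:9), v = vals)
  asg <- tibble::tibble(sample_id = paste0("s", 1:9), cluster = grp)
  out <- cluster_anova(asg, meta, "v", normalize_if_needed = FALSE)
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, grp, mean), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(out$f, f_hand, tolerance = 1e-10)
  expect_equal(out$r_squared, ssb / (ssb + ssw), tolerance = 1e-10)
  expect_equal(out$df_between, 2)
  expect_equal(out$df_within, 6)
  # R^2 equals squared correlation of fitted and observed
  fit <- lm(vals ~ grp)
  expect_equal(out$r_squared, cor(fitted(fit), vals)^2, tolerance = 1e-10)
  # Tukey table present when significant
  tk <- attr(out, "tukey")
  expect_false(is.null(tk))
  expect_equal(nrow(tk), 3)

  # perfect separation
  meta2 <- tibble::tibble(sample_id = paste0("s", 1:6), v = rep(c(1, 2), each = 3))
  asg2 <- tibble::tibble(sample_id = paste0("s", 1:6),
                         cluster = rep(c("a", "b"), each = 3))
  sep <- cluster_anova(asg2, meta2, "v")
  expect_true(!is.finite(sep$f) || sep$f > 1e12)
  expect_lt(sep$p, 1e-12)
  expect_equal(sep$r_squared, 1)
})

test_that("clusters with too few observed values are dropped per variable", {
  set.seed(77)
  meta <- tibble::tibble(sample_id = paste0("s", 1:12),
                         v = c(rnorm(10), NA, NA))
  asg <- tibble::tibble(sample_id = paste0("s", 1:12),
                        cluster = rep(c("a", "b", "c"), c(5, 5, 2)))
  expect_message(out <- cluster_anova(asg, meta, "v"), "dropped")
  expect_equal(out$df_between, 1)   # only clusters a and b remain
})

test_that("age-class ANOVA reproduces the two-group hand computation", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         depth = c(1, 2, 3, 2, 1, 9, 8, 7, 9, 8),
                         age_class = rep(c("Holocene", "Pleistocene"), each = 5))
  out <- age_class_anova(meta, "depth", normalize_if_needed = FALSE)
  f_hand <- anova(lm(depth ~ age_class, data = meta))[["F value"]][1]
  expect_equal(out$f, f_hand, tolerance = 1e-10)
  # identical groups: F near 0, p near 1
  meta$depth <- rep(c(1, 2, 3, 4, 5), 2)
  out0 <- age_class_anova(meta, "depth", normalize_if_needed = FALSE)
  expect_lt(out0$f, 1e-10)
  expect_gt(out0$p, 0.99)
  expect_error(age_class_anova(meta[meta$age_class == "Holocene", ], "depth"),
               "both age classes")
})

test_that("kappa matches the hand fixture and its invariances", {
  # 2x2 contingency {{45,5},{5,45}}: p_o 0.9, p_e 0.5, kappa 0.8
  a <- rep(c("x", "y"), each = 50)
  b <- a
  flip <- c(1:5, 51:55)
  b[flip] <- ifelse(a[flip] == "x", "y", "x")
  names(a) <- names(b) <- paste0("s", 1:100)
  k <- kappa_agreement(a, b, B = 199, seed = 1)
  expect_equal(k$observed_agreement, 0.9)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.8)
  expect_lt(k$permutation_p, 0.05)

  # identical labelings under any renaming give kappa 1
  b2 <- setNames(ifelse(a == "x", "apples", "pears"), names(a))
  expect_equal(kappa_agreement(a, b2, B = 19)$kappa, 1)

  # invariant to sample order and label names
  ord <- sample(names(a))
  k2 <- kappa_agreement(a[ord], b[ord], B = 199, seed = 1)
  expect_equal(k2$kappa, k$kappa)
  expect_error(kappa_agreement(a, b[1:50]), "different sample sets")
})

test_that("independent labelings give kappa near zero", {
  set.seed(56)
  ks <- replicate(30, {
    a <- sample(letters[1:4], 500, replace = TRUE)
    b <- sample(letters[1:4], 500, replace = TRUE)
    kappa_agreement(a, b, B = 0)$kappa
  })
  expect_gte(mean(abs(ks) < 0.1), 0.99)
})
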