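# Shared fixture builders. Everything is generated in code at test time.

# small nested metadata table: 2 continents x 1 region x 2 sites x n_per site
tiny_meta <- function(n_per = 3, seed = 1) {
  set.seed(seed)
  sites <- c("C1_R1_S1", "C1_R1_S2", "C2_R1_S1", "C2_R1_S2")
  tibble::tibble(
    sample_id = paste0(rep(sites, each = n_per), "_", seq_len(n_per)),
    continent = rep(c("C1", "C1", "C2", "C2"), each = n_per),
    region = rep(c("C1_R1", "C1_R1", "C2_R1", "C2_R1"), each = n_per),
    site = rep(sites, each = n_per),
    latitude = 65 + rnorm(4 * n_per),
    ph = 6.5 + rnorm(4 * n_per, sd = 0.5),
    depth = exp(rnorm(4 * n_per)),
    age = exp(rnorm(4 * n_per, 2)),
    age_class = rep(c("Holocene", "Pleistocene"), 2 * n_per))
}

# count tibble from a plain matrix
as_counts <- function(m, prefix = "s") {
  if (is.null(rownames(m))) rownames(m) <- paste0(prefix, seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "sample_id")
}

# NB count table under the null: same law at every sample; two sites
nb_null_data <- function(n_per_site = 4, n_genes = 300, alpha = 0.1,
                         mean_count = 200) {
  n <- 2 * n_per_site
  q <- rlnorm(n_genes, log(mean_count), 0.5)
  libs <- rlnorm(n, 0, 0.2)
  y <- matrix(rnbinom(n * n_genes, mu = outer(libs, q), size = 1 / alpha), n)
  colnames(y) <- sprintf("g%04d", seq_len(n_genes))
  rownames(y) <- paste0("s", seq_len(n))
  list(counts = as_counts(y),
       meta = tibble::tibble(sample_id = paste0("s", seq_len(n)),
                             site = rep(c("A", "B"), each = n_per_site)))
}

# brute-force hypergeometric upper tail P(X >= k), X ~ Hypergeom(N, K, n)
hyper_upper_brute <- function(N, K, n, k) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force Ward.D2 agglomeration via the Lance-Williams recursion;
# returns sorted merge heights
ward_d2_heights_brute <- function(X) {
  d2 <- as.matrix(dist(X))^2            # squared Euclidean distances
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  repeat {
    if (length(active) < 2) break
    dd <- d2[active, active]
    diag(dd) <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, sqrt(d2[i, j]))  # ward.D2 height = sqrt of merged d2
    ni <- sizes[i]; nj <- sizes[j]
    for (h in setdiff(active, c(i, j))) {
      nh <- sizes[h]
      d2[i, h] <- d2[h, i] <-
        ((ni + nh) * d2[i, h] + (nj + nh) * d2[j, h] - nh * d2[i, j]) /
        (ni + nj + nh)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
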