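# Synthetic-data generator: produces metadata, gene-count, taxa and
# annotation tables with the statistical structure the downstream analyses
# assume, together with a truth record used only by recovery tests.
# No analysis stage reads the truth object.

#' Build a simulation configuration
#'
#' Defines the structure of a synthetic permafrost metagenome study: a nested
#' continent/region/site sampling design, twelve correlated environmental
#' variables with missing-completely-at-random gaps, negative-binomial gene
#' counts with a planted subset of environment-linked variable genes
#' (including an "archaea-like" block tied to high-pH, deep sites), and a
#' taxa table whose expected Shannon diversity is unimodal in pH.
#'
#' Defaults give 3 continents x 2 regions x 2 sites x 4 samples (48 samples,
#' 12 sites), 300 genes of which 15 are planted variable genes, 25 taxonomic
#' classes, 10% missingness and a planted log2 effect size of 2.
#'
#' @param n_continents,n_regions_per_continent,n_sites_per_region Integers
#'   defining the nesting structure.
#' @param n_samples_per_site Samples per site (1 to 13, as in field designs
#'   where replication varies).
#' @param n_genes Number of gene (KEGG-ortholog-like) features.
#' @param n_planted_variable_genes Number of genes given site-level effects.
#' @param n_taxa_classes Number of taxonomic classes.
#' @param env_covariance Optional 12 x 12 positive-definite covariance for the
#'   latent environmental variables (default: a realistic block-correlation
#'   structure in which age, depth and pH are positively associated).
#' @param missing_rate MCAR missingness fraction in \[0, 0.5).
#' @param nb_dispersion_shape,nb_dispersion_rate Gamma law for per-gene NB
#'   dispersions (default mean 0.1).
#' @param effect_size Planted log2 fold change linking variable genes to
#'   site-level environment.
#' @param library_size_meanlog,library_size_sdlog Log-normal library sizes.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_continents = 3,
                       n_regions_per_continent = 2,
                       n_sites_per_region = 2,
                       n_samples_per_site = 4,
                       n_genes = 300,
                       n_planted_variable_genes = 15,
                       n_taxa_classes = 25,
                       env_covariance = NULL,
                       missing_rate = 0.10,
                       nb_dispersion_shape = 2,
                       nb_dispersion_rate = 20,
                       effect_size = 2,
                       library_size_meanlog = log(2e5),
                       library_size_sdlog = 0.25,
                       seed = 1L) {
  cfg <- list(n_continents = n_continents,
              n_regions_per_continent = n_regions_per_continent,
              n_sites_per_region = n_sites_per_region,
              n_samples_per_site = n_samples_per_site,
              n_genes = n_genes,
              n_planted_variable_genes = n_planted_variable_genes,
              n_taxa_classes = n_taxa_classes,
              env_covariance = env_covariance %||% default_env_covariance(),
              missing_rate = missing_rate,
              nb_dispersion_shape = nb_dispersion_shape,
              nb_dispersion_rate = nb_dispersion_rate,
              effect_size = effect_size,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              seed = as.integer(seed))
  if (cfg$n_planted_variable_genes > cfg$n_genes) {
    abort("n_planted_variable_genes must not exceed n_genes")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.5) {
    abort("missing_rate must be in [0, 0.5)")
  }
  if (cfg$n_samples_per_site < 1 || cfg$n_samples_per_site > 13) {
    abort("n_samples_per_site must be in 1..13")
  }
  S <- cfg$env_covariance
  if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0)) {
    abort("env_covariance must be symmetric positive-definite")
  }
  structure(cfg, class = "sim_config")
}

#' Default latent environmental correlation structure
#'
#' Age, depth and pH are positively correlated (older permafrost is deeper
#' and more alkaline, the confounding seen in field data); total C, total N
#' and organic C form a tight block; C/N tracks total C; latitude and
#' elevation are mildly negatively related.
#' @return A 12 x 12 positive-definite correlation matrix over the
#'   environmental variables.
#' @export
default_env_covariance <- function() {
  p <- length(ENV_VARS)
  R <- diag(p)
  dimnames(R) <- list(ENV_VARS, ENV_VARS)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("age", "depth", 0.6)
  set_r("age", "ph", 0.5)
  set_r("depth", "ph", 0.4)
  set_r("total_c", "total_n", 0.8)
  set_r("total_c", "organic_c", 0.8)
  set_r("total_n", "organic_c", 0.7)
  set_r("cn_ratio", "total_c", 0.4)
  set_r("latitude", "elevation", -0.3)
  set_r("ph", "organic_c", -0.3)
  set_r("age", "organic_c", -0.3)
  # guarantee positive-definiteness of the hand-set pattern
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) R <- R + diag(1e-6 - min(ev) + 1e-8, p)
  R
}

# draw n rows from N(0, Sigma) via Cholesky
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  matrix(rnorm(n * p), n, p) %*% chol(Sigma)
}

#' Simulate sample metadata with nested structure and MCAR missingness
#'
#' Site-level environmental latents are drawn multivariate normal with the
#' configured covariance and shared by all samples of a site, plus small
#' within-site noise.  Latents are mapped to realistic units (ages log-normal
#' in kyr, pH near neutral, carbon/nitrogen percentages strictly positive).
#' `age_class` derives from simulated age (>= 11.7 kyr is Pleistocene), and
#' the positive age-depth-pH covariance reproduces the age-class confounding
#' of field data.  Missingness is applied completely at random at
#' `missing_rate` to the numeric fields.
#'
#' @param cfg A [sim_config()].
#' @return A list with `meta` (validated metadata tibble) and `truth` (a
#'   `sim_truth` list holding site latents, pre-missingness pH and site-level
#'   true cluster labels; never read by analysis stages).
#' @export
simulate_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  n_sites <- cfg$n_continents * cfg$n_regions_per_continent * cfg$n_sites_per_region
  site_tbl <- tidyr::expand_grid(
    continent = sprintf("C%d", seq_len(cfg$n_continents)),
    region_i = seq_len(cfg$n_regions_per_continent),
    site_i = seq_len(cfg$n_sites_per_region)) %>%
    mutate(region = sprintf("%s_R%d", .data$continent, .data$region_i),
           site = sprintf("%s_S%d", .data$region, .data$site_i)) %>%
    select("continent", "region", "site")

  Z_site <- rmvn(n_sites, cfg$env_covariance)
  colnames(Z_site) <- ENV_VARS
  rownames(Z_site) <- site_tbl$site

  meta <- site_tbl[rep(seq_len(n_sites), each = cfg$n_samples_per_site), ]
  Z <- Z_site[rep(seq_len(n_sites), each = cfg$n_samples_per_site), , drop = FALSE] +
    matrix(rnorm(nrow(meta) * length(ENV_VARS), sd = 0.2),
           nrow(meta), length(ENV_VARS))
  meta$sample_id <- sprintf("%s_%02d", meta$site,
                            sequence(rep(cfg$n_samples_per_site, n_sites)))

  # map standardized latents to field units
  env <- tibble::tibble(
    latitude   = pmin(90, pmax(-90, 70 + 4 * Z[, "latitude"])),
    longitude  = -100 + 60 * Z[, "longitude"],
    elevation  = 300 + 150 * Z[, "elevation"],
    age        = exp(2.3 + 1.1 * Z[, "age"]),
    depth      = exp(1.0 + 1.0 * Z[, "depth"]),
    total_c    = exp(1.0 + 0.9 * Z[, "total_c"]),
    total_n    = exp(-1.5 + 0.8 * Z[, "total_n"]),
    cn_ratio   = exp(2.5 + 0.4 * Z[, "cn_ratio"]),
    organic_c  = exp(1.0 + 1.0 * Z[, "organic_c"]),
    ph         = pmin(9.5, pmax(3.5, 6.5 + 1.0 * Z[, "ph"])),
    ice_content = exp(-0.8 + 0.6 * Z[, "ice_content"]),
    ec         = exp(3.0 + 1.0 * Z[, "ec"]))
  meta <- bind_cols(meta, env)
  meta$age_class <- ifelse(meta$age >= 11.7, "Pleistocene", "Holocene")

  ph_full <- setNames(meta$ph, meta$sample_id)
  site_ph <- tapply(meta$ph, meta$site, mean)[site_tbl$site]
  site_depth <- tapply(meta$depth, meta$site, mean)[site_tbl$site]
  archaea_sites <- site_tbl$site[site_ph > 7 & site_depth > median(site_depth)]
  if (length(archaea_sites) < 2) {
    archaea_sites <- site_tbl$site[order(-(scale(site_ph) + scale(site_depth)))][1:2]
  }
  true_cluster <- ifelse(site_tbl$site %in% archaea_sites, "archaeal",
                         ifelse(site_ph > median(site_ph), "alkaline", "acidic"))

  # MCAR missingness on the numeric fields
  if (cfg$missing_rate > 0) {
    for (v in ENV_VARS) {
      drop <- runif(nrow(meta)) < cfg$missing_rate
      meta[[v]][drop] <- NA_real_
    }
  }
  meta <- validate_metadata(meta[, c("sample_id", "continent", "region", "site",
                                     ENV_VARS, "age_class")])
  truth <- structure(list(env_latents = Z_site,
                          ph_full = ph_full,
                          archaea_sites = archaea_sites,
                          true_cluster_labels = setNames(true_cluster, site_tbl$site)),
                     class = "sim_truth")
  list(meta = meta, truth = truth)
}

#' Simulate a gene count matrix with planted variable genes
#'
#' Counts are negative binomial, `NB(mean = library_size x baseline_g x
#' 2^(site effect), dispersion alpha_g)` with variance `mu + alpha mu^2`.
#' Library sizes are log-normal; per-gene dispersions gamma-distributed.
#' Non-planted genes have zero site effect ("housekeeping").  Planted genes
#' carry site-level log2 effects: most follow a standardized random site
#' pattern scaled by `effect_size`; a designated "archaea-like" block (about
#' a third of the planted genes) has a strong positive effect only in the
#' high-pH, deep sites recorded in the truth object, so sample clustering has
#' recoverable structure.
#'
#' @param cfg A [sim_config()].
#' @param meta,truth Output of [simulate_metadata()].
#' @return A list with `counts` (integer count tibble), `annotation` (a
#'   feature-to-set table in which the archaea-like block shares one set) and
#'   `truth` (the input truth extended with `planted_gene_ids` and the
#'   site-by-planted-gene `site_effect_matrix` on the log2 scale).
#' @export
simulate_gene_counts <- function(cfg, meta, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  withr::local_seed(cfg$seed + 1L)
  G <- cfg$n_genes
  gene_ids <- sprintf("K%05d", seq_len(G))
  sites <- sort(unique(meta$site))
  n_sites <- length(sites)

  n_pl <- cfg$n_planted_variable_genes
  planted <- if (n_pl > 0) sample(gene_ids, n_pl) else character()
  n_arch <- if (n_pl > 0) max(1L, floor(n_pl / 3)) else 0L
  archaea_genes <- head(planted, n_arch)

  E <- matrix(0, n_sites, n_pl, dimnames = list(sites, planted))
  for (g in planted) {
    if (g %in% archaea_genes) {
      E[truth$archaea_sites, g] <- 2 * cfg$effect_size
    } else {
      w <- rnorm(n_sites)
      w <- as.numeric(scale(w))          # mean 0, sd 1 across sites
      E[, g] <- cfg$effect_size * w
    }
  }

  baseline <- rlnorm(G, 0, 0.5)
  baseline <- baseline / sum(baseline)
  alpha <- rgamma(G, shape = cfg$nb_dispersion_shape, rate = cfg$nb_dispersion_rate)
  libsize <- rlnorm(nrow(meta), cfg$library_size_meanlog, cfg$library_size_sdlog)

  lfc <- matrix(0, nrow(meta), G, dimnames = list(meta$sample_id, gene_ids))
  if (n_pl > 0) lfc[, planted] <- E[meta$site, , drop = FALSE]
  mu <- libsize * sweep(2^lfc, 2, baseline, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = rep(1 / pmax(alpha, 1e-8), each = nrow(meta))),
                   nrow(meta), G, dimnames = dimnames(mu))

  # annotation: every gene in 1-2 random pathways; archaea block shares one set
  n_sets <- max(8L, ceiling(G / 25))
  set_ids <- sprintf("path%02d", seq_len(n_sets))
  ann <- purrr::map_dfr(gene_ids, function(g) {
    tibble::tibble(feature_id = g,
                   set_id = sample(set_ids, sample(1:2, 1)),
                   set_kind = "pathway")
  })
  ann <- bind_rows(ann, tibble::tibble(feature_id = archaea_genes,
                                       set_id = "methanogenesis_like",
                                       set_kind = "module")) %>% distinct()

  truth$planted_gene_ids <- planted
  truth$site_effect_matrix <- E
  truth$archaea_gene_ids <- archaea_genes
  list(counts = validate_counts(matrix_to_counts(counts), mode = "counts"),
       annotation = ann, truth = truth)
}

#' Simulate a class-level taxa table with pH-unimodal diversity
#'
#' Per-sample class abundances are Dirichlet with concentration
#' `c(pH) = max(c_min, c_max - b (pH - 7)^2)`, a quadratic in pH peaking at
#' neutral: near pH 7 the Dirichlet is concentrated around an even base
#' composition (high expected Shannon diversity), while acidic or alkaline
#' samples draw sparse compositions (low diversity).  Pre-missingness pH
#' values from the truth record are used, so missing metadata cells do not
#' distort the community simulation.
#'
#' @param cfg A [sim_config()].
#' @param meta Metadata from [simulate_metadata()].
#' @param truth The matching `sim_truth` (for pre-missingness pH).
#' @param c_max,b,c_min Parameters of the quadratic concentration profile.
#' @return A relative-abundance tibble (rows sum to 1).
#' @export
simulate_taxa <- function(cfg, meta, truth, c_max = 30, b = 8, c_min = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed + 2L)
  k <- cfg$n_taxa_classes
  ph <- truth$ph_full[meta$sample_id]
  conc <- pmax(c_min, c_max - b * (ph - 7)^2)
  base <- rep(1 / k, k)
  taxa <- t(vapply(conc, function(cc) {
    g <- rgamma(k, shape = cc * base * k / sum(base * k))
    if (sum(g) == 0) g[sample.int(k, 1)] <- 1
    g / sum(g)
  }, numeric(k)))
  dimnames(taxa) <- list(meta$sample_id, sprintf("class%02d", seq_len(k)))
  validate_counts(matrix_to_counts(taxa), mode = "relabund")
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_metadata()],
#' [simulate_gene_counts()] and [simulate_taxa()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list with `meta`, `genes`, `taxa`, `annotation`, `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  md <- simulate_metadata(cfg)
  gc <- simulate_gene_counts(cfg, md$meta, md$truth)
  taxa <- simulate_taxa(cfg, md$meta, gc$truth)
  list(meta = md$meta, genes = gc$counts, taxa = taxa,
       annotation = gc$annotation, truth = gc$truth)
}
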