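# Configuration-driven pipeline runner: chains simulate, impute, pca,
# permancova, hvg, enrich, cluster, rda and diversity stages, writing
# per-stage TSV/JSON results plus a structured run log.

#' Default pipeline configuration
#'
#' A nested list (serializable as YAML) naming input paths, stage toggles,
#' seeds, permutation counts and the output directory.  Every stochastic
#' stage takes an explicit integer seed (default 1).
#'
#' @param outdir Output directory.
#' @return Config list.
#' @export
default_config <- function(outdir = "permagrad_results") {
  list(
    outdir = outdir,
    seed = 1L,
    inputs = list(metadata = NULL, genes = NULL, taxa = NULL,
                  annotation = NULL),
    stages = list(simulate = FALSE, impute = TRUE, pca = TRUE,
                  permancova = TRUE, hvg = TRUE, enrich = TRUE,
                  cluster = TRUE, rda = TRUE, diversity = TRUE),
    simulate = list(),                 # overrides for sim_config()
    impute = list(tol = 1e-6, max_iter = 5000),
    permancova = list(permutations = 999, covariate = "PC1",
                      interaction = TRUE),
    hvg = list(fraction = 0.05, threshold = 0.01, use_adjusted = TRUE),
    cluster = list(k_range = c(2, 8), restarts = 50),
    rda = list(permutations = 999))
}

#' Read a pipeline configuration file
#'
#' @param path YAML config file (see [default_config()] for the shape).
#' @return Config list, defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_config(), cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing per-stage TSV/JSON outputs
#' under `config$outdir` together with `run_log.json` (package version,
#' seeds, stage parameters, row/feature counts in and out of every filter,
#' and stage timings).  Missing required inputs for an enabled stage raise
#' an error before any stage runs.  Given the same config and seed the
#' output tables are identical between runs.
#'
#' @param config A config list ([default_config()]) or a YAML path.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- if (is.character(config)) read_config(config) else
    modifyList(default_config(), config)
  st <- cfg$stages

  # pre-flight: every enabled stage must have its inputs
  if (!isTRUE(st$simulate)) {
    need <- c(if (isTRUE(st$impute) || isTRUE(st$pca) || isTRUE(st$permancova) ||
                  isTRUE(st$cluster) || isTRUE(st$rda)) "metadata",
              if (isTRUE(st$permancova) || isTRUE(st$hvg)) "genes",
              if (isTRUE(st$rda) || isTRUE(st$diversity)) "taxa",
              if (isTRUE(st$enrich)) "annotation")
    for (k in unique(need)) {
      if (is.null(cfg$inputs[[k]])) {
        abort(sprintf("stage requires input '%s' but none configured", k))
      }
    }
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package_version = as.character(packageVersion("permagrad")),
              r_version = as.character(getRversion()),
              seed = cfg$seed, stages = list())
  res <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    log$stages[[name]] <<- c(log$stages[[name]],
                             list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    out
  }

  if (isTRUE(st$simulate)) {
    res$sim <- t_stage("simulate", {
      sim <- simulate_dataset(do.call(sim_config,
                                      c(cfg$simulate, list(seed = cfg$seed))))
      write_table(sim$meta, file.path(cfg$outdir, "metadata.tsv"))
      write_table(sim$genes, file.path(cfg$outdir, "gene_counts.tsv"))
      write_table(sim$taxa, file.path(cfg$outdir, "taxa_relabund.tsv"))
      write_table(sim$annotation, file.path(cfg$outdir, "annotation.tsv"))
      jsonlite::write_json(
        list(planted_gene_ids = sim$truth$planted_gene_ids,
             archaea_gene_ids = sim$truth$archaea_gene_ids,
             archaea_sites = sim$truth$archaea_sites,
             true_cluster_labels = as.list(sim$truth$true_cluster_labels)),
        file.path(cfg$outdir, "sim_truth.json"), auto_unbox = TRUE, digits = NA)
      sim
    })
    meta <- res$sim$meta; genes <- res$sim$genes; taxa <- res$sim$taxa
    ann <- res$sim$annotation
  } else {
    meta <- if (!is.null(cfg$inputs$metadata)) read_metadata(cfg$inputs$metadata)
    genes <- if (!is.null(cfg$inputs$genes)) read_counts(cfg$inputs$genes, "counts")
    taxa <- if (!is.null(cfg$inputs$taxa)) read_counts(cfg$inputs$taxa, "relabund")
    ann <- if (!is.null(cfg$inputs$annotation)) read_annotation(cfg$inputs$annotation)
  }

  if (isTRUE(st$impute)) {
    res$imputed <- t_stage("impute", {
      imp <- em_impute(normalize_env(meta), tol = cfg$impute$tol,
                       max_iter = cfg$impute$max_iter)
      write_table(matrix_to_counts(imp$x),
                  file.path(cfg$outdir, "env_imputed.tsv"))
      write_table(matrix_to_counts(imp$imputation_mask * 1),
                  file.path(cfg$outdir, "env_imputed_mask.tsv"))
      imp
    })
    log$stages$impute$n_imputed_cells <- sum(res$imputed$imputation_mask)
  }
  if (isTRUE(st$pca)) {
    res$pca <- t_stage("pca", {
      pca <- pca_correlation(res$imputed)
      jsonlite::write_json(
        list(loadings = as.data.frame(pca$loadings),
             eigenvalues = pca$eigenvalues, pct_variance = pca$pct_variance),
        file.path(cfg$outdir, "pca.json"), digits = NA)
      write_table(pc_scores(pca), file.path(cfg$outdir, "pc_scores.tsv"))
      pca
    })
  }
  if (isTRUE(st$permancova)) {
    res$permancova <- t_stage("permancova", {
      filt <- abundance_filter(genes)
      log$stages$permancova$filter <- as.list(attr(filt, "filter_report"))
      d <- bray_curtis(filt)
      covs <- pc_scores(res$pca, cfg$permancova$covariate)
      pm <- permancova(d, meta, covariates = covs,
                       include_interaction = isTRUE(cfg$permancova$interaction),
                       B = cfg$permancova$permutations, seed = cfg$seed)
      write_table(tidy(pm), file.path(cfg$outdir, "permancova.tsv"))
      jsonlite::write_json(tidy(pm), file.path(cfg$outdir, "permancova.json"),
                           digits = NA)
      pm
    })
  }
  if (isTRUE(st$hvg)) {
    res$hvg <- t_stage("hvg", {
      hv <- run_hvg(genes, meta, fraction = cfg$hvg$fraction,
                    threshold = cfg$hvg$threshold,
                    use_adjusted = isTRUE(cfg$hvg$use_adjusted))
      log$stages$hvg$filter <- as.list(attr(hv$filtered, "filter_report"))
      write_table(hv$scores, file.path(cfg$outdir, "hvg_scores.tsv"))
      writeLines(hv$selected, file.path(cfg$outdir, "hvg_selected.txt"))
      if (!is.null(hv$clusters)) {
        write_table(tibble::tibble(gene_id = names(hv$clusters$labels),
                                   ward_group = unname(hv$clusters$labels)),
                    file.path(cfg$outdir, "hvg_ward_groups.tsv"))
      }
      hv
    })
  }
  if (isTRUE(st$enrich) && !is.null(res$hvg$clusters)) {
    res$enrich <- t_stage("enrich", {
      en <- hypergeom_enrich(res$hvg$clusters$labels, ann)
      write_table(en, file.path(cfg$outdir, "enrichment.tsv"))
      jsonlite::write_json(en, file.path(cfg$outdir, "enrichment.json"),
                           digits = NA)
      en
    })
  }
  if (isTRUE(st$cluster)) {
    res$cluster <- t_stage("cluster", {
      sel <- res$hvg$selected
      m <- counts_to_matrix(res$hvg$filtered)
      rel <- m / rowSums(m)
      Xj <- apply(rel[, sel, drop = FALSE], 2,
                  function(v) johnson_transform(v)$y)
      rownames(Xj) <- rownames(rel)
      kr <- cfg$cluster$k_range
      cl_genes <- kmeans_elbow(Xj, k_range = seq(kr[1], kr[2]),
                               restarts = cfg$cluster$restarts, seed = cfg$seed)
      write_table(tidy(cl_genes), file.path(cfg$outdir, "sample_clusters_genes.tsv"))
      write_table(cl_genes$elbow, file.path(cfg$outdir, "elbow_genes.tsv"))
      out <- list(genes = cl_genes)
      if (!is.null(taxa)) {
        mt <- counts_to_matrix(taxa)
        Xt <- apply(mt, 2, function(v) {
          tryCatch(johnson_transform(v)$y, error = function(e) as.numeric(scale(v)))
        })
        rownames(Xt) <- rownames(mt)
        Xt <- Xt[, colSums(!is.finite(Xt)) == 0, drop = FALSE]
        cl_taxa <- kmeans_elbow(Xt, k_range = seq(kr[1], kr[2]),
                                restarts = cfg$cluster$restarts, seed = cfg$seed)
        write_table(tidy(cl_taxa), file.path(cfg$outdir, "sample_clusters_taxa.tsv"))
        agree <- kappa_agreement(
          setNames(cl_genes$assignments$cluster, cl_genes$assignments$sample_id),
          setNames(cl_taxa$assignments$cluster, cl_taxa$assignments$sample_id),
          seed = cfg$seed)
        jsonlite::write_json(
          c(as.list(tidy(agree)),
            list(contingency = as.data.frame(unclass(agree$contingency)))),
          file.path(cfg$outdir, "cluster_agreement.json"), auto_unbox = TRUE,
          digits = NA)
        out$taxa <- cl_taxa
        out$agreement <- agree
      }
      anovas <- purrr::map_dfr(intersect(ENV_VARS, names(meta)), function(v) {
        tryCatch(cluster_anova(tidy(cl_genes), meta, v), error = function(e) NULL)
      })
      write_table(anovas, file.path(cfg$outdir, "cluster_anova.tsv"))
      out$anova <- anovas
      out
    })
  }
  if (isTRUE(st$rda)) {
    res$rda <- t_stage("rda", {
      H <- hellinger(taxa)
      X <- as.data.frame(res$imputed$x)
      rda_sel <- rda_forward_select(H, X, B = cfg$rda$permutations,
                                    seed = cfg$seed)
      write_table(tidy(rda_sel), file.path(cfg$outdir, "rda_selection.tsv"))
      jsonlite::write_json(as.list(glance(rda_sel)),
                           file.path(cfg$outdir, "rda_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      rda_sel
    })
  }
  if (isTRUE(st$diversity)) {
    res$diversity <- t_stage("diversity", {
      div <- shannon_diversity(taxa)
      ph <- meta$ph[match(div$sample_id, meta$sample_id)]
      div$ph <- ph
      fit <- tryCatch(fit_unimodal_ph(div), error = function(e) NULL)
      write_table(div, file.path(cfg$outdir, "diversity.tsv"))
      if (!is.null(fit)) {
        jsonlite::write_json(
          c(list(b0 = fit$b0, b1 = fit$b1, b2 = fit$b2, m = fit$m),
            as.list(glance(fit))),
          file.path(cfg$outdir, "diversity_ph_fit.json"), auto_unbox = TRUE,
          digits = NA)
      }
      list(records = div, fit = fit)
    })
  }
  jsonlite::write_json(log, file.path(cfg$outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
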