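# Class-level taxonomic analyses: Shannon diversity, the unimodal
# diversity-pH model, per-taxon environmental regressions, the Hellinger
# transform, variance-inflation filtering, and constrained redundancy
# analysis with forward selection of environmental predictors.

#' Shannon diversity of a proportion vector
#'
#' `H = -sum p_i ln p_i` in nats; zero entries are skipped.  Proportions are
#' renormalized when their sum is within 1e-6 of 1, otherwise an error.
#'
#' @param p Non-negative proportions.
#' @return Shannon diversity in nats.
#' @export
shannon <- function(p) {
  if (any(p < 0)) abort("negative proportion")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) abort("proportions must sum to 1 (within 1e-6)")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample diversity records from a taxa table
#'
#' @param taxa Relative-abundance tibble (`sample_id` + class columns).
#' @return Tibble `sample_id`, `shannon` (nats), `richness` (classes with
#'   abundance > 0).
#' @export
shannon_diversity <- function(taxa) {
  m <- counts_to_matrix(taxa)
  tibble::tibble(sample_id = rownames(m),
                 shannon = unname(apply(m, 1, shannon)),
                 richness = unname(rowSums(m > 0)))
}

#' Centered-quadratic fit of diversity against pH
#'
#' Ordinary least squares of Shannon diversity on
#' `[1, pH, (pH - m)^2]` with `m` the mean pH of the fitted samples — the
#' centered-quadratic parameterization in which a negative quadratic
#' coefficient indicates a unimodal (peaked) diversity-pH relationship.
#' Samples from an excluded site (e.g. a known outlier location) can be
#' dropped and the model refit.
#'
#' @param data Data frame with columns `shannon` and `ph` (e.g.
#'   [shannon_diversity()] joined to metadata); rows with missing values are
#'   dropped.
#' @param exclude_samples Optional sample ids to exclude before fitting.
#' @return Object of class `"unimodal_fit"` with `b0`, `b1`, `b2`, `m`,
#'   `r_squared`, `p_model`, `n`, `excluded_samples` and the underlying
#'   `lm` fit.  `tidy()`/`glance()` give coefficient and model summaries.
#' @export
fit_unimodal_ph <- function(data, exclude_samples = NULL) {
  df <- as.data.frame(data)
  if (!is.null(exclude_samples) && "sample_id" %in% names(df)) {
    df <- df[!df$sample_id %in% exclude_samples, , drop = FALSE]
  }
  df <- df[is.finite(df$shannon) & is.finite(df$ph), , drop = FALSE]
  if (nrow(df) < 10) abort("need at least 10 samples with diversity and pH")
  if (length(unique(df$ph)) < 4) abort("need at least 4 distinct pH values")
  m <- mean(df$ph)
  if (var(df$shannon) < 1e-24) {
    # constant response: flat model, nothing explained
    return(structure(list(b0 = df$shannon[1], b1 = 0, b2 = 0, m = m,
                          r_squared = 0, p_model = 1, n = nrow(df),
                          excluded_samples = exclude_samples %||% character(),
                          fit = NULL, data = tibble::as_tibble(df)),
                     class = "unimodal_fit"))
  }
  fit <- lm(shannon ~ ph + I((ph - m)^2), data = df)
  sm <- suppressWarnings(summary(fit))   # exact fits are legitimate inputs
  fstat <- sm$fstatistic
  p_model <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]),
                 b2 = unname(coef(fit)[3]), m = m,
                 r_squared = sm$r.squared, p_model = p_model,
                 n = nrow(df), excluded_samples = exclude_samples %||% character(),
                 fit = fit, data = tibble::as_tibble(df)),
            class = "unimodal_fit")
}

#' @method tidy unimodal_fit
#' @export
tidy.unimodal_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "ph", "ph_centered_sq"),
                 estimate = c(x$b0, x$b1, x$b2))
}

#' @method glance unimodal_fit
#' @export
glance.unimodal_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_model = x$p_model, n = x$n,
                 centering_ph = x$m, peaked = x$b2 < 0)
}

#' @export
print.unimodal_fit <- function(x, ...) {
  cat(sprintf("Shannon = %.4g + %.4g*pH + %.4g*(pH - %.4g)^2  (R^2 = %.3f, p = %.3g, n = %d)\n",
              x$b0, x$b1, x$b2, x$m, x$r_squared, x$p_model, x$n))
  invisible(x)
}

#' Per-taxon environmental regressions
#'
#' Simple OLS of each taxon's relative abundance on each environmental
#' variable, with a two-sided slope test and BH adjustment across the full
#' taxon x variable family.  Pairs with a zero-variance predictor are
#' skipped with a log message.
#'
#' @param taxa Relative-abundance tibble.
#' @param meta Metadata tibble.
#' @param taxa_subset Taxon columns to test (default: all).
#' @param variables Environmental variables to test (default: latitude,
#'   depth, pH, total C, organic C, total N, EC, ice content).
#' @return Tibble `taxon`, `variable`, `slope`, `r_squared`, `p`,
#'   `bh_adjusted_p`, `n`.
#' @export
taxon_env_regressions <- function(taxa, meta,
                                  taxa_subset = NULL,
                                  variables = c("latitude", "depth", "ph",
                                                "total_c", "organic_c",
                                                "total_n", "ec", "ice_content")) {
  m <- counts_to_matrix(taxa)
  taxa_subset <- taxa_subset %||% colnames(m)
  meta <- meta[match(rownames(m), meta$sample_id), ]
  grid <- tidyr::expand_grid(taxon = taxa_subset, variable = variables)
  out <- purrr::pmap_dfr(grid, function(taxon, variable) {
    y <- m[, taxon]
    x <- meta[[variable]]
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0) {
      inform(sprintf("skipping %s ~ %s (degenerate predictor)", taxon, variable))
      return(NULL)
    }
    fit <- lm(y[ok] ~ x[ok])
    sm <- suppressWarnings(summary(fit))
    tibble::tibble(taxon = taxon, variable = variable,
                   slope = unname(coef(fit)[2]),
                   r_squared = sm$r.squared,
                   p = sm$coefficients[2, 4],
                   n = sum(ok))
  })
  out$bh_adjusted_p <- benjamini_hochberg(out$p)
  out
}

#' Hellinger transform
#'
#' `y'_ij = sqrt(y_ij / y_i.)`: square roots of row-relative abundances.
#' Transformed rows lie on the unit sphere, making the table suitable for
#' linear ordination methods such as RDA.
#'
#' @param taxa Abundance tibble; all-zero rows are an error.
#' @return Transformed tibble in the same layout.
#' @export
hellinger <- function(taxa) {
  m <- counts_to_matrix(taxa)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("all-zero sample row(s): %s",
                  paste(rownames(m)[rs == 0], collapse = ", ")))
  }
  matrix_to_counts(sqrt(m / rs))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` (with intercept) on the remaining predictors.  Perfectly collinear
#' predictors report `Inf`.
#'
#' @param x Numeric predictor matrix or data frame, >= 2 columns, `n > p`.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  X <- as.matrix(x)
  if (ncol(X) < 2) abort("need at least 2 predictors")
  if (nrow(X) <= ncol(X)) abort("need more rows than predictors")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Iterative VIF filtering
#'
#' Drops the highest-VIF predictor one at a time until all remaining VIFs
#' are at or below `threshold`.
#'
#' @param x Predictor matrix or data frame.
#' @param threshold VIF threshold (default 10).
#' @return List `kept` (column names), `dropped`, `vifs` (final values).
#' @export
vif_filter <- function(x, threshold = 10) {
  X <- as.data.frame(x)
  dropped <- character()
  while (ncol(X) >= 2) {
    v <- vif(X)
    if (max(v) <= threshold) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    X <- X[, setdiff(names(X), worst), drop = FALSE]
  }
  list(kept = names(X), dropped = dropped,
       vifs = if (ncol(X) >= 2) vif(X) else setNames(1, names(X)))
}

#' Redundancy analysis with VIF filtering and forward selection
#'
#' Applies iterative VIF filtering (threshold 10) to the candidate
#' environmental predictors, then forward selection on an RDA of the
#' (Hellinger-transformed) community table: candidates enter by adjusted
#' R^2 with a permutation entry test at 0.05, stopping when the running
#' adjusted R^2 would exceed that of the global all-candidates model
#' (vegan's `ordiR2step`).  Each selected predictor then receives a marginal
#' permutation test, BH/FDR-adjusted.
#'
#' @param y Community tibble (`sample_id` + columns), already Hellinger
#'   transformed (see [hellinger()]), or a plain numeric matrix.
#' @param x Candidate predictor data frame (numeric columns, complete).
#' @param B Permutations for entry and marginal tests (default 999).
#' @param seed Integer seed.
#' @param vif_threshold VIF threshold (default 10).
#' @param R2scope Enforce the global adjusted-R^2 ceiling on entry (vegan's
#'   default, TRUE).  With uninformative extra candidates the ceiling can sit
#'   below a true predictor's own adjusted R^2 and block all entry; set FALSE
#'   to select by entry test alone.
#' @return Object of class `"rda_selection"`: `selected` (tibble with
#'   selection order and adjusted R^2 path), `marginal_tests` (tibble with
#'   permutation p and FDR-adjusted p), `vif` (the VIF-filtering record),
#'   `constrained_inertia`, `total_inertia`, and the final vegan `rda` fit.
#' @export
rda_forward_select <- function(y, x, B = 999, seed = 1L, vif_threshold = 10,
                               R2scope = TRUE) {
  Y <- if (is.data.frame(y) && names(y)[1] == "sample_id") counts_to_matrix(y)
       else as.matrix(y)
  X <- as.data.frame(x)
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  if (anyNA(X)) abort("predictors must be complete (impute first)")
  vf <- vif_filter(X, threshold = vif_threshold)
  X <- X[, vf$kept, drop = FALSE]

  set.seed(seed)
  # ordiR2step re-evaluates rda() calls in the formula environment, so give
  # the formulas an environment that can see vegan and the data
  ev <- new.env(parent = asNamespace("vegan"))
  ev$Y <- Y
  ev$X <- X
  f0 <- stats::as.formula("Y ~ 1", env = ev)
  f1 <- stats::as.formula(paste("Y ~", paste(names(X), collapse = " + ")),
                          env = ev)
  m0 <- vegan::rda(f0, data = X)
  m1 <- vegan::rda(f1, data = X)
  sel <- vegan::ordiR2step(m0, scope = stats::formula(m1), direction = "forward",
                           permutations = B, trace = FALSE, R2scope = R2scope,
                           Pin = 0.05)
  steps <- if (!is.null(sel$anova)) {
    tibble::as_tibble(sel$anova, rownames = "step") %>%
      filter(.data$step != "<All variables>") %>%
      mutate(variable = sub("^\\+ ", "", .data$step)) %>%
      select("variable", adj_r_squared = "R2.adj", f = "F",
             entry_p = "Pr(>F)")
  } else {
    tibble::tibble(variable = character(), adj_r_squared = numeric(),
                   f = numeric(), entry_p = numeric())
  }

  final <- sel
  marginal <- tibble::tibble(variable = character(), f = numeric(),
                             p = numeric(), fdr_adjusted_p = numeric())
  if (nrow(steps) > 0) {
    av <- vegan::anova.cca(final, by = "margin", permutations = B)
    keep <- rownames(av) != "Residual"
    marginal <- tibble::tibble(variable = rownames(av)[keep],
                               f = av$F[keep], p = av$`Pr(>F)`[keep])
    marginal$fdr_adjusted_p <- benjamini_hochberg(marginal$p)
  }
  structure(list(selected = steps, marginal_tests = marginal, vif = vf,
                 constrained_inertia = if (is.null(final$CCA)) 0 else final$CCA$tot.chi,
                 total_inertia = final$tot.chi,
                 fit = final, n_permutations = B, seed = seed),
            class = "rda_selection")
}

#' @method tidy rda_selection
#' @export
tidy.rda_selection <- function(x, ...) {
  left_join(x$selected, x$marginal_tests, by = "variable",
            suffix = c("_entry", "_marginal"))
}

#' @method glance rda_selection
#' @export
glance.rda_selection <- function(x, ...) {
  tibble::tibble(n_selected = nrow(x$selected),
                 constrained_inertia = x$constrained_inertia,
                 total_inertia = x$total_inertia,
                 prop_constrained = x$constrained_inertia / x$total_inertia)
}
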