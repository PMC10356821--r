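# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col labs
#'   theme_minimal autoplot stat_function geom_vline
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot for an environmental PCA
#'
#' @param object An `env_pca` object.
#' @param components Two component names (default PC1, PC2).
#' @param ... Unused.
#' @return A ggplot of sample scores with percent variance in the labels.
#' @method autoplot env_pca
#' @export
autoplot.env_pca <- function(object, components = c("PC1", "PC2"), ...) {
  sc <- tibble::as_tibble(object$scores[, components, drop = FALSE],
                          rownames = "sample_id")
  idx <- match(components, colnames(object$loadings))
  ggplot(sc, aes(x = .data[[components[1]]], y = .data[[components[2]]])) +
    geom_point(alpha = 0.8) +
    labs(x = sprintf("%s (%.1f%%)", components[1], object$pct_variance[idx[1]]),
         y = sprintf("%s (%.1f%%)", components[2], object$pct_variance[idx[2]]),
         title = "Environmental PCA (correlation matrix), sample z-scores") +
    theme_minimal()
}

#' Elbow curve for k-means model selection
#'
#' @param object A `cluster_result` from [kmeans_elbow()].
#' @param ... Unused.
#' @return A ggplot of total within-cluster SS against k, with the chosen k
#'   marked.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot(object$elbow, aes(x = .data$k, y = .data$within_ss)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$k, linetype = "dashed") +
    labs(x = "k", y = "total within-cluster SS",
         title = sprintf("Elbow curve (chosen k = %d)", object$k)) +
    theme_minimal()
}

#' Diversity-pH scatter with the fitted unimodal curve
#'
#' @param object A `unimodal_fit` from [fit_unimodal_ph()].
#' @param ... Unused.
#' @return A ggplot of Shannon diversity against pH with the fitted
#'   centered-quadratic curve.
#' @method autoplot unimodal_fit
#' @export
autoplot.unimodal_fit <- function(object, ...) {
  b0 <- object$b0; b1 <- object$b1; b2 <- object$b2; m <- object$m
  ggplot(object$data, aes(x = .data$ph, y = .data$shannon)) +
    geom_point(alpha = 0.7) +
    stat_function(fun = function(x) b0 + b1 * x + b2 * (x - m)^2,
                  linewidth = 0.8) +
    labs(x = "pH", y = "Shannon diversity (nats)",
         title = "Class-level diversity against permafrost pH") +
    theme_minimal()
}

#' Variance-partition bar chart for a PERMANCOVA table
#'
#' @param object A `permancova` object.
#' @param ... Unused.
#' @return A ggplot of percent variation explained per term.
#' @method autoplot permancova
#' @export
autoplot.permancova <- function(object, ...) {
  tab <- object$table %>% filter(.data$term != "Total")
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot(tab, aes(x = .data$pct_variation, y = .data$term)) +
    geom_col() +
    labs(x = "% variation (sequential SS)", y = NULL,
         title = "PERMANCOVA variance partition") +
    theme_minimal()
}
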