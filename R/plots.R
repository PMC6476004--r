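#' Plot a set of spectra
#'
#' Overlays spectra coloured by group, with the conventional reversed ppm
#' axis.
#'
#' @param x An `nmr_spectra` object.
#' @param samples Optional subset of sample ids to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_spectra <- function(x, samples = NULL, ...) {
  d <- tidy(x)
  if (!is.null(samples)) d <- dplyr::filter(d, .data$sample_id %in% samples)
  ggplot2::ggplot(d, ggplot2::aes(.data$ppm, .data$intensity,
                                  group = .data$sample_id,
                                  colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.2, alpha = 0.7) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @method autoplot nmr_spectra
#' @export
autoplot.nmr_spectra <- function(object, ...) plot_spectra(object, ...)

#' Score plot for a latent-variable model
#'
#' First two components (PC1/PC2 or tp1 against the first orthogonal score
#' for single-predictive-component OPLS-DA), coloured by group.
#'
#' @param object An `nmr_latent` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmr_latent
#' @export
autoplot.nmr_latent <- function(object, ...) {
  sc <- object$scores
  if (ncol(sc) >= 2) {
    d <- tibble::tibble(x = sc[, 1], y = sc[, 2], group = object$group)
    labs <- colnames(sc)[1:2]
  } else {
    d <- tibble::tibble(x = sc[, 1],
                        y = if (!is.null(object$orth_scores) &&
                                ncol(object$orth_scores) >= 1)
                          object$orth_scores[, 1] else seq_len(nrow(sc)),
                        group = object$group)
    labs <- c(colnames(sc)[1], if (!is.null(object$orth_scores) &&
                                   ncol(object$orth_scores) >= 1)
      "to1" else "sample index")
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = toupper(object$kind)) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object An `nmr_roc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmr_roc
#' @export
autoplot.nmr_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Permutation-validation plot
#'
#' Permuted R2Y and Q2 against the correlation of the permuted class vector
#' with the original, with the observed model at correlation 1 and the
#' regression lines whose intercepts summarize overfitting.
#'
#' @param object An `nmr_permutation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmr_permutation
#' @export
autoplot.nmr_permutation <- function(object, ...) {
  d <- object$permutations |>
    tidyr::pivot_longer(c("r2y", "q2"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(.data$correlation, .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$observed), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "|cor(permuted y, y)|", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
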