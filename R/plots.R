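# ggplot2 displays for scans, importances, purge trajectories and PCA
# trajectories.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_ribbon
#'   facet_wrap labs theme_minimal geom_path geom_col
#' @export
ggplot2::autoplot

#' @describeIn window_null Smoothed FST track with the resampled null
#'   envelope; outlier points highlighted.
#' @param object A `hatch_window_scan`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hatch_window_scan <- function(object, ...) {
  pts <- object$points
  ggplot(pts, aes(x = .data$cM)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey80", alpha = 0.7) +
    geom_line(aes(y = .data$smoothed), colour = "firebrick") +
    geom_point(data = pts[pts$outlier, ], aes(y = .data$smoothed),
               colour = "firebrick", size = 1) +
    facet_wrap(~chromosome, scales = "free_x") +
    labs(x = "position (cM)", y = expression(F[ST]),
         title = "Kernel-smoothed FST with 95% resampled null envelope") +
    theme_minimal()
}

#' Plot a per-locus FST track with its smoothed moving average
#'
#' @param track A [fst_track()].
#' @param smoothed Optional [smooth_fst()] output for the same track.
#' @return A ggplot.
#' @export
plot_fst_track <- function(track, smoothed = NULL) {
  p <- ggplot(dplyr::filter(track, !is.na(.data$cM)),
              aes(x = .data$cM, y = .data$theta)) +
    geom_point(alpha = 0.4, size = 0.6) +
    facet_wrap(~chromosome, scales = "free_x") +
    labs(x = "position (cM)", y = expression(theta)) +
    theme_minimal()
  if (!is.null(smoothed)) {
    p <- p + geom_line(data = smoothed, aes(y = .data$smoothed),
                       colour = "firebrick")
  }
  p
}

#' @describeIn grow_importances Top locus importances as a bar chart.
#' @param object A `hatch_importance`.
#' @param n Number of top loci shown.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hatch_importance <- function(object, n = 30, ...) {
  top <- utils::head(object, n)
  top$locus <- factor(top$locus, levels = rev(top$locus))
  ggplot(top, aes(x = .data$importance, y = .data$locus)) +
    geom_col(fill = "steelblue") +
    labs(x = "mean permutation importance", y = NULL) +
    theme_minimal()
}

#' @describeIn backward_purge Purging trajectory: OOB metric against set
#'   size, best set marked.
#' @param object A `hatch_predictors`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hatch_predictors <- function(object, ...) {
  tr <- object$trajectory
  best <- tr[tr$size == length(object$loci), , drop = FALSE]
  ggplot(tr, aes(x = .data$size, y = .data$metric)) +
    geom_line() + geom_point(size = 0.8) +
    geom_point(data = best, colour = "firebrick", size = 2) +
    labs(x = "predictor set size", y = object$metric_kind,
         title = paste("Backward purging:", object$trait)) +
    theme_minimal()
}

#' @describeIn pca_trajectories Centroid trajectories of both lines across
#'   generations in PC space.
#' @param object A `hatch_pca`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hatch_pca <- function(object, ...) {
  ce <- object$centroids
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            colour = .data$line)) +
    geom_point(alpha = 0.2, size = 0.7) +
    geom_path(data = ce, aes(group = .data$line), linewidth = 0.8) +
    geom_point(data = ce, aes(size = .data$generation)) +
    labs(title = "Trait-associated loci: line trajectories in PC space") +
    theme_minimal()
}
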