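#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot of a chemical-profile PCA
#'
#' @param object A `chem_pca` object.
#' @param components Two component indices to plot.
#' @param group Optional tibble (`individual`, `group`) or named vector for
#'   point colour (e.g. sex).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chem_pca <- function(object, components = c(1, 2), group = NULL,
                              ...) {
  cols <- paste0("PC", components)
  d <- object$scores[c("individual", cols)]
  names(d) <- c("individual", "x", "y")
  if (!is.null(group)) {
    if (is.data.frame(group)) group <- stats::setNames(group$group,
                                                       group$individual)
    d$group <- as.character(group[d$individual])
  }
  lab <- sprintf("%s (%.1f%%)", cols,
                 100 * object$var_explained[components])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
  if (is.null(group)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Permutation-null plot of a dyadic test
#'
#' Histogram of the permuted statistics with the observed value marked;
#' requires the test to have been run with `keep_perms = TRUE`.
#'
#' @param object A `dyadic_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dyadic_test <- function(object, ...) {
  if (is.null(object$perms)) {
    stop("test was run with `keep_perms = FALSE`; nothing to plot",
         call. = FALSE)
  }
  d <- tibble::tibble(stat = object$perms)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = object$statistic,
      y = "permutations",
      title = sprintf("%s = %.3f, p = %s (%d permutations)",
                      object$statistic, object$observed,
                      format.pval(object$p_value, digits = 3),
                      object$n_perm)
    ) +
    ggplot2::theme_minimal()
}

#' Best BIO-ENV correlation by subset size
#'
#' @param object A `bioenv_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bioenv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$correlation)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = d$k) +
    ggplot2::labs(x = "subset size k", y = "best Mantel correlation") +
    ggplot2::theme_minimal()
}

#' Interaction plot of chemical response against MHC diversity
#'
#' Scatter of a per-individual response against diversity with per-group
#' least-squares lines, the presentation convention for diversity x sex and
#' diversity x breeding-status interactions.
#'
#' @param data Per-individual tibble.
#' @param response,diversity Column names.
#' @param by Grouping: `"sex"`, or `"status"` to cut breeding status at
#'   mean +/- 1 s.d. into early/mid/late thirds.
#' @param status Breeding-status column (for `by = "status"`).
#' @return A ggplot.
#' @export
plot_diversity_interaction <- function(data, response, diversity,
                                       by = c("sex", "status"),
                                       status = "breeding_status") {
  by <- match.arg(by)
  d <- tibble::tibble(
    x = data[[diversity]],
    y = data[[response]]
  )
  if (by == "sex") {
    d$group <- as.character(data$sex)
  } else {
    s <- data[[status]]
    cuts <- c(-Inf, mean(s) - stats::sd(s) / 2, mean(s) + stats::sd(s) / 2,
              Inf)
    d$group <- as.character(cut(s, cuts, labels = c("early", "mid",
                                                    "late")))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = diversity, y = response, colour = by) +
    ggplot2::theme_minimal()
}
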