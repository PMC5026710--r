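#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_boxplot geom_col
#'   geom_errorbar geom_point scale_fill_manual scale_fill_gradient labs
#'   theme_minimal position_dodge facet_wrap vars
NULL

shade_fill_values <- c(none = "white", verylight = "grey85",
                       light = "grey60", dark = "grey30")

#' Plot a residue propensity table
#'
#' Bar chart of per-residue propensities with the table shading categories
#' as fill; the dashed line marks propensity 1 (no enrichment).
#'
#' @param object A `propensity_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propensity_table
#' @export
autoplot.propensity_table <- function(object, ...) {
  d <- tidy(object)
  d$residue <- factor(d$residue, levels = aa_standard())
  ggplot(d, aes(x = residue, y = propensity, fill = shade)) +
    geom_col(colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    scale_fill_manual(values = shade_fill_values, drop = FALSE) +
    labs(x = "residue", y = "propensity",
         title = attr(object, "group") %||% NULL) +
    theme_minimal()
}

#' Plot a dyad propensity matrix
#'
#' Grey-shaded 20 x 20 matrix in the conventional orientation: N-side
#' residue on the vertical axis, C-side residue on the horizontal axis,
#' cells filled by shading category.
#'
#' @param object A `dyad_propensity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dyad_propensity
#' @export
autoplot.dyad_propensity <- function(object, ...) {
  d <- tidy(object)
  d$n_side <- factor(d$n_side, levels = rev(aa_standard()))
  d$c_side <- factor(d$c_side, levels = aa_standard())
  d$shade[is.na(d$shade)] <- "none"
  ggplot(d, aes(x = c_side, y = n_side, fill = shade)) +
    geom_tile(colour = "grey75") +
    scale_fill_manual(values = shade_fill_values, drop = FALSE) +
    labs(x = "C-side residue", y = "N-side residue",
         title = object$group %||% NULL) +
    theme_minimal()
}

#' Box plots of AI distributions per region class
#'
#' Mirrors the conventional presentation: one box per region class (wHTH,
#' AAT, all linkers, then length bins), Tukey whiskers, outliers as
#' points; facetted by scale (and phylum when stratified).
#'
#' @param object A `scale_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scale_profile
#' @export
autoplot.scale_profile <- function(object, ...) {
  d <- object$values[!is.na(object$values$ai), , drop = FALSE]
  p <- ggplot(d, aes(x = group, y = ai)) +
    geom_boxplot(outlier.size = 0.8, fill = "grey90") +
    labs(x = NULL, y = "AI (average index)") +
    theme_minimal()
  if (object$by_phylum) {
    p + facet_wrap(vars(.data$scale_id, .data$phylum), scales = "free_y")
  } else {
    p + facet_wrap(vars(.data$scale_id), scales = "free_y")
  }
}

#' Bar chart of a linker length histogram
#'
#' @param object A `length_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot length_histogram
#' @export
autoplot.length_histogram <- function(object, ...) {
  ggplot(object, aes(x = bin, y = percentage)) +
    geom_col(fill = "grey60", colour = "grey20") +
    labs(x = "linker length interval", y = "% of linkers",
         title = unique(object$subgroup)) +
    theme_minimal()
}

#' Side-by-side bar chart of two length histograms
#'
#' @param comparison Output of [compare_histograms()].
#' @return A ggplot object.
#' @export
plot_histogram_comparison <- function(comparison) {
  sets <- attr(comparison, "sets") %||% c(a = "A", b = "B")
  d <- tidyr::pivot_longer(
    comparison[, c("bin", "percent_a", "percent_b")],
    cols = c("percent_a", "percent_b"),
    names_to = "set", values_to = "percentage")
  d$set <- ifelse(d$set == "percent_a", sets[["a"]], sets[["b"]])
  ggplot(d, aes(x = bin, y = percentage, fill = set)) +
    geom_col(position = position_dodge(), colour = "grey20") +
    ggplot2::scale_fill_grey(start = 0.35, end = 0.75) +
    labs(x = "linker length interval", y = "% of linkers", fill = NULL) +
    theme_minimal()
}
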