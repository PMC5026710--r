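#' Binned linker-length histogram for a subgroup
#'
#' Bins linker lengths with the fine histogram scheme (`0-20`, `21-30`,
#' `31-40`, `41-50`, `51-60`, `>60`; closed integer intervals, `>60`
#' unbounded) and reports counts and percentages per bin.
#'
#' @param linker_set A `linker_set` tibble (needs `length`; `subgroup`
#'   used for filtering when `subgroup_label` is given).
#' @param subgroup_label Optional label (e.g. `"GabR"`): restrict to
#'   members of that subgroup.
#' @return A `length_histogram` tibble with columns `subgroup`, `bin`,
#'   `count`, `percentage` (summing to 100).
#' @export
#' @examples
#' ls <- tibble::tibble(id = c("a", "b", "c"), length = c(10L, 25L, 61L))
#' length_histogram(ls)
length_histogram <- function(linker_set, subgroup_label = NULL) {
  stopifnot("length" %in% names(linker_set))
  d <- linker_set
  if (!is.null(subgroup_label)) {
    d <- d[!is.na(d$subgroup) & d$subgroup == subgroup_label, , drop = FALSE]
  }
  if (!nrow(d)) abort("No linkers in the (sub)set; cannot build a histogram.")
  if (any(d$length < 0)) abort("Negative linker length.")
  sc <- bin_scheme("histogram")
  idx <- findInterval(d$length, c(-Inf, sc$breaks), left.open = TRUE)
  counts <- tabulate(idx, nbins = length(sc$labels))
  out <- tibble(
    subgroup = subgroup_label %||% NA_character_,
    bin = factor(sc$labels, levels = sc$labels, ordered = TRUE),
    count = as.integer(counts),
    percentage = 100 * counts / nrow(d))
  class(out) <- c("length_histogram", class(out))
  attr(out, "n") <- nrow(d)
  out
}

#' Compare two linker-length histograms side by side
#'
#' @param hist_a,hist_b `length_histogram`s on the same bin scheme.
#' @return A tibble with one row per bin: counts and percentages for both
#'   sets and their percentage difference; each set's modal bin is stored
#'   in the `modal_bins` attribute.
#' @export
compare_histograms <- function(hist_a, hist_b) {
  stopifnot(inherits(hist_a, "length_histogram"),
            inherits(hist_b, "length_histogram"))
  if (!identical(as.character(hist_a$bin), as.character(hist_b$bin))) {
    abort("Histograms use different bin schemes; cannot compare.")
  }
  name_of <- function(h, default) {
    s <- unique(h$subgroup)
    if (length(s) == 1 && !is.na(s)) s else default
  }
  na <- name_of(hist_a, "A"); nb <- name_of(hist_b, "B")
  out <- tibble(
    bin = hist_a$bin,
    count_a = hist_a$count, percent_a = hist_a$percentage,
    count_b = hist_b$count, percent_b = hist_b$percentage,
    percent_diff = hist_a$percentage - hist_b$percentage)
  attr(out, "sets") <- c(a = na, b = nb)
  attr(out, "modal_bins") <- c(
    a = as.character(hist_a$bin[which.max(hist_a$count)]),
    b = as.character(hist_b$bin[which.max(hist_b$count)]))
  out
}
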