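#' Average index (AI) of peptides under an amino-acid scale
#'
#' The AI of a region is the arithmetic mean of the scale's per-residue
#' values over its standard-letter residues. Ambiguity letters are
#' excluded; a region whose exclusions exceed `max_ambiguous` is flagged,
#' and a region left empty after exclusion yields `NA` (propagated, never
#' 0). AI is a pure composition statistic: it is invariant under residue
#' permutation, and an affine transform of the scale maps every AI by the
#' same affine transform.
#'
#' @param peptides Character vector of region strings (names, if any, are
#'   kept as ids).
#' @param scale A `scale_definition` from [read_scale()] / [mocr_scales()].
#' @param max_ambiguous Flag threshold on the excluded fraction.
#' @return A tibble with columns `id`, `ai`, `n_used`, `n_excluded`,
#'   `flagged`.
#' @export
#' @examples
#' sc <- scale_definition("toy", values = stats::setNames(1:20 / 20, aa_standard()))
#' region_average("AAAA", sc)$ai  # = sc$values[["A"]]
region_average <- function(peptides, scale, max_ambiguous = 0.2) {
  stopifnot(inherits(scale, "scale_definition"))
  ids <- names(peptides) %||% as.character(seq_along(peptides))
  rows <- map(seq_along(peptides), function(k) {
    ch <- split_residues(peptides[[k]])
    keep <- ch %in% aa_standard()
    n_used <- sum(keep)
    n_exc <- length(ch) - n_used
    ai <- if (n_used > 0) mean(scale$values[ch[keep]]) else NA_real_
    frac <- if (length(ch) > 0) n_exc / length(ch) else 0
    tibble(id = ids[k], ai = ai, n_used = n_used, n_excluded = n_exc,
           flagged = is.na(ai) | frac > max_ambiguous)
  })
  bind_rows(rows)
}

#' Scale profiles of domains and linkers
#'
#' For each scale, computes the AI of every wHTH domain, every AAT domain,
#' every linker (as one `linker` class) and every linker again under its
#' length bin, then summarises each group's AI distribution. Group order is
#' fixed as wHTH, AAT, linker, then bins ascending. Optionally stratified
#' by phylum.
#'
#' @param sequences An annotated sequence tibble with populated regions
#'   (e.g. from [generate_set()]).
#' @param linker_set A binned `linker_set` for the same ids (see
#'   [assign_length_bins()]); if `NULL`, linkers are taken from the
#'   sequences' `linker` regions and binned with the analysis scheme.
#' @param scales A named list of `scale_definition`s, e.g. [mocr_scales()].
#' @param by_phylum Stratify groups by phylum.
#' @return A `scale_profile` list with `values` (tibble `scale_id`, `id`,
#'   `phylum`, `group`, `ai`) and `summaries` (per group: `n`, five-number
#'   summary, Tukey whiskers, outlier count). Groups with no finite AI are
#'   omitted with a warning.
#' @export
profile_groups <- function(sequences, linker_set = NULL, scales = mocr_scales(),
                           by_phylum = FALSE) {
  stopifnot(is.list(scales), length(scales) > 0)
  if (is.null(names(scales))) {
    names(scales) <- map_chr(scales, function(s) s$accession)
  }
  if (is.null(linker_set)) {
    linkers <- map_chr(seq_len(nrow(sequences)), function(i)
      region_string(sequences$sequence[i], sequences$regions[[i]], "linker"))
    linker_set <- tibble(id = sequences$id, phylum = sequences$phylum,
                         subgroup = sequences$subgroup,
                         linker = linkers, length = nchar(linkers))
    linker_set <- assign_length_bins(linker_set, "analysis")
  } else if (!("bin" %in% names(linker_set))) {
    linker_set <- assign_length_bins(linker_set, "analysis")
  }
  seg <- function(nm) {
    v <- map_chr(seq_len(nrow(sequences)), function(i)
      region_string(sequences$sequence[i], sequences$regions[[i]], nm))
    tibble(id = sequences$id, phylum = sequences$phylum, group = nm,
           peptide = v)
  }
  members <- bind_rows(
    seg("wHTH"), seg("AAT"),
    tibble(id = linker_set$id, phylum = linker_set$phylum,
           group = "linker", peptide = linker_set$linker),
    tibble(id = linker_set$id, phylum = linker_set$phylum,
           group = as.character(linker_set$bin), peptide = linker_set$linker))
  members <- members[!is.na(members$peptide), , drop = FALSE]
  levels_order <- c("wHTH", "AAT", "linker",
                    bin_scheme(attr(linker_set, "bin_scheme") %||% "analysis")$labels)
  values <- bind_rows(imap(scales, function(sc, nm) {
    av <- region_average(members$peptide, sc)
    tibble(scale_id = nm, id = members$id, phylum = members$phylum,
           group = factor(members$group, levels = levels_order),
           ai = av$ai, flagged = av$flagged)
  }))
  grp_cols <- c("scale_id", if (by_phylum) "phylum", "group")
  finite <- values[!is.na(values$ai), , drop = FALSE]
  n_groups_all <- nrow(distinct(values[, grp_cols]))
  summaries <- finite |>
    group_by(across(all_of(grp_cols))) |>
    summarise(five_num_summary(ai), .groups = "drop") |>
    arrange(across(all_of(grp_cols)))
  if (nrow(summaries) < n_groups_all) {
    warn(sprintf("%d group(s) had no finite AI values and were omitted.",
                 n_groups_all - nrow(summaries)))
  }
  structure(list(values = values, summaries = summaries,
                 scales = names(scales), by_phylum = by_phylum),
            class = "scale_profile")
}

# five-number summary + Tukey whiskers; quartiles by linear interpolation
# (stats::quantile type 7, the standard box-plot default)
five_num_summary <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  tibble(n = length(x), min = min(x), q1 = q[1], median = q[2], q3 = q[3],
         max = max(x),
         whisker_lo = min(inside), whisker_hi = max(inside),
         n_outliers = sum(x < lo_fence | x > hi_fence))
}

#' @export
print.scale_profile <- function(x, ...) {
  cat(sprintf("<scale_profile> %d scale(s), %d AI value(s)%s\n",
              length(x$scales), sum(!is.na(x$values$ai)),
              if (x$by_phylum) ", stratified by phylum" else ""))
  print(x$summaries, n = 12)
  invisible(x)
}

#' Box-plot-ready table from a scale profile
#'
#' One row per group per scale (per phylum when stratified): quartiles,
#' Tukey whiskers (most extreme data within 1.5 x IQR of the box) and the
#' outliers beyond them as a list-column.
#'
#' @param profile A `scale_profile` from [profile_groups()].
#' @return A tibble with `scale_id`, (`phylum`,) `group`, `q1`, `median`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `outliers` (list of numeric).
#' @export
summary_to_boxplot_data <- function(profile) {
  stopifnot(inherits(profile, "scale_profile"))
  s <- profile$summaries
  grp_cols <- intersect(c("scale_id", "phylum", "group"), names(s))
  vals <- profile$values[!is.na(profile$values$ai), , drop = FALSE]
  s$outliers <- map(seq_len(nrow(s)), function(i) {
    sel <- rep(TRUE, nrow(vals))
    for (g in grp_cols) sel <- sel & (as.character(vals[[g]]) == as.character(s[[g]][i]))
    v <- vals$ai[sel]
    v[v < s$whisker_lo[i] | v > s$whisker_hi[i]]
  })
  s[, c(grp_cols, "n", "q1", "median", "q3", "whisker_lo", "whisker_hi",
        "outliers")]
}
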