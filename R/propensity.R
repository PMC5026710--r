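#' Residue frequencies of a peptide pool
#'
#' Pools all residues of the input and returns the relative frequency of
#' each of the 20 standard letters. Ambiguity letters (B/Z/X/U/O) are
#' excluded from both numerator and denominator; the exclusion count is
#' recorded.
#'
#' @param x A `linker_set` tibble (its `linker` column is pooled), an
#'   annotated sequence tibble (`region` selects which region to pool), or
#'   a plain character vector of peptides.
#' @param region For annotated input: `"linker"`, `"wHTH"`, `"AAT"` or
#'   `"full"` (whole sequences).
#' @return A tibble with columns `residue`, `count`, `frequency` (20 rows,
#'   canonical order) and attributes `n_residues`, `n_excluded`.
#' @export
#' @examples
#' residue_frequencies(c("AAAB"))  # B excluded: f(A) = 1, n = 3
residue_frequencies <- function(x, region = "linker") {
  pool <- pool_residues(x, region)
  dropped <- drop_ambiguous(pool)
  if (dropped$n_excluded > 0) {
    inform(sprintf("Excluded %d ambiguity residue(s) from the pool.",
                   dropped$n_excluded))
  }
  kept <- dropped$kept
  if (!length(kept)) abort("Residue pool is empty after ambiguity exclusion.")
  counts <- table(factor(kept, levels = aa_standard()))
  out <- tibble(residue = aa_standard(),
                count = as.integer(counts),
                frequency = as.numeric(counts) / length(kept))
  attr(out, "n_residues") <- length(kept)
  attr(out, "n_excluded") <- dropped$n_excluded
  out
}

pool_residues <- function(x, region = "linker") {
  if (is.character(x)) return(split_residues(paste(x, collapse = "")))
  stopifnot(is.data.frame(x))
  if ("linker" %in% names(x) && region == "linker") {
    return(split_residues(paste(x$linker, collapse = "")))
  }
  if ("sequence" %in% names(x)) {
    if (region == "full") return(split_residues(paste(x$sequence, collapse = "")))
    stopifnot("regions" %in% names(x))
    segs <- map_chr(seq_len(nrow(x)), function(i)
      region_string(x$sequence[i], x$regions[[i]], region))
    return(split_residues(paste(segs[!is.na(segs)], collapse = "")))
  }
  abort("Cannot locate a residue pool in `x`.")
}

#' Residue propensities relative to a reference composition
#'
#' The propensity of residue *i* is `p_i = f_linker(i) / f_ref(i)`: 1 means
#' no enrichment relative to the reference. Cells are shaded with the
#' conventional categories of the propensity tables — light grey for
#' `1.01 <= p <= 1.19`, dark grey for `p >= 1.20` — assigned after rounding
#' to the tables' 2-decimal print precision.
#'
#' @param linker_freq Frequencies of the linker pool, from
#'   [residue_frequencies()].
#' @param ref_freq Reference composition: a frequency tibble, or a named
#'   numeric vector over the 20 letters (e.g. [aa_background()], or the
#'   pooled full-protein composition of the same set — the package default
#'   reference, see [pooled_reference()]).
#' @param group Optional label (e.g. "Firmicutes 21-40") carried as an
#'   attribute.
#' @return A `propensity_table` tibble with columns `residue`, `frequency`,
#'   `ref_frequency`, `propensity`, `shade`, and attributes `n_residues`,
#'   `group`. Letters absent from the linker pool get propensity 0; a letter
#'   observed in the linker pool but absent from the reference is an error
#'   (it signals an inadequate reference sample).
#' @export
#' @examples
#' lf <- residue_frequencies("PPAA")
#' residue_propensities(lf, aa_background())
residue_propensities <- function(linker_freq, ref_freq, group = NULL) {
  f <- as_freq_vector(linker_freq)
  r <- as_freq_vector(ref_freq)
  bad <- names(f)[f > 0 & r <= 0]
  if (length(bad)) {
    abort(sprintf(
      "Letter(s) %s observed in the linker pool but absent from the reference.",
      paste(bad, collapse = ", ")))
  }
  p <- ifelse(f == 0, 0, f / ifelse(r > 0, r, NA_real_))
  out <- tibble(residue = aa_standard(),
                frequency = unname(f),
                ref_frequency = unname(r),
                propensity = unname(p),
                shade = shade_residue(p))
  attr(out, "n_residues") <- attr(linker_freq, "n_residues")
  attr(out, "group") <- group
  class(out) <- c("propensity_table", class(out))
  out
}

as_freq_vector <- function(x) {
  if (is.data.frame(x)) x <- setNames(x$frequency, x$residue)
  stopifnot(is.numeric(x))
  if (!setequal(names(x), aa_standard())) {
    abort("Frequencies must be keyed by the 20 standard letters.")
  }
  x[aa_standard()]
}

#' Categorical shading of propensity values
#'
#' Residue tables: light grey for values in `[1.01, 1.19]`, dark grey for
#' `>= 1.20`. Dyad matrices: very light for `[1.10, 1.99]`, light for
#' `[2.00, 3.99]`, dark for `>= 4.00`. Values are rounded to 2 decimals
#' (the tables' print precision) before classification, so the category is
#' a pure function of the printed value.
#'
#' @param p Numeric propensity values.
#' @return A character vector of categories: `none`/`light`/`dark` for
#'   residues, `none`/`verylight`/`light`/`dark` for dyads. `NA` propagates.
#' @export
#' @examples
#' shade_residue(c(1.00, 1.01, 1.19, 1.20))
#' shade_dyad(c(1.09, 1.10, 1.99, 2.00, 3.99, 4.00))
shade_residue <- function(p) {
  p2 <- round(p, 2)
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p2)
  out[ok] <- ifelse(p2[ok] >= 1.20, "dark",
                    ifelse(p2[ok] >= 1.01, "light", "none"))
  out
}

#' @rdname shade_residue
#' @export
shade_dyad <- function(p) {
  p2 <- round(p, 2)
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p2)
  out[ok] <- ifelse(p2[ok] >= 4.00, "dark",
                    ifelse(p2[ok] >= 2.00, "light",
                           ifelse(p2[ok] >= 1.10, "verylight", "none")))
  out
}

#' Pooled full-protein reference composition
#'
#' The package's default reference for residue propensities: the pooled
#' composition of the full-length sequences (wHTH + linker + AAT) of the
#' same input set, so that propensities measure linker-versus-protein
#' enrichment. Any other reference (e.g. [aa_background()] or a
#' user-supplied table) can be passed to [residue_propensities()] instead.
#'
#' @param sequences An annotated sequence tibble.
#' @return A frequency tibble as from [residue_frequencies()].
#' @export
pooled_reference <- function(sequences) {
  residue_frequencies(sequences, region = "full")
}

# -- dyads --------------------------------------------------------------------

#' Count residue dyads (adjacent ordered pairs) in a peptide set
#'
#' Counts overlapping windows of width 2 within each peptide, never across
#' peptide boundaries: a peptide of length L contributes at most L - 1
#' dyads. Windows containing an ambiguity letter are skipped. Row index is
#' the N-side residue, column index the C-side residue.
#'
#' @param peptides Character vector of peptides, or a `linker_set` tibble.
#' @return A `dyad_counts` list: `counts` (20 x 20 integer matrix),
#'   `per_peptide` (tibble `id`, `n_pairs` of counted windows per peptide),
#'   `n_total`, `n_skipped` (windows dropped for ambiguity letters).
#' @export
#' @examples
#' count_dyads("AKAK")$counts["A", "K"]  # 2
count_dyads <- function(peptides) {
  ids <- NULL
  if (is.data.frame(peptides)) {
    ids <- peptides$id
    peptides <- peptides$linker
  }
  ids <- ids %||% as.character(seq_along(peptides))
  counts <- matrix(0L, 20, 20, dimnames = list(aa_standard(), aa_standard()))
  per <- integer(length(peptides))
  skipped <- 0L
  std <- aa_standard()
  for (k in seq_along(peptides)) {
    ch <- split_residues(peptides[k])
    if (length(ch) < 2L) next
    a <- ch[-length(ch)]; b <- ch[-1L]
    ok <- a %in% std & b %in% std
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      t2 <- table(factor(a[ok], levels = std), factor(b[ok], levels = std))
      counts <- counts + matrix(as.integer(t2), 20L, 20L)
    }
    per[k] <- sum(ok)
  }
  structure(list(counts = counts,
                 per_peptide = tibble(id = ids, n_pairs = per),
                 n_total = sum(counts), n_skipped = skipped),
            class = "dyad_counts")
}

#' @export
print.dyad_counts <- function(x, ...) {
  cat(sprintf("<dyad_counts> %d dyads over %d peptide(s); %d window(s) skipped\n",
              x$n_total, nrow(x$per_peptide), x$n_skipped))
  invisible(x)
}

#' Dyad propensities with a compositional or uniform expectation
#'
#' Observed dyad frequencies are compared with an expectation model:
#' `marginal_product` (default) expects `f(i) * f(j)` — deviation from
#' compositional independence — while `uniform` expects `1/400` for every
#' cell. Cells are shaded with the dyad-matrix conventions: very light
#' grey for propensities in `[1.10, 1.99]`, light for `[2.00, 3.99]`, dark
#' for `>= 4.00`. Cells with zero expected frequency are undefined (`NA`),
#' not 0 or infinite.
#'
#' @param counts A `dyad_counts` object from [count_dyads()], or a bare
#'   20 x 20 count matrix.
#' @param model `"marginal_product"` or `"uniform"`.
#' @param marginals Single-residue frequencies for the marginal-product
#'   expectation: by default the marginal composition of the counted dyads
#'   themselves; pass a named vector (e.g. [aa_background()]) to judge
#'   enrichment against an external composition.
#' @param group Optional label carried as an attribute.
#' @return A `dyad_propensity` list: `counts`, `observed`, `expected`,
#'   `propensity` (20 x 20 matrices, N-side rows / C-side columns), `shade`
#'   (character matrix), `model`, `n_total`.
#' @export
#' @examples
#' dp <- dyad_propensities(count_dyads("AA"))
#' dp$propensity["A", "A"]  # 1
dyad_propensities <- function(counts, model = c("marginal_product", "uniform"),
                              marginals = NULL, group = NULL) {
  model <- match.arg(model)
  cm <- if (inherits(counts, "dyad_counts")) counts$counts else counts
  stopifnot(is.matrix(cm), all(dim(cm) == c(20L, 20L)))
  if (any(cm < 0)) abort("Negative dyad counts.")
  total <- sum(cm)
  observed <- if (total > 0) cm / total else matrix(NA_real_, 20, 20,
                                                    dimnames = dimnames(cm))
  if (model == "uniform") {
    expected <- matrix(1 / 400, 20, 20, dimnames = dimnames(cm))
  } else {
    m <- if (is.null(marginals)) {
      if (total == 0) abort("Cannot derive marginals from an empty count matrix.")
      (rowSums(cm) + colSums(cm)) / (2 * total)
    } else {
      as_freq_vector(marginals)
    }
    expected <- outer(m, m)
    dimnames(expected) <- dimnames(cm)
  }
  propensity <- ifelse(expected > 0, observed / expected, NA_real_)
  shade <- matrix(shade_dyad(as.vector(propensity)), 20, 20,
                  dimnames = dimnames(cm))
  structure(list(counts = cm, observed = observed, expected = expected,
                 propensity = propensity, shade = shade,
                 model = model, n_total = total, group = group),
            class = "dyad_propensity")
}

#' @export
print.dyad_propensity <- function(x, ...) {
  cat(sprintf("<dyad_propensity> %d dyads, expectation model '%s'\n",
              x$n_total, x$model))
  nshade <- table(factor(x$shade, levels = c("none", "verylight", "light", "dark")))
  cat("  shaded cells:", paste(names(nshade), nshade, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Mean number of residue pairs per linker, by group
#'
#' Summarises the per-linker dyad counts as mean and sample standard
#' deviation (n - 1 denominator) within each phylum x length-bin cell,
#' formatted `"m±s"` to one decimal. A large mean signals a large pooled
#' dyad sample, hence more reliable dyad propensities for that cell.
#'
#' @param linker_set A binned `linker_set` (see [assign_length_bins()]).
#' @param by Grouping columns; default `c("phylum", "bin")`. Use
#'   `character(0)` for a single overall cell.
#' @return A tibble with the grouping columns plus `n_linkers`,
#'   `mean_pairs`, `sd_pairs`, `label`. Empty cells are absent (not 0).
#' @export
#' @examples
#' ls <- tibble::tibble(id = c("a", "b"), phylum = "Firmicutes",
#'                      subgroup = NA, linker = c("AKAK", "AK"),
#'                      length = c(4L, 2L))
#' pairs_summary(ls, by = "phylum")$label  # "2.0±1.4"
pairs_summary <- function(linker_set, by = c("phylum", "bin")) {
  stopifnot(is.data.frame(linker_set), "linker" %in% names(linker_set))
  dc <- count_dyads(linker_set)
  d <- linker_set
  d$n_pairs <- dc$per_peptide$n_pairs
  grouped <- if (length(by)) group_by(d, across(all_of(by))) else d
  out <- summarise(grouped,
                   n_linkers = n(),
                   mean_pairs = mean(n_pairs),
                   sd_pairs = if (n() > 1L) sd(n_pairs) else 0,
                   .groups = "drop")
  out$label <- sprintf("%.1f±%.1f", out$mean_pairs, out$sd_pairs)
  out
}
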