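#' Extract linker peptides by domain-boundary coordinates
#'
#' Slices each sequence at its boundary record: the linker is the 1-based
#' half-open interval `[start, end)`, i.e. `start` is the first linker
#' residue and `end` the first residue of the AAT domain, so
#' `length = end - start`. Boundary rows with no matching sequence, and
#' sequences with no boundary row, are skipped with a warning (or an error
#' for missing boundary ids under `strict = TRUE`).
#'
#' @param sequences A tibble with `id` and `sequence` columns (optionally
#'   `phylum`, `subgroup`), e.g. from [read_fasta()] or [generate_set()].
#' @param boundaries A boundary table from [read_boundary_table()] (columns
#'   `id`, `start`, `end`).
#' @param strict Error instead of warn when a boundary id has no sequence.
#' @return A `linker_set` tibble with columns `id`, `phylum`, `subgroup`,
#'   `linker`, `length`, one row per matched boundary record, plus
#'   `n_skipped_boundaries` / `n_unmatched_sequences` attributes.
#' @export
#' @examples
#' seqs <- annotated_sequences("s1", strrep("A", 200))
#' b <- tibble::tibble(id = "s1", start = 88L, end = 148L)
#' extract_by_coordinates(seqs, b)$length
extract_by_coordinates <- function(sequences, boundaries, strict = FALSE) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)),
            all(c("id", "start", "end") %in% names(boundaries)))
  missing_ids <- setdiff(boundaries$id, sequences$id)
  if (length(missing_ids)) {
    msg <- sprintf("%d boundary id(s) absent from the sequence set: %s",
                   length(missing_ids),
                   paste(head(missing_ids, 5), collapse = ", "))
    if (strict) abort(msg) else warn(paste0(msg, " (skipped)"))
  }
  unmatched_seq <- setdiff(sequences$id, boundaries$id)
  if (length(unmatched_seq)) {
    warn(sprintf("%d sequence(s) have no boundary row and were skipped.",
                 length(unmatched_seq)))
  }
  b <- boundaries[boundaries$id %in% sequences$id, , drop = FALSE]
  idx <- match(b$id, sequences$id)
  seq_n <- nchar(sequences$sequence[idx])
  too_far <- b$end > seq_n + 1L
  if (any(too_far)) {
    abort(sprintf("Boundary end exceeds sequence length + 1 for: %s",
                  paste(head(b$id[too_far], 5), collapse = ", ")))
  }
  if (any(b$start < 1L)) abort("Boundary start must be >= 1.")
  get_col <- function(nm) {
    if (nm %in% names(sequences)) as.character(sequences[[nm]][idx]) else
      rep(NA_character_, nrow(b))
  }
  out <- tibble(
    id = b$id,
    phylum = get_col("phylum"),
    subgroup = get_col("subgroup"),
    linker = substr(sequences$sequence[idx], b$start, b$end - 1L),
    length = as.integer(b$end - b$start)
  )
  attr(out, "n_skipped_boundaries") <- length(missing_ids)
  attr(out, "n_unmatched_sequences") <- length(unmatched_seq)
  class(out) <- c("linker_set", class(out))
  out
}

#' Map residue coordinates on an alignment row to alignment columns
#'
#' Converts a 1-based half-open residue interval `[start, end)` on the
#' degapped sequence of one alignment row into the minimal 1-based half-open
#' alignment-column interval whose degapped content in that row is exactly
#' the residue interval.
#'
#' @param alignment A tibble from [read_aligned_fasta()] (columns `id`,
#'   `alignment`).
#' @param row_id Which row to map on.
#' @param start,end Residue coordinates on the degapped row.
#' @return Integer vector `c(col_start, col_end)`.
#' @export
#' @examples
#' aln <- tibble::tibble(id = "a", alignment = "M-KV")
#' map_reference_to_columns(aln, "a", 2, 3)  # residue "K" -> columns [3, 4)
map_reference_to_columns <- function(alignment, row_id, start, end) {
  i <- match(row_id, alignment$id)
  if (is.na(i)) abort(sprintf("Row '%s' not in the alignment.", row_id))
  chars <- split_residues(alignment$alignment[i])
  res_cols <- which(chars != "-")
  n_res <- length(res_cols)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) abort("Require 1 <= start <= end.")
  if (end > n_res + 1L) {
    abort(sprintf("Residue interval [%d, %d) exceeds the %d residues of row '%s'.",
                  start, end, n_res, row_id))
  }
  if (start == end) {
    col <- if (start <= n_res) res_cols[start] else length(chars) + 1L
    return(c(col_start = col, col_end = col))
  }
  c(col_start = res_cols[start], col_end = res_cols[end - 1L] + 1L)
}

#' Extract linkers from an alignment via a reference row's boundaries
#'
#' Computes the reference row's linker column window with
#' [map_reference_to_columns()], slices every alignment row at those
#' columns and degaps each slice. Per-row linker lengths may differ from
#' the reference (insertions/deletions within the window); rows that are
#' all-gap in the window yield empty linkers (length 0) and are retained.
#'
#' @param alignment A tibble with `id` and `alignment` columns.
#' @param reference_id Row carrying the trusted boundaries.
#' @param start,end 1-based half-open residue coordinates of the linker on
#'   the degapped reference row.
#' @param meta Optional tibble with `id` and any of `phylum`, `subgroup`
#'   to label the extracted members.
#' @return A `linker_set` tibble (`id`, `phylum`, `subgroup`, `linker`,
#'   `length`) with the column window stored in the `columns` attribute.
#' @export
extract_from_alignment <- function(alignment, reference_id, start, end,
                                   meta = NULL) {
  win <- map_reference_to_columns(alignment, reference_id, start, end)
  slice <- if (win[["col_end"]] > win[["col_start"]]) {
    substr(alignment$alignment, win[["col_start"]], win[["col_end"]] - 1L)
  } else rep("", nrow(alignment))
  linkers <- gsub("-", "", slice, fixed = TRUE)
  out <- tibble(id = alignment$id,
                phylum = NA_character_, subgroup = NA_character_,
                linker = linkers, length = nchar(linkers))
  if (!is.null(meta)) {
    j <- match(out$id, meta$id)
    for (nm in intersect(c("phylum", "subgroup"), names(meta))) {
      out[[nm]] <- ifelse(is.na(j), out[[nm]], as.character(meta[[nm]])[j])
    }
  }
  attr(out, "columns") <- win
  class(out) <- c("linker_set", class(out))
  out
}

#' Length-bin schemes for linker sets
#'
#' Two closed-integer-interval schemes are used: the `analysis` scheme
#' (`0-20`, `21-40`, `41-60`, `61-200`) that stratifies the propensity
#' tables, and the finer `histogram` scheme (`0-20`, `21-30`, `31-40`,
#' `41-50`, `51-60`, `>60`) used for subgroup length distributions, where
#' `>60` is unbounded above.
#'
#' @param scheme `"analysis"` or `"histogram"`.
#' @return A list with `labels` and `breaks` (upper bounds, `Inf` for the
#'   open top bin).
#' @export
bin_scheme <- function(scheme = c("analysis", "histogram")) {
  scheme <- match.arg(scheme)
  if (scheme == "analysis") {
    list(labels = c("0-20", "21-40", "41-60", "61-200"),
         breaks = c(20, 40, 60, 200))
  } else {
    list(labels = c("0-20", "21-30", "31-40", "41-50", "51-60", ">60"),
         breaks = c(20, 30, 40, 50, 60, Inf))
  }
}

#' Assign each linker to a length bin
#'
#' @param linker_set A `linker_set` tibble (needs a `length` column).
#' @param scheme Bin scheme, see [bin_scheme()]. Under the `analysis`
#'   scheme, lengths above 200 are folded into `61-200` with a warning.
#' @return The linker set with an ordered-factor `bin` column and the
#'   scheme name in the `bin_scheme` attribute.
#' @export
assign_length_bins <- function(linker_set, scheme = c("analysis", "histogram")) {
  scheme <- match.arg(scheme)
  stopifnot("length" %in% names(linker_set))
  len <- linker_set$length
  if (any(len < 0)) abort("Negative linker length.")
  sc <- bin_scheme(scheme)
  if (scheme == "analysis" && any(len > 200)) {
    warn(sprintf("%d linker(s) longer than 200 residues folded into bin 61-200.",
                 sum(len > 200)))
    len <- pmin(len, 200L)
  }
  idx <- findInterval(len, c(-Inf, sc$breaks), left.open = TRUE)
  linker_set$bin <- factor(sc$labels[idx], levels = sc$labels, ordered = TRUE)
  attr(linker_set, "bin_scheme") <- scheme
  if (!inherits(linker_set, "linker_set")) {
    class(linker_set) <- c("linker_set", class(linker_set))
  }
  linker_set
}
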