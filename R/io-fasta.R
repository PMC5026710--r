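#' Read protein sequences from a FASTA file
#'
#' Reads unaligned amino-acid FASTA (via Biostrings) and applies the
#' package's normalisation rules: identifiers are truncated at the first
#' whitespace, sequences are upper-cased, a trailing `*` stop codon is
#' stripped, and any character outside the tolerated alphabet (20 standard
#' letters plus B/Z/X/U/O) is an error. Gap characters are rejected here;
#' use [read_aligned_fasta()] for alignments.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of annotated sequences with columns `id`, `sequence`,
#'   `phylum`, `subgroup` (both `NA` until annotated) and a `regions`
#'   list-column of per-sequence region tables (empty here; see
#'   [generate_set()] for populated regions).
#' @seealso [write_fasta()], [read_aligned_fasta()]
#' @export
read_fasta <- function(path) {
  raw <- read_fasta_raw(path)
  seqs <- toupper(raw$sequence)
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (grepl("-", seqs[i], fixed = TRUE)) {
      abort(sprintf(
        "Sequence '%s' contains gap characters; use read_aligned_fasta() for aligned input.",
        raw$id[i]))
    }
    check_alphabet(seqs[i], raw$id[i], allow_gap = FALSE)
  }
  annotated_sequences(id = raw$id, sequence = seqs)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' All records must share one gapped length; the gap character is `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `alignment` (the gapped, upper-cased
#'   row), in file order, with the common row length stored in the
#'   `alignment_length` attribute.
#' @export
read_aligned_fasta <- function(path) {
  raw <- read_fasta_raw(path)
  rows <- toupper(raw$sequence)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    ref <- as.integer(names(which.max(table(widths))))
    bad <- raw$id[widths != ref]
    abort(sprintf("Alignment rows have unequal lengths; offending IDs: %s",
                  paste(bad, collapse = ", ")))
  }
  for (i in seq_along(rows)) check_alphabet(rows[i], raw$id[i], allow_gap = TRUE)
  out <- tibble(id = raw$id, alignment = rows)
  attr(out, "alignment_length") <- if (nrow(out)) widths[1] else 0L
  out
}

#' Write sequences to FASTA
#'
#' @param x A tibble with an `id` column and either a `sequence` or
#'   `alignment` column (e.g. from [read_fasta()] or [generate_set()]), or a
#'   linker set from [extract_by_coordinates()] (the `linker` column is
#'   written and headers carry `phylum|subgroup|bin` metadata when present).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), "id" %in% names(x))
  seq_col <- intersect(c("sequence", "alignment", "linker"), names(x))[1]
  if (is.na(seq_col)) abort("No sequence column found (sequence/alignment/linker).")
  headers <- x$id
  if (seq_col == "linker") {
    meta <- cbind(
      if ("phylum" %in% names(x)) x$phylum else NA,
      if ("subgroup" %in% names(x)) x$subgroup else NA,
      if ("bin" %in% names(x)) as.character(x$bin) else NA
    )
    tags <- apply(meta, 1L, function(r) paste(r[!is.na(r)], collapse = "|"))
    headers <- ifelse(nzchar(tags), paste(headers, tags, sep = " "), headers)
  }
  set <- Biostrings::BStringSet(setNames(x[[seq_col]], headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

# raw FASTA records: ids truncated at first whitespace, duplicate check
read_fasta_raw <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("No FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(sprintf("Duplicate FASTA identifier(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  list(id = unname(ids), sequence = unname(as.character(set)))
}

check_alphabet <- function(seq, id, allow_gap = FALSE) {
  ok <- aa_alphabet()
  if (allow_gap) ok <- c(ok, "-")
  ch <- split_residues(seq)
  bad <- which(!(ch %in% ok))
  if (length(bad)) {
    abort(sprintf("Illegal character '%s' at position %d in sequence '%s'.",
                  ch[bad[1]], bad[1], id))
  }
  invisible(TRUE)
}

#' Construct a tibble of annotated sequences
#'
#' The package's central container: one row per protein, with optional
#' phylum/subgroup labels and a `regions` list-column mapping region names
#' (`wHTH`, `linker`, `AAT`) to 1-based half-open `[start, end)` intervals.
#' Regions, when present, must fall inside the sequence, must not overlap,
#' and must appear in wHTH, linker, AAT order.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of residue strings.
#' @param phylum,subgroup Optional categorical labels (recycled).
#' @param regions Optional list of per-sequence tibbles with columns
#'   `region`, `start`, `end`.
#' @return A tibble with class `annotated_seqs`.
#' @export
annotated_sequences <- function(id, sequence, phylum = NA_character_,
                                subgroup = NA_character_, regions = NULL) {
  n <- length(id)
  if (anyDuplicated(id)) abort("Sequence ids must be unique.")
  if (is.null(regions)) regions <- rep(list(empty_regions()), n)
  out <- tibble(
    id = as.character(id),
    sequence = as.character(sequence),
    phylum = rep_len(as.character(phylum), n),
    subgroup = rep_len(as.character(subgroup), n),
    regions = regions
  )
  for (i in seq_len(n)) validate_regions(out$regions[[i]], nchar(out$sequence[i]), out$id[i])
  class(out) <- c("annotated_seqs", class(out))
  out
}

empty_regions <- function() {
  tibble(region = character(), start = integer(), end = integer())
}

region_order <- c("wHTH", "linker", "AAT")

validate_regions <- function(reg, seq_len, id) {
  if (is.null(reg) || nrow(reg) == 0L) return(invisible(TRUE))
  stopifnot(all(c("region", "start", "end") %in% names(reg)))
  with(reg, {
    if (any(start < 1L) || any(end < start) || any(end > seq_len + 1L)) {
      abort(sprintf("Region coordinates out of range for sequence '%s'.", id))
    }
  })
  known <- reg[reg$region %in% region_order, , drop = FALSE]
  if (nrow(known) > 1L) {
    known <- known[order(match(known$region, region_order)), ]
    if (any(diff(known$start) < 0) ||
        any(known$end[-nrow(known)] > known$start[-1L])) {
      abort(sprintf(
        "Regions wHTH/linker/AAT must be non-overlapping and in order for '%s'.", id))
    }
  }
  invisible(TRUE)
}

# fetch one region's substring from an annotated_seqs row
region_string <- function(sequence, regions, name) {
  r <- regions[regions$region == name, ]
  if (nrow(r) != 1L) return(NA_character_)
  substr(sequence, r$start, r$end - 1L)
}
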