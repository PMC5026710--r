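#' Read a domain-boundary table
#'
#' Parses the per-sequence linker boundary table: whitespace- or
#' tab-separated columns `id`, `start`, `end` and optionally `length`, with
#' an optional header row. Coordinates are 1-based half-open, so `start` is
#' the first linker residue, `end` the first residue of the downstream (AAT)
#' domain, and `length = end - start`. When a length column is present it is
#' cross-checked against `end - start`; a mismatch is an error naming the
#' offending row.
#'
#' @param path Path to the table.
#' @return A tibble with columns `id`, `start`, `end`, `length`, in file
#'   order.
#' @export
#' @examples
#' p <- system.file("extdata", "mocr_long_linkers.tsv", package = "mocrlink")
#' head(read_boundary_table(p))
read_boundary_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("Empty boundary table: %s", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  # header row: second field non-numeric
  is_header <- suppressWarnings(is.na(as.numeric(fields[[1]][2])))
  if (is_header) fields <- fields[-1L]
  if (!length(fields)) abort(sprintf("Boundary table has a header but no rows: %s", path))
  parse_row <- function(f, row_no) {
    if (length(f) < 3L) {
      abort(sprintf("Boundary row %d ('%s'): expected at least id, start, end.",
                    row_no, paste(f, collapse = " ")))
    }
    num <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(num) || any(num != floor(num))) {
      abort(sprintf("Boundary row %d ('%s'): non-integer coordinate.", row_no, f[1]))
    }
    start <- as.integer(num[1]); end <- as.integer(num[2])
    if (start < 1L) abort(sprintf("Boundary row %d ('%s'): start must be >= 1.", row_no, f[1]))
    if (end < start) abort(sprintf("Boundary row %d ('%s'): end < start.", row_no, f[1]))
    if (length(num) >= 3L && num[3] != end - start) {
      abort(sprintf(
        "Boundary row %d ('%s'): stated length %d != end - start = %d.",
        row_no, f[1], as.integer(num[3]), end - start))
    }
    tibble(id = f[1], start = start, end = end, length = end - start)
  }
  out <- bind_rows(map2(fields, seq_along(fields), parse_row))
  dup <- out$id[duplicated(out$id)]
  if (length(dup)) {
    warn(sprintf("Duplicate boundary id(s): %s (all rows kept).",
                 paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write a boundary table
#'
#' @param boundaries A tibble with `id`, `start`, `end` (and optionally
#'   `length`) columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_table <- function(boundaries, path) {
  stopifnot(all(c("id", "start", "end") %in% names(boundaries)))
  b <- boundaries
  b$length <- b$end - b$start
  readr::write_tsv(b[, c("id", "start", "end", "length")], path)
  invisible(path)
}

#' Read an amino-acid scale
#'
#' Accepts either an AAindex1 flat-file entry (`H`/`D`/`I` lines, the `I`
#' block holding two rows of ten values in the canonical
#' A,R,N,D,C,Q,E,G,H,I / L,K,M,F,P,S,T,W,Y,V order) or a plain two-column
#' letter/value table. All 20 standard letters must receive a finite value.
#'
#' @param path Path to the scale file.
#' @param accession Optional accession; for flat files it is checked against
#'   the `H` line, for two-column tables it is attached as metadata.
#' @return A `scale_definition`: a list with elements `accession`,
#'   `description` and `values` (named numeric of length 20).
#' @export
read_scale <- function(path, accession = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^H ", lines))) {
    parse_aaindex1(lines, accession, path)
  } else {
    parse_scale_table(lines, accession, path)
  }
}

parse_aaindex1 <- function(lines, accession, path) {
  h <- sub("^H ", "", grep("^H ", lines, value = TRUE)[1])
  if (!is.null(accession) && h != accession) {
    abort(sprintf("Scale file %s holds accession %s, not %s.", path, h, accession))
  }
  d_line <- grep("^D ", lines, value = TRUE)
  descr <- if (length(d_line)) sub("^D ", "", d_line[1]) else ""
  i_at <- grep("^I ", lines)
  if (!length(i_at) || length(lines) < i_at[1] + 2L) {
    abort(sprintf("No I value block in AAindex1 file %s.", path))
  }
  rows <- lines[i_at[1] + 1:2]
  vals <- unlist(strsplit(trimws(rows), "[ \t]+"))
  if (length(vals) != 20L) {
    abort(sprintf("AAindex1 I block in %s has %d values, expected 20.",
                  path, length(vals)))
  }
  if (any(toupper(vals) == "NA")) {
    abort(sprintf("Accession %s has NA index values; scale unusable.", h))
  }
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num) || any(!is.finite(num))) {
    abort(sprintf("Non-numeric value in the I block of %s.", path))
  }
  scale_definition(h, descr, setNames(num, aa_standard()))
}

parse_scale_table <- function(lines, accession, path) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  fields <- strsplit(trimws(lines), "[ \t,]+")
  # tolerate a header row
  if (length(fields) && suppressWarnings(is.na(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1L]
  }
  letters_in <- toupper(map_chr(fields, 1L))
  vals <- suppressWarnings(as.numeric(map_chr(fields, 2L)))
  if (anyNA(vals)) abort(sprintf("Non-numeric scale value in %s.", path))
  if (anyDuplicated(letters_in)) {
    abort(sprintf("Duplicate letters in scale table %s.", path))
  }
  missing <- setdiff(aa_standard(), letters_in)
  if (length(missing)) {
    abort(sprintf("Scale table %s is missing letter(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(letters_in, aa_standard())
  if (length(extra)) {
    abort(sprintf("Scale table %s has non-standard letter(s): %s.",
                  path, paste(extra, collapse = ", ")))
  }
  v <- setNames(vals, letters_in)[aa_standard()]
  scale_definition(accession %||% "custom", "", v)
}

#' @rdname read_scale
#' @param description Free-text description of the scale.
#' @param values Named numeric vector over the 20 standard letters.
#' @export
scale_definition <- function(accession, description = "", values) {
  if (!setequal(names(values), aa_standard()) || length(values) != 20L) {
    abort("Scale values must be keyed by exactly the 20 standard letters.")
  }
  if (any(!is.finite(values))) abort("Scale values must all be finite.")
  structure(
    list(accession = accession, description = description,
         values = values[aa_standard()]),
    class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s\n  %s\n", x$accession, x$description))
  print(round(x$values, 3))
  invisible(x)
}

#' Bundled AAindex scales used for linker profiling
#'
#' Returns the seven physicochemical scales the linker analysis profiles:
#' flexibility (VINM940101), hydrophobicity (CIDH920105), linker propensity
#' (GEOR030101), Chou-Fasman beta-turn (CHOP780101), coil (CHAM830101),
#' alpha-helix (CHOP780201) and beta-sheet (CHOP780202) normalized
#' frequencies. The truncated or non-canonical codes GEOR03010, CHOP780102
#' and CHOP780103 sometimes seen in figure legends are accepted as aliases
#' of GEOR030101, CHOP780201 and CHOP780202 (the accessions the AAindex
#' databank actually assigns to those scales).
#'
#' @param accessions Accessions (or aliases) to load; default all seven.
#' @return A named list of `scale_definition` objects.
#' @export
#' @examples
#' names(mocr_scales())
mocr_scales <- function(accessions = NULL) {
  alias <- c(GEOR03010 = "GEOR030101",
             CHOP780102 = "CHOP780201",
             CHOP780103 = "CHOP780202")
  all_acc <- c("VINM940101", "CIDH920105", "GEOR030101", "CHOP780101",
               "CHAM830101", "CHOP780201", "CHOP780202")
  accessions <- accessions %||% all_acc
  resolved <- ifelse(accessions %in% names(alias), alias[accessions], accessions)
  out <- map(resolved, function(a) {
    p <- system.file("extdata", "aaindex", paste0(a, ".aaindex1"),
                     package = "mocrlink")
    if (!nzchar(p)) abort(sprintf("No bundled scale for accession %s.", a))
    read_scale(p, accession = a)
  })
  setNames(out, unname(resolved))
}

#' Write a result table to TSV or JSON
#'
#' Deterministic column order (as given) and fixed decimal rendering for
#' floating-point columns, matching the print precision of the analysis
#' tables.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param decimals Number of decimals for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json"), decimals = 2L) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  fmt <- as.data.frame(records)
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- formatC(fmt[[j]], format = "f", digits = decimals)
      fmt[[j]][fmt[[j]] %in% c("NA", "NaN")] <- NA_character_
    }
  }
  con <- tryCatch(file(path, "w"), condition = function(e) {
    abort(sprintf("Cannot write to %s: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(names(fmt), collapse = "\t"), con)
    if (nrow(fmt)) {
      body <- apply(fmt, 1L, function(r) paste(ifelse(is.na(r), "", r), collapse = "\t"))
      writeLines(body, con)
    }
  } else {
    writeLines(jsonlite::toJSON(fmt, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, pretty = TRUE), con)
  }
  invisible(path)
}
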