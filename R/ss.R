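#' Read three-state secondary-structure strings
#'
#' Reads a FASTA-like file of per-linker secondary-structure strings and
#' reduces them to the three states H (helix), E (strand), C (coil).
#' Letters outside H/E/C are mapped through `state_map` (default: the
#' DSSP-style reduction G,I -> H; B -> E; T,S and gaps -> C). When a
#' linker set is supplied, each record's length is checked against its
#' linker.
#'
#' @param path FASTA-like file of state strings; ids must match linker ids.
#' @param linkers Optional `linker_set` to validate lengths against.
#' @param state_map Named character vector mapping extra letters to H/E/C.
#' @return A tibble with columns `id`, `states`.
#' @export
read_ss <- function(path, linkers = NULL,
                    state_map = c(G = "H", I = "H", B = "E",
                                  T = "C", S = "C", "-" = "C")) {
  raw <- read_fasta_raw(path)
  states <- toupper(raw$sequence)
  recode <- function(s) {
    ch <- split_residues(s)
    hit <- ch %in% names(state_map)
    ch[hit] <- state_map[ch[hit]]
    bad <- setdiff(unique(ch), c("H", "E", "C"))
    if (length(bad)) {
      abort(sprintf("Unmappable secondary-structure letter(s) %s.",
                    paste(bad, collapse = ", ")))
    }
    paste(ch, collapse = "")
  }
  out <- tibble(id = raw$id, states = map_chr(states, recode))
  if (!is.null(linkers)) {
    j <- match(out$id, linkers$id)
    if (anyNA(j)) {
      abort(sprintf("Secondary-structure id(s) with no linker: %s",
                    paste(out$id[is.na(j)], collapse = ", ")))
    }
    mism <- nchar(out$states) != linkers$length[j]
    if (any(mism)) {
      abort(sprintf("State string length differs from linker length for: %s",
                    paste(out$id[mism], collapse = ", ")))
    }
  }
  out
}

#' Per-group secondary-structure fractions
#'
#' Summarises three-state strings into helix/strand/coil fractions per
#' group. The canonical `pooled` mode is residue-weighted: fraction(H) =
#' total H residues / total residues in the group, so the three fractions
#' sum to exactly 1 and are invariant to how the pooled content is split
#' into records. The alternative `mean` mode averages per-record fractions
#' (each record weighted equally).
#'
#' @param records A tibble with `id`, `states` (from [read_ss()]).
#' @param groups Optional tibble with `id` and a grouping column (`group`,
#'   or `phylum`); omitted ids form no group. Default: one overall group.
#' @param mode `"pooled"` (canonical) or `"mean"`.
#' @return A tibble with the group column plus `n_linkers`, `n_residues`,
#'   `helix`, `strand`, `coil`. Empty groups are omitted.
#' @export
#' @examples
#' ss_fractions(tibble::tibble(id = "a", states = "HHCC"))
ss_fractions <- function(records, groups = NULL, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  stopifnot(all(c("id", "states") %in% names(records)))
  d <- records
  if (is.null(groups)) {
    d$group <- "all"
  } else {
    gcol <- intersect(c("group", "phylum", "subgroup"), names(groups))[1]
    if (is.na(gcol)) abort("`groups` needs a group/phylum/subgroup column.")
    d$group <- as.character(groups[[gcol]])[match(d$id, groups$id)]
    d <- d[!is.na(d$group), , drop = FALSE]
  }
  if (!nrow(d)) abort("No grouped secondary-structure records.")
  frac_of <- function(s, letter) stringr::str_count(s, stringr::fixed(letter))
  d$nH <- frac_of(d$states, "H"); d$nE <- frac_of(d$states, "E")
  d$nC <- frac_of(d$states, "C"); d$len <- nchar(d$states)
  if (mode == "pooled") {
    out <- d |>
      group_by(group) |>
      summarise(n_linkers = n(), n_residues = sum(len),
                helix = sum(nH) / sum(len), strand = sum(nE) / sum(len),
                coil = sum(nC) / sum(len), .groups = "drop")
  } else {
    out <- d[d$len > 0, , drop = FALSE] |>
      group_by(group) |>
      summarise(n_linkers = n(), n_residues = sum(len),
                helix = mean(nH / len), strand = mean(nE / len),
                coil = mean(nC / len), .groups = "drop")
  }
  out
}
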