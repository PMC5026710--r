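#' Amino-acid alphabet used throughout the package
#'
#' `aa_standard()` returns the 20 standard one-letter codes in the canonical
#' AAindex order (A R N D C Q E G H I L K M F P S T W Y V). `aa_ambiguous()`
#' returns the tolerated ambiguity/non-standard letters (B, Z, X and the
#' rare translated residues U, O) which are accepted in input sequences but
#' excluded from all composition statistics.
#'
#' @return A character vector of one-letter residue codes.
#' @export
#' @examples
#' aa_standard()
aa_standard <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aa_standard
#' @export
aa_ambiguous <- function() c("B", "Z", "X", "U", "O")

# full tolerated alphabet for validation
aa_alphabet <- function() c(aa_standard(), aa_ambiguous())

#' Background amino-acid composition
#'
#' Average residue frequencies of the UniProtKB/Swiss-Prot databank, the
#' conventional background against which compositional enrichment is judged.
#' Values are renormalised to sum to exactly 1.
#'
#' @return A named numeric vector of length 20 (names in [aa_standard()]
#'   order) summing to 1.
#' @export
#' @examples
#' sum(aa_background())
aa_background <- function() {
  f <- c(
    A = 8.26, R = 5.53, N = 4.06, D = 5.46, C = 1.37, Q = 3.93, E = 6.74,
    G = 7.08, H = 2.27, I = 5.93, L = 9.65, K = 5.82, M = 2.41, F = 3.86,
    P = 4.72, S = 6.61, T = 5.35, W = 1.09, Y = 2.92, V = 6.86
  )
  f <- f[aa_standard()]
  f / sum(f)
}

# split a peptide string into single-letter vector
split_residues <- function(x) {
  if (length(x) == 1L) strsplit(x, "", fixed = TRUE)[[1]] else
    unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
}

# drop ambiguity letters; returns list(kept = chr, n_excluded = int)
drop_ambiguous <- function(residues) {
  amb <- residues %in% aa_ambiguous()
  list(kept = residues[!amb], n_excluded = sum(amb))
}
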