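#' Configuration for the MocR-like sequence generator
#'
#' Describes a synthetic population of MocR-family regulators: an N-terminal
#' winged-HTH domain (~60 residues), an inter-domain linker whose length is
#' drawn from a mixture over the analysis length bins, and a C-terminal
#' aminotransferase-like domain (~350 residues). Domain segments are drawn
#' i.i.d. from the background composition; linker segments from the
#' background multiplied by per-letter enrichment factors (renormalised), so
#' every downstream propensity statistic has a known ground truth.
#'
#' @param seed Integer seed; one global random stream per run.
#' @param n_sequences Sequences per phylum.
#' @param phyla Phylum labels.
#' @param whth_length_mean,whth_length_sd Gaussian length model for the wHTH
#'   domain, in residues.
#' @param aat_length_mean,aat_length_sd Same for the AAT domain.
#' @param linker_length_mixture Named weights over the analysis bins
#'   `0-20`, `21-40`, `41-60`, `61-200`; must sum to 1. Lengths are uniform
#'   within the chosen bin.
#' @param background_frequencies Named letter probabilities (sum 1); default
#'   the Swiss-Prot average composition of [aa_background()].
#' @param linker_enrichment Named multiplicative factors (> 0) applied to the
#'   background inside linkers; letters not named keep factor 1.
#' @param subgroup_labels Optional named list mapping a subgroup label (e.g.
#'   `GabR`, `PdxR`) to its own linker length mixture; sequences are split
#'   evenly across subgroups.
#' @return A validated `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, n_sequences = 5, phyla = "Firmicutes")
generator_config <- function(seed = 1L,
                             n_sequences = 50L,
                             phyla = c("Actinobacteria", "Alphaproteobacteria",
                                       "Betaproteobacteria", "Firmicutes",
                                       "Gammaproteobacteria"),
                             whth_length_mean = 60, whth_length_sd = 5,
                             aat_length_mean = 350, aat_length_sd = 20,
                             linker_length_mixture = c("0-20" = 0.15,
                                                       "21-40" = 0.40,
                                                       "41-60" = 0.30,
                                                       "61-200" = 0.15),
                             background_frequencies = aa_background(),
                             linker_enrichment = NULL,
                             subgroup_labels = NULL) {
  bins <- c("0-20", "21-40", "41-60", "61-200")
  check_mixture <- function(m, what) {
    if (!setequal(names(m), bins)) {
      abort(sprintf("%s must be named by the bins %s.", what,
                    paste(bins, collapse = ", ")))
    }
    if (abs(sum(m) - 1) > 1e-9) abort(sprintf("%s weights must sum to 1.", what))
    if (any(m < 0)) abort(sprintf("%s weights must be non-negative.", what))
    m[bins]
  }
  linker_length_mixture <- check_mixture(linker_length_mixture, "linker_length_mixture")
  bg <- background_frequencies
  if (!setequal(names(bg), aa_standard())) {
    abort("background_frequencies must be keyed by the 20 standard letters.")
  }
  if (abs(sum(bg) - 1) > 1e-9) abort("background_frequencies must sum to 1.")
  enr <- setNames(rep(1, 20), aa_standard())
  if (!is.null(linker_enrichment)) {
    bad <- setdiff(names(linker_enrichment), aa_standard())
    if (length(bad)) abort(sprintf("Unknown letters in linker_enrichment: %s.",
                                   paste(bad, collapse = ", ")))
    if (any(linker_enrichment <= 0)) abort("Enrichment factors must be > 0.")
    enr[names(linker_enrichment)] <- linker_enrichment
  }
  linker_probs <- bg[aa_standard()] * enr
  if (sum(linker_probs) <= 0) abort("Linker alphabet has zero total probability after enrichment.")
  if (!is.null(subgroup_labels)) {
    subgroup_labels <- map(subgroup_labels, check_mixture, what = "subgroup mixture")
  }
  structure(list(
    seed = as.integer(seed), n_sequences = as.integer(n_sequences),
    phyla = phyla,
    whth_length_mean = whth_length_mean, whth_length_sd = whth_length_sd,
    aat_length_mean = aat_length_mean, aat_length_sd = aat_length_sd,
    linker_length_mixture = linker_length_mixture,
    background_frequencies = bg[aa_standard()],
    linker_enrichment = enr,
    linker_frequencies = linker_probs / sum(linker_probs),
    subgroup_labels = subgroup_labels
  ), class = "generator_config")
}

bin_ranges <- list("0-20" = c(0L, 20L), "21-40" = c(21L, 40L),
                   "41-60" = c(41L, 60L), "61-200" = c(61L, 200L))

#' Generate a synthetic MocR-like sequence set with known ground truth
#'
#' @param config A [generator_config()].
#' @return A list of class `mocr_simulation` with elements
#'   \describe{
#'     \item{sequences}{an annotated tibble (see [annotated_sequences()])
#'       with populated `wHTH`/`linker`/`AAT` regions;}
#'     \item{boundaries}{a boundary table (`id`, `start`, `end`, `length`)
#'       for the linker of every sequence, in the 1-based half-open
#'       convention;}
#'     \item{truth}{the generating parameters: the config, the per-sequence
#'       linker bin and length, the exact linker letter distribution and the
#'       enrichment factors.}
#'   }
#'   Fully reproducible from `config$seed`.
#' @export
#' @examples
#' sim <- generate_set(generator_config(seed = 42, n_sequences = 3,
#'                                      phyla = "Firmicutes"))
#' sim$boundaries
generate_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  bg <- config$background_frequencies
  lp <- config$linker_frequencies
  grid <- expand.grid(k = seq_len(config$n_sequences), phylum = config$phyla,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  subgroups <- if (is.null(config$subgroup_labels)) rep(NA_character_, n) else
    rep_len(names(config$subgroup_labels), n)

  draw_len <- function(mean, sd, floor_at) {
    pmax(floor_at, as.integer(round(rnorm(n, mean, sd))))
  }
  whth_len <- draw_len(config$whth_length_mean, config$whth_length_sd, 10L)
  aat_len <- draw_len(config$aat_length_mean, config$aat_length_sd, 10L)
  linker_bin <- character(n); linker_len <- integer(n)
  for (i in seq_len(n)) {
    mix <- if (is.na(subgroups[i])) config$linker_length_mixture else
      config$subgroup_labels[[subgroups[i]]]
    b <- sample(names(mix), 1L, prob = mix)
    r <- bin_ranges[[b]]
    linker_bin[i] <- b
    linker_len[i] <- sample(seq.int(r[1], r[2]), 1L)
  }
  draw_seg <- function(len, probs) {
    paste(sample(aa_standard(), len, replace = TRUE, prob = probs), collapse = "")
  }
  whth <- map_chr(whth_len, draw_seg, probs = bg)
  linker <- map_chr(linker_len, draw_seg, probs = lp)
  aat <- map_chr(aat_len, draw_seg, probs = bg)

  ids <- sprintf("SYN%04d_%s", seq_len(n),
                 toupper(substr(grid$phylum, 1, 4)))
  regions <- pmap(list(whth_len, linker_len, aat_len), function(w, l, a) {
    tibble(region = c("wHTH", "linker", "AAT"),
           start = c(1L, w + 1L, w + l + 1L),
           end = c(w + 1L, w + l + 1L, w + l + a + 1L))
  })
  seqs <- annotated_sequences(
    id = ids, sequence = paste0(whth, linker, aat),
    phylum = grid$phylum, subgroup = subgroups, regions = regions)
  boundaries <- tibble(id = ids, start = whth_len + 1L,
                       end = whth_len + linker_len + 1L, length = linker_len)
  truth <- list(
    config = config,
    members = tibble(id = ids, phylum = grid$phylum, subgroup = subgroups,
                     bin = linker_bin, length = linker_len),
    linker_frequencies = lp,
    enrichment = config$linker_enrichment,
    mixture = config$linker_length_mixture)
  structure(list(sequences = seqs, boundaries = boundaries, truth = truth),
            class = "mocr_simulation")
}

#' @export
print.mocr_simulation <- function(x, ...) {
  cat(sprintf("<mocr_simulation> %d sequences, %d phyla, seed %d\n",
              nrow(x$sequences), length(unique(x$sequences$phylum)),
              x$truth$config$seed))
  invisible(x)
}

#' Build a synthetic alignment around generated sequences
#'
#' Produces a gapped alignment whose rows degap exactly to the generated
#' sequences, laid out as three column blocks (wHTH, linker, AAT). Within
#' each block every row's residues are scattered over seeded random column
#' positions and padded with gaps; the reference row's linker is pinned to
#' the first and last columns of the linker block, so the minimal column
#' window of the reference linker covers every row's linker residues. This
#' makes the alignment a faithful test-bed for window-based linker
#' extraction ([extract_from_alignment()]).
#'
#' @param sim A `mocr_simulation` from [generate_set()].
#' @param gap_fraction Fraction of extra gap columns added to each block
#'   (0 = blocks exactly as wide as the longest segment).
#' @param reference_id Row to use as extraction reference; default the
#'   sequence with the longest linker.
#' @param seed Seed for gap placement; default `config$seed + 1`.
#' @return A list with `alignment` (tibble `id`, `alignment`),
#'   `reference_id`, `linker_block` (1-based half-open column interval
#'   common to all rows) and `linker_columns` (per-row minimal column
#'   intervals of each row's own linker).
#' @export
generate_alignment <- function(sim, gap_fraction = 0.15, reference_id = NULL,
                               seed = NULL) {
  stopifnot(inherits(sim, "mocr_simulation"))
  set.seed(seed %||% (sim$truth$config$seed + 1L))
  seqs <- sim$sequences
  segs <- map(seq_len(nrow(seqs)), function(i) {
    r <- seqs$regions[[i]]
    map_chr(c("wHTH", "linker", "AAT"), function(nm)
      region_string(seqs$sequence[i], r, nm))
  })
  seg_len <- do.call(rbind, map(segs, nchar))
  ref_i <- if (is.null(reference_id)) which.max(seg_len[, 2]) else
    match(reference_id, seqs$id)
  if (is.na(ref_i)) abort(sprintf("reference_id '%s' not in the set.", reference_id))
  widths <- map_int(1:3, function(b) {
    mx <- max(seg_len[, b])
    as.integer(mx + ceiling(gap_fraction * mx))
  })
  # block 2 cannot be wider than the reference linker can span
  if (seg_len[ref_i, 2] < 2L) widths[2] <- max(seg_len[, 2])

  place <- function(len, width, pin_ends = FALSE) {
    if (len == 0L) return(integer(0))
    if (len >= width) return(seq_len(width))
    if (pin_ends && len >= 2L) {
      sort(c(1L, width, sample(2:(width - 1L), len - 2L)))
    } else {
      sort(sample.int(width, len))
    }
  }
  n <- nrow(seqs)
  rows <- character(n)
  linker_cols <- matrix(NA_integer_, n, 2)
  offset2 <- widths[1]
  for (i in seq_len(n)) {
    parts <- character(3)
    for (b in 1:3) {
      pos <- place(seg_len[i, b], widths[b],
                   pin_ends = (b == 2L && i == ref_i))
      chars <- rep("-", widths[b])
      chars[pos] <- split_residues(segs[[i]][b])[seq_along(pos)]
      parts[b] <- paste(chars, collapse = "")
      if (b == 2L) {
        linker_cols[i, ] <- if (length(pos)) {
          c(offset2 + min(pos), offset2 + max(pos) + 1L)
        } else c(offset2 + 1L, offset2 + 1L)
      }
    }
    rows[i] <- paste(parts, collapse = "")
  }
  list(
    alignment = structure(tibble(id = seqs$id, alignment = rows),
                          alignment_length = sum(widths)),
    reference_id = seqs$id[ref_i],
    linker_block = c(start = offset2 + 1L, end = offset2 + widths[2] + 1L),
    linker_columns = tibble(id = seqs$id,
                            col_start = linker_cols[, 1],
                            col_end = linker_cols[, 2]))
}

#' Inject an excess of one dyad into a peptide set
#'
#' Overwrites seeded random adjacent position pairs with the given dyad
#' until its expected observed frequency reaches
#' `excess * f_bg(N-side) * f_bg(C-side)`, i.e. `excess` times the
#' frequency expected under independent sampling from the background
#' composition. Ground truth for validating dyad-propensity recovery:
#' evaluated against the background marginals, the injected dyad's
#' propensity converges to `excess`.
#'
#' @param peptides Character vector of peptides.
#' @param dyad Two-letter string, N-side then C-side.
#' @param excess Target propensity relative to background independence.
#' @param background Background composition (named, sums to 1).
#' @param seed Optional seed.
#' @return A list with `peptides` (modified) and `truth` (dyad, target
#'   excess, achieved dyad count and window total).
#' @export
inject_dyad_excess <- function(peptides, dyad, excess,
                               background = aa_background(), seed = NULL) {
  stopifnot(nchar(dyad) == 2L, excess > 0)
  if (!is.null(seed)) set.seed(seed)
  d1 <- substr(dyad, 1, 1); d2 <- substr(dyad, 2, 2)
  lens <- nchar(peptides)
  n_windows <- sum(pmax(lens - 1L, 0L))
  if (n_windows == 0L) abort("Peptide set has no dyad windows.")
  target <- excess * background[[d1]] * background[[d2]] * n_windows
  current <- sum(stringr::str_count(peptides, paste0("(?=", d1, d2, ")")))
  k <- max(0L, as.integer(round(target - current)))
  if (k > 0L) {
    eligible <- which(lens >= 2L)
    pep_pick <- sample(eligible, k, replace = TRUE,
                       prob = pmax(lens[eligible] - 1L, 0L))
    chars <- strsplit(peptides, "", fixed = TRUE)
    for (p in pep_pick) {
      pos <- sample.int(lens[p] - 1L, 1L)
      chars[[p]][pos] <- d1
      chars[[p]][pos + 1L] <- d2
    }
    peptides <- map_chr(chars, paste, collapse = "")
  }
  achieved <- sum(stringr::str_count(peptides, paste0("(?=", d1, d2, ")")))
  list(peptides = peptides,
       truth = list(dyad = dyad, excess = excess,
                    achieved_count = achieved, n_windows = n_windows))
}
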