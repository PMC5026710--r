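test_that("coordinate extraction follows the half-open Start/End convention", {
  seqs <- annotated_sequences(c("s1", "s2", "s3"),
                              c(strrep("ACDEF", 80), "MKVLINKER", "MKV"))
  b <- tibble::tibble(id = c("s1", "s2", "s3"),
                      start = c(88L, 10L, 1L), end = c(148L, 10L, 4L))
  ls <- extract_by_coordinates(seqs, b)
  expect_equal(ls$length, c(60L, 0L, 3L))
  expect_equal(ls$linker[1], substr(seqs$sequence[1], 88, 147))
  # zero-length linker retained and binned into 0-20
  binned <- assign_length_bins(ls, "analysis")
  expect_equal(as.character(binned$bin[2]), "0-20")
  # end = len + 1 runs to the final residue
  expect_equal(ls$linker[3], "MKV")
})

test_that("unmatched ids warn and skip, or error under strict mode", {
  seqs <- annotated_sequences("s1", strrep("A", 50))
  b <- tibble::tibble(id = c("s1", "ghost"), start = c(10L, 1L),
                      end = c(20L, 5L))
  expect_warning(ls <- extract_by_coordinates(seqs, b), "ghost")
  expect_equal(nrow(ls), 1L)
  expect_equal(attr(ls, "n_skipped_boundaries"), 1L)
  expect_error(suppressWarnings(extract_by_coordinates(seqs, b, strict = TRUE)),
               "ghost")
  # out-of-range end is an error, not a skip
  b2 <- tibble::tibble(id = "s1", start = 10L, end = 52L)
  expect_error(suppressWarnings(extract_by_coordinates(seqs, b2)), "exceeds")
})

test_that("reference coordinates map to minimal alignment column windows", {
  aln <- tibble::tibble(id = c("a", "b"), alignment = c("M-KV", "MLKV"))
  expect_equal(unname(map_reference_to_columns(aln, "a", 2, 3)), c(3L, 4L))
  # gap-free row: columns equal residue coordinates
  expect_equal(unname(map_reference_to_columns(aln, "b", 2, 4)), c(2L, 4L))
  expect_error(map_reference_to_columns(aln, "a", 2, 5), "exceeds")
  expect_error(map_reference_to_columns(aln, "zz", 1, 2), "not in")
})

test_that("column mapping agrees with a brute-force slice-then-degap oracle", {
  set.seed(202)
  for (k in 1:300) {
    n_res <- sample(3:25, 1)
    res <- sample(aa_standard(), n_res, replace = TRUE)
    gapped <- character(0)
    for (ch in res) gapped <- c(gapped, rep("-", stats::rpois(1, 0.7)), ch)
    gapped <- c(gapped, rep("-", stats::rpois(1, 0.7)))
    row <- paste(gapped, collapse = "")
    aln <- tibble::tibble(id = "r", alignment = row)
    start <- sample.int(n_res, 1)
    end <- sample(start:(n_res + 1L), 1)
    win <- map_reference_to_columns(aln, "r", start, end)
    slice <- if (win[2] > win[1]) substr(row, win[1], win[2] - 1L) else ""
    expect_equal(gsub("-", "", slice, fixed = TRUE),
                 paste(res[seq_len(end - start) + start - 1L], collapse = ""))
  }
})

test_that("alignment extraction matches ground truth and the coordinate path", {
  sim <- small_sim(seed = 303, n = 10)
  truth <- extract_by_coordinates(sim$sequences, sim$boundaries)
  aln <- generate_alignment(sim, gap_fraction = 0.25)
  rb <- sim$boundaries[sim$boundaries$id == aln$reference_id, ]
  got <- extract_from_alignment(aln$alignment, aln$reference_id,
                                rb$start, rb$end,
                                meta = sim$sequences[, c("id", "phylum")])
  expect_equal(setNames(got$linker, got$id)[truth$id],
               setNames(truth$linker, truth$id))
  expect_equal(got$phylum, sim$sequences$phylum)

  # self-consistency: the reference row's extraction equals the direct slice
  ref_row <- got[got$id == aln$reference_id, ]
  expect_equal(ref_row$linker, truth$linker[truth$id == aln$reference_id])
})

test_that("all-gap rows in the window yield retained empty linkers", {
  aln <- tibble::tibble(id = c("ref", "gappy"),
                        alignment = c("MKVAPK", "MK---K"))
  got <- extract_from_alignment(aln, "ref", 3, 6)
  expect_equal(got$linker, c("VAP", ""))
  expect_equal(got$length, c(3L, 0L))
})

test_that("length bins partition lengths per scheme, with boundary cases exact", {
  ls <- tibble::tibble(id = as.character(1:6), phylum = NA, subgroup = NA,
                       linker = strrep("A", c(0, 20, 21, 60, 61, 200)),
                       length = c(0L, 20L, 21L, 60L, 61L, 200L))
  a <- assign_length_bins(ls, "analysis")
  expect_equal(as.character(a$bin),
               c("0-20", "0-20", "21-40", "41-60", "61-200", "61-200"))
  h <- assign_length_bins(ls, "histogram")
  expect_equal(as.character(h$bin),
               c("0-20", "0-20", "21-30", "51-60", ">60", ">60"))
  # >200 folds into the top analysis bin with a warning
  big <- tibble::tibble(id = "x", length = 250L, linker = strrep("A", 250))
  expect_warning(ab <- assign_length_bins(big, "analysis"), "200")
  expect_equal(as.character(ab$bin), "61-200")
  expect_error(assign_length_bins(tibble::tibble(length = -1L), "analysis"),
               "Negative")
})

test_that("analysis bins are disjoint and cover every length 0..200", {
  sc <- bin_scheme("analysis")
  for (len in 0:200) {
    idx <- findInterval(len, c(-Inf, sc$breaks), left.open = TRUE)
    expect_true(idx >= 1 && idx <= 4)
  }
  expect_equal(bin_scheme("histogram")$labels,
               c("0-20", "21-30", "31-40", "41-50", "51-60", ">60"))
})
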