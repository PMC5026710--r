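test_that("generator_config validates mixtures, backgrounds and enrichment", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(linker_length_mixture = c("0-20" = 1)), "bins")
  bad_mix <- c("0-20" = 0.5, "21-40" = 0.4, "41-60" = 0.2, "61-200" = 0)
  expect_error(generator_config(linker_length_mixture = bad_mix), "sum to 1")
  expect_error(generator_config(linker_enrichment = c(P = 0)), "> 0")
  expect_error(generator_config(linker_enrichment = c(J = 2)), "Unknown")
  bg <- aa_background(); bg[1] <- bg[1] + 0.1
  expect_error(generator_config(background_frequencies = bg), "sum to 1")
})

test_that("generated sets are reproducible and correctly annotated", {
  cfg <- generator_config(seed = 99, n_sequences = 4, phyla = "Firmicutes")
  s1 <- generate_set(cfg)
  s2 <- generate_set(cfg)
  expect_identical(s1$sequences$sequence, s2$sequences$sequence)
  expect_identical(s1$boundaries, s2$boundaries)

  # byte-identical FASTA from the same seed
  p1 <- tempfile(); p2 <- tempfile()
  write_fasta(s1$sequences, p1); write_fasta(s2$sequences, p2)
  expect_identical(readLines(p1), readLines(p2))

  # regions tile the sequence and match the boundary table
  for (i in seq_len(nrow(s1$sequences))) {
    r <- s1$sequences$regions[[i]]
    expect_equal(r$region, c("wHTH", "linker", "AAT"))
    expect_equal(r$start[-1], r$end[-3])
    expect_equal(r$end[3] - 1L, nchar(s1$sequences$sequence[i]))
  }
  lk <- s1$sequences$regions[[1]][2, ]
  expect_equal(s1$boundaries$start[1], lk$start)
  expect_equal(s1$boundaries$end[1], lk$end)
})

test_that("null enrichment gives linkers statistically matching the background", {
  cfg <- generator_config(seed = 1, n_sequences = 30, phyla = "Firmicutes",
                          linker_length_mixture = c("0-20" = 0, "21-40" = 0,
                                                    "41-60" = 1, "61-200" = 0))
  sim <- generate_set(cfg)
  lk <- extract_by_coordinates(sim$sequences, sim$boundaries)
  f <- residue_frequencies(lk)
  n <- attr(f, "n_residues")
  expect_gte(n, 1000)
  gof <- stats::chisq.test(f$count, p = aa_background())
  expect_gt(gof$p.value, 0.001)
})

test_that("linker enrichment factors are recovered from large samples", {
  cfg <- generator_config(seed = 31, n_sequences = 300,
                          phyla = c("A", "B"),
                          linker_length_mixture = c("0-20" = 0, "21-40" = 0,
                                                    "41-60" = 0, "61-200" = 1),
                          linker_enrichment = c(P = 2.0))
  sim <- generate_set(cfg)
  lk <- extract_by_coordinates(sim$sequences, sim$boundaries)
  f <- residue_frequencies(lk)
  ratio <- f$frequency[f$residue == "P"] / aa_background()[["P"]]
  # true linker frequency of P is bg*2 renormalised; compare to that target
  target <- sim$truth$linker_frequencies[["P"]] / aa_background()[["P"]]
  n <- attr(f, "n_residues")
  fP <- sim$truth$linker_frequencies[["P"]]
  se <- sqrt(fP * (1 - fP) / n) / aa_background()[["P"]]
  expect_lt(abs(ratio - target), 3 * se)
  # and the renormalised target itself is within 5% of the nominal factor 2
  expect_lt(abs(target - 2) / 2, 0.05)
})

test_that("length mixture weights are recovered within binomial 99% CIs", {
  mix <- c("0-20" = 0.2, "21-40" = 0.5, "41-60" = 0.2, "61-200" = 0.1)
  cfg <- generator_config(seed = 41, n_sequences = 400, phyla = "A",
                          linker_length_mixture = mix)
  sim <- generate_set(cfg)
  tab <- table(factor(sim$truth$members$bin, levels = names(mix)))
  n <- sum(tab)
  for (b in names(mix)) {
    ci <- stats::binom.test(tab[[b]], n, conf.level = 0.99)$conf.int
    expect_true(mix[[b]] >= ci[1] && mix[[b]] <= ci[2], label = b)
  }
})

test_that("subgroup-specific mixtures shift the length distribution as configured", {
  cfg <- generator_config(
    seed = 51, n_sequences = 200, phyla = "Firmicutes",
    subgroup_labels = list(
      GabR = c("0-20" = 0.1, "21-40" = 0.7, "41-60" = 0.15, "61-200" = 0.05),
      PdxR = c("0-20" = 0.05, "21-40" = 0.15, "41-60" = 0.7, "61-200" = 0.1)))
  sim <- generate_set(cfg)
  m <- sim$truth$members
  gab <- table(m$bin[m$subgroup == "GabR"])
  pdx <- table(m$bin[m$subgroup == "PdxR"])
  expect_equal(names(which.max(gab)), "21-40")
  expect_equal(names(which.max(pdx)), "41-60")
})

test_that("synthetic alignments degap back to their source sequences", {
  sim <- small_sim(seed = 61, n = 8)
  aln <- generate_alignment(sim, gap_fraction = 0.2)
  degapped <- gsub("-", "", aln$alignment$alignment, fixed = TRUE)
  expect_equal(degapped, sim$sequences$sequence)
  expect_equal(unique(nchar(aln$alignment$alignment)),
               attr(aln$alignment, "alignment_length"))

  # per-row linker columns degap to that row's annotated linker
  lk <- extract_by_coordinates(sim$sequences, sim$boundaries)
  for (i in seq_len(nrow(aln$alignment))) {
    cs <- aln$linker_columns$col_start[i]; ce <- aln$linker_columns$col_end[i]
    slice <- if (ce > cs) substr(aln$alignment$alignment[i], cs, ce - 1L) else ""
    expect_equal(gsub("-", "", slice, fixed = TRUE),
                 lk$linker[lk$id == aln$alignment$id[i]])
  }
})

test_that("zero extra gaps with equal segment lengths reproduces raw sequences", {
  cfg <- generator_config(seed = 71, n_sequences = 4, phyla = "A",
                          whth_length_sd = 0, aat_length_sd = 0,
                          linker_length_mixture = c("0-20" = 0, "21-40" = 0,
                                                    "41-60" = 1, "61-200" = 0))
  sim <- generate_set(cfg)
  # force one shared linker length so all rows fill their blocks exactly
  sim$boundaries$length <- NULL
  same_len <- all(nchar(sim$sequences$sequence) ==
                    nchar(sim$sequences$sequence)[1])
  aln <- generate_alignment(sim, gap_fraction = 0)
  if (same_len) {
    expect_equal(aln$alignment$alignment, sim$sequences$sequence)
  } else {
    expect_equal(gsub("-", "", aln$alignment$alignment, fixed = TRUE),
                 sim$sequences$sequence)
  }
})

test_that("dyad injection reaches its target frequency against the background", {
  set.seed(81)
  peptides <- random_peptides(300, max_len = 60)
  inj <- inject_dyad_excess(peptides, "GS", excess = 5, seed = 82)
  bg <- aa_background()
  achieved <- inj$truth$achieved_count / inj$truth$n_windows
  target <- 5 * bg[["G"]] * bg[["S"]]
  se <- sqrt(target * (1 - target) / inj$truth$n_windows)
  expect_lt(abs(achieved - target), 3 * se + 2 / inj$truth$n_windows)
  expect_equal(nchar(inj$peptides), nchar(peptides))
})
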