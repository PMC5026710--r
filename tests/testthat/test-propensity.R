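test_that("residue frequencies exclude ambiguity letters from both sides", {
  f <- suppressMessages(residue_frequencies("AAAB"))
  expect_equal(f$frequency[f$residue == "A"], 1)
  expect_equal(attr(f, "n_residues"), 3L)
  expect_equal(attr(f, "n_excluded"), 1L)

  f2 <- residue_frequencies("ACDE")
  expect_equal(sort(f2$frequency[f2$frequency > 0]), rep(0.25, 4))
  expect_equal(sum(f2$frequency), 1)

  expect_error(suppressMessages(residue_frequencies("XXBZ")), "empty")
})

test_that("propensity arithmetic, zero handling and reference errors", {
  f <- stats::setNames(rep(0.05, 20), aa_standard())
  r <- f
  f[["P"]] <- 0.10; f[["A"]] <- 0.0; f <- f / sum(f)
  lf <- tibble::tibble(residue = names(f), frequency = unname(f))
  pt <- residue_propensities(lf, r)
  expect_equal(pt$propensity[pt$residue == "P"], f[["P"]] / 0.05)
  expect_equal(pt$propensity[pt$residue == "A"], 0)

  # identical compositions give flat propensity 1, shade none
  lf2 <- tibble::tibble(residue = aa_standard(), frequency = rep(0.05, 20))
  pt2 <- residue_propensities(lf2, stats::setNames(rep(0.05, 20), aa_standard()))
  expect_true(all(pt2$propensity == 1))
  expect_true(all(pt2$shade == "none"))

  # observed letter with zero reference frequency must error, naming it
  r0 <- stats::setNames(rep(1 / 19, 20), aa_standard()); r0[["W"]] <- 0
  fw <- stats::setNames(rep(0, 20), aa_standard()); fw[["W"]] <- 1
  lw <- tibble::tibble(residue = names(fw), frequency = unname(fw))
  expect_error(residue_propensities(lw, r0), "W")
})

test_that("shading categories sit exactly on the quoted thresholds", {
  expect_equal(shade_residue(c(1.00, 1.01, 1.19, 1.20, 0.5, 3)),
               c("none", "light", "light", "dark", "none", "dark"))
  expect_equal(shade_dyad(c(1.09, 1.10, 1.99, 2.00, 3.99, 4.00, 0.2)),
               c("none", "verylight", "verylight", "light", "light", "dark",
                 "none"))
  # shading is applied to the printed (2-decimal) value
  expect_equal(shade_residue(1.195), "dark")
  expect_equal(shade_residue(1.194), "light")
  expect_true(is.na(shade_dyad(NA_real_)))
})

test_that("dyad counting uses overlapping within-peptide windows", {
  dc <- count_dyads("AKAK")
  expect_equal(dc$counts["A", "K"], 2L)
  expect_equal(dc$counts["K", "A"], 1L)
  expect_equal(dc$n_total, 3L)

  # ambiguity letters void every window they touch
  dc2 <- count_dyads("ABAB")
  expect_equal(dc2$n_total, 0L)
  expect_equal(dc2$n_skipped, 3L)

  # never across peptide boundaries; empty peptides contribute nothing
  dc3 <- count_dyads(c("AK", "", "KA"))
  expect_equal(dc3$n_total, 2L)
  expect_equal(dc3$per_peptide$n_pairs, c(1L, 0L, 1L))
})

test_that("dyad counts equal exhaustive position enumeration on random sets", {
  set.seed(404)
  for (k in 1:50) {
    peps <- random_peptides(sample.int(10, 1), max_len = 30,
                            alphabet = c(aa_standard(), "X", "B"))
    dc <- count_dyads(peps)
    expect_identical(dc$counts, oracle_count_dyads(peps))
    expect_equal(dc$n_total, sum(dc$per_peptide$n_pairs))
  }
})

test_that("dyad propensities honour both expectation models", {
  set.seed(505)
  peps <- random_peptides(40, max_len = 40)
  dc <- count_dyads(peps)
  dp <- dyad_propensities(dc)
  # marginal-product normalization: sum over defined cells of p * expected = 1
  ok <- !is.na(dp$propensity)
  expect_equal(sum((dp$propensity * dp$expected)[ok]), 1, tolerance = 1e-9)

  du <- dyad_propensities(dc, model = "uniform")
  expect_equal(unique(as.vector(du$expected)), 1 / 400)
  expect_equal(sum(du$propensity * du$expected), 1, tolerance = 1e-9)

  # degenerate single peptide "AA"
  d1 <- dyad_propensities(count_dyads("AA"))
  expect_equal(d1$propensity["A", "A"], 1)
  # independence null: observed = f(i) f(j) exactly => all defined p = 1
  m <- aa_background()
  fake <- outer(m, m) * 10000
  dpn <- dyad_propensities(fake, marginals = m)
  expect_true(all(abs(dpn$propensity - 1) < 1e-9))
  expect_error(dyad_propensities(-fake), "Negative")
})

test_that("injected dyad excess is recovered as a dark-shaded propensity", {
  cfg <- generator_config(seed = 77, n_sequences = 700, phyla = "A",
                          linker_length_mixture = c("0-20" = 0, "21-40" = 0,
                                                    "41-60" = 0, "61-200" = 1))
  sim <- generate_set(cfg)
  lk <- extract_by_coordinates(sim$sequences, sim$boundaries)
  inj <- inject_dyad_excess(lk$linker, "GS", excess = 5, seed = 78)
  dp <- dyad_propensities(count_dyads(inj$peptides),
                          marginals = aa_background())
  p_gs <- dp$propensity["G", "S"]
  n_win <- inj$truth$n_windows
  f_tgt <- 5 * aa_background()[["G"]] * aa_background()[["S"]]
  se <- sqrt(f_tgt / n_win) / (f_tgt / 5)   # delta-method SE on the ratio
  expect_lt(abs(p_gs - 5), 3 * se + 0.1)
  expect_equal(dp$shade["G", "S"], "dark")
  expect_gte(p_gs, 4.0)
})

test_that("pairs summaries report mean and n-1 standard deviation per cell", {
  ls <- tibble::tibble(id = as.character(1:3), phylum = "F", subgroup = NA,
                       linker = c("AKAKAKAKAKA", "AKAKAKAKAKA", "AKAKAKAKAKA"),
                       length = 11L)
  s <- pairs_summary(ls, by = "phylum")
  expect_equal(s$label, "10.0±0.0")

  ls2 <- tibble::tibble(id = c("a", "b"), phylum = "F", subgroup = NA,
                        linker = c("A", paste0(strrep("AK", 5), "A")),
                        length = c(1L, 11L))
  s2 <- pairs_summary(ls2, by = "phylum")
  expect_equal(s2$mean_pairs, 5)
  expect_equal(s2$sd_pairs, stats::sd(c(0, 10)))
  expect_equal(s2$label, "5.0±7.1")

  # fixed-length ambiguity-free linkers: pairs = length - 1 exactly
  sim <- small_sim(seed = 88, n = 5,
                   linker_length_mixture = c("0-20" = 0, "21-40" = 0,
                                             "41-60" = 1, "61-200" = 0))
  lk <- extract_binned(sim)
  s3 <- pairs_summary(lk, by = character(0))
  expect_equal(s3$mean_pairs, mean(lk$length - 1))
})

test_that("residue propensity normalization holds on synthetic runs", {
  for (seed in c(1, 2, 3)) {
    sim <- small_sim(seed = seed, n = 8,
                     linker_enrichment = c(P = 1.5, G = 1.2))
    lk <- extract_binned(sim)
    pt <- residue_propensities(residue_frequencies(lk),
                               pooled_reference(sim$sequences))
    expect_equal(sum(pt$propensity * pt$ref_frequency), 1, tolerance = 1e-9)
  }
})
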