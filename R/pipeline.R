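#' Configuration for a full linker-analysis run
#'
#' Collects the inputs, stage toggles and numeric conventions of one
#' pipeline run. Either supply `fasta` + `boundaries` paths, or a
#' [generator_config()] in `simulate` to run on synthetic data.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed used for any stage randomness.
#' @param fasta,boundaries,ss Input paths (FASTA, boundary table, optional
#'   secondary-structure FASTA).
#' @param simulate A [generator_config()], or `TRUE` for the default one
#'   (seeded with `seed`).
#' @param stages Stages to run, a subset of
#'   `c("extract", "propensity", "dyads", "properties", "ss", "lengths")`.
#' @param bin_scheme `"analysis"` or `"histogram"` (propensity
#'   stratification always uses the analysis bins).
#' @param expectation Dyad expectation model, `"marginal_product"` or
#'   `"uniform"`.
#' @param reference Residue-propensity reference: `"pooled"` (full-length
#'   proteins of the same set), `"background"` ([aa_background()]) or a
#'   path to a two-column scale-style frequency table.
#' @param scales Named list of scales for the properties stage; default
#'   [mocr_scales()].
#' @param decimals Decimals for rendered TSVs.
#' @param strict Strict id matching in extraction.
#' @return A validated `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L, fasta = NULL, boundaries = NULL,
                       ss = NULL, simulate = NULL,
                       stages = c("extract", "propensity", "dyads",
                                  "properties", "ss", "lengths"),
                       bin_scheme = c("analysis", "histogram"),
                       expectation = c("marginal_product", "uniform"),
                       reference = "pooled",
                       scales = NULL, decimals = 2L, strict = FALSE) {
  bin_scheme <- match.arg(bin_scheme)
  expectation <- match.arg(expectation)
  stages <- match.arg(stages, several.ok = TRUE)
  if (isTRUE(simulate)) simulate <- generator_config(seed = seed)
  if (is.null(simulate)) {
    if (is.null(fasta) || is.null(boundaries)) {
      abort("Provide `fasta` and `boundaries`, or set `simulate`.")
    }
    for (p in c(fasta, boundaries, ss)) {
      if (!file.exists(p)) abort(sprintf("Input path does not exist: %s", p))
    }
  } else {
    stopifnot(inherits(simulate, "generator_config"))
  }
  if (!(identical(reference, "pooled") || identical(reference, "background") ||
        file.exists(reference))) {
    abort("`reference` must be 'pooled', 'background' or an existing file.")
  }
  structure(list(outdir = outdir, seed = as.integer(seed), fasta = fasta,
                 boundaries = boundaries, ss = ss, simulate = simulate,
                 stages = stages, bin_scheme = bin_scheme,
                 expectation = expectation, reference = reference,
                 scales = scales, decimals = as.integer(decimals),
                 strict = strict),
            class = "run_config")
}

#' Run the full linker analysis and write its artifact set
#'
#' Orchestrates the pipeline: (simulated or read) sequences are sliced into
#' linkers, stratified into length bins, and summarised into the standard
#' artifact set — per-group residue propensity tables, dyad propensity
#' matrices and pair-count summaries, per-scale AI group summaries,
#' secondary-structure fractions (when provided) and length histograms —
#' each written as TSV under `config$outdir` and listed in `index.json`.
#' Runs are deterministic given the same config and seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results per stage and
#'   `index` (the written file list).
#' @export
run_linker_report <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  index <- list()
  results <- list()
  out_path <- function(...) file.path(config$outdir, ...)
  emit <- function(tbl, name) {
    write_table(tbl, out_path(name), "tsv", decimals = config$decimals)
    index[[length(index) + 1L]] <<- name
  }

  # inputs
  if (!is.null(config$simulate)) {
    say("Simulating sequence set (seed %d)", config$simulate$seed)
    sim <- generate_set(config$simulate)
    sequences <- sim$sequences
    boundaries <- sim$boundaries
    write_fasta(sequences, out_path("simulated_sequences.fasta"))
    write_boundary_table(boundaries, out_path("simulated_boundaries.tsv"))
    index <- c(index, list("simulated_sequences.fasta", "simulated_boundaries.tsv"))
    results$simulation <- sim
  } else {
    sequences <- read_fasta(config$fasta)
    boundaries <- read_boundary_table(config$boundaries)
  }

  # extraction
  linkers <- NULL
  if ("extract" %in% config$stages) {
    say("Extracting %d linker(s)", nrow(boundaries))
    linkers <- extract_by_coordinates(sequences, boundaries,
                                      strict = config$strict)
    linkers <- assign_length_bins(linkers, "analysis")
    members <- as_tibble(linkers)
    members$bin <- as.character(members$bin)
    emit(members, "linker_members.tsv")
    write_fasta(linkers[linkers$length > 0, ], out_path("linkers.fasta"))
    index <- c(index, list("linkers.fasta"))
    results$linkers <- linkers
  }
  needs_linkers <- intersect(c("propensity", "dyads", "properties", "lengths"),
                             config$stages)
  if (is.null(linkers) && length(needs_linkers)) {
    abort("Stages depend on extraction; include 'extract' in `stages`.")
  }

  # residue propensities per phylum x bin (+ pooled "all")
  if ("propensity" %in% config$stages) {
    ref <- switch_reference(config$reference, sequences)
    groups <- propensity_groups(linkers)
    tabs <- imap(groups, function(g, nm) {
      lf <- residue_frequencies(g$linker)
      tidy_tab <- tidy(residue_propensities(lf, ref, group = nm))
      tidy_tab$group <- nm
      tidy_tab$n_residues <- attr(lf, "n_residues")
      tidy_tab
    })
    emit(bind_rows(tabs), "residue_propensities.tsv")
    results$propensities <- tabs
  }

  # dyad propensities per phylum (+ all) and the pair-count summary
  if ("dyads" %in% config$stages) {
    phyla <- unique(linkers$phylum)
    sets <- c(list(all = linkers),
              if (length(phyla) > 1 || !all(is.na(phyla)))
                setNames(map(phyla, function(p) linkers[linkers$phylum %in% p, ]),
                         paste0("phylum_", phyla)))
    mats <- imap(keep(sets, function(s) sum(nchar(s$linker)) > 1),
                 function(s, nm) {
      dp <- dyad_propensities(count_dyads(s), model = config$expectation,
                              group = nm)
      long <- tidy(dp)
      long$group <- nm
      long
    })
    emit(bind_rows(mats), "dyad_propensities.tsv")
    by_cols <- if (all(is.na(linkers$phylum))) "bin" else c("phylum", "bin")
    emit(pairs_summary(linkers, by = by_cols), "pairs_summary.tsv")
    results$dyads <- mats
  }

  # physicochemical profiles
  if ("properties" %in% config$stages) {
    scales <- config$scales %||% mocr_scales()
    prof <- profile_groups(sequences, linkers, scales = scales,
                           by_phylum = !all(is.na(sequences$phylum)))
    emit(glance(prof), "scale_profiles.tsv")
    results$profiles <- prof
  }

  # secondary structure
  if ("ss" %in% config$stages && !is.null(config$ss)) {
    recs <- read_ss(config$ss, linkers = linkers)
    grp <- tibble(id = linkers$id,
                  group = ifelse(is.na(linkers$phylum), "all", linkers$phylum))
    emit(ss_fractions(recs, groups = grp), "ss_fractions.tsv")
    results$ss <- TRUE
  }

  # length histograms per subgroup
  if ("lengths" %in% config$stages) {
    subs <- unique(linkers$subgroup[!is.na(linkers$subgroup)])
    hists <- if (length(subs)) {
      setNames(map(subs, function(s) length_histogram(linkers, s)), subs)
    } else list(all = length_histogram(linkers))
    h_tbl <- bind_rows(map(hists, as_tibble))
    h_tbl$bin <- as.character(h_tbl$bin)
    emit(h_tbl, "length_histograms.tsv")
    if (length(hists) == 2L) {
      cmp <- compare_histograms(hists[[1]], hists[[2]])
      cmp_tbl <- as_tibble(cmp)
      cmp_tbl$bin <- as.character(cmp_tbl$bin)
      emit(cmp_tbl, "length_comparison.tsv")
      results$comparison <- cmp
    }
    results$histograms <- hists
  }

  run_log <- list(
    seed = config$seed, stages = config$stages,
    bin_scheme = config$bin_scheme, expectation = config$expectation,
    reference = config$reference,
    n_sequences = nrow(sequences), n_linkers = if (!is.null(linkers)) nrow(linkers) else 0L,
    n_skipped_boundaries = attr(linkers, "n_skipped_boundaries") %||% 0L,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(list(outputs = unlist(index), run = run_log),
                       out_path("index.json"), auto_unbox = TRUE, pretty = TRUE)
  results$index <- unlist(index)
  say("Wrote %d artifact(s) to %s", length(index), config$outdir)
  invisible(results)
}

switch_reference <- function(reference, sequences) {
  if (identical(reference, "pooled")) return(pooled_reference(sequences))
  if (identical(reference, "background")) return(aa_background())
  sc <- read_scale(reference)
  v <- sc$values
  if (any(v < 0) || abs(sum(v) - 1) > 1e-6) {
    abort("Reference frequency file must hold non-negative values summing to 1.")
  }
  v / sum(v)
}

# named list of linker subsets: all, per phylum, per phylum x bin
propensity_groups <- function(linkers) {
  out <- list(all = linkers)
  phyla <- unique(linkers$phylum[!is.na(linkers$phylum)])
  for (p in phyla) {
    sub <- linkers[linkers$phylum %in% p, , drop = FALSE]
    out[[p]] <- sub
    for (b in levels(droplevels(sub$bin))) {
      cell <- sub[sub$bin == b, , drop = FALSE]
      if (sum(nchar(cell$linker)) > 0) out[[paste(p, b)]] <- cell
    }
  }
  keep(out, function(s) sum(nchar(s$linker)) > 0)
}
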