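# shared fixture builders: everything is generated in code at test time

write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("fa", tmpdir = dir, fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile("tbl", fileext = ext)
  writeLines(lines, path)
  path
}

random_peptides <- function(n, max_len = 30, alphabet = aa_standard()) {
  lens <- sample.int(max_len, n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
}

# independent brute-force dyad counter: explicit position loop, no windows
oracle_count_dyads <- function(peptides) {
  std <- aa_standard()
  counts <- matrix(0L, 20, 20, dimnames = list(std, std))
  for (p in peptides) {
    ch <- strsplit(p, "")[[1]]
    if (length(ch) < 2) next
    for (i in seq_len(length(ch) - 1L)) {
      a <- ch[i]; b <- ch[i + 1L]
      if (a %in% std && b %in% std) counts[a, b] <- counts[a, b] + 1L
    }
  }
  counts
}

# small two-phylum simulation reused across tests
small_sim <- function(seed = 11, n = 6, ...) {
  generate_set(generator_config(
    seed = seed, n_sequences = n,
    phyla = c("Firmicutes", "Actinobacteria"), ...))
}

extract_binned <- function(sim, scheme = "analysis") {
  assign_length_bins(extract_by_coordinates(sim$sequences, sim$boundaries),
                     scheme)
}
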