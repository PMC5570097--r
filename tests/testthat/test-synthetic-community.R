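test_that("design validation enforces the mock-community invariants", {
  expect_error(taxon_spec("X", cells = 0), "positive")
  expect_error(taxon_spec("X", cells = 10, amp_bias = 0), "amp_bias")
  expect_error(taxon_spec("X", cells = 10, amp_bias = Inf), "amp_bias")
  expect_error(mock_design(list()), "at least 1 taxon")
  expect_error(mock_design(taxon_spec("X", 10), host_fraction = 1),
               "host_fraction")
  d <- control_mix_design(1)
  tab <- design_table(d)
  expect_equal(nrow(tab), 7L)
  expect_equal(sort(unique(tab$cells)), c(1e3, 1e4, 1e6, 1e7, 1e8))
  expect_equal(sum(expected_proportions(d, "its")), 1)
  expect_equal(sum(expected_proportions(d, "shotgun")), 1)
  # pooled anchor: two S. cerevisiae strains sum their cells
  expect_equal(unname(expected_cells(d)[["Saccharomyces cerevisiae"]]),
               1.01e6)
})

test_that("design YAML round-trips", {
  d <- control_mix_design(2, amp_bias = c("Metschnikowia pulcherrima" = 10))
  path <- tempfile(fileext = ".yaml")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(design_table(d), design_table(d2))
  expect_equal(d$host_fraction, d2$host_fraction)
})

test_that("build_references embeds the requested ITS copies and is seeded", {
  d <- mock_design(taxon_spec("Solo species", 100, genome_length = 5e4,
                              its_copy_number = 3))
  refs <- build_references(d, seed = 5)
  g <- refs$genomes[["Solo species"]]
  expect_equal(nchar(g), 5e4)
  tpl <- refs$its_templates[["Solo species"]]
  hits <- gregexpr(tpl, g, fixed = TRUE)[[1]]
  expect_equal(length(hits), 3L)
  expect_equal(as.integer(hits) - 1L, refs$its_positions[["Solo species"]])
  # same seed -> byte-identical FASTA output
  d1 <- tempfile(); d2 <- tempfile()
  write_references(build_references(d, seed = 5), d1)
  write_references(build_references(d, seed = 5), d2)
  for (f in c("genomes.fasta", "its_refs.fasta", "host.fasta"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # different seed -> different sequence content
  refs2 <- build_references(d, seed = 6)
  expect_false(identical(refs$genomes, refs2$genomes))
})

test_that("distinct taxa get mutually dissimilar ITS references", {
  refs <- build_references(control_mix_design(1), seed = 3)
  tpl <- refs$its_templates
  for (i in seq_along(tpl)[-1]) for (j in seq_len(i - 1)) {
    expect_lt(seq_identity(tpl[[i]], tpl[[j]]), 0.9)
  }
  expect_equal(nrow(refs$its_db), length(refs$species))
})

test_that("a genome too small to host its ITS copies is rejected", {
  d <- mock_design(taxon_spec("Crowded", 10, genome_length = 1000,
                              its_copy_number = 50))
  expect_error(build_references(d, seed = 1), "too small to host")
})

test_that("ITS read counts follow cells x copy number x amplification bias", {
  # single taxon: every pair from it
  d1 <- mock_design(taxon_spec("Solo species", 500))
  r1 <- build_references(d1, seed = 2)
  p1 <- simulate_its_reads(d1, r1, 200, error_rate = 0, seed = 2)
  expect_equal(unique(p1$truth$label), "Solo species")
  expect_equal(p1$n_pairs, 200L)
  # amp_bias 10 vs 1, equal cells/copies: biased taxon near 10/11
  taxa <- list(taxon_spec("Biased one", 1e5, amp_bias = 10),
               taxon_spec("Fair one", 1e5))
  d2 <- mock_design(taxa)
  r2 <- build_references(d2, seed = 2)
  n <- 10000
  p2 <- simulate_its_reads(d2, r2, n, error_rate = 0, seed = 9)
  prop <- mean(p2$truth$label == "Biased one")
  expected <- 10 / 11
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(prop - expected), 3 * se)
  expect_error(simulate_its_reads(d2, r2, 10, error_rate = 0.5), "error_rate")
})

test_that("error-free ITS reads are exact amplicon substrings", {
  d <- mock_design(taxon_spec("Solo species", 10))
  refs <- build_references(d, seed = 4)
  pairs <- simulate_its_reads(d, refs, 50, error_rate = 0, seed = 4)
  tpl <- refs$its_templates[["Solo species"]]
  # every forward read contains barcode + spacer + (some) primer, then ITS
  expect_true(all(startsWith(pairs$fwd_seq, "TAAGGCGA")))
  expect_true(all(vapply(pairs$fwd_seq, function(s)
    grepl(substr(tpl, 1, 50), s, fixed = TRUE), logical(1))))
  # merging the error-free pair reconstructs an amplicon containing the ITS
  m <- merge_pairs(reads_df(pairs$fwd_seq, pairs$fwd_qual, pairs$id),
                   reads_df(pairs$rev_seq, pairs$rev_qual, pairs$id))
  expect_equal(nrow(m$reads), 50L)
  expect_true(all(vapply(m$reads$seq, function(s)
    grepl(tpl, s, fixed = TRUE), logical(1))))
})

test_that("shotgun read counts follow cells x genome length, plus host", {
  taxa <- list(taxon_spec("Big genome", 1e6, genome_length = 2e4),
               taxon_spec("Small genome", 1e6, genome_length = 2e3))
  d <- mock_design(taxa, host_fraction = 0)
  refs <- build_references(d, seed = 8, read_length = 100,
                           its_length = 60)
  n <- 20000
  p <- simulate_shotgun_reads(d, refs, n, error_rate = 0, read_length = 100,
                              insert_mean = 300, seed = 8)
  share <- mean(p$truth$label == "Big genome")
  se <- sqrt(10 / 11 * (1 / 11) / n)
  expect_lt(abs(share - 10 / 11), 3 * se)
  # host fraction binomial expectation
  d2 <- mock_design(taxa, host_fraction = 0.01)
  refs2 <- build_references(d2, seed = 8, its_length = 60)
  p2 <- simulate_shotgun_reads(d2, refs2, 1e5, error_rate = 0, seed = 8)
  n_host <- sum(p2$truth$label == "host")
  se_host <- sqrt(1e5 * 0.01 * 0.99)
  expect_lt(abs(n_host - 1000), 3 * se_host)
  # empty request is a valid empty set
  p0 <- simulate_shotgun_reads(d, refs, 0, seed = 1)
  expect_equal(p0$n_pairs, 0L)
})

test_that("simulators are reproducible and conserve read counts", {
  d <- control_mix_design(1)
  refs <- build_references(d, seed = 3)
  a <- simulate_its_reads(d, refs, 300, seed = 11)
  b <- simulate_its_reads(d, refs, 300, seed = 11)
  expect_identical(a$fwd_seq, b$fwd_seq)
  expect_identical(a$rev_seq, b$rev_seq)
  # FASTQ bytes identical under the same seed
  t1 <- tempfile(); t2 <- tempfile()
  write_read_pairs(a, t1, "x"); write_read_pairs(b, t2, "x")
  expect_identical(readLines(file.path(t1, "x_R1.fastq")),
                   readLines(file.path(t2, "x_R1.fastq")))
  expect_equal(nrow(a$truth), 300L)
  p <- attr(a, "expected_proportions")
  expect_equal(sum(p), 1)
  s <- simulate_shotgun_reads(d, refs, 400, seed = 12)
  expect_equal(sum(attr(s, "expected_proportions")), 1)
  expect_equal(nrow(s$truth), 400L)
})

test_that("simulated per-base errors hit the requested rate", {
  d <- mock_design(taxon_spec("Solo species", 10, genome_length = 5e4))
  refs <- build_references(d, seed = 6)
  p <- simulate_shotgun_reads(d, refs, 3000, error_rate = 0.01, seed = 6)
  m <- map_reads(setNames(p$fwd_seq, p$id), refs$genomes)
  ident <- 1 - m$alignments$mismatches / m$alignments$read_length
  expect_equal(mean(ident), 0.99, tolerance = 0.002)
})
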