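test_that("trailing-quality trimming applies the TRAILING/MINLEN rule", {
  # 100 bp read, last 10 bases at Q15, rest Q35 -> 90 bp retained
  r <- reads_df(strrep("A", 100), paste0(phred_string(rep(35, 90)),
                                         phred_string(rep(15, 10))))
  out <- quality_trim(r, trailing_q = 20, min_len = 50)
  expect_equal(nchar(out$reads$seq), 90L)
  expect_equal(nchar(out$reads$qual), 90L)
  # read trimmed below min_len -> rejected
  r2 <- reads_df(strrep("A", 55), paste0(phred_string(rep(35, 49)),
                                         phred_string(rep(10, 6))))
  out2 <- quality_trim(r2, trailing_q = 20, min_len = 50)
  expect_equal(nrow(out2$reads), 0L)
  expect_equal(out2$rejected, "r001")
  # all bases at or above the threshold -> unchanged
  r3 <- reads_df("ACGTACGTACGT", phred_string(rep(20, 12)))
  out3 <- quality_trim(r3, trailing_q = 20, min_len = 5)
  expect_equal(out3$reads$seq, "ACGTACGTACGT")
  # malformed record identified
  bad <- data.frame(id = "oops", seq = "ACGT", qual = "III",
                    stringsAsFactors = FALSE)
  expect_error(quality_trim(bad), "oops")
})

test_that("pair merging finds exact, outie, and no overlaps", {
  set.seed(301)
  # 150 bp fragment, 2 x 100 bp reads, no errors -> the fragment
  frag <- random_dna(150)
  f <- reads_df(substr(frag, 1, 100))
  r <- reads_df(revcomp(substr(frag, 51, 150)))
  m <- merge_pairs(f, r)
  expect_equal(m$reads$seq, frag)
  expect_equal(nchar(m$reads$qual), 150L)
  # 80 bp insert with fully-overlapping reads (adaptor trimmed upstream)
  frag2 <- random_dna(80)
  m2 <- merge_pairs(reads_df(frag2), reads_df(revcomp(frag2)))
  expect_equal(m2$reads$seq, frag2)
  # true outie: reverse mate starts before the forward mate
  core <- random_dna(70)
  a <- paste0(core, random_dna(20))          # fwd runs past the fragment
  b_rc <- paste0(random_dna(20), core)       # rev (rc) starts early
  m3 <- merge_pairs(reads_df(a), reads_df(revcomp(b_rc)))
  expect_equal(m3$reads$seq, core)
  # unrelated mates -> rejection, matching the exhaustive-scan oracle
  for (i in 1:20) {
    x <- random_dna(60); y <- random_dna(60)
    got <- merge_pairs(reads_df(x), reads_df(y), min_overlap = 15,
                       max_mismatch_frac = 0.1)
    want <- oracle_merge(x, revcomp(y), 15, 0.1)
    if (is.null(want)) {
      expect_equal(nrow(got$reads), 0L)
      expect_equal(got$unmerged, "r001")
    } else {
      expect_equal(got$reads$seq, want)
    }
  }
  # empty mate counted separately
  me <- merge_pairs(reads_df(""), reads_df("ACGTACGTACGT"))
  expect_equal(me$empty, "r001")
  expect_equal(nrow(me$reads), 0L)
})

test_that("merging agrees with the exhaustive offset-scan oracle on noisy pairs", {
  set.seed(302)
  for (i in 1:25) {
    frag <- random_dna(sample(90:140, 1))
    a <- substr(frag, 1, 80)
    b <- revcomp(substr(frag, nchar(frag) - 79, nchar(frag)))
    # sprinkle a couple of errors on the forward read
    av <- strsplit(a, "")[[1]]
    pos <- sample(80, 2)
    av[pos] <- vapply(av[pos], function(c)
      sample(setdiff(c("A", "C", "G", "T"), c), 1), character(1))
    a <- paste(av, collapse = "")
    got <- merge_pairs(reads_df(a), reads_df(b))
    want <- oracle_merge(a, revcomp(b), 10, 0.25)
    expect_identical(got$reads$seq,
                     if (is.null(want)) character(0) else want)
  }
})

test_that("residual adapter trimming follows overlap and error-rate rules", {
  core <- "ACGTACGTACGTACGTACGT"
  # 5' adapter prefix removed
  t1 <- trim_residual_adapters(reads_df(paste0("CTTCCGATCT", core)))
  expect_equal(t1$seq, core)
  # 3' adapter with 1 mismatch over 10 bases removed (0.1 allowed)
  ad <- "AGATCGGAAG"
  ad_mm <- paste0(substr(ad, 1, 9), "T")  # AGATCGGAAT
  t2 <- trim_residual_adapters(reads_df(paste0(core, ad_mm)))
  expect_equal(t2$seq, core)
  # 5-base adapter fragment below the 6-base minimum overlap -> unchanged
  t3 <- trim_residual_adapters(reads_df(paste0(core, substr(ad, 1, 5))))
  expect_equal(t3$seq, paste0(core, substr(ad, 1, 5)))
  # partial-overlap removal at the 5' end: suffix of the 5' adapter
  t4 <- trim_residual_adapters(reads_df(paste0("CCGATCT", core)))
  expect_equal(t4$seq, core)
})

test_that("demultiplexing assigns by dual inline barcodes within 1 mismatch", {
  scheme <- barcode_scheme()
  tpl <- random_dna(120)
  build_read <- function(fbc = "TAAGGCGA", rbc = "TAAGGCGA") {
    paste0(fbc, "ACCTGCGGAAGGATCA", tpl,
           revcomp(paste0(rbc, "GAGATCCATTGCTGAAAGTT")))
  }
  # exact barcodes
  d1 <- demultiplex(reads_df(build_read()), scheme)
  expect_equal(nrow(d1$samples$mock), 1L)
  expect_equal(d1$samples$mock$seq, tpl)
  # one mismatch in one barcode -> still assigned
  d2 <- demultiplex(reads_df(build_read(fbc = "TAAGGCGT")), scheme)
  expect_equal(nrow(d2$samples$mock), 1L)
  # two mismatches -> unassigned
  d3 <- demultiplex(reads_df(build_read(fbc = "TAAGGAAT")), scheme)
  expect_equal(nrow(d3$samples$mock), 0L)
  expect_equal(nrow(d3$unassigned), 1L)
  # reverse-complemented read recovered via orientation testing
  d4 <- demultiplex(reads_df(revcomp(build_read())), scheme)
  expect_equal(nrow(d4$samples$mock), 1L)
  expect_equal(d4$samples$mock$seq, tpl)
  expect_equal(d4$samples$mock$orientation, "rev")
})

test_that("demultiplexing separates combinatorial barcode pairs", {
  scheme <- barcode_scheme(data.frame(
    sample_id = c("s_11", "s_23"),
    fwd_index = c("N701", "N702"), rev_index = c("N701", "N703")))
  tpl <- random_dna(100)
  r11 <- paste0("TAAGGCGA", "ACCTGCGGAAGGATCA", tpl,
                revcomp(paste0("TAAGGCGA", "GAGATCCATTGCTGAAAGTT")))
  r23 <- paste0("CGTACTAG", "C", "ACCTGCGGAAGGATCA", tpl,
                revcomp(paste0("AGGCAGAA", "TC", "GAGATCCATTGCTGAAAGTT")))
  # a cross pair (fwd of s_11, rev of s_23) matches no configured sample
  cross <- paste0("TAAGGCGA", "ACCTGCGGAAGGATCA", tpl,
                  revcomp(paste0("AGGCAGAA", "TC", "GAGATCCATTGCTGAAAGTT")))
  out <- demultiplex(reads_df(c(r11, r23, cross)), scheme)
  expect_equal(out$samples$s_11$id, "r001")
  expect_equal(out$samples$s_23$id, "r002")
  expect_equal(out$unassigned$id, "r003")
  # stripping then re-prepending the recorded ends reconstructs the read
  s <- out$samples$s_23
  expect_equal(paste0(s$prefix, s$seq, s$suffix), r23)
})

test_that("a scheme violating the barcode-distance invariant is rejected", {
  bad <- data.frame(sample_id = c("a", "b"),
                    fwd_barcode = c("AAAAAAAA", "AAAAAAAT"),
                    fwd_spacer = "", rev_barcode = c("AAAAAAAA", "AAAAAAAT"),
                    rev_spacer = "", fwd_primer = "ACGT", rev_primer = "ACGT",
                    stringsAsFactors = FALSE)
  expect_error(validate_barcode_scheme(bad), "Hamming")
  expect_error(demultiplex(reads_df("ACGT"), bad), "Hamming")
})

test_that("demultiplexing conserves reads across bins", {
  d <- control_mix_design(1)
  refs <- build_references(d, seed = 21)
  pairs <- simulate_its_reads(d, refs, 800, error_rate = 0.02, seed = 21)
  m <- merge_pairs(reads_df(pairs$fwd_seq, pairs$fwd_qual, pairs$id),
                   reads_df(pairs$rev_seq, pairs$rev_qual, pairs$id))
  dm <- demultiplex(m$reads, barcode_scheme())
  n_assigned <- sum(vapply(dm$samples, nrow, integer(1)))
  expect_equal(n_assigned + nrow(dm$unassigned), nrow(m$reads))
})
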