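test_that("seed-and-extend mapping places, counts mismatches, flags ties", {
  set.seed(90)
  refs <- c(g1 = random_dna(5000), g2 = random_dna(5000))
  # verbatim read from a unique position: 1 record, 0 mismatches, unique
  read <- substr(refs[["g1"]], 1001, 1100)
  m <- map_reads(c(r1 = read), refs)
  expect_equal(nrow(m$alignments), 1L)
  expect_equal(m$alignments$target, "g1")
  expect_equal(m$alignments$start, 1000L)
  expect_equal(m$alignments$end, 1100L)
  expect_equal(m$alignments$mismatches, 0L)
  expect_true(m$alignments$unique)
  # reverse-complement placement found on the minus strand
  m_rc <- map_reads(c(r1 = revcomp(read)), refs)
  expect_equal(m_rc$alignments$start, 1000L)
  expect_equal(m_rc$alignments$strand, "-")
  # read present identically in two references -> flagged non-unique
  shared <- substr(refs[["g1"]], 2001, 2100)
  refs_dup <- c(refs, g3 = paste0(random_dna(500), shared, random_dna(500)))
  m2 <- map_reads(c(r1 = shared), refs_dup)
  expect_false(m2$alignments$unique)
  # 2 substitutions -> mapped with mismatches 2
  rv <- strsplit(read, "")[[1]]
  rv[c(10, 60)] <- vapply(rv[c(10, 60)], function(c)
    sample(setdiff(c("A", "C", "G", "T"), c), 1), character(1))
  m3 <- map_reads(c(r1 = paste(rv, collapse = "")), refs)
  expect_equal(m3$alignments$mismatches, 2L)
  # unrelated read -> unaligned pool
  m4 <- map_reads(c(r1 = random_dna(100)), refs)
  expect_equal(m4$unaligned, "r1")
  expect_error(map_reads(c(a = "ACGT"), c(x = "ACGT", x = "AAAA")),
               "duplicate")
})

test_that("host filtering retains pairs only when neither mate matches", {
  set.seed(91)
  host <- random_dna(20000)
  community <- random_dna(20000)
  mk_pairs <- function(ids, f, r) {
    fermentome:::new_read_pairs(ids, f, strrep("I", nchar(f)),
                                r, strrep("I", nchar(r)),
                                data.frame(read_id = ids, label = NA,
                                           strain = NA), "shotgun")
  }
  host_read <- function(at) substr(host, at, at + 99)
  comm_read <- function(at) substr(community, at, at + 99)
  pairs <- mk_pairs(c("hh", "hc", "cc"),
                    f = c(host_read(1), host_read(501), comm_read(1)),
                    r = c(revcomp(host_read(201)), revcomp(comm_read(501)),
                          revcomp(comm_read(201))))
  out <- host_filter(pairs, c(host = host))
  expect_equal(out$pairs$id, "cc")  # one host mate is enough to remove
  expect_equal(out$removed, 2L)
  expect_equal(out$removed_fraction, 2 / 3)
  # all-host input: empty output, removal fraction 1
  allhost <- mk_pairs("h1", host_read(301), revcomp(host_read(451)))
  out2 <- host_filter(allhost, c(host = host))
  expect_equal(out2$pairs$n_pairs, 0L)
  expect_equal(out2$removed_fraction, 1)
})

test_that("windows tile references half-open with a short remainder", {
  w <- make_windows(c(chr = 25000))
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$end, c(10000, 20000, 25000))
  expect_equal(make_windows(c(a = 10000))$end, 10000)
  w2 <- make_windows(c(a = 9999))
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$end, 9999)
  expect_error(make_windows(c(a = 100), width = 0), "width")
})

test_that("window counts use >=1 bp overlap; boundary reads count twice", {
  w <- make_windows(c(chr = 30000))
  aln <- data.frame(read_id = "b", target = "chr", start = 9990L,
                    end = 10090L, mismatches = 0L, read_length = 100L,
                    unique = TRUE, strand = "+", stringsAsFactors = FALSE)
  prof <- window_coverage(aln, w)
  expect_equal(prof$read_count, c(1L, 1L, 0L))
  # no alignments -> all zero counts, NA identity
  p0 <- window_coverage(aln[0, ], w)
  expect_equal(p0$read_count, c(0L, 0L, 0L))
  expect_true(all(is.na(p0$id_factor)))
  # n reads inside one window -> count n (conservation)
  inw <- do.call(rbind, replicate(7, aln, simplify = FALSE))
  inw$start <- 15000L + 10L * (0:6); inw$end <- inw$start + 100L
  p7 <- window_coverage(inw, w)
  expect_equal(p7$read_count, c(0L, 7L, 0L))
  expect_equal(sum(p7$read_count), 7L)
  # unknown target is a hard failure
  bad <- aln; bad$target <- "elsewhere"
  expect_error(window_coverage(bad, w), "unknown target")
})

test_that("window identity averages 1 - mismatches/length over reads", {
  w <- make_windows(c(chr = 10000))
  aln <- data.frame(read_id = c("a", "b"), target = "chr",
                    start = c(0L, 200L), end = c(100L, 300L),
                    mismatches = c(1L, 3L), read_length = 100L,
                    unique = TRUE, strand = "+", stringsAsFactors = FALSE)
  prof <- window_identity(aln, w)
  expect_equal(prof$id_factor, 0.98)  # mean of 0.99 and 0.97
  aln$mismatches <- c(0L, 0L)
  expect_equal(window_identity(aln, w)$id_factor, 1.0)
})

test_that("id_factor tracks the simulated error rate and decreases with it", {
  d <- mock_design(taxon_spec("Solo species", 100, genome_length = 4e4))
  refs <- build_references(d, seed = 13)
  ids <- vapply(c(0, 0.01, 0.03), function(e) {
    p <- simulate_shotgun_reads(d, refs, 1500, error_rate = e, seed = 13)
    res <- run_shotgun_pipeline(p, refs)
    w <- res$windows
    mean(w$id_factor[w$read_count > 0])
  }, numeric(1))
  expect_equal(ids[1], 1.0)
  expect_equal(ids[2], 0.99, tolerance = 0.003)
  expect_true(all(diff(ids) < 0))
})

test_that("species summaries apply the 20% breadth rule", {
  mk <- function(counts) data.frame(target = "sp", start = 0, end = 1,
                                    read_count = counts,
                                    id_factor = NA_real_,
                                    stringsAsFactors = FALSE)
  s1 <- species_summary(mk(c(30, rep(0, 9))))
  expect_equal(s1$breadth, 0.1)
  expect_equal(s1$mean, 3)
  expect_equal(s1$adjusted_mean, 0)  # breadth below threshold
  s2 <- species_summary(mk(c(5, 5, 5, 5, rep(0, 6))))
  expect_equal(s2$breadth, 0.4)
  expect_equal(s2$mean, 2)
  expect_equal(s2$adjusted_mean, 2)
  s3 <- species_summary(mk(rep(7, 10)))
  expect_equal(s3$mean, 7)
  expect_equal(s3$median, 7)
  expect_equal(s3$adjusted_mean, 7)
  empty <- data.frame(target = character(0), start = numeric(0),
                      end = numeric(0), read_count = integer(0),
                      id_factor = numeric(0), stringsAsFactors = FALSE)
  expect_error(species_summary(empty), "zero windows")
})

test_that("per-million normalisation scales as documented", {
  expect_equal(normalize_abundance(3, 1.5e6), 2)
  expect_equal(normalize_abundance(0, 1e6), 0)
  x <- normalize_abundance(5, 1e6)
  expect_equal(normalize_abundance(5, 2e6), x / 2)
  expect_error(normalize_abundance(1, 0), "positive")
  # ranking by adjusted mean is invariant to the normalisation
  am <- c(a = 9, b = 2, c = 5)
  expect_equal(order(normalize_abundance(am, 3e6)), order(am))
})

test_that("SAM ingestion recovers targets, positions and NM mismatches", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrA\tLN:1000",
    paste("r1", 0, "chrA", 101, 42, "50M", "*", 0, 0,
          strrep("A", 50), strrep("I", 50), "NM:i:2", sep = "\t"),
    paste("r2", 16, "chrA", 301, 3, "50M", "*", 0, 0,
          strrep("C", 50), strrep("I", 50), "NM:i:0", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("G", 50), strrep("I", 50), sep = "\t")), sam)
  aln <- read_sam_alignments(sam)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$target, c("chrA", "chrA"))
  expect_equal(aln$start, c(100L, 300L))
  expect_equal(aln$mismatches, c(2L, 0L))
  expect_equal(aln$unique, c(TRUE, FALSE))  # mapq 42 vs 3 against -q 10
  expect_equal(aln$strand, c("+", "-"))
})

test_that("window-count totals equal per-read window overlaps exactly", {
  set.seed(92)
  d <- mock_design(taxon_spec("Solo species", 50, genome_length = 3e4))
  refs <- build_references(d, seed = 14)
  p <- simulate_shotgun_reads(d, refs, 800, error_rate = 0.01, seed = 14)
  res <- run_shotgun_pipeline(p, refs)
  aln <- res$alignments
  w <- make_windows(setNames(nchar(refs$genomes), names(refs$genomes)))
  per_read <- vapply(seq_len(nrow(aln)), function(i) {
    sum(w$target == aln$target[i] & w$start < aln$end[i] &
          aln$start[i] < w$end)
  }, numeric(1))
  expect_equal(sum(res$windows$read_count), sum(per_read))
})
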