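#' ITS amplification primers and inline barcodes
#'
#' The fungal-specific primer pair used for first-round ITS amplification
#' (`BITS` forward, `B58S3` reverse, written 5'-3' with IUPAC degeneracies)
#' and the four 8-bp inline barcodes with their phasing spacers (0-3 bp).
#'
#' @return `bits_primers()`: list with `fwd` and `rev`.
#'   `bits_barcodes()`: data.frame with `index`, `barcode`, `spacer`.
#' @export
bits_primers <- function() {
  list(fwd = "ACCTGCGGARGGATCA", rev = "GAGATCCRTTGYTRAAAGTT")
}

#' @rdname bits_primers
#' @export
bits_barcodes <- function() {
  data.frame(index = c("N701", "N702", "N703", "N704"),
             barcode = c("TAAGGCGA", "CGTACTAG", "AGGCAGAA", "TCCTGAGC"),
             spacer = c("", "C", "TC", "ATC"),
             stringsAsFactors = FALSE)
}

#' Build an inline-barcode demultiplexing scheme
#'
#' Each sample is identified by the combination of its forward and reverse
#' inline barcodes (the scheme makes explicit whether barcode pairs are
#' matched, e.g. N701/N701, or combinatorial). Barcodes must be 8 bp and
#' pairwise Hamming distance >= 3 apart so that 1-mismatch assignment is
#' unambiguous.
#'
#' @param samples data.frame with columns `sample_id`, `fwd_index`,
#'   `rev_index` (indices among `bits_barcodes()$index`). Default: a single
#'   sample using the N701/N701 pair.
#' @return data.frame of class `"barcode_scheme"` with one row per sample:
#'   `sample_id`, `fwd_barcode`, `fwd_spacer`, `rev_barcode`, `rev_spacer`,
#'   `fwd_primer`, `rev_primer`.
#' @export
barcode_scheme <- function(samples = data.frame(sample_id = "mock",
                                                fwd_index = "N701",
                                                rev_index = "N701")) {
  bc <- bits_barcodes()
  pr <- bits_primers()
  f <- match(samples$fwd_index, bc$index)
  r <- match(samples$rev_index, bc$index)
  if (anyNA(f) || anyNA(r)) stop("unknown barcode index")
  out <- data.frame(sample_id = samples$sample_id,
                    fwd_barcode = bc$barcode[f], fwd_spacer = bc$spacer[f],
                    rev_barcode = bc$barcode[r], rev_spacer = bc$spacer[r],
                    fwd_primer = pr$fwd, rev_primer = pr$rev,
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_scheme", "data.frame")
  validate_barcode_scheme(out)
  out
}

#' Validate a demultiplexing scheme
#'
#' Checks barcode lengths (8 bp) and that all distinct barcodes are at
#' pairwise Hamming distance >= `2 * max_mismatch + 1`, the condition for
#' unambiguous assignment at the configured mismatch allowance.
#'
#' @param scheme A [barcode_scheme()]-like data.frame.
#' @param max_mismatch Mismatches tolerated per barcode at demultiplexing.
#' @return `scheme`, invisibly; errors on violation.
#' @export
validate_barcode_scheme <- function(scheme, max_mismatch = 1) {
  bcs <- unique(c(scheme$fwd_barcode, scheme$rev_barcode))
  if (any(nchar(bcs) != 8L)) stop("barcodes must be 8 bp")
  if (length(bcs) > 1L) {
    for (i in seq_along(bcs)[-1]) for (j in seq_len(i - 1)) {
      if (cpp_hamming(bcs[i], bcs[j]) < 2 * max_mismatch + 1)
        stop("barcodes ", bcs[i], " and ", bcs[j],
             " are closer than Hamming distance ", 2 * max_mismatch + 1)
    }
  }
  key <- paste(scheme$fwd_barcode, scheme$rev_barcode)
  if (anyDuplicated(key)) stop("duplicated barcode combination in scheme")
  invisible(scheme)
}

# all concrete instantiations of an IUPAC-degenerate primer
expand_iupac <- function(x) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T"))
  chars <- strsplit(x, "")[[1]]
  opts <- lapply(chars, function(c) codes[[c]])
  apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

new_read_pairs <- function(id, fwd_seq, fwd_qual, rev_seq, rev_qual, truth,
                           type) {
  structure(list(id = id, fwd_seq = fwd_seq, fwd_qual = fwd_qual,
                 rev_seq = rev_seq, rev_qual = rev_qual, truth = truth,
                 n_pairs = length(id), type = type),
            class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs:", x$n_pairs, x$type, "pairs\n")
  invisible(x)
}

quality_string <- function(lens, q = 40L, tail_len = 0L, tail_q = 10L) {
  main <- strrep(rawToChar(as.raw(q + 33L)), pmax(0L, lens - tail_len))
  if (tail_len > 0L)
    main <- paste0(main, strrep(rawToChar(as.raw(tail_q + 33L)),
                                pmin(lens, tail_len)))
  main
}

#' Simulate barcoded ITS amplicon read pairs
#'
#' Read counts per strain are multinomial with weights
#' `cells * its_copy_number * amp_bias` — the statistical structure that
#' makes ribosomal copy number and primer efficiency act as multiplicative
#' biases on amplicon abundances. Each amplicon is
#' `barcode | spacer | primer | ITS | rc(primer) | rc(spacer) | rc(barcode)`
#' with degenerate primer positions instantiated at random per molecule;
#' paired reads of `read_length` are taken from both ends and substitution
#' errors applied at `error_rate` per base. Quality strings are constant
#' high quality, with an optional low-quality 3' tail to exercise trailing
#' quality trimming.
#'
#' @param design A [mock_design()].
#' @param refs Matching [build_references()] output.
#' @param n_pairs Number of read pairs (> 0).
#' @param error_rate Per-base substitution probability, in `[0, 0.2]`.
#' @param read_length Read length in bases.
#' @param scheme A [barcode_scheme()]; pairs are spread evenly across its
#'   samples.
#' @param tail_len,tail_q Length and Phred quality of an optional low-quality
#'   3' tail (default none).
#' @param seed Integer seed for reproducibility.
#' @return A `"read_pairs"` object; `$truth` holds per-read source labels and
#'   the attribute `"expected_proportions"` the per-species multinomial
#'   weights (normalised).
#' @export
simulate_its_reads <- function(design, refs, n_pairs, error_rate = 0.01,
                               read_length = 150, scheme = barcode_scheme(),
                               tail_len = 0L, tail_q = 10L, seed = NULL) {
  stopifnot(inherits(design, "mock_design"), inherits(refs, "mock_references"))
  if (n_pairs <= 0) stop("'n_pairs' must be > 0")
  if (error_rate < 0 || error_rate > 0.2)
    stop("'error_rate' must be in [0, 0.2]")
  validate_barcode_scheme(scheme)
  tab <- design_table(design)
  with_seed(seed, {
    w <- tab$cells * tab$its_copy_number * tab$amp_bias
    strain_idx <- sample.int(nrow(tab), n_pairs, replace = TRUE, prob = w)
    entry_idx <- sample.int(nrow(scheme), n_pairs, replace = TRUE)
    fwd_vars <- expand_iupac(bits_primers()$fwd)
    rev_vars <- expand_iupac(bits_primers()$rev)
    fv <- sample.int(length(fwd_vars), n_pairs, replace = TRUE)
    rv <- sample.int(length(rev_vars), n_pairs, replace = TRUE)
    # amplicon table over (entry, species, fwd variant, rev variant)
    species <- refs$species
    amp <- array("", dim = c(nrow(scheme), length(species), length(fwd_vars),
                             length(rev_vars)))
    for (e in seq_len(nrow(scheme))) for (s in seq_along(species))
      for (i in seq_along(fwd_vars)) for (j in seq_along(rev_vars))
        amp[e, s, i, j] <- paste0(
          scheme$fwd_barcode[e], scheme$fwd_spacer[e], fwd_vars[i],
          refs$its_templates[species[s]],
          revcomp(paste0(scheme$rev_barcode[e], scheme$rev_spacer[e],
                         rev_vars[j])))
    sp_idx <- match(tab$label[strain_idx], species)
    amps <- amp[cbind(entry_idx, sp_idx, fv, rv)]
    len <- nchar(amps)
    fwd <- substring(amps, 1L, pmin(read_length, len))
    rev <- revcomp(substring(amps, pmax(1L, len - read_length + 1L), len))
    fwd <- cpp_add_errors(fwd, error_rate)
    rev <- cpp_add_errors(rev, error_rate)
    id <- sprintf("its_%06d", seq_len(n_pairs))
    truth <- data.frame(read_id = id,
                        sample_id = scheme$sample_id[entry_idx],
                        label = tab$label[strain_idx],
                        strain = tab$strain[strain_idx],
                        stringsAsFactors = FALSE)
    out <- new_read_pairs(id, fwd, quality_string(nchar(fwd), 40L, tail_len, tail_q),
                          rev, quality_string(nchar(rev), 40L, tail_len, tail_q),
                          truth, "its")
    attr(out, "expected_proportions") <- expected_proportions(design, "its")
    out
  })
}

#' Simulate shotgun metagenomic read pairs
#'
#' Total DNA is sequenced directly, so per-strain pair counts are multinomial
#' with weights `cells * genome_length` — amplification bias does not apply,
#' which is what makes the shotgun channel the unbiased yardstick. A
#' `host_fraction` of pairs is drawn from the generated host genome
#' (grapevine-like contamination). Fragment starts are uniform over each
#' genome, insert sizes normal around `insert_mean`, and substitution errors
#' applied at `error_rate` per base.
#'
#' @inheritParams simulate_its_reads
#' @param read_length Read length (default 100, 2x100 chemistry).
#' @param insert_mean,insert_sd Insert size distribution in bases; inserts
#'   are clamped to at least `read_length` and at most the genome length.
#' @return A `"read_pairs"` object; host pairs carry label `"host"` in
#'   `$truth`.
#' @export
simulate_shotgun_reads <- function(design, refs, n_pairs, error_rate = 0.01,
                                   read_length = 100, insert_mean = 350,
                                   insert_sd = 35, seed = NULL) {
  stopifnot(inherits(design, "mock_design"), inherits(refs, "mock_references"))
  if (n_pairs < 0) stop("'n_pairs' must be >= 0")
  if (error_rate < 0 || error_rate > 0.2)
    stop("'error_rate' must be in [0, 0.2]")
  tab <- design_table(design)
  with_seed(seed, {
    if (n_pairs == 0) {
      return(new_read_pairs(character(0), character(0), character(0),
                            character(0), character(0),
                            data.frame(read_id = character(0),
                                       label = character(0),
                                       strain = character(0)),
                            "shotgun"))
    }
    glen <- nchar(refs$genomes)[match(tab$label, names(refs$genomes))]
    w <- tab$cells * glen
    w <- w / sum(w) * (1 - design$host_fraction)
    probs <- c(w, host = design$host_fraction)
    src <- sample.int(length(probs), n_pairs, replace = TRUE, prob = probs)
    is_host <- src > nrow(tab)
    genome_of <- c(refs$genomes[match(tab$label, names(refs$genomes))],
                   refs$host)
    gl <- nchar(genome_of)[src]
    ins <- pmin(gl, pmax(read_length, round(rnorm(n_pairs, insert_mean,
                                                  insert_sd))))
    start <- floor(runif(n_pairs) * (gl - ins + 1))  # 0-based
    g <- genome_of[src]
    fwd <- substring(g, start + 1L, start + read_length)
    rev <- revcomp(substring(g, start + ins - read_length + 1L, start + ins))
    fwd <- cpp_add_errors(fwd, error_rate)
    rev <- cpp_add_errors(rev, error_rate)
    id <- sprintf("shot_%06d", seq_len(n_pairs))
    truth <- data.frame(read_id = id,
                        label = ifelse(is_host, "host", tab$label[src]),
                        strain = ifelse(is_host, "host", tab$strain[src]),
                        stringsAsFactors = FALSE)
    out <- new_read_pairs(id, fwd, quality_string(nchar(fwd)),
                          rev, quality_string(nchar(rev)), truth, "shotgun")
    p <- expected_proportions(design, "shotgun") * (1 - design$host_fraction)
    attr(out, "expected_proportions") <- c(p, host = design$host_fraction)
    out
  })
}

#' Write / read paired FASTQ (4-line, Phred+33)
#'
#' @param pairs A `"read_pairs"` object.
#' @param dir Output directory.
#' @param prefix File prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`
#'   and the ground-truth table `<prefix>_truth.tsv`.
#' @return Paths of the two FASTQ files, invisibly.
#' @export
write_read_pairs <- function(pairs, dir, prefix = pairs$type) {
  stopifnot(inherits(pairs, "read_pairs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  w <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, pairs$id))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  w(pairs$fwd_seq, pairs$fwd_qual, p1)
  w(pairs$rev_seq, pairs$rev_qual, p2)
  write.table(pairs$truth, file.path(dir, paste0(prefix, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_read_pairs
#' @param r1,r2 Paths to the two mate FASTQ files.
#' @export
read_read_pairs <- function(r1, r2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1); b <- rd(r2)
  if (!identical(a$id, b$id)) stop("mate FASTQ files disagree on read ids")
  new_read_pairs(a$id, a$seq, a$qual, b$seq, b$qual,
                 data.frame(read_id = a$id, label = NA_character_,
                            strain = NA_character_, stringsAsFactors = FALSE),
                 "unknown")
}
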