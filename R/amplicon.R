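#' Extract one mate of a read-pair set as a reads table
#'
#' @param pairs A `"read_pairs"` object.
#' @param mate 1 (forward) or 2 (reverse).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
reads_table <- function(pairs, mate = 1) {
  stopifnot(inherits(pairs, "read_pairs"), mate %in% c(1, 2))
  if (mate == 1)
    data.frame(id = pairs$id, seq = pairs$fwd_seq, qual = pairs$fwd_qual,
               stringsAsFactors = FALSE)
  else
    data.frame(id = pairs$id, seq = pairs$rev_seq, qual = pairs$rev_qual,
               stringsAsFactors = FALSE)
}

check_reads_df <- function(reads) {
  if (!is.data.frame(reads) || !all(c("id", "seq", "qual") %in% names(reads)))
    stop("reads must be a data.frame with columns id, seq, qual")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop("malformed FASTQ record '", reads$id[bad[1]],
         "': sequence and quality lengths differ")
  invisible(reads)
}

#' Trailing-quality trimming with a minimum-length filter
#'
#' Bases are removed from the 3' end while the terminal base quality is below
#' `trailing_q` (Phred+33); records shorter than `min_len` after trimming are
#' rejected (the `TRAILING:20 MINLEN:50` rule).
#'
#' @param reads data.frame with `id`, `seq`, `qual` (see [reads_table()]).
#' @param trailing_q Phred quality threshold.
#' @param min_len Minimum retained length in bases.
#' @return List with `reads` (trimmed survivors), `rejected` (ids of records
#'   dropped by the length filter).
#' @export
quality_trim <- function(reads, trailing_q = 20, min_len = 50) {
  check_reads_df(reads)
  tr <- cpp_quality_trim(reads$seq, reads$qual, as.integer(trailing_q),
                         as.integer(min_len))
  keep <- tr$keep
  list(reads = data.frame(id = reads$id[keep], seq = tr$seq[keep],
                          qual = tr$qual[keep], stringsAsFactors = FALSE),
       rejected = reads$id[!keep])
}

#' Merge read pairs by best ungapped overlap
#'
#' The reverse mate is reverse-complemented and the best ungapped overlap
#' (maximising matches minus mismatches) is chosen among all offsets with
#' overlap >= `min_overlap` and mismatch fraction <= `max_mismatch_frac` —
#' including "outie" offsets where the insert is shorter than the reads, in
#' which case only the overlapping fragment is reported. Disagreeing overlap
#' bases are resolved in favour of the higher-quality base. Pairs with no
#' qualifying overlap are rejected; pairs with an empty mate are rejected and
#' counted separately.
#'
#' @param fwd,rev data.frames with `id`, `seq`, `qual`, matched row by row
#'   (same read ids).
#' @param min_overlap Minimum overlap in bases.
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return List with `reads` (merged synthetic reads), `unmerged` (ids),
#'   `empty` (ids with an empty mate).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 10, max_mismatch_frac = 0.25) {
  check_reads_df(fwd); check_reads_df(rev)
  if (!identical(fwd$id, rev$id)) stop("mates must carry identical read ids")
  empty <- nchar(fwd$seq) == 0 | nchar(rev$seq) == 0
  res <- cpp_merge_pairs(fwd$seq, fwd$qual, revcomp(rev$seq),
                         str_rev(rev$qual), as.integer(min_overlap),
                         max_mismatch_frac)
  ok <- res$merged & !empty
  list(reads = data.frame(id = fwd$id[ok], seq = res$seq[ok],
                          qual = res$qual[ok], stringsAsFactors = FALSE),
       unmerged = fwd$id[!res$merged & !empty],
       empty = fwd$id[empty])
}

#' Trim residual sequencing adapters from merged reads
#'
#' Removes a read prefix matching a suffix of the 5' adapter and a read
#' suffix matching a prefix of the 3' adapter when the overlap is at least
#' `min_overlap` bases with a mismatch fraction of at most `error_rate`
#' (`-a AGATCGGAAG -g CTTCCGATCT -e 0.1 -O 6` semantics). Non-matching reads
#' pass through unchanged.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param adapter_5p Adapter expected at the 5' end.
#' @param adapter_3p Adapter expected at the 3' end.
#' @param error_rate Allowed mismatch fraction over the matched overlap.
#' @param min_overlap Minimum adapter overlap in bases.
#' @return data.frame of trimmed reads (same rows, possibly shorter).
#' @export
trim_residual_adapters <- function(reads, adapter_5p = "CTTCCGATCT",
                                   adapter_3p = "AGATCGGAAG",
                                   error_rate = 0.1, min_overlap = 6) {
  check_reads_df(reads)
  res <- cpp_trim_adapters(reads$seq, reads$qual, adapter_5p, adapter_3p,
                           error_rate, as.integer(min_overlap))
  data.frame(id = reads$id, seq = res$seq, qual = res$qual,
             stringsAsFactors = FALSE)
}

#' Demultiplex merged reads by inline barcode combinations
#'
#' A read is assigned to the unique sample whose forward and reverse 8-bp
#' inline barcodes each match the read ends within `max_mismatch` Hamming
#' distance; both ends are then stripped through the primer. Reads failing
#' the forward-orientation test are also tested reverse-complemented (after
#' merging, two-sided inline barcoding makes orientation ambiguous); when a
#' sample's barcode pair is orientation-symmetric the primer sequences decide
#' the orientation. Ambiguous (multi-sample) or unmatched reads are routed to
#' the unassigned bin.
#'
#' @param reads data.frame with `id`, `seq` (and optionally `qual`).
#' @param scheme A [barcode_scheme()].
#' @param max_mismatch Mismatches tolerated per barcode.
#' @return List with `samples` (named list of data.frames: `id`, `seq`,
#'   `prefix`, `suffix`, `orientation` — prefix/suffix are the stripped
#'   barcode/spacer/primer ends, so the merged read can be reconstructed) and
#'   `unassigned` (data.frame of unassigned reads).
#' @export
demultiplex <- function(reads, scheme, max_mismatch = 1) {
  if (!all(c("id", "seq") %in% names(reads)))
    stop("reads must have columns id, seq")
  validate_barcode_scheme(scheme, max_mismatch)
  n <- nrow(reads)
  ne <- nrow(scheme)
  seq_f <- reads$seq
  seq_r <- revcomp(seq_f)
  len <- nchar(seq_f)
  # barcode regions per orientation
  head_f <- substr(seq_f, 1L, 8L); tailrc_f <- substr(seq_r, 1L, 8L)
  head_r <- substr(seq_r, 1L, 8L); tailrc_r <- substr(seq_f, 1L, 8L)
  # per (entry, orientation): logical match matrix and primer score
  match_mat <- array(FALSE, dim = c(n, ne, 2))
  pscore <- array(NA_integer_, dim = c(n, ne, 2))
  for (e in seq_len(ne)) {
    fb <- scheme$fwd_barcode[e]; rb <- scheme$rev_barcode[e]
    fp <- scheme$fwd_primer[e];  rp <- scheme$rev_primer[e]
    f_off <- 8L + nchar(scheme$fwd_spacer[e]) + 1L
    r_off <- 8L + nchar(scheme$rev_spacer[e]) + 1L
    for (o in 1:2) {
      s <- if (o == 1) seq_f else seq_r
      s_rc <- if (o == 1) seq_r else seq_f
      hd <- if (o == 1) head_f else head_r
      tl <- if (o == 1) tailrc_f else tailrc_r
      m <- cpp_hamming_vec(hd, fb) <= max_mismatch &
           cpp_hamming_vec(tl, rb) <= max_mismatch
      match_mat[, e, o] <- m
      if (any(m)) {
        ps <- rep(NA_integer_, n)
        ps[m] <- cpp_iupac_mismatch(s[m], fp, rep(f_off, sum(m))) +
                 cpp_iupac_mismatch(s_rc[m], rp, rep(r_off, sum(m)))
        pscore[, e, o] <- ps
      }
    }
  }
  hits1 <- matrix(match_mat[, , 1], nrow = n)
  hits2 <- matrix(match_mat[, , 2], nrow = n)
  entry_any <- hits1 | hits2
  n_entry_hits <- rowSums(entry_any)
  assigned_entry <- rep(NA_integer_, n)
  assigned_orient <- rep(NA_integer_, n)
  single <- which(n_entry_hits == 1)
  if (length(single)) {
    e <- max.col(entry_any[single, , drop = FALSE], ties.method = "first")
    m1 <- hits1[cbind(single, e)]
    m2 <- hits2[cbind(single, e)]
    ps1 <- pscore[cbind(single, e, 1L)]
    ps2 <- pscore[cbind(single, e, 2L)]
    # orientation-symmetric barcode pairs match both ways: primers decide,
    # ties go to the forward orientation
    o <- ifelse(m1 & m2, ifelse(!is.na(ps2) & !is.na(ps1) & ps2 < ps1, 2L, 1L),
                ifelse(m2, 2L, 1L))
    assigned_entry[single] <- e
    assigned_orient[single] <- o
  }
  # strip ends through the primer
  samples <- setNames(vector("list", ne), scheme$sample_id)
  ok <- !is.na(assigned_entry)
  for (e in seq_len(ne)) {
    idx <- which(ok & assigned_entry == e)
    if (!length(idx)) {
      samples[[e]] <- data.frame(id = character(0), seq = character(0),
                                 prefix = character(0), suffix = character(0),
                                 orientation = character(0),
                                 stringsAsFactors = FALSE)
      next
    }
    front <- 8L + nchar(scheme$fwd_spacer[e]) + nchar(scheme$fwd_primer[e])
    back <- 8L + nchar(scheme$rev_spacer[e]) + nchar(scheme$rev_primer[e])
    s <- ifelse(assigned_orient[idx] == 1, seq_f[idx], seq_r[idx])
    l <- nchar(s)
    long_enough <- l > front + back
    if (!all(long_enough)) {
      ok[idx[!long_enough]] <- FALSE
      idx <- idx[long_enough]; s <- s[long_enough]; l <- l[long_enough]
    }
    samples[[e]] <- data.frame(
      id = reads$id[idx],
      seq = substr(s, front + 1L, l - back),
      prefix = substr(s, 1L, front),
      suffix = substr(s, l - back + 1L, l),
      orientation = ifelse(assigned_orient[idx] == 1, "fwd", "rev"),
      stringsAsFactors = FALSE)
  }
  list(samples = samples,
       unassigned = data.frame(id = reads$id[!ok], seq = seq_f[!ok],
                               stringsAsFactors = FALSE))
}
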