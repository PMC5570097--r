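as_reference_set <- function(refs) {
  if (inherits(refs, "mock_references")) refs <- refs$genomes
  if (methods::is(refs, "DNAStringSet")) refs <- setNames(as.character(refs),
                                                          names(refs))
  if (!is.character(refs) || is.null(names(refs)))
    stop("references must be a named character vector or DNAStringSet")
  if (anyDuplicated(names(refs))) stop("reference set has duplicate ids")
  refs
}

#' Map reads to a reference set by ungapped seed-and-extend
#'
#' Each read receives its best end-to-end ungapped placement (both strands)
#' found through a k-mer seed index; mismatches are counted against the
#' reference. Reads whose best placement is tied across two or more
#' locations are flagged non-unique (the mapping-quality filter analog:
#' uniqueness of the best placement); reads whose best mismatch fraction
#' exceeds `max_mismatch_frac` go to the unaligned pool. Adequate for
#' high-complexity (synthetic i.i.d.) references; externally produced SAM
#' can be ingested instead via [read_sam_alignments()].
#'
#' @param reads Character vector of read sequences, optionally named by read
#'   id, or a data.frame with `id` and `seq`.
#' @param refs Named character vector / `DNAStringSet` of reference
#'   sequences, or a [build_references()] result (its genomes are used).
#' @param k Seed k-mer length.
#' @param max_mismatch_frac Maximum mismatch fraction for an accepted
#'   placement.
#' @return List with `alignments` (data.frame: `read_id`, `target`, `start`
#'   (0-based), `end` (half-open), `mismatches`, `read_length`, `unique`,
#'   `strand`) and `unaligned` (character vector of read ids).
#' @export
map_reads <- function(reads, refs, k = 21, max_mismatch_frac = 0.1) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  refs <- as_reference_set(refs)
  ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  res <- cpp_map_reads(unname(reads), unname(refs), as.integer(k),
                       max_mismatch_frac)
  aligned <- !is.na(res$ref)
  aln <- data.frame(read_id = ids[aligned],
                    target = names(refs)[res$ref[aligned]],
                    start = res$start[aligned],
                    end = res$start[aligned] + res$read_length[aligned],
                    mismatches = res$mismatches[aligned],
                    read_length = res$read_length[aligned],
                    unique = res$n_best[aligned] == 1L,
                    strand = res$strand[aligned],
                    stringsAsFactors = FALSE)
  list(alignments = aln, unaligned = ids[!aligned])
}

#' Remove read pairs matching the host genome
#'
#' A pair is retained only if *neither* mate aligns to the host reference
#' (within `max_mismatch_frac`); a missing/empty mate counts as failing to
#' align. The removal count is also reported as a fraction of input pairs.
#'
#' @param pairs A `"read_pairs"` object.
#' @param host Host reference: character string, named character vector,
#'   `DNAStringSet`, or a [build_references()] result (its `$host` is used).
#' @inheritParams map_reads
#' @return List with `pairs` (retained subset), `removed` (count) and
#'   `removed_fraction`.
#' @export
host_filter <- function(pairs, host, k = 21, max_mismatch_frac = 0.1) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (inherits(host, "mock_references")) host <- c(host = host$host)
  if (is.character(host) && is.null(names(host))) names(host) <- "host"
  host <- as_reference_set(host)
  hit_ids <- function(seqs) {
    m <- map_reads(setNames(seqs, pairs$id), host, k, max_mismatch_frac)
    unique(m$alignments$read_id)
  }
  hits <- union(hit_ids(pairs$fwd_seq), hit_ids(pairs$rev_seq))
  keep <- !(pairs$id %in% hits)
  kept <- new_read_pairs(pairs$id[keep], pairs$fwd_seq[keep],
                         pairs$fwd_qual[keep], pairs$rev_seq[keep],
                         pairs$rev_qual[keep],
                         pairs$truth[keep, , drop = FALSE], pairs$type)
  list(pairs = kept, removed = sum(!keep),
       removed_fraction = if (pairs$n_pairs > 0) sum(!keep) / pairs$n_pairs
                          else 0)
}

#' Drop discordant mate pairs
#'
#' Keeps alignments of pairs whose two mates map to the same target in
#' opposite orientations with an insert of at most `max_insert` bases;
#' single-mate alignments (the other mate unaligned or non-unique) are kept.
#' Mate ids are read ids (one alignment per mate at most).
#'
#' @param alignments Alignment data.frame from [map_reads()] (unique reads,
#'   both mates pooled with identical read ids per pair).
#' @param max_insert Maximum insert size in bases.
#' @return Filtered alignment data.frame.
#' @export
enforce_pair_concordance <- function(alignments, max_insert = 1500) {
  if (nrow(alignments) == 0) return(alignments)
  ord <- order(alignments$read_id)
  a <- alignments[ord, , drop = FALSE]
  cnt <- table(a$read_id)
  paired <- a$read_id %in% names(cnt)[cnt == 2]
  i1 <- which(paired)[c(TRUE, FALSE)]  # first mate of each sorted pair
  i2 <- i1 + 1L
  bad <- !(a$target[i1] == a$target[i2] & a$strand[i1] != a$strand[i2] &
             (pmax(a$end[i1], a$end[i2]) - pmin(a$start[i1], a$start[i2])) <=
               max_insert)
  drop <- c(i1[bad], i2[bad])
  if (length(drop)) a <- a[-drop, , drop = FALSE]
  a
}

#' Tile reference sequences into fixed-width windows
#'
#' Half-open 0-based tiling `[0,w), [w,2w), ...`; a trailing remainder is
#' kept as a short final window.
#'
#' @param ref_lengths Named integer vector of reference lengths, or a
#'   reference set accepted by [map_reads()].
#' @param width Window width in bases (default 10 kb).
#' @return data.frame with `target`, `start`, `end`.
#' @export
make_windows <- function(ref_lengths, width = 10000) {
  if (width <= 0) stop("'width' must be positive")
  if (!is.numeric(ref_lengths)) {
    refs <- as_reference_set(ref_lengths)
    ref_lengths <- setNames(nchar(refs), names(refs))
  }
  if (any(ref_lengths <= 0)) stop("reference lengths must be positive")
  out <- lapply(names(ref_lengths), function(t) {
    L <- ref_lengths[[t]]
    starts <- seq(0L, L - 1L, by = width)
    data.frame(target = t, start = starts,
               end = pmin(starts + width, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(windows$target,
                         IRanges::IRanges(start = windows$start + 1L,
                                          end = windows$end))
}

alignments_to_granges <- function(alignments, targets) {
  unknown <- setdiff(unique(alignments$target), targets)
  if (length(unknown))
    stop("alignments refer to unknown target(s): ",
         paste(unknown, collapse = ", "))
  GenomicRanges::GRanges(alignments$target,
                         IRanges::IRanges(start = alignments$start + 1L,
                                          end = alignments$end))
}

#' Per-window read counts and mean read identity
#'
#' A read increments every window its interval overlaps by at least one base
#' (a window-boundary-spanning read counts in both windows). The identity
#' factor of a window is the mean over contributing reads of
#' `1 - mismatches / read_length` — a proxy for the evolutionary distance
#' between the sampled strain and the reference; it is `NA` for windows
#' without reads.
#'
#' @param alignments Alignment data.frame (filter to `unique` placements
#'   first).
#' @param windows Window data.frame from [make_windows()].
#' @return `windows` with added columns `read_count` and `id_factor`.
#' @export
window_coverage <- function(alignments, windows) {
  wg <- windows_to_granges(windows)
  windows$read_count <- 0L
  windows$id_factor <- NA_real_
  if (nrow(alignments) > 0) {
    ag <- alignments_to_granges(alignments, unique(windows$target))
    windows$read_count <- GenomicRanges::countOverlaps(wg, ag, minoverlap = 1L)
    hits <- GenomicRanges::findOverlaps(wg, ag, minoverlap = 1L)
    ident <- 1 - alignments$mismatches / alignments$read_length
    means <- tapply(ident[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
    windows$id_factor[as.integer(names(means))] <- as.numeric(means)
  }
  windows
}

#' @rdname window_coverage
#' @export
window_identity <- window_coverage

#' Windowed per-species abundance summaries
#'
#' For each species, the mean and median read count over *all* of its windows
#' (zero-count windows included), the breadth (fraction of windows with at
#' least one read) and the adjusted mean: the mean is retained only when
#' breadth is at least `breadth_threshold` (default 20% of windows),
#' otherwise 0 — a guard against a handful of high-count windows (mis-mapping
#' or horizontally transferred segments) fabricating abundance for an absent
#' genome.
#'
#' @param profiles Window profiles from [window_coverage()] (every window of
#'   each reference present).
#' @param species_map Named character vector mapping target id -> species
#'   (defaults to target = species).
#' @param breadth_threshold Minimum breadth for retaining the mean.
#' @return data.frame with `species`, `n_windows`, `mean`, `median`,
#'   `breadth`, `adjusted_mean`.
#' @export
species_summary <- function(profiles, species_map = NULL,
                            breadth_threshold = 0.2) {
  if (!all(c("target", "read_count") %in% names(profiles)))
    stop("'profiles' must come from window_coverage()")
  if (nrow(profiles) == 0) stop("species with zero windows")
  sp <- if (is.null(species_map)) profiles$target
        else {
          miss <- setdiff(unique(profiles$target), names(species_map))
          if (length(miss)) stop("species_map missing targets: ",
                                 paste(miss, collapse = ", "))
          unname(species_map[profiles$target])
        }
  out <- do.call(rbind, lapply(split(profiles$read_count, sp), function(x) {
    data.frame(n_windows = length(x), mean = mean(x),
               median = as.numeric(median(x)), breadth = mean(x >= 1))
  }))
  out$species <- rownames(out)
  rownames(out) <- NULL
  out$adjusted_mean <- ifelse(out$breadth >= breadth_threshold, out$mean, 0)
  out[, c("species", "n_windows", "mean", "median", "breadth",
          "adjusted_mean")]
}

#' Per-million normalisation of windowed abundance
#'
#' `adjusted_mean * 1e6 / total_sample_reads`: reads per million sequenced
#' reads per 10-kb genomic window. The denominator is the total read count
#' of the sample *before* host filtering and including unaligned reads.
#'
#' @param adjusted_mean Numeric vector of adjusted means.
#' @param total_sample_reads Total reads in the sample (> 0).
#' @return Numeric vector of normalised abundances.
#' @export
normalize_abundance <- function(adjusted_mean, total_sample_reads) {
  if (length(total_sample_reads) != 1 || total_sample_reads <= 0)
    stop("'total_sample_reads' must be a single positive count")
  adjusted_mean * 1e6 / total_sample_reads
}

#' Ingest a SAM file as alignment records
#'
#' Reads the subset of SAM needed downstream (read id, target, position,
#' read length, NM mismatch count, mapping quality) via Rsamtools. The
#' uniqueness flag is `mapq >= mapq_min`, mirroring a `-q 10` filter.
#'
#' @param path Path to a SAM (or BAM) file with NM tags.
#' @param mapq_min Mapping-quality threshold for the uniqueness flag.
#' @return Alignment data.frame as from [map_reads()].
#' @export
read_sam_alignments <- function(path, mapq_min = 10) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam_alignments() requires the Rsamtools package")
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "mapq", "strand"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(x$pos)
  data.frame(read_id = x$qname[mapped],
             target = as.character(x$rname[mapped]),
             start = x$pos[mapped] - 1L,
             end = x$pos[mapped] - 1L + x$qwidth[mapped],
             mismatches = x$tag$NM[mapped],
             read_length = x$qwidth[mapped],
             unique = x$mapq[mapped] >= mapq_min,
             strand = as.character(x$strand[mapped]),
             stringsAsFactors = FALSE)
}
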