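#' Dereplicate full-length sequences across samples
#'
#' Identical full-length sequences (uppercased) are collapsed into one record
#' keyed by the md5 hex digest of the sequence — a stable name that makes
#' identical OTUs directly comparable across experiments. Per-sample counts
#' are preserved; records are ordered by decreasing total count, ties broken
#' lexicographically by key.
#'
#' @param sample_seqs Named list: sample id -> character vector of sequences
#'   (a single character vector is treated as one sample, `"sample1"`).
#' @return An object of class `"derep_set"`: list with `records` (data.frame
#'   `key`, `sequence`, `total`) and `counts` (integer matrix, records x
#'   samples).
#' @export
dereplicate <- function(sample_seqs) {
  if (is.character(sample_seqs)) sample_seqs <- list(sample1 = sample_seqs)
  if (is.null(names(sample_seqs)) || any(!nzchar(names(sample_seqs))))
    stop("'sample_seqs' must be a named list of sequence vectors")
  samples <- names(sample_seqs)
  seqs <- toupper(unlist(sample_seqs, use.names = FALSE))
  from <- rep(samples, lengths(sample_seqs))
  uniq <- unique(seqs)
  keys <- as.character(openssl::md5(uniq))
  counts <- matrix(0L, nrow = length(uniq), ncol = length(samples),
                   dimnames = list(keys, samples))
  idx <- match(seqs, uniq)
  for (s in samples) {
    t <- tabulate(idx[from == s], nbins = length(uniq))
    counts[, s] <- t
  }
  total <- as.integer(rowSums(counts))
  ord <- order(-total, keys)
  structure(list(records = data.frame(key = keys[ord], sequence = uniq[ord],
                                      total = total[ord],
                                      stringsAsFactors = FALSE),
                 counts = counts[ord, , drop = FALSE]),
            class = "derep_set")
}

#' @export
print.derep_set <- function(x, ...) {
  cat("derep_set:", nrow(x$records), "unique sequences,",
      sum(x$records$total), "reads,", ncol(x$counts), "sample(s)\n")
  invisible(x)
}

#' Single-linkage OTU clustering at a small edit-distance radius
#'
#' Dereplicated records are linked whenever their edit distance
#' (substitutions and indels) is at most `d`; OTUs are the connected
#' components of that graph, so linkage is transitive — a chain A-B-C with
#' consecutive distances 1 forms one OTU even though A and C are 2 edits
#' apart. The OTU abundance is the sum of member counts; the representative
#' is the most abundant member (ties to the lexicographically smallest key);
#' OTUs with total abundance below `min_size` are discarded after clustering.
#' For `d = 1` a hashed candidate search keeps clustering near-linear in the
#' number of records; `d >= 2` falls back to all-pairs comparison.
#'
#' @param derep A [dereplicate()] result.
#' @param d Maximum edit distance linking two records (>= 1).
#' @param min_size Minimum final OTU size.
#' @param fastidious Optionally graft OTUs with fewer than 3 reads onto a
#'   larger OTU whose representative lies within edit distance `2 * d`
#'   (a simplified second-pass refinement; default off).
#' @return An object of class `"otu_set"`: list with `otus` (data.frame
#'   `key`, `sequence`, `total` for each retained OTU, ordered by decreasing
#'   total then key), `counts` (matrix, OTUs x samples), `members` (list of
#'   member keys per OTU), `discarded_total` (reads in sub-threshold OTUs).
#' @export
cluster_otus <- function(derep, d = 1, min_size = 10, fastidious = FALSE) {
  stopifnot(inherits(derep, "derep_set"))
  if (d < 1) stop("'d' must be >= 1")
  rec <- derep$records
  n <- nrow(rec)
  if (n == 0) stop("empty dereplicated set")
  lab <- if (d == 1) cpp_cluster_d1(rec$sequence)
         else cpp_cluster_bruteforce(rec$sequence, as.integer(d))
  totals <- tapply(rec$total, lab, sum)
  if (fastidious) {
    small <- as.integer(names(totals)[totals < 3])
    large <- as.integer(names(totals)[totals >= 3])
    if (length(small) && length(large)) {
      rep_of <- function(l) {
        m <- which(lab == l)
        m[order(-rec$total[m], rec$key[m])][1]
      }
      large_reps <- vapply(large, rep_of, integer(1))
      for (l in small) {
        r <- rep_of(l)
        dist2 <- vapply(large_reps, function(j)
          cpp_bounded_edit(rec$sequence[r], rec$sequence[j],
                           as.integer(2 * d)), integer(1))
        hit <- which(dist2 <= 2 * d)
        if (length(hit)) {
          # graft onto the most abundant qualifying OTU
          best <- hit[order(-totals[as.character(large[hit])])][1]
          lab[lab == l] <- large[best]
        }
      }
      totals <- tapply(rec$total, lab, sum)
    }
  }
  # representative per cluster: most abundant member, tie -> smallest key
  ord <- order(lab, -rec$total, rec$key)
  first <- ord[!duplicated(lab[ord])]
  cl_lab <- lab[first]
  cl <- data.frame(label = cl_lab, key = rec$key[first],
                   sequence = rec$sequence[first],
                   total = as.integer(totals[as.character(cl_lab)]),
                   stringsAsFactors = FALSE)
  keep <- cl$total >= min_size
  discarded_total <- sum(cl$total[!keep])
  cl <- cl[keep, , drop = FALSE]
  cl <- cl[order(-cl$total, cl$key), , drop = FALSE]
  members <- split(rec$key, lab)
  counts <- rowsum(derep$counts, group = lab, reorder = FALSE)
  rownames(counts) <- vapply(rownames(counts), function(l)
    cl$key[match(as.integer(l), cl$label)] %||% NA_character_, character(1))
  counts <- counts[match(cl$key, rownames(counts)), , drop = FALSE]
  structure(list(otus = data.frame(key = cl$key, sequence = cl$sequence,
                                   total = cl$total, stringsAsFactors = FALSE),
                 counts = counts,
                 members = setNames(members[as.character(cl$label)], cl$key),
                 discarded_total = discarded_total),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat("otu_set:", nrow(x$otus), "OTUs,", sum(x$otus$total), "reads retained,",
      x$discarded_total, "reads in discarded clusters\n")
  invisible(x)
}

# split a lineage string into trimmed rank labels
split_lineage <- function(x) trimws(strsplit(x, ";", fixed = TRUE)[[1]])

#' Consensus taxonomy assignment against an ITS reference database
#'
#' For each query, references with global alignment identity at least
#' `min_similarity` are collected in decreasing identity order up to
#' `max_accepts`. Descending the ranks from domain, the most frequent taxon
#' among the accepts is kept while its fraction is at least
#' `min_consensus_fraction` *and* it is the unique mode; otherwise the
#' lineage is truncated at the parent rank. Queries with no accepts are
#' `"Unassigned"`.
#'
#' @param seqs Character vector of query sequences (OTU representatives).
#' @param ref_db data.frame with `id`, `sequence`, `taxonomy` (UNITE-style
#'   rank-prefixed lineages), e.g. from [read_its_db()] or
#'   [build_references()]`$its_db`.
#' @param min_similarity Identity threshold for accepting a reference.
#' @param max_accepts Maximum number of accepted references per query.
#' @param min_consensus_fraction Minimum fraction of accepts that must agree
#'   at a rank for it to be kept.
#' @return Character vector of lineage strings.
#' @export
assign_taxonomy <- function(seqs, ref_db, min_similarity = 0.98,
                            max_accepts = 10, min_consensus_fraction = 0.4) {
  if (nrow(ref_db) == 0) stop("empty reference database")
  idmat <- vapply(seq_len(nrow(ref_db)), function(j)
    seq_identity_many(seqs, ref_db$sequence[j]), numeric(length(seqs)))
  idmat <- matrix(idmat, nrow = length(seqs))
  vapply(seq_along(seqs), function(i) {
    ids <- idmat[i, ]
    acc <- which(ids >= min_similarity)
    if (!length(acc)) return("Unassigned")
    acc <- acc[order(-ids[acc])]
    acc <- head(acc, max_accepts)
    lineages <- lapply(ref_db$taxonomy[acc], split_lineage)
    depth <- max(lengths(lineages))
    kept <- character(0)
    for (r in seq_len(depth)) {
      vals <- vapply(lineages, function(l)
        if (length(l) >= r) l[r] else NA_character_, character(1))
      tab <- table(vals[!is.na(vals)])
      if (!length(tab)) break
      mx <- max(tab)
      modes <- names(tab)[tab == mx]
      frac <- mx / length(acc)
      if (length(modes) != 1L || frac < min_consensus_fraction) break
      kept <- c(kept, modes)
    }
    if (!length(kept)) "Unassigned" else paste(kept, collapse = ";")
  }, character(1))
}

#' Extract one rank from rank-prefixed lineages
#'
#' @param lineage Character vector of lineage strings.
#' @param prefix Rank prefix, e.g. `"s__"` or `"g__"`.
#' @param pretty Replace underscores by spaces in the returned labels.
#' @return Character vector (NA where the rank is absent).
#' @export
lineage_rank <- function(lineage, prefix = "s__", pretty = TRUE) {
  out <- vapply(lineage, function(x) {
    parts <- split_lineage(x)
    hit <- grep(paste0("^", prefix), parts, value = TRUE)
    if (!length(hit)) NA_character_ else sub(paste0("^", prefix), "", hit[1])
  }, character(1), USE.NAMES = FALSE)
  if (pretty) out <- gsub("_", " ", out)
  out
}

#' Map per-sample dereplicated records onto a global OTU table
#'
#' Each sample's dereplicated records are matched by md5 key to the global
#' cluster membership; abundances are summed per global OTU. Reads whose key
#' belongs to no retained global OTU are reported as unmapped.
#'
#' @param sample_dereps Named list: sample id -> [dereplicate()] result (or
#'   character vector of that sample's reads).
#' @param otus A global [cluster_otus()] result.
#' @return List with `counts` (matrix, global OTUs x samples) and `unmapped`
#'   (named integer vector of unmapped reads per sample).
#' @export
combine_samples <- function(sample_dereps, otus) {
  stopifnot(inherits(otus, "otu_set"))
  key2otu <- rep(names(otus$members), lengths(otus$members))
  names(key2otu) <- unlist(otus$members, use.names = FALSE)
  samples <- names(sample_dereps)
  counts <- matrix(0L, nrow = nrow(otus$otus), ncol = length(samples),
                   dimnames = list(otus$otus$key, samples))
  unmapped <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    d <- sample_dereps[[s]]
    if (is.character(d)) d <- dereplicate(setNames(list(d), s))
    rec <- d$records
    hit <- key2otu[rec$key]
    unmapped[s] <- sum(rec$total[is.na(hit)])
    ok <- !is.na(hit)
    if (any(ok)) {
      agg <- tapply(rec$total[ok], hit[ok], sum)
      counts[names(agg), s] <- counts[names(agg), s] + as.integer(agg)
    }
  }
  list(counts = counts, unmapped = unmapped)
}
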