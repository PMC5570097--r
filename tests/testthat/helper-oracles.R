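# Independent oracles and fixture builders used across the suite.

# connected components of the <= d edit-distance graph, via base R's adist()
# and a plain union-find (independent of the package's clustering code)
oracle_components <- function(seqs, d = 1) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  dm <- utils::adist(seqs, seqs)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (dm[i, j] <= d) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition (for comparing labelings)
partition_signature <- function(labels) {
  unname(sort(vapply(split(seq_along(labels), labels),
                     function(i) paste(i, collapse = ","), character(1))))
}

# exhaustive ungapped overlap scan (independent of the C++ merger):
# returns the merged sequence or NULL
oracle_merge <- function(a, b_rc, min_overlap, max_mismatch_frac) {
  La <- nchar(a); Lb <- nchar(b_rc)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b_rc, "")[[1]]
  best <- NULL; best_score <- -Inf; best_ov <- -1
  for (o in seq(-(Lb - min_overlap), La - min_overlap)) {
    s <- max(0, o); e <- min(La, o + Lb)
    ov <- e - s
    if (ov < min_overlap) next
    mm <- sum(av[(s + 1):e] != bv[(s + 1):e - o])
    if (mm > max_mismatch_frac * ov) next
    score <- ov - 2 * mm
    if (score > best_score || (score == best_score && ov > best_ov)) {
      best_score <- score; best_ov <- ov
      merged <- if (o >= 0) {
        tail_part <- if (o + Lb > La) paste(bv[(La - o + 1):Lb], collapse = "") else ""
        paste0(substr(a, 1, s), substr(a, s + 1, e), tail_part)
      } else substr(a, s + 1, e)
      best <- merged
    }
  }
  best
}

random_seqs <- function(n, len_range = c(6, 14)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"),
                 sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# instance with genuine <=1-edit structure: seed sequences plus 1- and 2-edit
# variants (substitutions and indels)
random_cluster_instance <- function(n_base = 8, n_var = 60, len = 10) {
  mutate1 <- function(s) {
    i <- sample(nchar(s), 1)
    op <- sample(c("sub", "ins", "del"), 1)
    if (op == "sub") {
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, i, i)), 1)
      s
    } else if (op == "ins") {
      paste0(substr(s, 1, i), sample(c("A", "C", "G", "T"), 1),
             substr(s, i + 1, nchar(s)))
    } else if (nchar(s) > 2) {
      paste0(substr(s, 1, i - 1), substr(s, i + 1, nchar(s)))
    } else s
  }
  base <- random_seqs(n_base, c(len, len))
  vars <- replicate(n_var, {
    s <- sample(base, 1)
    k <- sample(1:2, 1)
    for (j in seq_len(k)) s <- mutate1(s)
    s
  })
  unique(c(base, vars))
}

# a derep_set built directly from named counts (sequence -> count, one sample)
derep_from_counts <- function(counts, sample = "s1") {
  seqs <- rep(names(counts), counts)
  dereplicate(setNames(list(seqs), sample))
}

# balanced 4-species design used for bias-recovery runs
balanced_design <- function(bias_taxon = NULL, bias = 1, cells = 1e6) {
  species <- c("Saccharomyces cerevisiae", "Metschnikowia pulcherrima",
               "Torulaspora delbrueckii", "Hanseniaspora uvarum")
  taxa <- lapply(species, function(sp) {
    b <- if (!is.null(bias_taxon) && sp == bias_taxon) bias else 1
    taxon_spec(sp, cells = cells, amp_bias = b)
  })
  mock_design(taxa)
}

reads_df <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

phred_string <- function(qs) {
  intToUtf8(qs + 33L, multiple = FALSE)
}
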