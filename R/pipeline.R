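#' Published observed abundances of the seven-strain control mixes
#'
#' The observed ITS-fragment and shotgun abundance values (and the published
#' internally normalised observed/expected ratios) for the two control
#' populations, as printed in the study that assembled them. Together with
#' [control_mix_design()] these allow the observed/expected ratio analysis
#' to be reproduced by exact arithmetic.
#'
#' @return data.frame with `mix`, `species`, `its_observed`,
#'   `shotgun_observed`, `its_ratio_printed`, `shotgun_ratio_printed`.
#' @export
control_mix_observed <- function() {
  path <- system.file("extdata", "control_mix_observed.tsv",
                      package = "fermentome", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

as_its_db <- function(ref_db) {
  if (inherits(ref_db, "mock_references")) ref_db <- ref_db$its_db
  if (!is.data.frame(ref_db) ||
      !all(c("id", "sequence", "taxonomy") %in% names(ref_db)))
    stop("'ref_db' must have columns id, sequence, taxonomy")
  ref_db
}

#' Run the full ITS meta-barcoding pipeline
#'
#' Quality trimming, pair merging, residual-adapter trimming, inline-barcode
#' demultiplexing, whole-dataset md5 dereplication, single-linkage OTU
#' clustering with a minimum OTU size, and consensus taxonomy assignment —
#' producing a combined taxonomy-annotated OTU table plus per-species
#' abundances.
#'
#' @param pairs A `"read_pairs"` object (e.g. [simulate_its_reads()]) or a
#'   list as returned by [read_read_pairs()].
#' @param ref_db ITS reference database (data.frame `id`, `sequence`,
#'   `taxonomy`, or a [build_references()] result).
#' @param scheme A [barcode_scheme()].
#' @param trailing_q,min_len Quality-trimming parameters ([quality_trim()]).
#' @param merge_min_overlap,merge_max_mismatch Pair-merging parameters
#'   ([merge_pairs()]).
#' @param d,min_size,fastidious Clustering parameters ([cluster_otus()]).
#' @param min_similarity,max_accepts,min_consensus_fraction Taxonomy
#'   parameters ([assign_taxonomy()]).
#' @return List with `otus` (data.frame: `key`, `sequence`, `taxonomy`,
#'   `total`, per-sample counts in `counts`), `counts`, `species_abundance`
#'   (named vector: reads per species, from OTUs resolved to species rank),
#'   `derep`, `otu_set`, and `stats` (read accounting at every stage).
#' @export
run_its_pipeline <- function(pairs, ref_db, scheme = barcode_scheme(),
                             trailing_q = 20, min_len = 50,
                             merge_min_overlap = 10, merge_max_mismatch = 0.25,
                             d = 1, min_size = 10, fastidious = FALSE,
                             min_similarity = 0.98, max_accepts = 10,
                             min_consensus_fraction = 0.4) {
  ref_db <- as_its_db(ref_db)
  fwd <- reads_table(pairs, 1)
  rev <- reads_table(pairs, 2)
  n_input <- nrow(fwd)
  t1 <- quality_trim(fwd, trailing_q, min_len)
  t2 <- quality_trim(rev, trailing_q, min_len)
  shared <- intersect(t1$reads$id, t2$reads$id)
  f <- t1$reads[match(shared, t1$reads$id), ]
  r <- t2$reads[match(shared, t2$reads$id), ]
  mg <- merge_pairs(f, r, merge_min_overlap, merge_max_mismatch)
  merged <- trim_residual_adapters(mg$reads)
  dm <- demultiplex(merged, scheme)
  sample_seqs <- lapply(dm$samples, function(s) s$seq)
  n_assigned <- sum(lengths(sample_seqs))
  if (n_assigned == 0) stop("no reads were assigned to any sample")
  derep <- dereplicate(sample_seqs)
  otus <- cluster_otus(derep, d = d, min_size = min_size,
                       fastidious = fastidious)
  taxonomy <- assign_taxonomy(otus$otus$sequence, ref_db, min_similarity,
                              max_accepts, min_consensus_fraction)
  tab <- cbind(otus$otus[, c("key", "sequence", "total")],
               taxonomy = taxonomy, stringsAsFactors = FALSE)
  species <- lineage_rank(taxonomy, "s__")
  ok <- !is.na(species)
  species_abundance <- if (any(ok))
    tapply(tab$total[ok], species[ok], sum)[unique(species[ok])]
  else setNames(numeric(0), character(0))
  stats <- list(n_input = n_input,
                n_quality_rejected = n_input - length(shared),
                n_merged = nrow(mg$reads),
                n_unmerged = length(mg$unmerged) + length(mg$empty),
                n_assigned = n_assigned,
                n_unassigned = nrow(dm$unassigned),
                n_in_otus = sum(otus$otus$total),
                n_discarded_small_otus = otus$discarded_total)
  list(otus = tab, counts = otus$counts,
       species_abundance = species_abundance,
       derep = derep, otu_set = otus, stats = stats)
}

#' Run the full shotgun abundance pipeline
#'
#' Host filtering (pairs retained only when neither mate matches the host),
#' per-mate mapping to the community reference set, exclusion of non-unique
#' placements, optional pair-concordance filtering, 10-kb windowing with
#' per-window counts and mean read identity, breadth-filtered species
#' summaries, and per-million normalisation against the total reads of the
#' sample before any filtering.
#'
#' @param pairs A `"read_pairs"` object (e.g. [simulate_shotgun_reads()]).
#' @param refs Reference set: a [build_references()] result (community
#'   genomes + host), or a named vector/DNAStringSet of genomes (then `host`
#'   must be given separately or `NULL` to skip host filtering).
#' @param host Host reference; defaults to `refs$host` when `refs` is a
#'   [build_references()] result. `NULL` disables host filtering.
#' @param window_width Window width in bases.
#' @param breadth_threshold Minimum fraction of a species' windows with >= 1
#'   read for its mean to be retained ([species_summary()]).
#' @param k,max_mismatch_frac Mapping parameters ([map_reads()]).
#' @param max_insert Maximum concordant insert size; `NULL` disables the
#'   concordance filter.
#' @param exclude Reference ids to exclude from the set before mapping
#'   (e.g. organelle sequences with variable copy number).
#' @return List with `species` (data.frame incl. `adjusted_mean` and
#'   `normalized` reads/million/10-kb window), `windows` (per-window
#'   profiles), `alignments`, `unaligned` (read ids), and `stats`.
#' @export
run_shotgun_pipeline <- function(pairs, refs, host = NULL,
                                 window_width = 10000,
                                 breadth_threshold = 0.2, k = 21,
                                 max_mismatch_frac = 0.1, max_insert = 1500,
                                 exclude = character(0)) {
  if (inherits(refs, "mock_references")) {
    if (is.null(host)) host <- c(host = refs$host)
    refs <- refs$genomes
  }
  refs <- as_reference_set(refs)
  refs <- refs[setdiff(names(refs), exclude)]
  total_reads <- 2L * pairs$n_pairs
  host_removed_fraction <- 0
  if (!is.null(host)) {
    hf <- host_filter(pairs, host, k, max_mismatch_frac)
    host_removed_fraction <- hf$removed_fraction
    pairs <- hf$pairs
  }
  m1 <- map_reads(setNames(pairs$fwd_seq, pairs$id), refs, k,
                  max_mismatch_frac)
  m2 <- map_reads(setNames(pairs$rev_seq, pairs$id), refs, k,
                  max_mismatch_frac)
  aln <- rbind(m1$alignments, m2$alignments)
  n_nonunique <- sum(!aln$unique)
  aln <- aln[aln$unique, , drop = FALSE]
  if (!is.null(max_insert)) aln <- enforce_pair_concordance(aln, max_insert)
  windows <- make_windows(setNames(nchar(refs), names(refs)), window_width)
  profiles <- window_coverage(aln, windows)
  species <- species_summary(profiles, breadth_threshold = breadth_threshold)
  species$normalized <- normalize_abundance(species$adjusted_mean,
                                            total_reads)
  unaligned <- c(m1$unaligned, m2$unaligned)
  stats <- list(total_reads = total_reads,
                host_removed_fraction = host_removed_fraction,
                n_aligned = nrow(aln), n_nonunique = n_nonunique,
                n_unaligned = length(unaligned),
                aligned_fraction = nrow(aln) / max(1L, 2L * pairs$n_pairs))
  list(species = species, windows = profiles, alignments = aln,
       unaligned = unaligned, stats = stats)
}

#' Simulate and analyse a mock community end to end
#'
#' Builds references for `design`, simulates ITS amplicon and shotgun read
#' pairs, runs both pipeline branches, and computes the internally
#' normalised observed/expected ratio report for each platform together
#' with per-taxon ITS/shotgun bias factors.
#'
#' @param design A [mock_design()].
#' @param seed Integer seed governing references and both simulations.
#' @param n_pairs_its,n_pairs_shotgun Read pairs per platform.
#' @param error_rate Per-base substitution error rate.
#' @param anchor Anchor species for internal normalisation.
#' @param fold_threshold Fold threshold for headline bias flags.
#' @return List with `report` (per-taxon data.frame: expected cells,
#'   observed abundances, platform ratios, `bias_factor`, flags), the two
#'   platform [mock_ratios()] reports, the pipeline results (`its`,
#'   `shotgun`) and `refs`.
#' @export
run_mock_experiment <- function(design, seed, n_pairs_its = 50000,
                                n_pairs_shotgun = 50000, error_rate = 0.01,
                                anchor = "Saccharomyces cerevisiae",
                                fold_threshold = 5) {
  refs <- build_references(design, seed = seed)
  its_pairs <- simulate_its_reads(design, refs, n_pairs_its, error_rate,
                                  seed = seed + 1L)
  shot_pairs <- simulate_shotgun_reads(design, refs, n_pairs_shotgun,
                                       error_rate, seed = seed + 2L)
  its <- run_its_pipeline(its_pairs, refs)
  shotgun <- run_shotgun_pipeline(shot_pairs, refs)
  its_obs <- its$species_abundance
  shot_obs <- setNames(shotgun$species$normalized, shotgun$species$species)
  ratios_its <- flag_bias(mock_ratios(its_obs, design, anchor),
                          fold_threshold)
  ratios_shotgun <- flag_bias(mock_ratios(shot_obs, design, anchor),
                              fold_threshold)
  report <- data.frame(taxon = ratios_its$taxon,
                       expected_cells = ratios_its$expected_cells,
                       observed_its = ratios_its$observed,
                       observed_shotgun = ratios_shotgun$observed,
                       ratio_its = ratios_its$ratio,
                       ratio_shotgun = ratios_shotgun$ratio,
                       bias_factor = ifelse(ratios_shotgun$ratio > 0,
                                            ratios_its$ratio /
                                              ratios_shotgun$ratio, NA),
                       flagged_its = ratios_its$flagged,
                       flagged_shotgun = ratios_shotgun$flagged,
                       stringsAsFactors = FALSE)
  list(report = report, ratios_its = ratios_its,
       ratios_shotgun = ratios_shotgun, its = its, shotgun = shotgun,
       refs = refs)
}
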