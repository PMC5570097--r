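#' Specify one taxon of a mock community
#'
#' A taxon here is a strain-level entry: conspecific strains (same `label`)
#' may appear as separate entries with their own cell counts, ITS copy numbers
#' and amplification bias, but share one species-level reference genome and
#' ITS template (the two assay platforms cannot separate conspecific strains).
#'
#' @param label Species name, e.g. `"Saccharomyces cerevisiae"`.
#' @param cells Number of cells added to the mix (> 0).
#' @param strain Strain identifier; defaults to the label.
#' @param genome_length Reference genome length in bases.
#' @param its_copy_number Ribosomal ITS copies per genome (>= 1). Unequal
#'   copy number of the ribosomal repeat is one driver of amplicon bias and is
#'   modelled as a constant per taxon.
#' @param amp_bias Multiplicative ITS amplification factor (> 0, finite);
#'   1 means unbiased. Folds in primer-efficiency effects.
#' @param taxonomy Rank-delimited lineage string (`k__...;p__...;...;s__...`).
#'   Derived from `label` when `NULL`.
#' @return An object of class `"taxon_spec"`.
#' @export
taxon_spec <- function(label, cells, strain = label, genome_length = 1e5,
                       its_copy_number = 4, amp_bias = 1, taxonomy = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(cells) || length(cells) != 1L || !is.finite(cells) || cells <= 0)
    stop("'cells' must be a single positive number")
  if (!is.finite(amp_bias) || amp_bias <= 0)
    stop("'amp_bias' must be finite and positive")
  if (its_copy_number < 1) stop("'its_copy_number' must be >= 1")
  if (genome_length <= 0) stop("'genome_length' must be positive")
  if (is.null(taxonomy)) {
    genus <- strsplit(label, " ")[[1]][1]
    sp <- gsub(" ", "_", label)
    taxonomy <- paste0("k__Fungi;p__Ascomycota;c__Saccharomycetes;",
                       "o__Saccharomycetales;f__unknown;g__", genus,
                       ";s__", sp)
  }
  structure(list(label = label, strain = strain, cells = cells,
                 genome_length = as.integer(genome_length),
                 its_copy_number = as.integer(its_copy_number),
                 amp_bias = amp_bias, taxonomy = taxonomy),
            class = "taxon_spec")
}

#' Define a mock-community design
#'
#' The design is the ground truth of a simulated experiment: which strains
#' are present, at what cell counts, with which ITS copy numbers and
#' amplification biases, plus the fraction of shotgun read pairs contributed
#' by the (grapevine-like) host.
#'
#' @param taxa A list of [taxon_spec()] entries (at least one).
#' @param host_fraction Proportion of shotgun pairs drawn from the host
#'   genome, in `[0, 1)`.
#' @return An object of class `"mock_design"`.
#' @export
mock_design <- function(taxa, host_fraction = 0.01) {
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  if (length(taxa) < 1L) stop("a design needs at least 1 taxon")
  if (!all(vapply(taxa, inherits, logical(1), "taxon_spec")))
    stop("'taxa' must be a list of taxon_spec objects")
  if (host_fraction < 0 || host_fraction >= 1)
    stop("'host_fraction' must be in [0, 1)")
  structure(list(taxa = taxa, host_fraction = host_fraction),
            class = "mock_design")
}

#' @export
print.mock_design <- function(x, ...) {
  cat("Mock community design:", length(x$taxa), "taxa, host fraction",
      x$host_fraction, "\n")
  print(design_table(x), row.names = FALSE)
  invisible(x)
}

#' Tabular view of a mock design
#'
#' @param design A [mock_design()].
#' @return A data.frame with one row per strain.
#' @export
design_table <- function(design) {
  stopifnot(inherits(design, "mock_design"))
  do.call(rbind, lapply(design$taxa, function(t)
    data.frame(label = t$label, strain = t$strain, cells = t$cells,
               genome_length = t$genome_length,
               its_copy_number = t$its_copy_number, amp_bias = t$amp_bias,
               taxonomy = t$taxonomy, stringsAsFactors = FALSE)))
}

# Reference lineages for the seven wine yeasts of the control mixes.
.wine_yeast_taxonomy <- c(
  "Saccharomyces cerevisiae" = "k__Fungi;p__Ascomycota;c__Saccharomycetes;o__Saccharomycetales;f__Saccharomycetaceae;g__Saccharomyces;s__Saccharomyces_cerevisiae",
  "Saccharomyces uvarum"     = "k__Fungi;p__Ascomycota;c__Saccharomycetes;o__Saccharomycetales;f__Saccharomycetaceae;g__Saccharomyces;s__Saccharomyces_uvarum",
  "Metschnikowia pulcherrima" = "k__Fungi;p__Ascomycota;c__Saccharomycetes;o__Saccharomycetales;f__Metschnikowiaceae;g__Metschnikowia;s__Metschnikowia_pulcherrima",
  "Torulaspora delbrueckii"  = "k__Fungi;p__Ascomycota;c__Saccharomycetes;o__Saccharomycetales;f__Saccharomycetaceae;g__Torulaspora;s__Torulaspora_delbrueckii",
  "Debaryomyces hansenii"    = "k__Fungi;p__Ascomycota;c__Saccharomycetes;o__Saccharomycetales;f__Debaryomycetaceae;g__Debaryomyces;s__Debaryomyces_hansenii",
  "Hanseniaspora uvarum"     = "k__Fungi;p__Ascomycota;c__Saccharomycetes;o__Saccharomycetales;f__Saccharomycodaceae;g__Hanseniaspora;s__Hanseniaspora_uvarum")

#' Control-mix designs of the seven-strain wine-yeast mock community
#'
#' Two control populations of 7 wine-yeast strains (6 species, including two
#' *S. cerevisiae* strains) with cell counts spanning five orders of
#' magnitude (1e3 to 1e8 cells).
#'
#' @param mix Which control mix, 1 or 2.
#' @param amp_bias Named numeric vector of amplification-bias overrides keyed
#'   by species label (unlisted species get 1).
#' @param its_copy_number ITS copies per genome, applied to every strain.
#' @param genome_length Reference genome length per species, in bases.
#' @param host_fraction Host (grapevine-like) shotgun read fraction.
#' @return A [mock_design()].
#' @export
control_mix_design <- function(mix = 1, amp_bias = NULL, its_copy_number = 4,
                               genome_length = 1e5, host_fraction = 0.01) {
  stopifnot(mix %in% c(1, 2))
  strains <- c("AWRI796", "AWRI1498", "AWRI1149", "AWRI1152", "AWRI1157",
               "AWRI1176", "AWRI1274")
  species <- c("Saccharomyces cerevisiae", "Saccharomyces cerevisiae",
               "Metschnikowia pulcherrima", "Torulaspora delbrueckii",
               "Debaryomyces hansenii", "Saccharomyces uvarum",
               "Hanseniaspora uvarum")
  cells <- if (mix == 1) c(1e6, 1e4, 1e4, 1e6, 1e7, 1e3, 1e8)
           else          c(1e8, 1e8, 1e6, 1e5, 1e3, 1e5, 1e4)
  taxa <- lapply(seq_along(strains), function(i) {
    b <- 1
    if (!is.null(amp_bias) && species[i] %in% names(amp_bias))
      b <- unname(amp_bias[[species[i]]])
    taxon_spec(label = species[i], strain = strains[i], cells = cells[i],
               genome_length = genome_length,
               its_copy_number = its_copy_number, amp_bias = b,
               taxonomy = unname(.wine_yeast_taxonomy[species[i]]))
  })
  mock_design(taxa, host_fraction = host_fraction)
}

#' Expected read proportions implied by a design
#'
#' ITS amplicon reads are expected in proportion to
#' `cells * its_copy_number * amp_bias`; shotgun reads in proportion to
#' `cells * genome_length` (shotgun is the unbiased channel). Proportions are
#' aggregated to species level and sum to 1.
#'
#' @param design A [mock_design()].
#' @param platform `"its"` or `"shotgun"`.
#' @return Named numeric vector of per-species proportions.
#' @export
expected_proportions <- function(design, platform = c("its", "shotgun")) {
  platform <- match.arg(platform)
  tab <- design_table(design)
  w <- if (platform == "its") tab$cells * tab$its_copy_number * tab$amp_bias
       else tab$cells * tab$genome_length
  p <- tapply(w, tab$label, sum)
  p <- p / sum(p)
  p[unique(tab$label)]
}

#' Expected cell counts per species
#'
#' Conspecific strains are pooled by summing their cells.
#'
#' @param design A [mock_design()].
#' @return Named numeric vector of cells per species.
#' @export
expected_cells <- function(design) {
  tab <- design_table(design)
  out <- tapply(tab$cells, tab$label, sum)
  out[unique(tab$label)]
}

#' Read or write a mock design as YAML
#'
#' @param design A [mock_design()].
#' @param path File path.
#' @return `read_design()` returns a [mock_design()]; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mock_design"))
  x <- list(host_fraction = design$host_fraction,
            taxa = lapply(design$taxa, unclass))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  taxa <- lapply(x$taxa, function(t)
    taxon_spec(label = t$label, cells = t$cells,
               strain = t$strain %||% t$label,
               genome_length = t$genome_length %||% 1e5,
               its_copy_number = t$its_copy_number %||% 4,
               amp_bias = t$amp_bias %||% 1,
               taxonomy = t$taxonomy))
  mock_design(taxa, host_fraction = x$host_fraction %||% 0)
}
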