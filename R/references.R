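#' Generate reference genomes and an ITS reference database for a design
#'
#' One genome and one ITS template are generated per species (conspecific
#' strains share them); `its_copy_number` identical copies of the species'
#' ITS template are embedded at evenly spaced positions in the genome, so the
#' ribosomal repeat is part of the shotgun reference just as in real genomes.
#' Genome and template sequences are i.i.d. uniform over `{A,C,G,T}`, which
#' keeps k-mers effectively unique and ITS templates mutually dissimilar; the
#' pairwise identity between distinct species' templates is verified to be
#' below `max_its_identity` (templates are resampled on the rare violation),
#' so taxonomic classification of the synthetic community is unambiguous.
#'
#' @param design A [mock_design()].
#' @param seed Integer seed; the same seed and design give byte-identical
#'   references.
#' @param its_length ITS template length in bases.
#' @param read_length Read length the references must support; each genome
#'   must be at least 10 times this long.
#' @param host_genome_length Length of the generated host (grapevine-like)
#'   contaminant genome.
#' @param max_its_identity Maximum tolerated pairwise identity between ITS
#'   templates of distinct species.
#' @return An object of class `"mock_references"`: a list with elements
#'   `genomes` (named character vector, one per species), `host` (character),
#'   `its_db` (data.frame: `id`, `sequence`, `taxonomy`), `its_templates`
#'   (named character vector), `its_positions` (list of 0-based copy start
#'   positions per species) and `species` (character vector).
#' @export
build_references <- function(design, seed = NULL, its_length = 160,
                             read_length = 100, host_genome_length = 1e5,
                             max_its_identity = 0.9) {
  stopifnot(inherits(design, "mock_design"))
  tab <- design_table(design)
  species <- unique(tab$label)
  with_seed(seed, {
    glen <- copies <- integer(0)
    tax <- character(0)
    for (sp in species) {
      rows <- tab[tab$label == sp, , drop = FALSE]
      if (length(unique(rows$genome_length)) > 1L)
        stop("conspecific strains of '", sp, "' declare different genome lengths")
      glen[sp] <- rows$genome_length[1]
      copies[sp] <- rows$its_copy_number[1]
      tax[sp] <- rows$taxonomy[1]
      if (glen[sp] < 10 * read_length)
        stop("genome of '", sp, "' (", glen[sp],
             " bp) is shorter than 10 read lengths")
      if (copies[sp] * its_length > glen[sp] / 2)
        stop("genome of '", sp, "' (", glen[sp], " bp) is too small to host ",
             copies[sp], " ITS copies of ", its_length, " bp")
    }
    # ITS templates, mutually dissimilar
    templates <- setNames(vapply(species, function(s) random_dna(its_length),
                                 character(1)), species)
    if (length(species) > 1L) {
      for (iter in 1:25) {
        bad <- FALSE
        for (i in seq_along(species)[-1]) for (j in seq_len(i - 1)) {
          if (seq_identity(templates[i], templates[j]) >= max_its_identity) {
            templates[i] <- random_dna(its_length)
            bad <- TRUE
          }
        }
        if (!bad) break
      }
    }
    genomes <- character(0)
    its_positions <- list()
    for (sp in species) {
      g <- random_dna(glen[sp])
      k <- copies[sp]
      slot <- glen[sp] %/% k
      starts <- (seq_len(k) - 1L) * slot  # 0-based
      for (s in starts)
        substr(g, s + 1L, s + its_length) <- templates[sp]
      genomes[sp] <- g
      its_positions[[sp]] <- starts
    }
    host <- random_dna(host_genome_length)
    its_db <- data.frame(id = gsub(" ", "_", species),
                         sequence = unname(templates),
                         taxonomy = unname(tax),
                         stringsAsFactors = FALSE)
    structure(list(genomes = genomes, host = host, its_db = its_db,
                   its_templates = templates, its_positions = its_positions,
                   species = species),
              class = "mock_references")
  })
}

#' @export
print.mock_references <- function(x, ...) {
  cat("Synthetic reference set:", length(x$genomes), "genomes (",
      sum(nchar(x$genomes)), "bp ), ITS db of", nrow(x$its_db),
      "sequences, host genome", nchar(x$host), "bp\n")
  invisible(x)
}

#' Write a reference set to disk
#'
#' Writes `genomes.fasta`, `host.fasta`, `its_refs.fasta` and
#' `its_taxonomy.tsv` (UNITE-style: id, lineage) into `dir`.
#'
#' @param refs A [build_references()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_references <- function(refs, dir) {
  stopifnot(inherits(refs, "mock_references"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- Biostrings::DNAStringSet(refs$genomes)
  Biostrings::writeXStringSet(gen, file.path(dir, "genomes.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(host = refs$host)),
                              file.path(dir, "host.fasta"))
  its <- Biostrings::DNAStringSet(setNames(refs$its_db$sequence, refs$its_db$id))
  Biostrings::writeXStringSet(its, file.path(dir, "its_refs.fasta"))
  write.table(refs$its_db[, c("id", "taxonomy")],
              file.path(dir, "its_taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an ITS reference database (FASTA + taxonomy TSV)
#'
#' @param fasta Path to the reference FASTA.
#' @param taxonomy Path to a two-plus-column TSV with `id` and `taxonomy`.
#' @return A data.frame with `id`, `sequence`, `taxonomy`.
#' @export
read_its_db <- function(fasta, taxonomy) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tax <- read.delim(taxonomy, stringsAsFactors = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  m <- match(ids, tax$id)
  if (anyNA(m)) stop("taxonomy table is missing entries for: ",
                     paste(ids[is.na(m)], collapse = ", "))
  data.frame(id = ids, sequence = as.character(seqs),
             taxonomy = tax$taxonomy[m], stringsAsFactors = FALSE)
}
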