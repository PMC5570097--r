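#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so seeded simulations do not perturb the session's random stream.
#' With `seed = NULL` the expression is evaluated against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' i.i.d. uniform bases; used for synthetic genomes, ITS templates and the
#' host contaminant genome, where k-mer uniqueness makes simple seed-and-extend
#' mapping adequate.
#'
#' @param length Sequence length in bases.
#' @return A single character string over `{A,C,G,T}`.
#' @export
random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Reverse complement of character sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse plain character strings (for quality strings)
str_rev <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b Character strings of equal length.
#' @return Integer count of differing positions (`NA` if lengths differ).
#' @export
hamming <- function(a, b) cpp_hamming(a, b)

#' Global pairwise identity between two sequences
#'
#' Needleman-Wunsch global alignment (match 2, mismatch -1, gap open 2,
#' gap extend 1); identity is the fraction of matching positions over the
#' aligned length including internal gaps.
#'
#' @param a,b DNA sequences as character strings.
#' @return Identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

# identity of many queries against one subject, same scoring as seq_identity()
seq_identity_many <- function(queries, subject) {
  if (length(queries) == 0) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a
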