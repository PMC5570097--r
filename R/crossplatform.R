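as_abundance_vector <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("taxon", "species", "label"), names(x))
    val <- intersect(c("value", "abundance", "normalized"), names(x))
    if (!length(cols) || !length(val))
      stop("abundance tables need a taxon column and a value column")
    x <- setNames(x[[val[1]]], x[[cols[1]]])
  }
  if (!is.numeric(x) || is.null(names(x)))
    stop("abundance must be a named numeric vector")
  if (any(x < 0)) stop("abundances must be non-negative")
  x
}

#' Scale an abundance table to an anchor taxon of one million
#'
#' Every value is multiplied by `1e6 / value[anchor]`, putting both platforms
#' on a common scale where the anchor species' theoretical abundance is 100%
#' (one million ITS reads per million fragments, or one million shotgun reads
#' per million reads per 10-kb window).
#'
#' @param x Named numeric abundance vector (or data.frame with taxon/value
#'   columns).
#' @param anchor Anchor taxon name (default *S. cerevisiae*).
#' @return Named numeric vector with `x[anchor] == 1e6` exactly.
#' @export
scale_to_anchor <- function(x, anchor = "Saccharomyces cerevisiae") {
  x <- as_abundance_vector(x)
  if (!anchor %in% names(x) || !is.finite(x[[anchor]]) || x[[anchor]] <= 0)
    stop("anchor taxon '", anchor, "' is absent or has no positive abundance")
  x * 1e6 / x[[anchor]]
}

#' Observed/expected abundance ratios for a mock community
#'
#' The raw ratio of each taxon is observed abundance divided by expected
#' abundance (the total cells added to the mix, conspecific strains pooled);
#' reported ratios are internally normalised so the anchor taxon's ratio is
#' exactly 1, which cancels the arbitrary units of either platform. Taxa
#' expected but not observed get ratio 0; taxa observed but absent from the
#' design are listed separately (attribute `"unexpected"`), with no ratio.
#'
#' @param observed Named numeric vector of observed abundances for one
#'   platform (any consistent unit).
#' @param design The [mock_design()] providing expected cell counts, or a
#'   named numeric vector of expected cells per species.
#' @param anchor Anchor species (must be in the design with observed > 0).
#' @return data.frame of class `"bias_ratios"`: `taxon`, `expected_cells`,
#'   `observed`, `raw_ratio`, `ratio`.
#' @export
mock_ratios <- function(observed, design,
                        anchor = "Saccharomyces cerevisiae") {
  observed <- as_abundance_vector(observed)
  expected <- if (inherits(design, "mock_design")) expected_cells(design)
              else design
  if (!anchor %in% names(expected)) stop("anchor '", anchor,
                                         "' not in the design")
  unexpected <- setdiff(names(observed), names(expected))
  obs <- setNames(rep(0, length(expected)), names(expected))
  shared <- intersect(names(observed), names(expected))
  obs[shared] <- observed[shared]
  if (obs[[anchor]] <= 0) stop("anchor '", anchor, "' has no observed reads")
  raw <- obs / expected
  out <- data.frame(taxon = names(expected),
                    expected_cells = as.numeric(expected),
                    observed = as.numeric(obs),
                    raw_ratio = as.numeric(raw),
                    ratio = as.numeric(raw / raw[[anchor]]),
                    stringsAsFactors = FALSE)
  attr(out, "anchor") <- anchor
  attr(out, "unexpected") <- observed[unexpected]
  class(out) <- c("bias_ratios", "data.frame")
  out
}

#' Flag taxa whose observed/expected ratio departs beyond a fold threshold
#'
#' Symmetric rule: flagged iff `ratio > fold_threshold` or
#' `ratio < 1/fold_threshold` (a ratio of 0 with positive expected cells is
#' also flagged).
#'
#' @param report A [mock_ratios()] result.
#' @param fold_threshold Fold-change threshold (> 1). 2 for routine
#'   reporting; 5 for headline amplicon-bias flags.
#' @return `report` with an added logical `flagged` column.
#' @export
flag_bias <- function(report, fold_threshold = 5) {
  stopifnot(inherits(report, "bias_ratios"))
  if (fold_threshold <= 1) stop("'fold_threshold' must be > 1")
  report$flagged <- (report$ratio > fold_threshold |
                     report$ratio < 1 / fold_threshold |
                     (report$ratio == 0 & report$expected_cells > 0))
  report
}

#' ITS-versus-shotgun fold bias of a taxon
#'
#' The ratio of the taxon's internally normalised observed/expected ratios
#' on the two platforms: the multiplicative factor by which the ITS amplicon
#' channel over-represents the taxon relative to the (unbiased) shotgun
#' channel. Dividing ITS abundances by this factor corrects the bias.
#'
#' @param its_report,shotgun_report [mock_ratios()] results for the two
#'   platforms.
#' @param taxon Taxon name.
#' @return Fold bias (numeric); `NA` with a warning when the shotgun ratio
#'   is 0.
#' @export
estimate_bias_factor <- function(its_report, shotgun_report, taxon) {
  stopifnot(inherits(its_report, "bias_ratios"),
            inherits(shotgun_report, "bias_ratios"))
  ri <- its_report$ratio[match(taxon, its_report$taxon)]
  rs <- shotgun_report$ratio[match(taxon, shotgun_report$taxon)]
  if (is.na(ri) || is.na(rs)) stop("taxon '", taxon,
                                   "' missing from a report")
  if (rs == 0) {
    warning("shotgun ratio for '", taxon, "' is 0; bias factor undefined")
    return(NA_real_)
  }
  ri / rs
}

#' Agreement between ITS and shotgun abundance profiles
#'
#' Ordinary least squares on log10 abundances over taxa positive on both
#' platforms (zeros are excluded, not pseudocounted, and reported
#' separately); the squared correlation and per-taxon ITS/shotgun fold
#' differences are returned.
#'
#' @param its,shotgun Named numeric abundance vectors on a common scale
#'   (e.g. from [scale_to_anchor()]).
#' @return List with `r_squared` (NA with a reason when fewer than 3 taxa
#'   are positive on both platforms), `n_shared`, `fold_difference` (named,
#'   ITS/shotgun) and `zero_on_one_platform` (taxa positive on exactly one).
#' @export
platform_agreement <- function(its, shotgun) {
  its <- as_abundance_vector(its)
  shotgun <- as_abundance_vector(shotgun)
  taxa <- union(names(its), names(shotgun))
  i <- setNames(rep(0, length(taxa)), taxa); i[names(its)] <- its
  s <- setNames(rep(0, length(taxa)), taxa); s[names(shotgun)] <- shotgun
  shared <- taxa[i > 0 & s > 0]
  zero_one <- taxa[xor(i > 0, s > 0)]
  if (length(shared) < 3) {
    return(list(r_squared = NA_real_,
                reason = "fewer than 3 taxa positive on both platforms",
                n_shared = length(shared),
                fold_difference = i[shared] / s[shared],
                zero_on_one_platform = zero_one))
  }
  # OLS R^2 of a simple regression is the squared correlation
  list(r_squared = stats::cor(log10(i[shared]), log10(s[shared]))^2,
       n_shared = length(shared),
       fold_difference = i[shared] / s[shared],
       zero_on_one_platform = zero_one)
}
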