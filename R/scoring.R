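#' Alignment scoring scheme
#'
#' Bundle of the four affine-gap alignment parameters used throughout the
#' package: a (positive) match reward, a (negative) mismatch penalty, and
#' negative gap-open / gap-extension penalties.  A gap of length `L` costs
#' `gap_open + (L - 1) * gap_ext`, i.e. the first gapped base pays the open
#' penalty and every further base the extension penalty.  The defaults
#' (match +1, mismatch -2, gap open -3, gap extension -1) are the values the
#' method was calibrated with for nucleotide-level gene stitching.
#'
#' @param match score for aligning two identical non-N bases (> 0).
#' @param mismatch score for aligning two different bases (< 0).  `N` is
#'   scored as a mismatch against everything, including `N`.
#' @param gap_open score of the first base of a gap (<= `gap_ext`).
#' @param gap_ext score of each subsequent gap base (< 0).
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(match = 2, mismatch = -3)
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -3,
                           gap_ext = -1) {
  if (match <= 0) abort("`match` must be positive")
  if (mismatch >= 0) abort("`mismatch` must be negative")
  if (gap_ext >= 0) abort("`gap_ext` must be negative")
  if (gap_open > gap_ext) abort("`gap_open` must be <= `gap_ext`")
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext)),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match %+d, mismatch %+d, gap open %+d, gap ext %+d\n",
    x$match, x$mismatch, x$gap_open, x$gap_ext))
  invisible(x)
}

#' Score a single base pair
#'
#' The elementary scoring function of the network-matching alignment:
#' the match reward if the two nucleotides are identical (and not `N`),
#' otherwise the mismatch penalty.
#'
#' @param a,b single nucleotide characters in `A`, `C`, `G`, `T`, `N`
#'   (vectors are recycled element-wise).
#' @param scheme a [scoring_scheme()].
#' @return Integer vector of scores.
#' @examples
#' nucleotide_score("A", "A")  # +1
#' nucleotide_score("A", "C")  # -2
#' @export
nucleotide_score <- function(a, b, scheme = scoring_scheme()) {
  ok <- c("A", "C", "G", "T", "N")
  if (!all(a %in% ok) || !all(b %in% ok)) {
    abort("non-nucleotide symbol in `nucleotide_score()`")
  }
  ifelse(a == b & a != "N", scheme$match, scheme$mismatch)
}

#' Gene-path acceptance and merging thresholds
#'
#' Cut-offs applied when turning raw graph alignments into reported gene
#' paths and gene graphs: a path is kept if its alignment score, identity
#' and reference coverage all reach their minima; two paths sharing a
#' contig are merged into one gene graph only if their references are at
#' least `merge_ref_identity` identical; neighbouring contigs at least
#' `extend_identity` identical to a member contig are recruited during
#' gene-graph extension.
#'
#' @param min_score minimum network-matching alignment score (default 50).
#' @param min_identity minimum alignment identity, matches over all aligned
#'   columns including gaps (default 0.60).
#' @param min_ref_coverage minimum fraction of the reference length spanned
#'   by the alignment (default 0.40).
#' @param merge_ref_identity minimum identity between two references for
#'   their overlapping paths to merge (default 0.70).
#' @param extend_identity minimum contig-vs-contig identity for recruiting
#'   a neighbouring contig during extension (default 0.70).
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(min_score = 50, min_identity = 0.60,
                       min_ref_coverage = 0.40, merge_ref_identity = 0.70,
                       extend_identity = 0.70) {
  ids <- c(min_identity, min_ref_coverage, merge_ref_identity, extend_identity)
  if (any(ids <= 0) || any(ids > 1)) {
    abort("identity/coverage thresholds must lie in (0, 1]")
  }
  if (min_score <= 0) abort("`min_score` must be positive")
  structure(
    list(min_score = min_score, min_identity = min_identity,
         min_ref_coverage = min_ref_coverage,
         merge_ref_identity = merge_ref_identity,
         extend_identity = extend_identity),
    class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("<thresholds> score >= %g, identity >= %g, ref coverage >= %g,\n",
           "  merge ref identity >= %g, extension identity >= %g\n"),
    x$min_score, x$min_identity, x$min_ref_coverage,
    x$merge_ref_identity, x$extend_identity))
  invisible(x)
}
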