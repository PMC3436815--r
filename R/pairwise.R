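# Pairwise local alignment utilities.  All pairwise (sequence vs sequence)
# alignment in the package goes through Biostrings::pairwiseAlignment with
# the package scoring scheme translated to its conventions: a gap of length
# L costs gapOpening + L * gapExtension, so gapOpening = gap_ext - gap_open
# and gapExtension = -gap_ext reproduce "first gap base gap_open, each
# further base gap_ext".

substitution_matrix <- function(scheme) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scheme$match
  m["N", "N"] <- scheme$mismatch # N never matches anything
  m
}

# best local alignment of a vs b (both plain character); returns NULL when
# no positive-scoring alignment exists.
local_align_one <- function(a, b, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = substitution_matrix(scheme),
    gapOpening = abs(scheme$gap_open) - abs(scheme$gap_ext),
    gapExtension = abs(scheme$gap_ext))
  sc <- Biostrings::score(pa)
  ncol_aln <- Biostrings::nchar(pa)
  if (ncol_aln == 0 || sc <= 0) return(NULL)
  list(
    score = sc,
    n_columns = ncol_aln,
    n_match = Biostrings::nmatch(pa),
    identity = Biostrings::nmatch(pa) / ncol_aln,
    a_start = Biostrings::start(Biostrings::pattern(pa)),
    a_end = Biostrings::end(Biostrings::pattern(pa)),
    b_start = Biostrings::start(Biostrings::subject(pa)),
    b_end = Biostrings::end(Biostrings::subject(pa)))
}

#' Best local alignment between two sequences
#'
#' Affine-gap local alignment of `a` against `b` under the package scoring
#' scheme, optionally over both strands of `b` (the better strand wins,
#' ties to `+`).  Coordinates are 1-based on the forward strands of both
#' inputs.
#'
#' @param a,b nucleotide strings.
#' @param scheme a [scoring_scheme()].
#' @param both_strands also try the reverse complement of `b`?
#' @return A one-row tibble with `score`, `identity` (matches over aligned
#'   columns, gaps included), `n_columns`, `strand`, `a_start`, `a_end`,
#'   `b_start`, `b_end`; or a zero-row tibble if no positive-scoring local
#'   alignment exists.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), both_strands = TRUE) {
  a <- toupper(a); b <- toupper(b)
  fwd <- local_align_one(a, b, scheme)
  rev <- if (both_strands) local_align_one(a, revcomp(b), scheme) else NULL
  empty <- tibble(score = double(), identity = double(),
                  n_columns = integer(), strand = character(),
                  a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer())
  if (is.null(fwd) && is.null(rev)) return(empty)
  use_rev <- !is.null(rev) && (is.null(fwd) || rev$score > fwd$score)
  h <- if (use_rev) rev else fwd
  bs <- h$b_start; be <- h$b_end
  if (use_rev) { # back to forward coordinates of b
    m <- nchar(b)
    bs <- m - h$b_end + 1L
    be <- m - h$b_start + 1L
  }
  tibble(score = h$score, identity = h$identity,
         n_columns = h$n_columns, strand = if (use_rev) "-" else "+",
         a_start = h$a_start, a_end = h$a_end, b_start = bs, b_end = be)
}

# forward-strand w-mers of a sequence
kmers_fwd <- function(x, w) {
  n <- nchar(x) - w + 1L
  if (n < 1L) return(character(0))
  unique(substring(x, seq_len(n), seq_len(n) + w - 1L))
}

# w-mers of both strands, for use as a seed-word target set
kmers_both <- function(x, w) {
  unique(c(kmers_fwd(x, w), kmers_fwd(revcomp(x), w)))
}

# do two sequences share any w-mer (either strand)? cheap alignment
# prefilter.  `b_kmers` may carry a precomputed kmers_both(b, w) when b is
# matched against many sequences.
shares_kmer <- function(a, b = NULL, w = 11L, b_kmers = NULL) {
  a <- toupper(a)
  if (is.null(b_kmers)) b_kmers <- kmers_both(toupper(b), w)
  any(kmers_fwd(a, w) %in% b_kmers)
}
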