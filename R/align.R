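#' Align a contig graph against one reference gene (network matching)
#'
#' The core stitching step: an affine-gap local alignment between all paths
#' of the contig de Bruijn graph and a reference nucleotide sequence,
#' computed by dynamic programming over the graph without enumerating
#' paths.  For every contig position `i` (in contig `v`) and reference
#' position `j`, three scores are maintained: the best alignment ending in
#' a match/mismatch, ending with a reference base gapped against the graph,
#' and ending with a graph base gapped against the reference.  Within a
#' contig the recurrences are those of ordinary Smith-Waterman; at a contig
#' start (`i == 1`) the diagonal and the graph-gap recurrences instead draw
#' from the junction cell of every predecessor contig, so the alignment may
#' walk across edges.  Junction overlaps are scored once: crossing an edge
#' leaves the predecessor at its last non-overlap base, the shared `k - 1`
#' bases being represented by the successor's prefix.  All match-state
#' scores are floored at zero (local alignment) and traceback runs from the
#' global maximum until a zero score is reached.
#'
#' The reference is aligned in both orientations (its reverse complement is
#' aligned rather than the graph being doubled) and the better strand is
#' reported, ties going to `+`.  Cycles are handled by processing contigs
#' in a topological order of the graph with back-edges removed; back-edges
#' still feed the diagonal recurrence (which looks one reference column
#' back), so scores remain bounded and deterministic, and traceback caps
#' each contig's visit count at two.
#'
#' @param graph a [contig_graph()].
#' @param ref reference nucleotide sequence (character scalar).
#' @param ref_id identifier recorded in the result.
#' @param scheme a [scoring_scheme()].
#' @param min_score smallest raw score considered reportable (default 1);
#'   lower optima mean no local similarity and return `NULL`.
#' @return A `gene_path` object, or `NULL` if no alignment of score at
#'   least `min_score` exists.  A `gene_path` carries: `ref_id`, `strand`,
#'   `score`, `node_ids` (the contig chain in graph order), `ops`
#'   (per-column operations `=`, `X`, `I`, `D`; `I` consumes a reference
#'   base, `D` a graph base), `identity` (matches over all aligned columns,
#'   gaps included), `ref_coverage` (aligned reference span over reference
#'   length), `ref_start`/`ref_end` (1-based, on the forward reference),
#'   `node_start`/`node_end` (1-based positions within the first and last
#'   chain contig) and `stitched_seq` (the spelled subsequence covered by
#'   the alignment, forward graph strand).
#' @examples
#' g <- contig_graph(c(a = "AACGT", b = "CGTTA"),
#'                   data.frame(from = "a", to = "b"), k = 4)
#' p <- align_graph(g, "AACGTTA", ref_id = "gene1")
#' p$score; p$node_ids
#' @export
align_graph <- function(graph, ref, ref_id = "ref", scheme = scoring_scheme(),
                        min_score = 1) {
  ref <- toupper(ref)
  if (nchar(ref) < 1) abort("empty reference sequence")
  if (grepl("[^ACGTN]", ref)) abort("non-ACGTN characters in reference")
  if (length(graph$seqs) == 0) return(NULL)

  fwd <- nm_strand(graph, ref, scheme)
  rev <- nm_strand(graph, revcomp(ref), scheme)
  use_rev <- rev$score > fwd$score # ties go to "+"
  hit <- if (use_rev) rev else fwd
  if (hit$score < min_score) return(NULL)
  m <- nchar(ref)
  ref_start <- hit$j_start
  ref_end <- hit$j_end
  if (use_rev) { # map back to forward reference coordinates
    ref_start <- m - hit$j_end + 1L
    ref_end <- m - hit$j_start + 1L
  }
  if (isTRUE(hit$truncated)) {
    warn(sprintf(
      "traceback for %s truncated: cyclic path revisited a contig more than twice",
      ref_id))
  }
  ncol_aln <- nchar(hit$ops)
  path <- structure(list(
    ref_id = ref_id,
    strand = if (use_rev) "-" else "+",
    score = hit$score,
    node_ids = hit$node_ids,
    ops = hit$ops,
    identity = hit$n_match / ncol_aln,
    ref_coverage = (ref_end - ref_start + 1L) / m,
    ref_len = m,
    ref_start = ref_start,
    ref_end = ref_end,
    node_start = hit$i_start,
    node_end = hit$i_end,
    stitched_seq = stitched_sequence(graph, hit),
    n_match = hit$n_match,
    n_columns = ncol_aln
  ), class = "gene_path")
  path
}

# run the DP for one reference orientation; returns raw hit fields
nm_strand <- function(graph, ref, scheme) {
  ids <- names(graph$seqs)
  from <- match(graph$edges$from, ids) - 1L
  to <- match(graph$edges$to, ids) - 1L
  res <- nm_align_cpp(unname(graph$seqs), from, to, graph$k, ref,
                      scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_ext)
  if (res$score < 1) return(list(score = 0))
  res$node_ids <- ids[res$chain + 1L]
  res
}

# spelled subsequence covered by the alignment, on the forward graph strand
stitched_sequence <- function(graph, hit) {
  chain <- hit$node_ids
  spelled <- spell_path(graph, chain)
  eff <- nchar(graph$seqs[chain]) - (graph$k - 1L)
  start <- hit$i_start
  if (length(chain) > 1) {
    end <- sum(eff[-length(eff)]) + hit$i_end
  } else {
    end <- hit$i_end
  }
  substr(spelled, start, end)
}

#' @export
print.gene_path <- function(x, ...) {
  cat(sprintf(
    "<gene_path> %s (%s): score %d, identity %.3f, ref coverage %.3f\n  %d contig(s): %s\n",
    x$ref_id, x$strand, x$score, x$identity, x$ref_coverage,
    length(x$node_ids), paste(x$node_ids, collapse = ",")))
  invisible(x)
}

#' Identity and reference coverage of a gene path
#'
#' Identity is the number of matched columns over all aligned columns (gap
#' columns count in the denominator); reference coverage is the 1-based
#' aligned reference span divided by the reference length.
#'
#' @param path a `gene_path` from [align_graph()].
#' @return A one-row tibble with `identity` and `ref_coverage`.
#' @export
path_stats <- function(path) {
  if (is.null(path$ops) || nchar(path$ops) == 0) {
    abort("gene path has an empty alignment")
  }
  tibble(identity = path$identity, ref_coverage = path$ref_coverage)
}

#' Recompute a gene path's score from its alignment columns
#'
#' Walks the per-column operations and re-derives the alignment score under
#' a scoring scheme; used as an internal consistency check (the recomputed
#' score must equal the stored one).
#'
#' @param path a `gene_path`.
#' @param ref the forward reference sequence the path was aligned to.
#' @param graph the [contig_graph()] the path lives in.
#' @param scheme a [scoring_scheme()].
#' @return The recomputed integer score.
#' @export
rescore_path <- function(path, ref, graph, scheme = scoring_scheme()) {
  ops <- strsplit(path$ops, "")[[1]]
  refseq <- toupper(ref)
  if (path$strand == "-") refseq <- revcomp(refseq)
  m <- nchar(refseq)
  j0 <- if (path$strand == "-") m - path$ref_end + 1L else path$ref_start
  gseq <- strsplit(path$stitched_seq, "")[[1]]
  rseq <- strsplit(refseq, "")[[1]]
  gi <- 0L; rj <- j0 - 1L
  score <- 0L
  prev_gap <- ""
  for (op in ops) {
    if (op %in% c("=", "X")) {
      gi <- gi + 1L; rj <- rj + 1L
      score <- score + nucleotide_score(gseq[gi], rseq[rj], scheme)
      prev_gap <- ""
    } else if (op == "I") {
      rj <- rj + 1L
      score <- score + if (prev_gap == "I") scheme$gap_ext else scheme$gap_open
      prev_gap <- "I"
    } else if (op == "D") {
      gi <- gi + 1L
      score <- score + if (prev_gap == "D") scheme$gap_ext else scheme$gap_open
      prev_gap <- "D"
    }
  }
  score
}

#' Align a contig graph against many references
#'
#' Runs [align_graph()] for each reference record and collects the
#' resulting gene paths.
#'
#' @param graph a [contig_graph()].
#' @param refs a data frame with columns `id` and `seq` (e.g. from
#'   [read_fasta()]), or a named character vector.
#' @param scheme a [scoring_scheme()].
#' @param min_score smallest reportable raw score (default 1).
#' @return A list of `gene_path` objects (references with no alignment are
#'   dropped); see [tidy.gene_path_list()] for a tabular view.
#' @export
align_refs <- function(graph, refs, scheme = scoring_scheme(), min_score = 1) {
  refs <- as_ref_tibble(refs)
  paths <- purrr::map2(refs$seq, refs$id, function(s, id) {
    align_graph(graph, s, ref_id = id, scheme = scheme, min_score = min_score)
  })
  paths <- purrr::compact(paths)
  structure(paths, class = "gene_path_list")
}

as_ref_tibble <- function(refs) {
  if (is.character(refs)) {
    if (is.null(names(refs))) abort("reference vector must be named")
    refs <- tibble(id = names(refs), seq = unname(refs))
  }
  refs <- as_tibble(refs)
  if (anyDuplicated(refs$id)) abort("duplicate reference ids")
  refs$seq <- toupper(refs$seq)
  refs
}

#' Tabulate gene paths
#'
#' One row per gene path: reference, strand, score, identity, reference
#' coverage and span, and the contig chain.
#'
#' @param x a list of `gene_path` objects (class `gene_path_list`).
#' @param ... unused.
#' @return A tibble.
#' @method tidy gene_path_list
#' @export
tidy.gene_path_list <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble(ref_id = character(), strand = character(),
                  score = integer(), identity = double(),
                  ref_coverage = double(), ref_start = integer(),
                  ref_end = integer(), n_nodes = integer(),
                  node_ids = character(), cigar = character()))
  }
  purrr::map_dfr(x, function(p) {
    tibble(ref_id = p$ref_id, strand = p$strand, score = p$score,
           identity = p$identity, ref_coverage = p$ref_coverage,
           ref_start = p$ref_start, ref_end = p$ref_end,
           n_nodes = length(p$node_ids),
           node_ids = paste(p$node_ids, collapse = ","),
           cigar = compress_ops(p$ops))
  })
}

#' @method tidy gene_path
#' @export
tidy.gene_path <- function(x, ...) {
  tidy.gene_path_list(structure(list(x), class = "gene_path_list"))
}

# "===XX=" -> "3=2X1="
compress_ops <- function(ops) {
  r <- rle(strsplit(ops, "")[[1]])
  paste0(r$lengths, r$values, collapse = "")
}
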