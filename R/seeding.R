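#' Find contig-vs-reference similarity hits
#'
#' Seeds the per-reference subgraph search.  Two modes:
#'
#' * `mode = "internal"`: a bundled seeded local-alignment search — contigs
#'   sharing an 11-mer with a reference (either strand) are aligned with
#'   [local_align()] and hits with raw score >= `min_internal_score` are
#'   reported.  This keeps the package self-contained; it does not compute
#'   E-values.
#' * `mode = "blast_tab"`: read precomputed hits from a BLAST tabular
#'   (outfmt 6) file with contigs as queries and references as subjects,
#'   keeping rows with `evalue <= evalue_cutoff`.
#'
#' Hits are returned in a deterministic order: score descending, then
#' contig id, then reference id.
#'
#' @param graph a [contig_graph()].
#' @param refs reference records (data frame with `id`, `seq`, or a named
#'   character vector).
#' @param mode `"internal"` or `"blast_tab"`.
#' @param evalue_cutoff E-value cut-off applied in `blast_tab` mode
#'   (default 0.1, a deliberately permissive value so that short fragments
#'   are not lost).
#' @param blast_file path to the outfmt-6 file (`blast_tab` mode).
#' @param scheme a [scoring_scheme()] (`internal` mode).
#' @param min_internal_score minimum raw alignment score for an internal
#'   hit (default 20).
#' @param seed_width seed word length for the internal prefilter
#'   (default 11).
#' @return A tibble with columns `contig_id`, `ref_id`, `score`, `evalue`
#'   (`NA` in internal mode), `contig_start`, `contig_end`, `ref_start`,
#'   `ref_end` (1-based).
#' @export
find_hits <- function(graph, refs, mode = c("internal", "blast_tab"),
                      evalue_cutoff = 0.1, blast_file = NULL,
                      scheme = scoring_scheme(), min_internal_score = 20,
                      seed_width = 11L) {
  mode <- match.arg(mode)
  refs <- as_ref_tibble(refs)
  if (mode == "blast_tab") {
    if (is.null(blast_file)) abort("`blast_file` is required in blast_tab mode")
    hits <- read_blast_tab(blast_file)
    hits <- hits[hits$evalue <= evalue_cutoff, ]
    hits <- hits[hits$contig_id %in% contig_ids(graph) &
                   hits$ref_id %in% refs$id, ]
  } else {
    rows <- list()
    cmers <- lapply(graph$seqs, kmers_fwd, w = seed_width)
    for (ri in seq_len(nrow(refs))) {
      rmers <- kmers_both(refs$seq[ri], seed_width)
      for (cid in contig_ids(graph)) {
        if (!any(cmers[[cid]] %in% rmers)) next
        al <- local_align(graph$seqs[[cid]], refs$seq[ri], scheme = scheme)
        if (nrow(al) == 0 || al$score < min_internal_score) next
        rows[[length(rows) + 1L]] <- tibble(
          contig_id = cid, ref_id = refs$id[ri], score = al$score,
          evalue = NA_real_, contig_start = al$a_start,
          contig_end = al$a_end, ref_start = al$b_start,
          ref_end = al$b_end)
      }
    }
    hits <- if (length(rows) == 0) {
      tibble(contig_id = character(), ref_id = character(), score = double(),
             evalue = double(), contig_start = integer(),
             contig_end = integer(), ref_start = integer(),
             ref_end = integer())
    } else {
      dplyr::bind_rows(rows)
    }
  }
  dplyr::arrange(hits, dplyr::desc(.data$score), .data$contig_id,
                 .data$ref_id)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) with the contig as the
#' query.  The bit score is used as the hit score.
#'
#' @param path path to the tabular file.
#' @return A tibble with the same columns as [find_hits()].
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(contig_id = character(), ref_id = character(),
                  score = double(), evalue = double(),
                  contig_start = integer(), contig_end = integer(),
                  ref_start = integer(), ref_end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12)) {
    abort(sprintf("malformed BLAST tabular line %d: %d field(s), expected 12",
                  which(nf < 12)[1], nf[which(nf < 12)[1]]))
  }
  f <- function(i) vapply(parts, `[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(v)) {
      abort(sprintf("malformed BLAST tabular line %d: non-numeric %s",
                    which(is.na(v))[1], what))
    }
    v
  }
  tibble(contig_id = f(1), ref_id = f(2), score = num(12, "bitscore"),
         evalue = num(11, "evalue"),
         contig_start = as.integer(num(7, "qstart")),
         contig_end = as.integer(num(8, "qend")),
         ref_start = as.integer(num(9, "sstart")),
         ref_end = as.integer(num(10, "send")))
}

#' Recruit the seeded subgraph for one reference
#'
#' Constrains the network-matching search space: starting from the contig
#' with the best hit against the reference, a breadth-first search over
#' both in- and out-edges recruits neighbouring contigs.  Contigs with
#' their own hit against this reference are recruited at unlimited depth
#' and reset the hit-free counter; contigs without a hit are recruited only
#' while the count of consecutive hit-free layers since the last
#' hit-bearing contig is at most `n_layers`.  The search runs to a
#' fixpoint, so the recruited set is independent of traversal order.
#'
#' @param graph a [contig_graph()].
#' @param ref_id the reference whose hits seed the subgraph.
#' @param hits hit table from [find_hits()].
#' @param n_layers maximum number of consecutive hit-free layers
#'   (default 5).
#' @return A list of class `seeded_subgraph` with `ref_id`, `seed_id` (the
#'   best-hit contig, ties to the smaller id), `node_ids` and `graph` (the
#'   induced [contig_graph()]); or `NULL` if the reference has no hits.
#' @export
build_subgraph <- function(graph, ref_id, hits, n_layers = 5) {
  h <- hits[hits$ref_id == ref_id, ]
  if (nrow(h) == 0) return(NULL)
  h <- dplyr::arrange(h, dplyr::desc(.data$score), .data$contig_id)
  seed <- h$contig_id[1]
  hit_nodes <- unique(h$contig_id)

  # undirected neighbour map
  nbr <- split(c(graph$edges$to, graph$edges$from),
               c(graph$edges$from, graph$edges$to))
  # smallest number of consecutive hit-free layers on any route from the
  # seed; hit-bearing nodes sit at depth 0.  Dijkstra-like relaxation.
  depth <- setNames(rep(Inf, length(graph$seqs)), contig_ids(graph))
  depth[seed] <- 0
  queue <- seed
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in unique(nbr[[u]])) {
      d <- if (v %in% hit_nodes) 0 else depth[[u]] + 1
      if (d < depth[[v]] && d <= n_layers) {
        depth[[v]] <- d
        queue <- c(queue, v)
      }
    }
  }
  keep <- names(depth)[is.finite(depth)]
  structure(list(ref_id = ref_id, seed_id = seed,
                 node_ids = keep,
                 graph = induced_subgraph(graph, keep)),
            class = "seeded_subgraph")
}

#' @export
print.seeded_subgraph <- function(x, ...) {
  cat(sprintf("<seeded_subgraph> %s: seed %s, %d contig(s)\n",
              x$ref_id, x$seed_id, length(x$node_ids)))
  invisible(x)
}

#' Mask intact genes out of a contig graph
#'
#' Removes predicted genes that lie wholly interior to a contig (touching
#' neither its first nor its last base) before network matching: such genes
#' need no stitching, and removing them shrinks the search space.  Each
#' contig is cut at its (merged) intact-gene intervals; the leftmost
#' remnant keeps the contig's original in-edges, the rightmost remnant its
#' out-edges, and remnants between two intact genes are isolated.  No new
#' edge is ever created, and remnants shorter than `k` are dropped together
#' with their incident edges.  Remnant ids are `<id>.L`, `<id>.M1`, ...,
#' `<id>.R`.  Predictions touching a contig end (fragmented genes) leave
#' the contig unchanged.
#'
#' @param graph a [contig_graph()].
#' @param annotations gene annotations, e.g. from [find_orfs()] or
#'   [read_gff_genes()]: a data frame with columns `contig_id`, `start`,
#'   `end` (1-based inclusive) and optionally `intact` (recomputed from the
#'   boundary rule regardless).
#' @return A [contig_graph()] with intact genes removed.
#' @export
mask_intact_genes <- function(graph, annotations) {
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0) return(graph)
  missing <- setdiff(unique(ann$contig_id), contig_ids(graph))
  if (length(missing) > 0) {
    abort(paste0("annotations reference unknown contig(s): ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  len <- nchar(graph$seqs)
  bad <- ann$start < 1 | ann$end > len[ann$contig_id] | ann$start > ann$end
  if (any(bad)) abort("annotation interval outside its contig")
  # intact = strictly interior
  ann <- ann[ann$start > 1 & ann$end < len[ann$contig_id], ]
  if (nrow(ann) == 0) return(graph)

  new_seqs <- character(0)
  drop_ids <- character(0)
  left_of <- character(0)  # old id -> leftmost remnant id
  right_of <- character(0) # old id -> rightmost remnant id
  k <- graph$k
  for (cid in unique(ann$contig_id)) {
    iv <- merge_intervals(ann[ann$contig_id == cid, c("start", "end")])
    L <- len[[cid]]
    seq <- graph$seqs[[cid]]
    # remnant intervals between/around the masked ones
    starts <- c(1L, iv$end + 1L)
    ends <- c(iv$start - 1L, L)
    keep <- ends >= starts
    rs <- starts[keep]; re <- ends[keep]
    nseg <- length(rs)
    if (nseg == 0) { drop_ids <- c(drop_ids, cid); next }
    labs <- remnant_labels(rs, re, L)
    for (s in seq_len(nseg)) {
      rid <- paste0(cid, ".", labs[s])
      if (re[s] - rs[s] + 1L < k) next # too short to carry graph structure
      new_seqs[[rid]] <- substr(seq, rs[s], re[s])
      if (rs[s] == 1L) left_of[[cid]] <- rid
      if (re[s] == L) right_of[[cid]] <- rid
    }
    drop_ids <- c(drop_ids, cid)
  }
  seqs <- c(graph$seqs[setdiff(contig_ids(graph), drop_ids)], new_seqs)
  remap <- function(ids, map, keep_ids) {
    out <- ids
    hit <- ids %in% names(map)
    out[hit] <- unname(map[ids[hit]])
    out[!hit & !(ids %in% keep_ids)] <- NA_character_
    out
  }
  keep_ids <- setdiff(contig_ids(graph), drop_ids)
  e <- graph$edges
  e$to <- remap(e$to, left_of, keep_ids)    # in-edges follow the left remnant
  e$from <- remap(e$from, right_of, keep_ids) # out-edges follow the right one
  e <- e[!is.na(e$from) & !is.na(e$to), ]
  contig_graph(seqs, e, k = k)
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  if (nrow(iv) > 1) {
    for (r in 2:nrow(iv)) {
      if (iv$start[r] <= out_e[length(out_e)] + 1L) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[r])
      } else {
        out_s <- c(out_s, iv$start[r]); out_e <- c(out_e, iv$end[r])
      }
    }
  }
  tibble(start = out_s, end = out_e)
}

remnant_labels <- function(rs, re, L) {
  n <- length(rs)
  labs <- character(n)
  mid <- 0L
  for (s in seq_len(n)) {
    if (rs[s] == 1L) labs[s] <- "L"
    else if (re[s] == L) labs[s] <- "R"
    else { mid <- mid + 1L; labs[s] <- paste0("M", mid) }
  }
  labs
}

#' Find open reading frames in a contig
#'
#' A simple six-frame ORF caller used when no external gene predictions are
#' supplied: every maximal `ATG`-to-stop ORF of at least `min_len` bases is
#' reported on both strands, with the `intact` flag set when the ORF
#' touches neither the first nor the last base of the contig.
#'
#' @param seq contig nucleotide sequence.
#' @param contig_id id recorded in the result.
#' @param min_len minimum ORF length in bases, start through stop codon
#'   inclusive (>= 60; default 180).
#' @return A tibble with `contig_id`, `start`, `end` (1-based, forward
#'   coordinates), `strand` and `intact`.
#' @export
find_orfs <- function(seq, contig_id = "contig", min_len = 180) {
  if (min_len < 60) abort("`min_len` must be >= 60")
  seq <- toupper(seq)
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  orf_fwd <- function(s) {
    out <- list()
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3
      if (n_cod < 2) next
      pos <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
      cods <- substring(s, pos, pos + 2L)
      stop_ix <- which(cods %in% stops)
      region_start <- 1L # codon index opening each stop-to-stop region
      for (si in stop_ix) {
        atg <- which(cods[region_start:si] == "ATG")
        if (length(atg) > 0) {
          a <- region_start + atg[1] - 1L
          if ((si - a + 1L) * 3L >= min_len) {
            out[[length(out) + 1L]] <- c(pos[a], pos[si] + 2L)
          }
        }
        region_start <- si + 1L
      }
    }
    out
  }
  rows <- list()
  for (iv in orf_fwd(seq)) {
    rows[[length(rows) + 1L]] <- tibble(contig_id = contig_id,
                                        start = iv[1], end = iv[2],
                                        strand = "+")
  }
  rc <- revcomp(seq)
  for (iv in orf_fwd(rc)) {
    rows[[length(rows) + 1L]] <- tibble(contig_id = contig_id,
                                        start = L - iv[2] + 1L,
                                        end = L - iv[1] + 1L,
                                        strand = "-")
  }
  if (length(rows) == 0) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), strand = character(), intact = logical()))
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$end)
  out$intact <- out$start > 1L & out$end < L
  out
}

#' Read gene annotations from GFF3
#'
#' Keeps `gene` and `CDS` features; coordinates are 1-based inclusive as in
#' the format.
#'
#' @param path path to a GFF3 file.
#' @return A tibble with `contig_id`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(contig_id = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8)) {
    abort(sprintf("malformed GFF3 line %d", which(nf < 8)[1]))
  }
  f <- function(i) vapply(parts, `[`, "", i)
  keep <- f(3) %in% c("gene", "CDS")
  tibble(contig_id = f(1)[keep],
         start = as.integer(f(4)[keep]),
         end = as.integer(f(5)[keep]),
         strand = f(7)[keep])
}
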