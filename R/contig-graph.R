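#' Contig de Bruijn graph
#'
#' A directed graph whose nodes are contigs and whose edges join two contigs
#' that overlap in exactly `k - 1` nucleotides (the suffix of the source
#' equals the prefix of the target).  This is the contig-level view of a
#' de Bruijn assembly graph: a path through it spells a longer sequence in
#' which each junction overlap is carried once.
#'
#' Validation enforced on construction:
#' * every edge endpoint names an existing contig;
#' * for every edge `u -> v`, the last `k - 1` bases of `u` equal the first
#'   `k - 1` bases of `v`;
#' * contigs incident to an edge are at least `k` long (so a junction always
#'   leaves at least one non-overlap base in each contig);
#' * sequences are uppercase over `A`, `C`, `G`, `T`, `N`.
#'
#' @param seqs named character vector of contig sequences (names are ids).
#' @param edges data frame with character columns `from` and `to`.
#' @param k k-mer size of the underlying de Bruijn graph (>= 2); edges carry
#'   `k - 1` base overlaps.
#' @return An object of class `contig_graph` with elements `k`, `seqs`
#'   (named character) and `edges` (tibble with `from`, `to`).
#' @examples
#' g <- contig_graph(c(a = "AACGT", b = "CGTTA"),
#'                   data.frame(from = "a", to = "b"), k = 4)
#' g
#' @export
contig_graph <- function(seqs, edges = NULL, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2) abort("`k` must be an integer >= 2")
  ids <- names(seqs)
  seqs <- setNames(toupper(as.character(seqs)), ids)
  if (length(seqs) == 0) {
    # an empty graph is valid (e.g. everything masked away)
    return(structure(list(k = k, seqs = setNames(character(0), character(0)),
                          edges = tibble(from = character(),
                                         to = character())),
                     class = "contig_graph"))
  }
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    abort("`seqs` must be a named character vector of contig sequences")
  }
  if (anyDuplicated(ids)) abort("duplicate contig ids")
  if (any(nchar(seqs) < 1)) abort("empty contig sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in contig(s): ",
                 paste(utils::head(ids[bad], 3), collapse = ", ")))
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- tibble(from = character(), to = character())
  } else {
    edges <- tibble(from = as.character(edges$from),
                    to = as.character(edges$to))
    edges <- dplyr::distinct(edges)
  }
  g <- structure(list(k = k, seqs = seqs, edges = edges),
                 class = "contig_graph")
  validate_contig_graph(g)
}

validate_contig_graph <- function(g) {
  ids <- names(g$seqs)
  missing <- setdiff(c(g$edges$from, g$edges$to), ids)
  if (length(missing) > 0) {
    abort(paste0("edge references unknown contig id(s): ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  if (nrow(g$edges) > 0) {
    ov <- g$k - 1L
    lens <- nchar(g$seqs)
    short <- union(g$edges$from[lens[g$edges$from] < g$k],
                   g$edges$to[lens[g$edges$to] < g$k])
    if (length(short) > 0) {
      abort(paste0("contig(s) shorter than k participate in edges: ",
                   paste(utils::head(short, 3), collapse = ", ")))
    }
    suf <- substr(g$seqs[g$edges$from],
                  lens[g$edges$from] - ov + 1L, lens[g$edges$from])
    pre <- substr(g$seqs[g$edges$to], 1L, ov)
    bad <- which(suf != pre)
    if (length(bad) > 0) {
      e <- g$edges[bad[1], ]
      abort(sprintf(
        "overlap mismatch on edge %s -> %s: suffix %s != prefix %s",
        e$from, e$to, suf[bad[1]], pre[bad[1]]))
    }
  }
  g
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("<contig_graph> k = %d: %d contigs (%s bp total), %d edges\n",
              x$k, length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ","), nrow(x$edges)))
  invisible(x)
}

#' @rdname contig_graph
#' @param x a `contig_graph`.
#' @export
contig_ids <- function(x) names(x$seqs)

#' Summarise contigs of a graph as a tibble
#'
#' @param x a [contig_graph()].
#' @param ... unused.
#' @return A tibble with columns `id`, `length`, `out_degree`, `in_degree`.
#' @method tidy contig_graph
#' @export
tidy.contig_graph <- function(x, ...) {
  ids <- contig_ids(x)
  tibble(
    id = ids,
    length = unname(nchar(x$seqs)),
    out_degree = as.integer(table(factor(x$edges$from, levels = ids))),
    in_degree = as.integer(table(factor(x$edges$to, levels = ids))))
}

#' Read a contig graph from GFA 1.0
#'
#' Parses `S` (segment) and `L` (link) lines.  All links must carry the same
#' exact-match overlap CIGAR `<n>M`; the k-mer size is inferred as `n + 1`.
#' The graph is held in a single fixed orientation: only `+`/`+` links are
#' used and any other orientation (or any non-S/L line) is skipped with a
#' warning.  Every link is validated against the sequences it joins.
#'
#' @param path path to a GFA 1.0 file.
#' @return A validated [contig_graph()].
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  type <- substr(lines, 1, 1)
  other <- setdiff(unique(type), c("S", "L", "H", "#"))
  if (length(other) > 0) {
    warn(paste0("ignoring GFA line type(s): ", paste(other, collapse = ", ")))
  }
  sfield <- strsplit(lines[type == "S"], "\t", fixed = TRUE)
  if (length(sfield) == 0) abort("GFA contains no S lines")
  ids <- vapply(sfield, `[`, "", 2)
  seqs <- setNames(vapply(sfield, `[`, "", 3), ids)
  lfield <- strsplit(lines[type == "L"], "\t", fixed = TRUE)
  edges <- NULL
  k <- NULL
  if (length(lfield) > 0) {
    lmat <- t(vapply(lfield, function(f) f[2:6], character(5)))
    keep <- lmat[, 2] == "+" & lmat[, 4] == "+"
    if (any(!keep)) {
      warn(sprintf("ignoring %d non-+/+ GFA link(s)", sum(!keep)))
    }
    lmat <- lmat[keep, , drop = FALSE]
    if (nrow(lmat) > 0) {
      cig <- lmat[, 5]
      bad <- !grepl("^[0-9]+M$", cig)
      if (any(bad)) {
        abort(paste0("unsupported link overlap CIGAR: ", cig[bad][1],
                     " (only exact-match <n>M is supported)"))
      }
      ov <- as.integer(sub("M$", "", cig))
      if (length(unique(ov)) > 1) {
        abort(sprintf(
          "heterogeneous overlap lengths in GFA links: %s",
          paste(sort(unique(ov)), collapse = ", ")))
      }
      k <- ov[1] + 1L
      edges <- tibble(from = lmat[, 1], to = lmat[, 3])
    }
  }
  if (is.null(k)) {
    abort("cannot infer k: GFA has no usable L lines (pass the graph as FASTA + edge list with an explicit k instead)")
  }
  contig_graph(seqs, edges, k = k)
}

#' Write a contig graph to GFA 1.0
#'
#' @param graph a [contig_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%s\t%s", names(graph$seqs), graph$seqs), con)
  if (nrow(graph$edges) > 0) {
    writeLines(sprintf("L\t%s\t+\t%s\t+\t%dM",
                       graph$edges$from, graph$edges$to, graph$k - 1L), con)
  }
  invisible(path)
}

#' Read a contig graph from FASTA plus an edge list
#'
#' Alternative input surface for assemblers that do not emit GFA: contig
#' sequences as FASTA and directed edges as a two-column tab-separated file
#' (`from_id<TAB>to_id`, no header).  The same overlap validation as
#' [read_gfa()] applies.
#'
#' @param fasta path to the contig FASTA.
#' @param edges_tsv path to the edge list TSV; an empty file yields a graph
#'   with no edges.
#' @param k k-mer size (required; it cannot be inferred from this format).
#' @return A validated [contig_graph()].
#' @export
read_edge_list <- function(fasta, edges_tsv, k) {
  recs <- read_fasta(fasta)
  seqs <- setNames(recs$seq, recs$id)
  lines <- readLines(edges_tsv)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(contig_graph(seqs, NULL, k = k))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    abort(sprintf("malformed edge list line %d: expected from<TAB>to",
                  which(nf < 2)[1]))
  }
  edges <- tibble(from = vapply(parts, `[`, "", 1),
                  to = vapply(parts, `[`, "", 2))
  contig_graph(seqs, edges, k = k)
}

#' Spell the sequence of a contig path
#'
#' Concatenates the contig sequences along an edge-consistent path, dropping
#' one copy of the `k - 1` junction overlap at every edge, so the result has
#' length `sum(contig lengths) - (n_contigs - 1) * (k - 1)`.
#'
#' @param graph a [contig_graph()].
#' @param node_ids character vector of contig ids forming a path; every
#'   consecutive pair must be joined by an edge.
#' @return The spelled nucleotide string.
#' @examples
#' g <- contig_graph(c(a = "AACGT", b = "CGTTA"),
#'                   data.frame(from = "a", to = "b"), k = 4)
#' spell_path(g, c("a", "b"))  # "AACGTTA"
#' @export
spell_path <- function(graph, node_ids) {
  node_ids <- as.character(node_ids)
  missing <- setdiff(node_ids, contig_ids(graph))
  if (length(missing) > 0) {
    abort(paste0("unknown contig id(s) in path: ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  if (length(node_ids) == 0) return("")
  if (length(node_ids) > 1) {
    key <- paste(graph$edges$from, graph$edges$to, sep = "\r")
    want <- paste(node_ids[-length(node_ids)], node_ids[-1], sep = "\r")
    bad <- which(!(want %in% key))
    if (length(bad) > 0) {
      abort(sprintf("contigs %s and %s are not joined by an edge",
                    node_ids[bad[1]], node_ids[bad[1] + 1]))
    }
  }
  seqs <- graph$seqs[node_ids]
  rest <- substring(seqs[-1], graph$k)
  paste0(seqs[1], paste(rest, collapse = ""))
}

#' Extract the node-induced subgraph of a contig graph
#'
#' @param graph a [contig_graph()].
#' @param node_ids contig ids to keep; edges with both endpoints kept are
#'   retained.
#' @return A [contig_graph()] over the selected contigs.
#' @export
induced_subgraph <- function(graph, node_ids) {
  node_ids <- intersect(contig_ids(graph), node_ids)
  e <- graph$edges[graph$edges$from %in% node_ids &
                     graph$edges$to %in% node_ids, ]
  contig_graph(graph$seqs[node_ids], e, k = graph$k)
}

#' Reverse-complement a contig graph
#'
#' Reverse-complements every contig and reverses every edge; useful for
#' strand-symmetry checks.
#'
#' @param graph a [contig_graph()].
#' @return A [contig_graph()].
#' @export
reverse_complement_graph <- function(graph) {
  seqs <- setNames(revcomp(graph$seqs), names(graph$seqs))
  contig_graph(seqs, tibble(from = graph$edges$to, to = graph$edges$from),
               k = graph$k)
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
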