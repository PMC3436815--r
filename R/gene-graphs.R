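#' Filter gene paths by the acceptance thresholds
#'
#' Keeps paths whose alignment score, identity and reference coverage all
#' reach their thresholds (boundary values are kept: the comparisons are
#' `>=`).
#'
#' @param paths a `gene_path_list` from [align_refs()] (or a plain list of
#'   `gene_path` objects).
#' @param th a [thresholds()].
#' @return A filtered `gene_path_list`.
#' @export
filter_paths <- function(paths, th = thresholds()) {
  keep <- vapply(paths, function(p) {
    p$score >= th$min_score && p$identity >= th$min_identity &&
      p$ref_coverage >= th$min_ref_coverage
  }, logical(1))
  structure(unclass(paths)[keep], class = "gene_path_list")
}

#' Identity between two reference genes
#'
#' Identity (matches over all aligned columns, gaps included) of the best
#' local alignment between two sequences, over both strands.  Used to
#' decide whether two gene paths inferred from different references may be
#' merged into one gene graph.
#'
#' Unrelated sequences always share some short perfect word, and the
#' identity of a ten-base exact match says nothing about homology, so the
#' alignment must also cover at least `min_cover` of the shorter sequence
#' to count; otherwise the identity is reported as 0 (no meaningful
#' similarity), which parallels a similarity search returning no hit
#' between the two references.
#'
#' @param a,b nucleotide sequences.
#' @param scheme a [scoring_scheme()].
#' @param min_cover minimum fraction of the shorter sequence the alignment
#'   must span (default 0.4, the same coverage floor applied to gene
#'   paths).
#' @return A fraction in `[0, 1]`; 0 if no local alignment scores above 0
#'   or none covers `min_cover` of the shorter input.
#' @export
reference_identity <- function(a, b, scheme = scoring_scheme(),
                               min_cover = 0.4) {
  al <- local_align(a, b, scheme = scheme, both_strands = TRUE)
  if (nrow(al) == 0) return(0)
  shorter <- min(nchar(a), nchar(b))
  span <- min(al$a_end - al$a_start + 1, al$b_end - al$b_start + 1)
  if (span < min_cover * shorter) return(0)
  al$identity
}

#' Merge overlapping gene paths into gene graphs
#'
#' Two gene paths are mergeable when they share at least one contig and
#' the references they were inferred from are at least
#' `th$merge_ref_identity` identical ([reference_identity()]).  Merging is
#' run to a fixpoint with union-find over the sorted pair list, so it is
#' transitive and independent of input order; the result is a partition of
#' the paths.
#'
#' @param paths a filtered `gene_path_list`.
#' @param refs reference records (data frame with `id`, `seq`, or named
#'   character vector) covering every `ref_id` in `paths`.
#' @param th a [thresholds()].
#' @param scheme a [scoring_scheme()] for the reference-vs-reference
#'   alignments.
#' @return A list of `gene_graph` objects (class `gene_graph_list`), each
#'   with `member_paths`, `node_ids`, and `representative` (see
#'   [representative()]).
#' @export
merge_paths <- function(paths, refs, th = thresholds(),
                        scheme = scoring_scheme()) {
  paths <- unclass(paths)
  n <- length(paths)
  if (n == 0) return(structure(list(), class = "gene_graph_list"))
  refs <- as_ref_tibble(refs)
  missing <- setdiff(vapply(paths, `[[`, "", "ref_id"), refs$id)
  if (length(missing) > 0) {
    abort(paste0("no reference sequence for path ref_id(s): ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  refseq <- setNames(refs$seq, refs$id)

  # deterministic processing order: by ref_id then score
  ord <- order(vapply(paths, `[[`, "", "ref_id"),
               -vapply(paths, function(p) p$score, numeric(1)))
  paths <- paths[ord]

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ref_ident <- new.env(parent = emptyenv()) # cache of pairwise identities
  pair_identity <- function(r1, r2) {
    key <- paste(sort(c(r1, r2)), collapse = "\r")
    got <- get0(key, envir = ref_ident)
    if (!is.null(got)) return(got)
    v <- if (r1 == r2) 1 else
      reference_identity(refseq[[r1]], refseq[[r2]], scheme = scheme)
    assign(key, v, envir = ref_ident)
    v
  }
  nodesets <- lapply(paths, `[[`, "node_ids")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (length(intersect(nodesets[[i]], nodesets[[j]])) == 0) next
      pi <- paths[[i]]; pj <- paths[[j]]
      if (pair_identity(pi$ref_id, pj$ref_id) >= th$merge_ref_identity) {
        parent[find(j)] <- find(i)
      }
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  out <- lapply(unname(groups), function(ix) {
    members <- structure(paths[ix], class = "gene_path_list")
    new_gene_graph(members)
  })
  structure(out, class = "gene_graph_list")
}

new_gene_graph <- function(members, extra_nodes = character(0)) {
  nodes <- unique(c(unlist(lapply(members, `[[`, "node_ids")), extra_nodes))
  gg <- list(member_paths = members, node_ids = nodes,
             representative = representative_of(members))
  structure(gg, class = "gene_graph")
}

representative_of <- function(members) {
  score <- vapply(members, function(p) p$score, numeric(1))
  ident <- vapply(members, function(p) p$identity, numeric(1))
  rid <- vapply(members, `[[`, "", "ref_id")
  ord <- order(-score, -ident, rid)
  members[[ord[1]]]
}

#' Representative gene path of a gene graph
#'
#' The member path with the highest network-matching alignment score; ties
#' broken by higher identity, then by the smaller reference id.  Its
#' stitched sequence is the gene graph's reported gene.
#'
#' @param gg a `gene_graph`.
#' @return A `gene_path`.
#' @export
representative <- function(gg) {
  if (length(gg$member_paths) == 0) abort("empty gene graph")
  gg$representative
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf(
    "<gene_graph> %d path(s), %d contig(s); representative %s (score %d)\n",
    length(x$member_paths), length(x$node_ids),
    x$representative$ref_id, x$representative$score))
  invisible(x)
}

#' Extend a gene graph with similar neighbouring contigs
#'
#' Gene segments not similar enough to any reference may sit just outside
#' a gene graph.  Extension repeatedly recruits in- and out-neighbours of
#' the graph's contigs whose best local alignment against any contig
#' already in the graph has identity at least `th$extend_identity` over at
#' least `k` aligned columns, until no more contigs can be added.  Member
#' paths and the representative are unchanged; only the node set grows.
#'
#' @param graph the full [contig_graph()] the gene graph lives in.
#' @param gg a `gene_graph` from [merge_paths()].
#' @param th a [thresholds()].
#' @param scheme a [scoring_scheme()].
#' @return The extended `gene_graph`.
#' @export
extend_gene_graph <- function(graph, gg, th = thresholds(),
                              scheme = scoring_scheme()) {
  nodes <- gg$node_ids
  nbr <- split(c(graph$edges$to, graph$edges$from),
               c(graph$edges$from, graph$edges$to))
  w <- min(11L, graph$k)
  kb_cache <- new.env(parent = emptyenv()) # both-strand seed words per node
  node_kmers <- function(u) {
    got <- get0(u, envir = kb_cache)
    if (is.null(got)) {
      got <- kmers_both(graph$seqs[[u]], w)
      assign(u, got, envir = kb_cache)
    }
    got
  }
  rejected <- character(0) # contigs already tested against the current set
  repeat {
    cand <- setdiff(unique(unlist(nbr[nodes])), c(nodes, rejected))
    if (length(cand) == 0) break
    added <- character(0)
    for (v in sort(cand)) {
      vk <- kmers_fwd(graph$seqs[[v]], w)
      ok <- FALSE
      for (u in nodes) {
        if (!any(vk %in% node_kmers(u))) next
        al <- local_align(graph$seqs[[v]], graph$seqs[[u]], scheme = scheme)
        if (nrow(al) > 0 && al$identity >= th$extend_identity &&
              al$n_columns >= graph$k) { ok <- TRUE; break }
      }
      if (ok) added <- c(added, v) else rejected <- c(rejected, v)
    }
    if (length(added) == 0) break
    nodes <- c(nodes, added)
    rejected <- character(0) # the member set grew; re-test neighbours
  }
  gg$node_ids <- nodes
  gg
}

#' Tabulate gene graphs
#'
#' One row per gene graph: member/contig counts and the representative
#' path's reference, score, identity and coverage.
#'
#' @param x a `gene_graph_list` from [merge_paths()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy gene_graph_list
#' @export
tidy.gene_graph_list <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble(gene_graph_id = character(), n_paths = integer(),
                  n_nodes = integer(), representative_ref = character(),
                  strand = character(), score = integer(),
                  identity = double(), ref_coverage = double(),
                  node_ids = character()))
  }
  purrr::imap_dfr(x, function(gg, i) {
    r <- gg$representative
    tibble(gene_graph_id = sprintf("gg%03d", i),
           n_paths = length(gg$member_paths),
           n_nodes = length(gg$node_ids),
           representative_ref = r$ref_id, strand = r$strand,
           score = r$score, identity = r$identity,
           ref_coverage = r$ref_coverage,
           node_ids = paste(gg$node_ids, collapse = ","))
  })
}
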