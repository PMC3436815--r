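#' Stitch genes end-to-end
#'
#' Runs the full workflow on a contig graph and a reference gene set:
#'
#' 1. optionally mask intact predicted genes out of the contigs
#'    ([mask_intact_genes()]);
#' 2. find contig-vs-reference hits ([find_hits()]);
#' 3. for each reference, recruit its seeded subgraph ([build_subgraph()])
#'    and align it with the network-matching DP ([align_graph()]);
#' 4. filter the gene paths by score/identity/coverage ([filter_paths()]);
#' 5. merge overlapping paths from similar references into gene graphs
#'    ([merge_paths()]) and extend them with similar neighbouring contigs
#'    ([extend_gene_graph()]);
#' 6. report each gene graph's representative stitched sequence.
#'
#' @param graph a [contig_graph()].
#' @param refs reference gene records (data frame with `id`, `seq`, or a
#'   named character vector).
#' @param annotations optional gene annotations for intact-gene masking
#'   (`NULL` to skip; `"orf"` to call ORFs internally with [find_orfs()]).
#' @param hits optional precomputed hit table (e.g. from
#'   [read_blast_tab()]); computed internally when `NULL`.
#' @param scheme a [scoring_scheme()].
#' @param th a [thresholds()].
#' @param n_layers hit-free recruitment depth for seeding (default 5).
#' @param orf_min_len minimum ORF length when `annotations = "orf"`
#'   (default 180).
#' @param extend extend gene graphs after merging? (default `TRUE`).
#' @return An object of class `genestitch_result` with elements `graph`
#'   (the possibly masked working graph), `paths` (all gene paths found),
#'   `kept_paths` (after filtering), `gene_graphs`, and `genes` (tibble of
#'   representative genes: `gene_id`, `ref_id`, `strand`, `score`,
#'   `identity`, `ref_coverage`, `n_nodes`, `seq`).
#' @export
stitch_genes <- function(graph, refs, annotations = NULL, hits = NULL,
                         scheme = scoring_scheme(), th = thresholds(),
                         n_layers = 5, orf_min_len = 180, extend = TRUE) {
  refs <- as_ref_tibble(refs)

  work <- graph
  if (!is.null(annotations)) {
    if (identical(annotations, "orf")) {
      annotations <- purrr::map_dfr(contig_ids(work), function(cid) {
        find_orfs(work$seqs[[cid]], contig_id = cid, min_len = orf_min_len)
      })
    }
    ann <- as_tibble(annotations)
    if (nrow(ann) > 0) work <- mask_intact_genes(work, ann)
  }

  if (is.null(hits)) {
    hits <- find_hits(work, refs, mode = "internal", scheme = scheme)
  }

  paths <- list()
  for (rid in refs$id) {
    sub <- build_subgraph(work, rid, hits, n_layers = n_layers)
    if (is.null(sub)) next
    p <- align_graph(sub$graph, refs$seq[refs$id == rid], ref_id = rid,
                     scheme = scheme)
    if (!is.null(p)) paths[[length(paths) + 1L]] <- p
  }
  paths <- structure(paths, class = "gene_path_list")

  kept <- filter_paths(paths, th = th)
  ggs <- merge_paths(kept, refs, th = th, scheme = scheme)
  if (extend && length(ggs) > 0) {
    ggs <- structure(lapply(ggs, function(gg) {
      extend_gene_graph(work, gg, th = th, scheme = scheme)
    }), class = "gene_graph_list")
  }

  genes <- purrr::imap_dfr(ggs, function(gg, i) {
    r <- gg$representative
    tibble(gene_id = sprintf("stitched_gene_%03d", i),
           ref_id = r$ref_id, strand = r$strand, score = r$score,
           identity = r$identity, ref_coverage = r$ref_coverage,
           n_nodes = length(r$node_ids), seq = r$stitched_seq)
  })
  structure(list(graph = work, paths = paths, kept_paths = kept,
                 gene_graphs = ggs, genes = genes),
            class = "genestitch_result")
}

#' @export
print.genestitch_result <- function(x, ...) {
  cat(sprintf(
    "<genestitch_result> %d path(s) found, %d kept, %d gene graph(s)\n",
    length(x$paths), length(x$kept_paths), length(x$gene_graphs)))
  invisible(x)
}

#' @method tidy genestitch_result
#' @export
tidy.genestitch_result <- function(x, ...) tidy(x$gene_graphs)

#' @method glance genestitch_result
#' @export
glance.genestitch_result <- function(x, ...) {
  tibble(n_paths = length(x$paths), n_kept = length(x$kept_paths),
         n_gene_graphs = length(x$gene_graphs),
         n_genes = nrow(x$genes),
         mean_identity = if (nrow(x$genes)) mean(x$genes$identity) else NA_real_,
         mean_ref_coverage = if (nrow(x$genes)) mean(x$genes$ref_coverage)
                             else NA_real_)
}

#' Read scoring and threshold settings from YAML
#'
#' Reads a configuration file with optional top-level blocks `scoring`
#' (`match`, `mismatch`, `gap_open`, `gap_ext`) and `thresholds`
#' (`min_score`, `min_identity`, `min_ref_coverage`, `merge_ref_identity`,
#' `extend_identity`); missing entries fall back to the package defaults.
#'
#' @param path path to the YAML file.
#' @return A list with `scheme` and `th`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scoring %||% list()
  th <- cfg$thresholds %||% list()
  list(scheme = do.call(scoring_scheme, sc),
       th = do.call(thresholds, th))
}
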