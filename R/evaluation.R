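# Evaluation of assembled genes against ground truth.  All mapping is by
# affine-gap local alignment (both strands) under the package scoring
# scheme, with explicit identity/coverage thresholds in place of an
# external read mapper's internal ones.

eval_records <- function(x, what) {
  if (is.character(x)) {
    if (is.null(names(x))) abort(paste0("`", what, "` must be named"))
    x <- tibble(id = names(x), seq = unname(x))
  }
  x <- as_tibble(x)
  x$seq <- toupper(x$seq)
  x
}

# identity-filtered local alignments of each assembled seq against one
# target; returns best row or NULL.  `t_kmers` may carry the target's
# precomputed both-strand seed words.
best_alignment <- function(aseq, tseq, scheme, min_identity,
                           t_kmers = NULL) {
  if (!shares_kmer(aseq, tseq, b_kmers = t_kmers)) return(NULL)
  al <- local_align(aseq, tseq, scheme = scheme)
  if (nrow(al) == 0 || al$identity < min_identity) return(NULL)
  al
}

#' Mean gene coverage of an assembly
#'
#' For each truth gene, the fraction of its length covered by its
#' best-matching assembled sequence (best local alignment over both
#' strands, counted only when the alignment identity is at least
#' `min_identity`); genes with no qualifying match contribute 0.  The
#' returned value is the mean over truth genes.
#'
#' @param assembled assembled gene records (data frame with `id`, `seq`,
#'   or named character vector).
#' @param truth_genes truth gene records, same forms.
#' @param scheme a [scoring_scheme()].
#' @param min_identity identity floor for a covering alignment
#'   (default 0.98).
#' @return A list with `mean_coverage` and `per_gene` (tibble `gene_id`,
#'   `coverage`, `best_match`).
#' @export
gene_coverage <- function(assembled, truth_genes, scheme = scoring_scheme(),
                          min_identity = 0.98) {
  assembled <- eval_records(assembled, "assembled")
  truth <- eval_records(truth_genes, "truth_genes")
  per <- purrr::map_dfr(seq_len(nrow(truth)), function(ti) {
    tlen <- nchar(truth$seq[ti])
    tk <- kmers_both(truth$seq[ti], 11L)
    best_cov <- 0; best_id <- NA_character_
    for (ai in seq_len(nrow(assembled))) {
      al <- best_alignment(assembled$seq[ai], truth$seq[ti], scheme,
                           min_identity, t_kmers = tk)
      if (is.null(al)) next
      cov <- (al$b_end - al$b_start + 1) / tlen
      if (cov > best_cov) { best_cov <- cov; best_id <- assembled$id[ai] }
    }
    tibble(gene_id = truth$id[ti], coverage = best_cov, best_match = best_id)
  })
  list(mean_coverage = if (nrow(per) == 0) 0 else mean(per$coverage),
       per_gene = per)
}

#' Count completely assembled genes
#'
#' A truth gene counts as complete when an assembled sequence covers at
#' least `min_coverage` of its length at identity at least `min_identity`;
#' each assembled sequence may complete at most one truth gene (its best
#' match by covered fraction, ties to the higher identity).
#'
#' @inheritParams gene_coverage
#' @param min_coverage completeness coverage floor (default 0.90).
#' @param min_identity completeness identity floor (default 0.98).
#' @return A list with `n_complete`, `complete_ratio` and `per_gene`
#'   (tibble `gene_id`, `complete`, `by`).
#' @export
count_complete <- function(assembled, truth_genes,
                           scheme = scoring_scheme(),
                           min_coverage = 0.90, min_identity = 0.98) {
  assembled <- eval_records(assembled, "assembled")
  truth <- eval_records(truth_genes, "truth_genes")
  # qualifying pairs
  pairs <- list()
  tks <- lapply(truth$seq, kmers_both, w = 11L)
  for (ai in seq_len(nrow(assembled))) {
    for (ti in seq_len(nrow(truth))) {
      al <- best_alignment(assembled$seq[ai], truth$seq[ti], scheme,
                           min_identity, t_kmers = tks[[ti]])
      if (is.null(al)) next
      cov <- (al$b_end - al$b_start + 1) / nchar(truth$seq[ti])
      if (cov >= min_coverage) {
        pairs[[length(pairs) + 1L]] <- tibble(
          assembled_id = assembled$id[ai], gene_id = truth$id[ti],
          coverage = cov, identity = al$identity)
      }
    }
  }
  completed_by <- setNames(rep(NA_character_, nrow(truth)), truth$id)
  if (length(pairs) > 0) {
    pairs <- dplyr::bind_rows(pairs)
    # each assembled sequence completes only its best still-open gene
    # (greedy matching in deterministic order, so duplicate assembled
    # copies complete duplicate genes rather than piling onto one)
    pairs <- dplyr::arrange(pairs, .data$assembled_id,
                            dplyr::desc(.data$coverage),
                            dplyr::desc(.data$identity), .data$gene_id)
    for (aid in unique(pairs$assembled_id)) {
      mine <- pairs[pairs$assembled_id == aid, ]
      open <- mine$gene_id[is.na(completed_by[mine$gene_id])]
      if (length(open) > 0) completed_by[open[1]] <- aid
    }
  }
  per <- tibble(gene_id = truth$id, complete = !is.na(completed_by),
                by = unname(completed_by))
  list(n_complete = sum(per$complete),
       complete_ratio = if (nrow(per) == 0) 0 else mean(per$complete),
       per_gene = per)
}

#' Detect misassembled genes
#'
#' Each assembled gene is aligned (both strands) against all truth
#' genomes.  It maps cleanly when a single local alignment covers at least
#' `min_map_coverage` of the assembled sequence at identity at least
#' `min_map_identity`.  Otherwise the assembled sequence is misassembled
#' if it cannot be placed at all, or if two disjoint segments (each at
#' least `min_segment` bp) place at different genomic locations — a
#' chimera.  A chimera whose two segments place inside two homologous
#' truth genes (same family) is additionally flagged `minor`, the pattern
#' expected when near-identical genes from related community members are
#' interleaved.
#'
#' @param assembled assembled gene records.
#' @param truth_genomes truth genome records.
#' @param gene_locations optional tibble (`gene_id`, `genome_id`, `start`,
#'   `end`) of truth gene placements, used with `gene_families` to flag
#'   minor chimeras.
#' @param gene_families optional named character vector gene_id -> family.
#' @param scheme a [scoring_scheme()].
#' @param min_map_coverage fraction of the assembled sequence a clean
#'   mapping must cover (default 0.90).
#' @param min_map_identity identity floor for mapping (default 0.95).
#' @param min_segment minimum chimera segment length in bp (default 100).
#' @return A list with `n_misassembled`, `misassembly_rate`, and `per_gene`
#'   (tibble `assembled_id`, `status` in `mapped` / `unmapped` / `chimeric`,
#'   `minor`).
#' @export
misassembly <- function(assembled, truth_genomes, gene_locations = NULL,
                        gene_families = NULL, scheme = scoring_scheme(),
                        min_map_coverage = 0.90, min_map_identity = 0.95,
                        min_segment = 100) {
  assembled <- eval_records(assembled, "assembled")
  genomes <- eval_records(truth_genomes, "truth_genomes")

  gks <- lapply(genomes$seq, kmers_both, w = 11L)
  place <- function(seq) { # best placement across genomes
    best <- NULL
    for (gi in seq_len(nrow(genomes))) {
      al <- best_alignment(seq, genomes$seq[gi], scheme, min_map_identity,
                           t_kmers = gks[[gi]])
      if (is.null(al)) next
      if (is.null(best) || al$score > best$score) {
        best <- al; best$genome_id <- genomes$id[gi]
      }
    }
    best
  }
  gene_at <- function(genome_id, s, e) {
    if (is.null(gene_locations)) return(NA_character_)
    gl <- gene_locations[gene_locations$genome_id == genome_id &
                           gene_locations$end >= s &
                           gene_locations$start <= e, ]
    if (nrow(gl) == 0) NA_character_ else gl$gene_id[1]
  }

  per <- purrr::map_dfr(seq_len(nrow(assembled)), function(ai) {
    seq <- assembled$seq[ai]
    alen <- nchar(seq)
    p1 <- place(seq)
    if (is.null(p1)) {
      return(tibble(assembled_id = assembled$id[ai], status = "unmapped",
                    minor = FALSE))
    }
    cov1 <- (p1$a_end - p1$a_start + 1) / alen
    if (cov1 >= min_map_coverage) {
      return(tibble(assembled_id = assembled$id[ai], status = "mapped",
                    minor = FALSE))
    }
    # chimera check: mask the placed segment, try the larger remainder
    left <- substr(seq, 1, p1$a_start - 1)
    right <- substr(seq, p1$a_end + 1, alen)
    rest <- if (nchar(left) >= nchar(right)) left else right
    if (nchar(rest) < min_segment || (p1$a_end - p1$a_start + 1) < min_segment) {
      # covers < 90% but no second mappable segment of useful size
      return(tibble(assembled_id = assembled$id[ai], status = "unmapped",
                    minor = FALSE))
    }
    p2 <- place(rest)
    if (is.null(p2) || (p2$a_end - p2$a_start + 1) < min_segment) {
      return(tibble(assembled_id = assembled$id[ai], status = "unmapped",
                    minor = FALSE))
    }
    # two disjoint segments at different locations -> chimeric
    g1 <- gene_at(p1$genome_id, p1$b_start, p1$b_end)
    g2 <- gene_at(p2$genome_id, p2$b_start, p2$b_end)
    minor <- FALSE
    if (!is.null(gene_families) && !is.na(g1) && !is.na(g2) && g1 != g2) {
      minor <- identical(unname(gene_families[g1]), unname(gene_families[g2]))
    }
    tibble(assembled_id = assembled$id[ai], status = "chimeric",
           minor = minor)
  })
  mis <- per$status != "mapped"
  list(n_misassembled = sum(mis),
       misassembly_rate = if (nrow(per) == 0) 0 else mean(mis),
       per_gene = per)
}

#' Evaluate assembled genes against simulation ground truth
#'
#' Convenience wrapper computing the three evaluation metrics of the
#' method — mean gene coverage, complete-gene count and misassembly rate —
#' for an assembled gene set against a [simulate_community()] truth.
#'
#' @param assembled assembled gene records.
#' @param truth a `synthetic_truth`.
#' @param scheme a [scoring_scheme()].
#' @return An object of class `eval_report` with the fields of
#'   [gene_coverage()], [count_complete()] and [misassembly()].
#' @export
evaluate_assembly <- function(assembled, truth, scheme = scoring_scheme()) {
  fams <- setNames(truth$community_genes$family, truth$community_genes$id)
  cov <- gene_coverage(assembled, truth$community_genes, scheme = scheme)
  cmp <- count_complete(assembled, truth$community_genes, scheme = scheme)
  mis <- misassembly(assembled, truth$genomes,
                     gene_locations = truth$gene_locations,
                     gene_families = fams, scheme = scheme)
  structure(list(gene_coverage = cov$mean_coverage,
                 n_complete = cmp$n_complete,
                 complete_ratio = cmp$complete_ratio,
                 n_misassembled = mis$n_misassembled,
                 misassembly_rate = mis$misassembly_rate,
                 per_gene = dplyr::left_join(cov$per_gene,
                                             cmp$per_gene, by = "gene_id"),
                 mapping = mis$per_gene),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report> gene coverage %.1f%%, complete %d/%d (%.1f%%), ",
           "misassembled %d (%.1f%%)\n"),
    100 * x$gene_coverage, x$n_complete, nrow(x$per_gene),
    100 * x$complete_ratio, x$n_misassembled, 100 * x$misassembly_rate))
  invisible(x)
}

#' One-row summary of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(gene_coverage = x$gene_coverage, n_genes = nrow(x$per_gene),
         n_complete = x$n_complete, complete_ratio = x$complete_ratio,
         n_misassembled = x$n_misassembled,
         misassembly_rate = x$misassembly_rate)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_gene

#' Bar chart of per-gene coverage
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- object$per_gene
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$gene_id,
                                                     .data$coverage),
                                  y = .data$coverage,
                                  fill = .data$complete)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of gene covered",
                  fill = "complete") +
    ggplot2::theme_minimal()
}
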