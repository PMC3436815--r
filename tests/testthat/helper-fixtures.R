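# Small fixture builders shared across test files.

# a chain graph u1 -> u2 -> ... -> un with valid k-1 overlaps
chain_graph <- function(n, k, node_len = 12) {
  stopifnot(node_len >= 2 * (k - 1) + 1)
  seqs <- character(n)
  seqs[1] <- random_seq(node_len)
  for (i in seq_len(n - 1)) {
    ov <- substr(seqs[i], node_len - k + 2, node_len)
    seqs[i + 1] <- paste0(ov, random_seq(node_len - k + 1))
  }
  ids <- sprintf("u%02d", seq_len(n))
  names(seqs) <- ids
  edges <- if (n > 1) data.frame(from = ids[-n], to = ids[-1]) else NULL
  contig_graph(seqs, edges, k = k)
}

# write a minimal GFA file, returning its path
write_tmp_gfa <- function(s_lines, l_lines) {
  path <- tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  path
}

# a synthetic gene_path record with given summary stats (for threshold and
# merge logic tests that do not need a real alignment)
fake_path <- function(ref_id, score, identity, ref_coverage,
                      node_ids = "c1", strand = "+") {
  structure(list(ref_id = ref_id, strand = strand, score = score,
                 node_ids = node_ids, ops = strrep("=", max(score, 1)),
                 identity = identity, ref_coverage = ref_coverage,
                 ref_len = 100L, ref_start = 1L, ref_end = 40L,
                 node_start = 1L, node_end = 10L, stitched_seq = "ACGT",
                 n_match = score, n_columns = max(score, 1)),
            class = "gene_path")
}

fake_path_list <- function(...) {
  structure(list(...), class = "gene_path_list")
}

# two sequences of length 100 at exactly 76% identity: 24 single-base
# mismatches, each flanked by at least 3 matching bases, so the full-length
# alignment is the unique local optimum and its identity is 24/100
seq_pair_76 <- function() {
  a <- strsplit(random_seq(100), "")[[1]]
  b <- a
  pos <- 4 * seq_len(24)  # 4, 8, ..., 96: spacing 3 matches between sites
  for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), a[p])[1]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# two sequences of length 100 at 50% identity (alternating mismatches):
# no local alignment of meaningful extent reaches 70% identity
seq_pair_50 <- function() {
  a <- strsplit(random_seq(100), "")[[1]]
  b <- a
  for (p in seq(2, 100, by = 2)) b[p] <- setdiff(c("A", "C", "G", "T"), a[p])[1]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
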