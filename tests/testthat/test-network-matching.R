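test_that("base-pair scoring follows the match/mismatch rule, N never matches", {
  sc <- scoring_scheme()
  expect_equal(nucleotide_score("A", "A", sc), 1L)
  expect_equal(nucleotide_score("A", "C", sc), -2L)
  expect_equal(nucleotide_score("N", "N", sc), -2L)
  expect_equal(nucleotide_score(c("A", "G", "N"), c("A", "T", "N"), sc),
               c(1L, -2L, -2L))
  expect_error(nucleotide_score("A", "U", sc), "non-nucleotide")
})

test_that("a contig identical to the reference aligns perfectly", {
  withr::with_seed(21, {
    s <- random_seq(80)
  })
  g <- contig_graph(setNames(s, "c1"), NULL, k = 31)
  p <- align_graph(g, s)
  expect_equal(p$score, 80L)
  expect_equal(p$identity, 1)
  expect_equal(p$ref_coverage, 1)
  expect_equal(p$node_ids, "c1")
  expect_equal(p$stitched_seq, s)
  expect_equal(c(p$ref_start, p$ref_end), c(1L, 80L))
})

test_that("an exact two-contig path scores spelled length times the match reward", {
  withr::with_seed(22, {
    g <- chain_graph(2, k = 5, node_len = 20)
  })
  ref <- spell_path(g, contig_ids(g))
  p <- align_graph(g, ref)
  expect_equal(p$node_ids, contig_ids(g))
  expect_equal(p$score, nchar(ref) * 1L)
  expect_equal(p$stitched_seq, ref)
  expect_equal(p$identity, 1)
})

test_that("junction-crossing optimum spells the planted gene exactly", {
  # the reference is an interior window of the spelled chain, so the
  # optimal alignment must cross the k-1 junction
  withr::with_seed(23, {
    g <- chain_graph(2, k = 5, node_len = 20)
  })
  spelled <- spell_path(g, contig_ids(g))
  gene <- substr(spelled, 8, 30) # spans the junction at position 16/17
  p <- align_graph(g, gene)
  expect_equal(length(p$node_ids), 2L)
  expect_equal(p$stitched_seq, gene)
  expect_equal(p$score, nchar(gene))
  expect_equal(p$ref_coverage, 1)
})

test_that("single-node alignment reduces exactly to Smith-Waterman", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      a <- random_seq(sample(30:90, 1))
      b <- random_seq(sample(30:90, 1))
      g <- contig_graph(setNames(a, "x"), NULL, k = 4)
      got <- genestitch:::nm_strand(g, b, scoring_scheme())
      orc <- sw_local(a, b, traceback = TRUE)
      expect_identical(got$score %||% 0L, orc$score)
      if (orc$score >= 1) {
        expect_identical(got$ops, orc$ops)
        expect_identical(got$i_start, orc$a_start)
        expect_identical(got$i_end, orc$a_end)
        expect_identical(got$j_start, orc$b_start)
        expect_identical(got$j_end, orc$b_end)
        # and the score agrees with a second, independent aligner
        expect_identical(as.numeric(orc$score), bios_local_score(a, b))
      }
    }
  })
})

test_that("graph score equals the brute-force best over all simple paths", {
  withr::with_seed(32, {
    for (rep in 1:40) {
      k <- sample(4:5, 1)
      g <- random_contig_dag(sample(2:8, 1), k)
      ref <- random_seq(sample(20:60, 1))
      got <- genestitch:::nm_strand(g, ref, scoring_scheme())$score %||% 0L
      expect_identical(got, brute_force_graph_score(g, ref))
    }
  })
})

test_that("adding an edge never decreases the optimal score", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      g <- random_contig_dag(6, 4, p_edge = 0.5)
      ref <- random_seq(50)
      full <- genestitch:::nm_strand(g, ref, scoring_scheme())$score %||% 0L
      if (nrow(g$edges) == 0) next
      drop <- sample(nrow(g$edges), 1)
      g2 <- contig_graph(g$seqs, g$edges[-drop, ], k = g$k)
      reduced <- genestitch:::nm_strand(g2, ref, scoring_scheme())$score %||% 0L
      expect_lte(reduced, full)
    }
  })
})

test_that("alignment is symmetric under reverse-complementing graph and reference", {
  withr::with_seed(34, {
    for (rep in 1:8) {
      g <- random_contig_dag(5, 4, p_edge = 0.4)
      ref <- random_seq(40)
      fwd <- genestitch:::nm_strand(g, ref, scoring_scheme())$score %||% 0L
      rg <- reverse_complement_graph(g)
      rev <- genestitch:::nm_strand(rg, revcomp(ref), scoring_scheme())$score %||% 0L
      expect_identical(fwd, rev)
    }
  })
})

test_that("returned paths rescore exactly from their alignment columns", {
  withr::with_seed(35, {
    for (rep in 1:15) {
      g <- random_contig_dag(sample(2:7, 1), 4)
      ref <- random_seq(sample(30:60, 1))
      p <- align_graph(g, ref)
      if (is.null(p)) next
      expect_identical(rescore_path(p, ref, g), p$score)
      # reported stats are consistent
      st <- path_stats(p)
      expect_equal(st$identity, p$n_match / p$n_columns)
      expect_equal(st$ref_coverage, (p$ref_end - p$ref_start + 1) / nchar(ref))
    }
  })
})

test_that("the better reference strand wins and coordinates map back", {
  withr::with_seed(36, {
    g <- chain_graph(2, k = 5, node_len = 25)
  })
  spelled <- spell_path(g, contig_ids(g))
  gene <- substr(spelled, 5, 40)
  p <- align_graph(g, revcomp(gene))
  expect_equal(p$strand, "-")
  expect_equal(p$stitched_seq, gene)     # stitched is forward graph strand
  expect_equal(p$score, nchar(gene))
  expect_equal(p$ref_coverage, 1)
  expect_identical(rescore_path(p, revcomp(gene), g), p$score)
})

test_that("no-similarity and degenerate inputs return no path", {
  g <- contig_graph(c(a = "AAAAAAAA"), NULL, k = 4)
  expect_null(align_graph(g, "CCCCCCCC"))
  empty <- contig_graph(character(0), NULL, k = 4)
  expect_null(align_graph(empty, "ACGTACGT"))
  expect_error(align_graph(g, ""), "empty reference")
})

test_that("cyclic graphs align deterministically with bounded traceback", {
  # 3-cycle a -> b -> c -> a with consistent 2-base overlaps
  seqs <- c(a = "GGACCTT", b = "TTCAAGG", c = "GGTTAGG")
  g <- contig_graph(seqs, data.frame(from = c("a", "b", "c"),
                                     to = c("b", "c", "a")), k = 3)
  ref <- spell_path(g, c("a", "b"))
  p1 <- align_graph(g, ref)
  p2 <- align_graph(g, ref)
  expect_identical(tidy(p1), tidy(p2)) # deterministic
  expect_gte(p1$score, nchar(ref) - 4) # near-exact despite the cycle
  expect_identical(rescore_path(p1, ref, g), p1$score)
})
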