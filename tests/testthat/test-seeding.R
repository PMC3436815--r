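test_that("internal hit search finds identical contigs and skips unrelated ones", {
  withr::with_seed(41, {
    ref <- random_seq(100)
    other <- random_seq(60)
  })
  g <- contig_graph(c(c1 = ref, c2 = other), NULL, k = 31)
  hits <- find_hits(g, c(r1 = ref))
  expect_equal(hits$contig_id[1], "c1")
  expect_equal(hits$score[1], 100)
  expect_equal(c(hits$contig_start[1], hits$contig_end[1]), c(1L, 100L))
  # c2 shares no 11-mer with the reference: no hit
  expect_false("c2" %in% hits$contig_id)
})

test_that("BLAST tabular mode applies the E-value cutoff and validates rows", {
  g <- contig_graph(c(c1 = strrep("ACGT", 10), c2 = strrep("GGCA", 10)),
                    NULL, k = 5)
  tab <- tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tr1\t98.0\t40\t1\t0\t1\t40\t1\t40\t0.001\t55.5",
    "c2\tr1\t90.0\t30\t3\t0\t1\t30\t5\t34\t0.5\t30.1"), tab)
  hits <- find_hits(g, c(r1 = strrep("ACGT", 10)), mode = "blast_tab",
                    blast_file = tab, evalue_cutoff = 0.1)
  expect_equal(hits$contig_id, "c1")  # the 0.5 E-value row is filtered out
  expect_equal(hits$score, 55.5)
  writeLines("c1\tr1\tbroken", tab)
  expect_error(find_hits(g, c(r1 = "ACGT"), mode = "blast_tab",
                         blast_file = tab), "line 1")
})

test_that("recruitment walks N hit-free layers and hits reset the counter", {
  withr::with_seed(42, {
    g <- chain_graph(12, k = 4, node_len = 10)
  })
  ids <- contig_ids(g)
  hit1 <- tibble::tibble(contig_id = ids[1], ref_id = "r", score = 50,
                         evalue = NA_real_, contig_start = 1L,
                         contig_end = 10L, ref_start = 1L, ref_end = 10L)
  sub <- build_subgraph(g, "r", hit1, n_layers = 5)
  expect_equal(sort(sub$node_ids), sort(ids[1:6]))
  expect_equal(sub$seed_id, ids[1])

  # an extra hit at node 7 resets the hit-free depth: all 12 recruited
  hit2 <- rbind(hit1, within(hit1, contig_id <- ids[7]))
  sub2 <- build_subgraph(g, "r", hit2, n_layers = 5)
  expect_equal(sort(sub2$node_ids), sort(ids))

  # a hit-free gap of 5 then a hit: everything in between is recruited
  hit3 <- rbind(hit1, within(hit1, contig_id <- ids[7]))
  g7 <- induced_subgraph(g, ids[1:7])
  sub3 <- build_subgraph(g7, "r", hit3, n_layers = 5)
  expect_equal(sort(sub3$node_ids), sort(ids[1:7]))

  # no hits for the reference: skipped
  expect_null(build_subgraph(g, "other", hit1))

  # isolated seed node
  g1 <- induced_subgraph(g, ids[1])
  expect_equal(build_subgraph(g1, "r", hit1)$node_ids, ids[1])
})

test_that("recruited set does not depend on hit-table row order", {
  withr::with_seed(43, {
    g <- chain_graph(10, k = 4, node_len = 10)
    ids <- contig_ids(g)
    hits <- tibble::tibble(
      contig_id = ids[c(2, 6, 9)], ref_id = "r", score = c(30, 80, 55),
      evalue = NA_real_, contig_start = 1L, contig_end = 10L,
      ref_start = 1L, ref_end = 10L)
    base <- sort(build_subgraph(g, "r", hits, n_layers = 2)$node_ids)
    for (i in 1:5) {
      shuf <- hits[sample(nrow(hits)), ]
      expect_equal(sort(build_subgraph(g, "r", shuf, n_layers = 2)$node_ids),
                   base)
    }
  })
})

test_that("intact-gene masking splits contigs and conserves sequence", {
  withr::with_seed(44, {
    s <- random_seq(1000)
  })
  g <- contig_graph(setNames(s, "c"), NULL, k = 31)
  ann <- tibble::tibble(contig_id = "c", start = 201L, end = 800L)
  masked <- mask_intact_genes(g, ann)
  expect_setequal(contig_ids(masked), c("c.L", "c.R"))
  expect_equal(unname(nchar(masked$seqs)), c(200L, 200L))
  expect_equal(masked$seqs[["c.L"]], substr(s, 1, 200))
  expect_equal(masked$seqs[["c.R"]], substr(s, 801, 1000))
  expect_equal(nrow(masked$edges), 0L)

  # a prediction covering position 1 is a fragmented gene: no change
  ann2 <- tibble::tibble(contig_id = "c", start = 1L, end = 500L)
  expect_identical(mask_intact_genes(g, ann2)$seqs, g$seqs)

  # remnants shorter than k are dropped
  ann3 <- tibble::tibble(contig_id = "c", start = 11L, end = 990L)
  masked3 <- mask_intact_genes(g, ann3)
  expect_equal(length(masked3$seqs), 0L)
})

test_that("masking keeps in-edges on the left remnant and out-edges on the right", {
  withr::with_seed(45, {
    g <- chain_graph(3, k = 5, node_len = 60)
  })
  ids <- contig_ids(g)
  mid <- ids[2]
  ann <- tibble::tibble(contig_id = mid, start = 21L, end = 40L)
  masked <- mask_intact_genes(g, ann)
  expect_setequal(contig_ids(masked),
                  c(ids[1], paste0(mid, ".L"), paste0(mid, ".R"), ids[3]))
  expect_true(any(masked$edges$from == ids[1] &
                    masked$edges$to == paste0(mid, ".L")))
  expect_true(any(masked$edges$from == paste0(mid, ".R") &
                    masked$edges$to == ids[3]))
  # the two remnants are not joined
  expect_false(any(masked$edges$from == paste0(mid, ".L") &
                     masked$edges$to == paste0(mid, ".R")))
})

test_that("masking conserves total length on random annotated graphs", {
  withr::with_seed(46, {
    for (rep in 1:25) {
      n <- sample(2:5, 1)
      k <- sample(c(5L, 7L), 1)
      g <- chain_graph(n, k = k, node_len = sample(40:80, 1))
      ids <- contig_ids(g)
      lens <- nchar(g$seqs)
      # random (possibly overlapping) interior annotations
      ann <- purrr::map_dfr(sample(ids, sample(n, 1)), function(cid) {
        s <- sample(2:(lens[[cid]] - 2), 1)
        e <- min(lens[[cid]] - 1, s + sample(5:30, 1))
        tibble::tibble(contig_id = cid, start = s, end = e)
      })
      masked <- mask_intact_genes(g, ann)

      # independent conservation accounting from merged intervals
      expected <- sum(lens)
      for (cid in unique(ann$contig_id)) {
        iv <- ann[ann$contig_id == cid, ]
        iv <- iv[iv$start > 1 & iv$end < lens[[cid]], ]
        if (nrow(iv) == 0) next
        merged <- genestitch:::merge_intervals(iv[, c("start", "end")])
        expected <- expected - sum(merged$end - merged$start + 1)
        rs <- c(1L, merged$end + 1L); re <- c(merged$start - 1L, lens[[cid]])
        keep <- re >= rs
        seg <- (re - rs + 1L)[keep]
        expected <- expected - sum(seg[seg < k]) # dropped short remnants
      }
      expect_equal(sum(nchar(masked$seqs)), expected)
      # no new adjacency: every edge maps onto an original one
      orig_pairs <- paste(g$edges$from, g$edges$to)
      strip <- function(x) sub("\\.(L|R|M[0-9]+)$", "", x)
      expect_true(all(paste(strip(masked$edges$from),
                            strip(masked$edges$to)) %in% orig_pairs))
    }
  })
})

test_that("ORF finder respects frames, strands, and the intact boundary rule", {
  withr::with_seed(47, {
    # build an ORF of 59 codons: ATG + 57 sense codons + TAA
    body <- paste(replicate(57, sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), 1)), collapse = "")
    orf <- paste0("ATG", body, "TAA")
  })
  expect_equal(nchar(orf), 177L)
  # exactly spanning the contig: found, not intact
  ann <- find_orfs(orf, min_len = 60)
  row <- ann[ann$start == 1 & ann$end == 177 & ann$strand == "+", ]
  expect_equal(nrow(row), 1L)
  expect_false(row$intact)
  # embedded with 50-bp flanks: intact.  The upstream flank ends with an
  # in-frame stop so the embedded ORF cannot extend leftwards.
  withr::with_seed(48, {
    flank5 <- paste0(random_seq(47), "TAA"); flank3 <- random_seq(50)
  })
  emb <- paste0(flank5, orf, flank3)
  ann2 <- find_orfs(emb, min_len = 60)
  row2 <- ann2[ann2$start == 51 & ann2$end == 227, ]
  expect_gte(nrow(row2), 1L)
  expect_true(all(row2$intact))
  # reverse-strand detection
  ann3 <- find_orfs(revcomp(emb), min_len = 60)
  expect_true(any(ann3$strand == "-" & ann3$end - ann3$start + 1 == 177))
  # poly-N yields nothing
  expect_equal(nrow(find_orfs(strrep("N", 300), min_len = 60)), 0L)
  expect_error(find_orfs(orf, min_len = 30), ">= 60")
})

test_that("GFF3 gene features parse into annotation rows", {
  p <- tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    "c1\tpred\tgene\t10\t200\t.\t+\t.\tID=g1",
    "c1\tpred\texon\t10\t100\t.\t+\t.\tID=e1",
    "c2\tpred\tCDS\t5\t80\t.\t-\t0\tID=c"), p)
  ann <- read_gff_genes(p)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$contig_id, c("c1", "c2"))
  expect_equal(ann$start, c(10L, 5L))
  expect_equal(ann$strand, c("+", "-"))
})
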