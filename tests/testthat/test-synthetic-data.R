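test_that("unitig compression handles simple and tangled inputs", {
  withr::with_seed(61, {
    s <- random_seq(200)
  })
  # one sequence without repeated (k-1)-mers: a single contig, no edges
  u <- build_unitig_graph(c(g1 = s), k = 31)
  expect_length(u$graph$seqs, 1L)
  expect_equal(nrow(u$graph$edges), 0L)
  expect_equal(unname(u$graph$seqs[[u$true_paths$g1]]), s)

  # an exact duplicate adds nothing: identical k-mer set, identical graph
  u2 <- build_unitig_graph(c(g1 = s, g2 = s), k = 31)
  expect_equal(sort(unname(u2$graph$seqs)), sort(unname(u$graph$seqs)))
  expect_equal(nrow(u2$graph$edges), 0L)

  # two sequences sharing an interior >= k window branch around a shared
  # middle unitig
  withr::with_seed(62, {
    core <- random_seq(40)
    a <- paste0(random_seq(80), core, random_seq(80))
    b <- paste0(random_seq(80), core, random_seq(80))
  })
  u3 <- build_unitig_graph(c(a = a, b = b), k = 31)
  expect_gte(length(u3$graph$seqs), 4L)
  shared <- intersect(u3$true_paths$a, u3$true_paths$b)
  expect_length(shared, 1L)  # the shared core unitig
  expect_true(grepl(substr(core, 6, 35), u3$graph$seqs[[shared]],
                    fixed = TRUE))

  expect_error(build_unitig_graph(c(x = "ACGT"), k = 31), "at least k")
})

test_that("spelling a recorded walk reproduces every input sequence", {
  withr::with_seed(63, {
    core <- random_seq(50)
    seqs <- setNames(vapply(1:3, function(i) {
      paste0(random_seq(60), core, random_seq(60))
    }, ""), c("s1", "s2", "s3"))
  })
  u <- build_unitig_graph(seqs, k = 31)
  for (id in names(seqs)) {
    expect_identical(spell_path(u$graph, u$true_paths[[id]]), seqs[[id]])
  }
})

test_that("unitigs are maximal: no compressible junction survives", {
  withr::with_seed(64, {
    core <- random_seq(45)
    seqs <- c(a = paste0(random_seq(70), core, random_seq(70)),
              b = paste0(random_seq(70), core, random_seq(70)))
  })
  u <- build_unitig_graph(seqs, k = 31)
  deg <- tidy(u$graph)
  for (r in seq_len(nrow(u$graph$edges))) {
    from <- u$graph$edges$from[r]; to <- u$graph$edges$to[r]
    compressible <- deg$out_degree[deg$id == from] == 1 &&
      deg$in_degree[deg$id == to] == 1
    expect_false(compressible)
  }
})

test_that("the simulator is reproducible and its ground truth is consistent", {
  cfg <- sim_config(seed = 7, n_families = 3, gene_len = 300,
                    intergenic_len = 80)
  tr1 <- simulate_community(cfg)
  tr2 <- simulate_community(cfg)
  expect_identical(tr1$graph$seqs, tr2$graph$seqs)
  expect_identical(tr1$community_genes, tr2$community_genes)
  expect_identical(tr1$reference_genes, tr2$reference_genes)

  # genomes spell exactly; genes are exact substrings of their spelled path
  for (r in seq_len(nrow(tr1$genomes))) {
    expect_identical(
      spell_path(tr1$graph, tr1$genome_paths[[tr1$genomes$id[r]]]),
      tr1$genomes$seq[r])
  }
  for (i in seq_len(nrow(tr1$community_genes))) {
    gid <- tr1$community_genes$id[i]
    expect_true(grepl(tr1$community_genes$seq[i],
                      spell_path(tr1$graph, tr1$true_paths[[gid]]),
                      fixed = TRUE))
  }
  # per-contig annotations point at real gene sequence
  ann <- tr1$annotations
  for (r in sample(nrow(ann), min(10, nrow(ann)))) {
    piece <- substr(tr1$graph$seqs[[ann$contig_id[r]]], ann$start[r],
                    ann$end[r])
    gene <- tr1$community_genes$seq[tr1$community_genes$id == ann$gene_id[r]]
    expect_true(grepl(piece, gene, fixed = TRUE))
  }
})

test_that("zero divergence collapses family members onto shared contigs", {
  cfg <- sim_config(seed = 8, n_families = 2, genes_per_family = 2,
                    gene_len = 300, community_divergence = 0,
                    reference_divergence = 0, intergenic_len = 80)
  tr <- simulate_community(cfg)
  # identical members: the gene body collapses into contigs shared by both
  # genomes (only the spacer-boundary contigs differ)
  for (fam in unique(tr$community_genes$family)) {
    ids <- tr$community_genes$id[tr$community_genes$family == fam]
    shared <- intersect(tr$true_paths[[ids[1]]], tr$true_paths[[ids[2]]])
    expect_gt(length(shared), 0L)
    gene <- tr$community_genes$seq[tr$community_genes$id == ids[1]]
    expect_true(any(vapply(shared, function(cid)
      grepl(tr$graph$seqs[[cid]], gene, fixed = TRUE) ||
        grepl(gene, tr$graph$seqs[[cid]], fixed = TRUE), logical(1))))
  }
  # references identical to the community genes
  expect_identical(
    tr$reference_genes$seq,
    tr$community_genes$seq[match(sub("_ref$", "", tr$reference_genes$id),
                                 tr$community_genes$id)])
})

test_that("fragmentation modes split unitigs but preserve spelled walks", {
  cfg <- sim_config(seed = 9, n_families = 2, gene_len = 300,
                    intergenic_len = 80, fragmentation = "random_breaks",
                    fragmentation_rate = 0.01)
  tr <- simulate_community(cfg)
  for (r in seq_len(nrow(tr$genomes))) {
    expect_identical(
      spell_path(tr$graph, tr$genome_paths[[tr$genomes$id[r]]]),
      tr$genomes$seq[r])
  }
  cfg2 <- sim_config(seed = 9, n_families = 2, gene_len = 300,
                     intergenic_len = 80,
                     fragmentation = "break_at_shared_kmers")
  tr2 <- simulate_community(cfg2)
  for (r in seq_len(nrow(tr2$genomes))) {
    expect_identical(
      spell_path(tr2$graph, tr2$genome_paths[[tr2$genomes$id[r]]]),
      tr2$genomes$seq[r])
  }
  expect_error(sim_config(community_divergence = 0.9), "0.75")
  expect_error(sim_config(gene_len = 50, k = 31), "3 \\* k")
})
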