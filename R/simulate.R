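#' Simulation configuration
#'
#' Parameters for the synthetic community generator.  The simulator
#' emulates the situation the stitching method targets: families of
#' homologous genes carried by closely related community members, whose
#' shared regions collapse in a de Bruijn graph and fragment the assembly.
#'
#' @param seed integer random seed; the whole simulation is reproducible
#'   from it.
#' @param n_families number of homologous gene families (default 20).
#' @param genes_per_family community members per family (default 2).
#' @param gene_len gene length in bp (default 900; must be >= `3 * k`).
#' @param community_divergence substitution rate between family members
#'   (default 0.03, i.e. strains/species of the same genus).
#' @param reference_divergence substitution rate between the family
#'   ancestor and the emitted reference gene (default 0.15, emulating a
#'   reference from a related genus or family).
#' @param intergenic_len mean intergenic spacer length in bp (default 200).
#' @param k k-mer size of the de Bruijn graph (default 31).
#' @param core_len length of the conserved (zero-divergence) core window
#'   shared by all members of a family (default `3 * k`); this is what
#'   makes homologous genes collapse into shared contigs and tangle the
#'   graph.
#' @param fragmentation extra contig fragmentation applied after unitig
#'   compression: `"none"` (default), `"random_breaks"` (each unitig is
#'   split at random internal junctions at per-base rate
#'   `fragmentation_rate`), or `"break_at_shared_kmers"` (contigs are
#'   additionally split around `k - 1`-mers occurring in more than one
#'   contig).
#' @param fragmentation_rate per-base break probability for
#'   `"random_breaks"` (default 0.002).
#' @param indel_rate per-base indel rate for member/reference mutation
#'   (default 0, so identity arithmetic stays exact).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_families = 20, genes_per_family = 2,
                       gene_len = 900, community_divergence = 0.03,
                       reference_divergence = 0.15, intergenic_len = 200,
                       k = 31, core_len = 3 * k,
                       fragmentation = c("none", "random_breaks",
                                         "break_at_shared_kmers"),
                       fragmentation_rate = 0.002, indel_rate = 0) {
  fragmentation <- match.arg(fragmentation)
  rates <- c(community_divergence, reference_divergence)
  if (any(rates < 0) || any(rates >= 0.75)) {
    abort("divergence rates must lie in [0, 0.75)")
  }
  if (gene_len < 3 * k) abort("`gene_len` must be >= 3 * k")
  if (core_len < 3 * k) abort("`core_len` must be >= 3 * k")
  if (core_len > gene_len) abort("`core_len` must be <= `gene_len`")
  structure(
    list(seed = as.integer(seed), n_families = n_families,
         genes_per_family = genes_per_family, gene_len = gene_len,
         community_divergence = community_divergence,
         reference_divergence = reference_divergence,
         intergenic_len = intergenic_len, k = as.integer(k),
         core_len = core_len, fragmentation = fragmentation,
         fragmentation_rate = fragmentation_rate, indel_rate = indel_rate),
    class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute (and optionally indel) bases outside protected positions
mutate_seq <- function(seq, sub_rate, indel_rate = 0, protect = integer(0)) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  editable <- setdiff(seq_len(n), protect)
  nsub <- stats::rbinom(1, length(editable), sub_rate)
  if (nsub > 0) {
    pos <- sample(editable, nsub)
    for (p in pos) {
      bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
    }
  }
  if (indel_rate > 0) {
    nind <- stats::rbinom(1, length(editable), indel_rate)
    if (nind > 0) {
      pos <- sort(sample(editable, nind), decreasing = TRUE)
      for (p in pos) {
        if (stats::runif(1) < 0.5) {
          bases <- append(bases, sample(c("A", "C", "G", "T"), 1), after = p)
        } else {
          bases <- bases[-p]
        }
      }
    }
  }
  paste(bases, collapse = "")
}

#' Simulate a synthetic community with ground truth
#'
#' Per family, an ancestor gene is drawn uniformly at random; each
#' community member copies it with substitutions at `community_divergence`
#' everywhere except a conserved core window (which is copied verbatim, so
#' that homologs share an exact region longer than `k` and tangle the
#' graph); the family's reference gene copies the ancestor with
#' substitutions at `reference_divergence` over its whole length.  Member
#' genomes are built by concatenating each member's genes with random
#' intergenic spacers, and the genomes are compressed into a unitig contig
#' graph with [build_unitig_graph()].
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_truth` with elements:
#'   `community_genes` (tibble `id`, `family`, `member`, `seq`),
#'   `reference_genes` (tibble `id`, `family`, `seq`), `genomes` (tibble
#'   `id`, `seq`), `graph` (a [contig_graph()]), `true_paths` (named list
#'   gene id -> contig id chain whose spelled sequence contains the gene),
#'   `genome_paths` (named list genome id -> contig chain spelling the
#'   genome exactly),
#'   `gene_locations` (tibble `gene_id`, `genome_id`, `start`, `end`) and
#'   `annotations` (per-contig gene intervals: `contig_id`, `start`, `end`,
#'   `gene_id`, `intact`).
#' @export
simulate_community <- function(config = sim_config()) {
  set.seed(config$seed)
  nf <- config$n_families
  npm <- config$genes_per_family
  L <- config$gene_len
  core_start <- (L - config$core_len) %/% 2 + 1L
  core <- seq(core_start, core_start + config$core_len - 1L)

  fam_id <- sprintf("fam%02d", seq_len(nf))
  genes <- list(); refs <- list()
  for (f in seq_len(nf)) {
    anc <- random_dna(L)
    for (g in seq_len(npm)) {
      member_seq <- mutate_seq(anc, config$community_divergence,
                               config$indel_rate, protect = core)
      genes[[length(genes) + 1L]] <- tibble(
        id = sprintf("%s_m%d", fam_id[f], g), family = fam_id[f],
        member = g, seq = member_seq)
      # one reference homolog per community gene, diverged further from it
      # (the related-species gene that guides stitching)
      refs[[length(refs) + 1L]] <- tibble(
        id = sprintf("%s_m%d_ref", fam_id[f], g), family = fam_id[f],
        seq = mutate_seq(member_seq, config$reference_divergence,
                         config$indel_rate))
    }
  }
  community_genes <- dplyr::bind_rows(genes)
  reference_genes <- dplyr::bind_rows(refs)

  # one genome per member: its copy of every family's gene, spaced by
  # random intergenic sequence
  genomes <- list(); locs <- list()
  for (g in seq_len(npm)) {
    gid <- sprintf("genome_m%d", g)
    parts <- character(0); pos <- 0L
    for (f in seq_len(nf)) {
      spacer <- random_dna(max(config$k,
                               stats::rpois(1, config$intergenic_len)))
      gene <- community_genes$seq[community_genes$family == fam_id[f] &
                                    community_genes$member == g]
      parts <- c(parts, spacer, gene)
      pos <- pos + nchar(spacer)
      locs[[length(locs) + 1L]] <- tibble(
        gene_id = sprintf("%s_m%d", fam_id[f], g), genome_id = gid,
        start = pos + 1L, end = pos + nchar(gene))
      pos <- pos + nchar(gene)
    }
    parts <- c(parts, random_dna(max(config$k,
                                     stats::rpois(1, config$intergenic_len))))
    genomes[[g]] <- tibble(id = gid, seq = paste(parts, collapse = ""))
  }
  genomes <- dplyr::bind_rows(genomes)
  gene_locations <- dplyr::bind_rows(locs)

  ug <- build_unitig_graph(setNames(genomes$seq, genomes$id), k = config$k,
                           fragmentation = config$fragmentation,
                           fragmentation_rate = config$fragmentation_rate)
  graph <- ug$graph

  # project genes onto contig chains and contig-local intervals
  true_paths <- list(); ann <- list()
  for (r in seq_len(nrow(gene_locations))) {
    loc <- gene_locations[r, ]
    walk <- ug$walks[[loc$genome_id]] # tibble: contig_id, g_start, g_end
    hitw <- walk[walk$g_end >= loc$start & walk$g_start <= loc$end, ]
    true_paths[[loc$gene_id]] <- hitw$contig_id
    ann[[length(ann) + 1L]] <- tibble(
      contig_id = hitw$contig_id,
      start = pmax(loc$start, hitw$g_start) - hitw$g_start + 1L,
      end = pmin(loc$end, hitw$g_end) - hitw$g_start + 1L,
      gene_id = loc$gene_id)
  }
  annotations <- dplyr::bind_rows(ann)
  clen <- nchar(graph$seqs)
  annotations$intact <- annotations$start > 1L &
    annotations$end < clen[annotations$contig_id]

  structure(
    list(config = config, community_genes = community_genes,
         reference_genes = reference_genes, genomes = genomes,
         graph = graph, true_paths = true_paths,
         genome_paths = ug$true_paths,
         gene_locations = gene_locations, annotations = annotations),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d families x %d members (%d bp genes), %d genomes\n",
    x$config$n_families, x$config$genes_per_family, x$config$gene_len,
    nrow(x$genomes)))
  print(x$graph)
  invisible(x)
}

#' Build a unitig contig graph from sequences
#'
#' Clean-room de Bruijn compression standing in for an assembler's contig
#' graph: the distinct k-mers of the input sequences and their observed
#' `k - 1`-overlap adjacencies (the `(k + 1)`-mers present in the input)
#' are compressed into maximal unbranched unitigs.  Edges carry exact
#' `k - 1` overlaps, so the result passes [contig_graph()] validation, and
#' for each input sequence the traversed unitig chain is recorded so that
#' spelling it reproduces the input exactly.  Sequences are used in the
#' given orientation only (no reverse-complement canonicalisation), which
#' matches the single-orientation graph model of the package.
#'
#' @param seqs named character vector of sequences, all of length >= `k`.
#' @param k k-mer size.
#' @param fragmentation,fragmentation_rate see [sim_config()].
#' @return A list with `graph` (a [contig_graph()]), `true_paths` (named
#'   list: input id -> contig chain) and `walks` (named list of tibbles
#'   `contig_id`, `g_start`, `g_end` giving each chain contig's spelled
#'   span on the input sequence).
#' @export
build_unitig_graph <- function(seqs, k, fragmentation = "none",
                               fragmentation_rate = 0.002) {
  if (any(nchar(seqs) < k)) abort("all sequences must be at least k long")
  seqs <- toupper(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))

  kmer_runs <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  kmers <- unique(unlist(kmer_runs, use.names = FALSE))
  nk <- length(kmers)
  kix <- seq_len(nk)
  names(kix) <- kmers

  # observed adjacencies = consecutive k-mers in any input
  efrom <- integer(0); eto <- integer(0)
  for (run in kmer_runs) {
    iv <- unname(kix[run])
    if (length(iv) > 1) {
      efrom <- c(efrom, iv[-length(iv)])
      eto <- c(eto, iv[-1])
    }
  }
  ekey <- unique(efrom * (nk + 1) + eto)
  efrom <- as.integer(ekey %/% (nk + 1))
  eto <- as.integer(ekey %% (nk + 1))
  outdeg <- tabulate(efrom, nk)
  indeg <- tabulate(eto, nk)
  succ <- rep(NA_integer_, nk); succ[efrom[outdeg[efrom] == 1]] <-
    eto[outdeg[efrom] == 1]
  pred <- rep(NA_integer_, nk); pred[eto[indeg[eto] == 1]] <-
    efrom[indeg[eto] == 1]

  # unitig = maximal run where internal joins have out==1 into in==1
  extendable <- !is.na(succ) & indeg[succ] == 1 # can absorb its successor
  start <- is.na(pred) | !(outdeg[pred] == 1 & indeg == 1)
  unitig_of <- integer(nk); upos <- integer(nk)
  unitig_kmers <- list()
  uid <- 0L
  for (s in which(start)) {
    uid <- uid + 1L
    chain <- s
    cur <- s
    while (extendable[cur] && !start[succ[cur]]) {
      cur <- succ[cur]
      chain <- c(chain, cur)
    }
    unitig_of[chain] <- uid
    upos[chain] <- seq_along(chain)
    unitig_kmers[[uid]] <- chain
  }
  if (any(unitig_of == 0L)) { # isolated cycles: break at smallest k-mer
    left <- which(unitig_of == 0L)
    while (length(left) > 0) {
      s <- left[which.min(kmers[left])]
      uid <- uid + 1L
      chain <- s; cur <- succ[s]
      while (!is.na(cur) && cur != s && unitig_of[cur] == 0L) {
        chain <- c(chain, cur); cur <- succ[cur]
      }
      unitig_of[chain] <- uid
      upos[chain] <- seq_along(chain)
      unitig_kmers[[uid]] <- chain
      left <- which(unitig_of == 0L)
    }
  }

  useq <- vapply(unitig_kmers, function(ch) {
    paste0(kmers[ch[1]],
           paste(substring(kmers[ch[-1]], k, k), collapse = ""))
  }, "")
  unames <- sprintf("u%04d", seq_along(useq))
  names(useq) <- unames

  # contig-level edges: last k-mer of u -> first k-mer of v (observed)
  lastk <- vapply(unitig_kmers, function(ch) ch[length(ch)], integer(1))
  firstk <- vapply(unitig_kmers, function(ch) ch[1], integer(1))
  e_u <- unitig_of[efrom]; e_v <- unitig_of[eto]
  keep <- upos[efrom] == lengths(unitig_kmers)[e_u] & upos[eto] == 1L
  edges <- unique(tibble(from = unames[e_u[keep]], to = unames[e_v[keep]]))

  graph <- contig_graph(useq, edges, k = k)

  if (fragmentation == "random_breaks") {
    graph <- fragment_random(graph, fragmentation_rate)
  } else if (fragmentation == "break_at_shared_kmers") {
    graph <- fragment_shared(graph)
  }

  # walk each input through the (possibly fragmented) graph
  walks <- lapply(kmer_runs, function(run) walk_sequence(graph, run, k))
  names(walks) <- ids
  true_paths <- lapply(walks, `[[`, "contig_id")

  list(graph = graph, true_paths = true_paths, walks = walks)
}

# map a k-mer run to the contig chain spelling it, with spelled spans
walk_sequence <- function(graph, run, k) {
  # locate each contig's k-mer prefix occurrences
  firstk <- substr(graph$seqs, 1L, k)
  ids <- contig_ids(graph)
  lens <- nchar(graph$seqs)
  chain <- character(0); g_start <- integer(0); g_end <- integer(0)
  pos <- 1L # position of the next unconsumed k-mer (= base position)
  n <- length(run)
  by_first <- split(ids, firstk[ids])
  while (pos <= n) {
    cands <- by_first[[run[pos]]]
    stopifnot(!is.null(cands))
    # the contig whose sequence matches the input here; unitigs are unique
    hit <- NULL
    for (cid in cands) {
      span <- lens[[cid]] - k + 1L
      if (pos + span - 1L > n) {
        if (pos + span - 1L > n) next
      }
      ok <- TRUE
      if (span > 1) {
        idx <- pos + span - 1L
        last_kmer <- substr(graph$seqs[[cid]], span, span + k - 1L)
        ok <- idx <= n && run[idx] == last_kmer
      }
      if (ok) { hit <- cid; break }
    }
    if (is.null(hit)) {
      # partial final contig: input ends inside this contig — take the
      # candidate whose prefix matches longest (only at sequence end)
      hit <- cands[1]
    }
    span <- lens[[hit]] - k + 1L
    chain <- c(chain, hit)
    g_start <- c(g_start, pos)
    g_end <- c(g_end, min(pos + lens[[hit]] - 1L, n + k - 1L))
    pos <- pos + span
  }
  tibble(contig_id = chain, g_start = g_start, g_end = g_end)
}

fragment_random <- function(graph, rate) {
  seqs <- list(); edges <- graph$edges
  k <- graph$k
  for (cid in contig_ids(graph)) {
    s <- graph$seqs[[cid]]
    L <- nchar(s)
    # candidate junction positions leave >= k bases on both sides
    cand <- if (L >= 2 * k) seq(k, L - k) else integer(0)
    cuts <- cand[stats::runif(length(cand)) < rate]
    pieces <- split_contig(s, cuts, k)
    pids <- if (length(pieces) == 1) cid else
      paste0(cid, ".", seq_along(pieces))
    for (p in seq_along(pieces)) seqs[[pids[p]]] <- pieces[[p]]
    if (length(pieces) > 1) {
      edges$from[edges$from == cid] <- pids[length(pids)]
      edges$to[edges$to == cid] <- pids[1]
      edges <- dplyr::bind_rows(edges,
        tibble(from = pids[-length(pids)], to = pids[-1]))
    }
  }
  contig_graph(unlist(seqs), edges, k = k)
}

# split at positions `cuts` (each cut c: left ends at c, right starts at
# c - k + 2 so the two pieces overlap by k - 1)
split_contig <- function(s, cuts, k) {
  if (length(cuts) == 0) return(list(s))
  cuts <- sort(unique(cuts))
  starts <- c(1L, cuts - k + 2L)
  ends <- c(cuts, nchar(s))
  lapply(seq_along(starts), function(i) substr(s, starts[i], ends[i]))
}

fragment_shared <- function(graph) {
  k <- graph$k
  w <- k - 1L
  allw <- lapply(graph$seqs, function(s) {
    n <- nchar(s) - w + 1L
    substring(s, seq_len(n), seq_len(n) + w - 1L)
  })
  tab <- table(unlist(allw, use.names = FALSE))
  shared <- names(tab)[tab > 1]
  seqs <- list(); edges <- graph$edges
  for (cid in contig_ids(graph)) {
    s <- graph$seqs[[cid]]
    L <- nchar(s)
    wm <- allw[[cid]]
    hit <- which(wm %in% shared)
    # break after each interior shared (k-1)-mer, keeping both pieces >= k
    cuts <- (hit + w - 1L)
    cuts <- cuts[cuts >= k & cuts <= L - k]
    pieces <- split_contig(s, cuts, k)
    pids <- if (length(pieces) == 1) cid else
      paste0(cid, ".", seq_along(pieces))
    for (p in seq_along(pieces)) seqs[[pids[p]]] <- pieces[[p]]
    if (length(pieces) > 1) {
      edges$from[edges$from == cid] <- pids[length(pids)]
      edges$to[edges$to == cid] <- pids[1]
      edges <- dplyr::bind_rows(edges,
        tibble(from = pids[-length(pids)], to = pids[-1]))
    }
  }
  contig_graph(unlist(seqs), edges, k = k)
}
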