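# Independent oracles used across the test suite.
#
# sw_local(): a plain-R affine-gap local aligner (Gotoh), written directly
# from the recurrences and independent of the package's C++ graph DP.  Its
# conventions mirror the package's: first gap base costs gap_open, each
# further gap base gap_ext; N is a mismatch against everything; the S
# matrix is floored at 0; I looks only left, D only up; tie preference for
# the diagonal source is S > D > I; the global maximum is the first one
# encountered scanning j (query) ascending then i (target/graph) ascending.

sw_local <- function(a, b, scheme = scoring_scheme(), traceback = FALSE) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  go <- scheme$gap_open; ge <- scheme$gap_ext
  S <- matrix(0L, n + 1, m + 1)
  I <- matrix(0L, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)
  SM <- matrix(0L, n + 1, m + 1) # 1 from S, 2 from D, 3 from I, 0 floor
  IM <- matrix(0L, n + 1, m + 1) # 1 open, 2 extend
  DM <- matrix(0L, n + 1, m + 1)
  best <- 0L; bi <- 0L; bj <- 0L
  for (j in 2:(m + 1)) {
    for (i in 2:(n + 1)) {
      gg <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") scheme$match else
        scheme$mismatch
      io <- S[i, j - 1] + go; ie <- I[i, j - 1] + ge
      if (io >= ie) { I[i, j] <- io; IM[i, j] <- 1L }
      else          { I[i, j] <- ie; IM[i, j] <- 2L }
      do_ <- S[i - 1, j] + go; de <- D[i - 1, j] + ge
      if (do_ >= de) { D[i, j] <- do_; DM[i, j] <- 1L }
      else           { D[i, j] <- de;  DM[i, j] <- 2L }
      v <- 0L; mv <- 0L
      if (S[i - 1, j - 1] + gg > v) { v <- S[i - 1, j - 1] + gg; mv <- 1L }
      if (D[i - 1, j - 1] + gg > v) { v <- D[i - 1, j - 1] + gg; mv <- 2L }
      if (I[i - 1, j - 1] + gg > v) { v <- I[i - 1, j - 1] + gg; mv <- 3L }
      S[i, j] <- v; SM[i, j] <- mv
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  if (!traceback || best < 1L) {
    return(list(score = best))
  }
  ops <- character(0)
  i <- bi; j <- bj; mat <- 1L # 1 S, 2 D, 3 I
  a_start <- bi - 1L; b_start <- bj - 1L
  repeat {
    if (mat == 1L) {
      if (S[i, j] <= 0L) break
      ops <- c(ops, if (A[i - 1] == B[j - 1] && A[i - 1] != "N") "=" else "X")
      a_start <- i - 1L; b_start <- j - 1L
      mat <- SM[i, j]
      i <- i - 1L; j <- j - 1L
      if (mat == 0L) break
      mat <- c(1L, 2L, 3L)[mat]
    } else if (mat == 2L) {
      ops <- c(ops, "D")
      a_start <- i - 1L
      mat <- if (DM[i, j] == 1L) 1L else 2L
      i <- i - 1L
    } else {
      ops <- c(ops, "I")
      b_start <- j - 1L
      mat <- if (IM[i, j] == 1L) 1L else 3L
      j <- j - 1L
    }
  }
  ops <- rev(ops)
  list(score = best, ops = paste(ops, collapse = ""),
       a_start = a_start, a_end = bi - 1L,
       b_start = b_start, b_end = bj - 1L,
       n_match = sum(ops == "="),
       identity = sum(ops == "=") / length(ops))
}

# Biostrings-based local score, a second independent check (score only)
bios_local_score <- function(a, b, scheme = scoring_scheme()) {
  bs <- c("A", "C", "G", "T", "N")
  mat <- matrix(scheme$mismatch, 5, 5, dimnames = list(bs, bs))
  diag(mat) <- scheme$match
  mat["N", "N"] <- scheme$mismatch
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "local", substitutionMatrix = mat,
    gapOpening = abs(scheme$gap_open) - abs(scheme$gap_ext),
    gapExtension = abs(scheme$gap_ext))
  max(0, Biostrings::score(pa))
}

# enumerate all simple paths (as id vectors) of a contig_graph
enumerate_simple_paths <- function(graph, max_len = Inf) {
  ids <- contig_ids(graph)
  adj <- split(graph$edges$to, graph$edges$from)
  paths <- list()
  walk <- function(path) {
    paths[[length(paths) + 1L]] <<- path
    if (length(path) >= max_len) return()
    for (nxt in adj[[path[length(path)]]]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  for (v in ids) walk(v)
  paths
}

# best over all simple paths of local SW on the spelled sequence; the
# brute-force reference for the graph aligner (score level)
brute_force_graph_score <- function(graph, ref, scheme = scoring_scheme()) {
  paths <- enumerate_simple_paths(graph)
  best <- 0L
  for (p in paths) {
    s <- sw_local(spell_path(graph, p), ref, scheme)$score
    if (s > best) best <- s
  }
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random DAG with valid k-1 overlaps.  Nodes are topologically ordered by
# construction (edges go low -> high).  Junction constraint: all edges
# leaving u share u's suffix; all edges entering v share v's prefix; an
# edge u->v forces suffix(u) == prefix(v).  Solved with union-find over
# 2*n junction slots, then random (k-1)-mers per class.
random_contig_dag <- function(n_nodes, k, p_edge = 0.35,
                              min_len = 2 * (k - 1) + 1, max_len = 20) {
  repeat {
    edges <- NULL
    if (n_nodes > 1) {
      pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
      take <- stats::runif(nrow(pairs)) < p_edge
      edges <- pairs[take, , drop = FALSE]
    }
    # union-find over slots: suffix slot of u = u, prefix slot of v = n + v
    parent <- seq_len(2 * n_nodes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (!is.null(edges) && nrow(edges) > 0) {
      for (r in seq_len(nrow(edges))) {
        a <- find(edges[r, 1]); b <- find(n_nodes + edges[r, 2])
        if (a != b) parent[b] <- a
      }
    }
    classes <- vapply(seq_len(2 * n_nodes), find, integer(1))
    lab <- vapply(unique(classes), function(cl) random_seq(k - 1), "")
    names(lab) <- as.character(unique(classes))
    ids <- sprintf("n%02d", seq_len(n_nodes))
    seqs <- vapply(seq_len(n_nodes), function(v) {
      len <- sample(min_len:max_len, 1)
      mid <- random_seq(len - 2 * (k - 1))
      paste0(lab[[as.character(classes[n_nodes + v])]], mid,
             lab[[as.character(classes[v])]])
    }, "")
    names(seqs) <- ids
    ed <- if (is.null(edges) || nrow(edges) == 0) NULL else
      data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]])
    g <- tryCatch(contig_graph(seqs, ed, k = k), error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
}
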