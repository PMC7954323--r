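# Independent oracles and in-code fixture builders shared by the suite.
# Oracles are deliberately naive (exhaustive enumeration, brute force)
# and never share code with the implementation paths they check.

# ---- alignment oracles (Gotoh affine-gap DP, small sequences only) ------

.blosum62_test <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                  envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# optimal global affine-gap alignment score; gap of length L costs
# open + L * extend (matching the pairwiseAlignment convention)
oracle_global_score <- function(a, b, open = 10, extend = 0.5,
                                mat = .blosum62_test()) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - i * extend
  for (j in seq_len(m)) Y[1, j + 1] <- -open - j * extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[a[i], b[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                           X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                           Y[i + 1, j] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# optimal local affine-gap alignment score (Smith-Waterman)
oracle_local_score <- function(a, b, open = 11, extend = 1,
                               mat = .blosum62_test()) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- X
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[a[i], b[j]]
    M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                           X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                           Y[i + 1, j] - extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# ---- graph/statistics oracles ------------------------------------------

# betweenness centrality by explicit shortest-path counting (BFS per pair)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s, counting shortest paths
    dist <- rep(Inf, n); sigma <- numeric(n); preds <- vector("list", n)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s; order <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; order <- c(order, v)
      for (w in which(adj[v, ])) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1; queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2   # undirected
}

# connected components of a thresholded distance matrix by repeated
# neighbourhood expansion
oracle_components <- function(dmat, cutoff) {
  n <- nrow(dmat)
  comp <- rep(NA_integer_, n); cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    frontier <- s; comp[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(dmat[v, ] <= cutoff & is.na(comp))
        comp[nb] <- cur
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs); p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b); n <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(x), n)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs); p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- in-code fixtures ---------------------------------------------------

# build a structure_model directly from residue coordinates:
# coords is a list of per-residue atom matrices (k x 3)
make_structure <- function(coords, aa = NULL, chain = "A") {
  n <- length(coords)
  if (is.null(aa)) aa <- rep("A", n)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- coords[[i]]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    data.frame(residx = i, name = paste0("C", seq_len(nrow(xyz))),
               element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, stringsAsFactors = FALSE)
  }))
  residues <- data.frame(residx = seq_len(n), resno = seq_len(n),
                         icode = "", aa = aa, stringsAsFactors = FALSE)
  structure(list(chain = chain, residues = residues, atoms = atoms,
                 sequence = paste(aa, collapse = "")),
            class = "structure_model")
}

# write a tiny GTF + FASTA gene fixture and read it back; `exons` is a
# named list of c(start, end) (0-based half-open), `transcripts` a named
# list of exon-id vectors, `cds` an optional named list overriding the
# CDS extent per (transcript, exon) as list(tid = list(eid = c(s, e)))
make_toy_gene <- function(exons, transcripts, seq_len_nt = NULL,
                          strand = "+", cds = NULL, genome_seq = NULL) {
  dir <- tempfile("toygene"); dir.create(dir)
  total <- max(vapply(exons, `[`, numeric(1), 2)) + 10
  if (is.null(genome_seq))
    genome_seq <- paste(sample(c("A", "C", "G", "T"), total,
                               replace = TRUE), collapse = "")
  fa <- file.path(dir, "g.fa")
  ss <- Biostrings::DNAStringSet(genome_seq); names(ss) <- "chrT"
  Biostrings::writeXStringSet(ss, fa)
  lines <- character()
  for (tid in names(transcripts)) {
    for (eid in transcripts[[tid]]) {
      co <- exons[[eid]]
      attrs <- sprintf('gene_id "gX"; transcript_id "%s";', tid)
      lines <- c(lines, sprintf("chrT\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                                co[1] + 1, co[2], strand, attrs))
      cc <- if (!is.null(cds[[tid]]) && !is.null(cds[[tid]][[eid]]))
        cds[[tid]][[eid]] else co
      if (!any(is.na(cc)))
        lines <- c(lines, sprintf("chrT\ttest\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  cc[1] + 1, cc[2], strand, attrs))
    }
  }
  gtf <- file.path(dir, "g.gtf")
  writeLines(lines, gtf)
  genes <- suppressWarnings(read_annotation(gtf, fa))
  list(gene = genes[["gX"]], genome = attr(genes, "genome"),
       gtf = gtf, fasta = fa)
}
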