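# MXE detection, the exon graph, filters, cassette exons, microexons and
# combinatorial isoform counting.

test_that("co-occurrence graph has overlap and co-occurrence edges", {
  fx <- make_toy_gene(
    exons = list(E1 = c(0, 9), E2 = c(20, 29), E3 = c(40, 49),
                 E2p = c(28, 37), E4 = c(60, 69)),
    transcripts = list(t1 = c("E1", "E2", "E4"),
                       t2 = c("E1", "E3", "E4"),
                       t3 = c("E2p", "E4")))
  g <- build_cooccurrence_graph(fx$gene)
  ids <- fx$gene$transcripts
  id_of <- function(tid, k) ids[[tid]]$exons$exon_id[k]
  e1 <- id_of("t1", 1); e2 <- id_of("t1", 2); e4 <- id_of("t1", 3)
  e3 <- id_of("t2", 2); e2p <- id_of("t3", 1)
  has_edge <- function(a, b)
    igraph::are_adjacent(g, a, b)
  expect_false(has_edge(e2, e3))          # no transcript, no overlap
  expect_true(has_edge(e2, e2p))          # 1-nt genomic overlap
  expect_true(has_edge(e1, e2))           # co-occur in t1
  # adjacency equals the brute-force pairwise check
  ex <- fx$gene$exons[fx$gene$exons$coding, ]
  for (i in seq_len(nrow(ex) - 1)) for (j in (i + 1):nrow(ex)) {
    overlap <- ex$start[i] < ex$end[j] && ex$start[j] < ex$end[i]
    cooccur <- any(vapply(fx$gene$transcripts, function(t)
      all(ex$exon_id[c(i, j)] %in% t$exons$exon_id), logical(1)))
    expect_equal(has_edge(ex$exon_id[i], ex$exon_id[j]),
                 overlap || cooccur)
  }
})

test_that("planted fixtures give candidates; co-occurrence removes them", {
  base <- list(E1 = c(0, 9), E2 = c(20, 29), E3 = c(40, 49),
               E4 = c(60, 69))
  fx <- make_toy_gene(base, list(t1 = c("E1", "E2", "E4"),
                                 t2 = c("E1", "E3", "E4")))
  cand <- suppressWarnings(
    detect_mxe_pairs(fx$gene, fx$genome, apply_homology = FALSE))
  pass <- cand[cand$pass, ]
  expect_equal(nrow(pass), 1)
  e2 <- fx$gene$transcripts$t1$exons$exon_id[2]
  e3 <- fx$gene$transcripts$t2$exons$exon_id[2]
  expect_setequal(c(pass$exon_a, pass$exon_b), c(e2, e3))

  # adding a transcript containing both kills the candidate
  fx2 <- make_toy_gene(base, list(t1 = c("E1", "E2", "E4"),
                                  t2 = c("E1", "E3", "E4"),
                                  t3 = c("E1", "E2", "E3", "E4")))
  cand2 <- suppressWarnings(
    detect_mxe_pairs(fx2$gene, fx2$genome, apply_homology = FALSE))
  expect_equal(sum(cand2$pass), 0)
  row <- cand2[cand2$exon_a == e2 & cand2$exon_b == e3, ]
  expect_false(row$pass_cooccur)
})

test_that("transitive linkage through an overlapping exon excludes a pair", {
  # E2pp overlaps E3 and co-occurs with E2 -> (E2,E3) linked
  exons <- list(E1 = c(0, 9), E2 = c(20, 29), E3 = c(40, 49),
                E2pp = c(45, 55), E4 = c(70, 79))
  fx <- make_toy_gene(exons, list(t1 = c("E1", "E2", "E4"),
                                  t2 = c("E1", "E3", "E4"),
                                  t3 = c("E1", "E2", "E2pp", "E4")))
  cand <- suppressWarnings(
    detect_mxe_pairs(fx$gene, fx$genome, apply_homology = FALSE))
  e2 <- fx$gene$transcripts$t1$exons$exon_id[2]
  e3 <- fx$gene$transcripts$t2$exons$exon_id[2]
  row <- cand[cand$exon_a == e2 & cand$exon_b == e3, ]
  expect_true(row$pass_cooccur)     # never directly together
  expect_false(row$pass_graph)      # linked via overlap group + co-occurrence

  # brute-force closure oracle: group exons by overlap chains, then look
  # for any cross-group co-occurrence other than the pair itself
  ex <- fx$gene$exons[fx$gene$exons$coding, ]
  ov <- outer(seq_len(nrow(ex)), seq_len(nrow(ex)), Vectorize(function(i, j)
    i != j && ex$start[i] < ex$end[j] && ex$start[j] < ex$end[i]))
  grp <- oracle_components(ifelse(ov, 0, 10), 0.5)
  ga <- ex$exon_id[grp == grp[match(e2, ex$exon_id)]]
  gb <- ex$exon_id[grp == grp[match(e3, ex$exon_id)]]
  linked <- FALSE
  for (x in ga) for (y in gb) {
    if (setequal(c(x, y), c(e2, e3))) next
    if (any(vapply(fx$gene$transcripts, function(t)
      all(c(x, y) %in% t$exons$exon_id), logical(1)))) linked <- TRUE
  }
  expect_true(linked)
})

test_that("length-ratio filter implements |log10 ratio| <= 0.25", {
  expect_true(length_ratio_filter(108, 108))
  expect_false(length_ratio_filter(100, 200))   # log10(2) = 0.301
  expect_true(length_ratio_filter(90, 150))     # log10(5/3) = 0.222
  expect_true(length_ratio_filter(150, 90))     # symmetric
  expect_error(length_ratio_filter(0, 10), "positive")
})

test_that("homology filter enforces length, identity and E-value", {
  pep <- paste(rep("ACDEFGHIK", 4), collapse = "")
  r <- homology_filter(pep, pep)
  expect_true(r$pass)
  expect_equal(r$identity_pct, 100)

  # a 7-residue member fails regardless of identity
  r7 <- homology_filter("ACDEFGH", "ACDEFGH")
  expect_false(r7$pass)
  expect_equal(r7$reason, "min_len")
  # 8 residues passes the length precondition
  r8 <- homology_filter("ACDEFGHI", "ACDEFGHI")
  expect_true(r8$pass)

  expect_error(homology_filter("ACDB1", pep), "non-amino-acid")
})

test_that("homology verdicts match an independent local-alignment oracle", {
  set.seed(42)
  for (k in 1:12) {
    a <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 36,
                      replace = TRUE), collapse = "")
    b <- if (k %% 3 == 0) a else
      paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 36,
                   replace = TRUE), collapse = "")
    got <- homology_filter(a, b)
    s_oracle <- oracle_local_score(a, b)
    expect_equal(got$score, s_oracle, tolerance = 1e-9)
    e_oracle <- 0.041 * 36 * 36 * exp(-0.267 * s_oracle)
    expect_equal(got$evalue, e_oracle, tolerance = 1e-9)
    expect_equal(got$pass, got$identity_pct >= 25 && e_oracle <= 0.005)
  }
})

test_that("isoform counting multiplies cluster sizes", {
  expect_equal(enumerate_isoforms(list(letters[1:12], LETTERS[1:24],
                                       paste0("x", 1:48)[1:48],
                                       paste0("y", 1:33), c("z1", "z2"))[
                                         c(1, 3, 4, 5)]), 38016)
  expect_equal(enumerate_isoforms(list()), 1)
  expect_equal(enumerate_isoforms(NULL), 1)
  expect_equal(enumerate_isoforms(list(c("a", "b"), c("c", "d", "e"))), 6)
  expect_error(enumerate_isoforms(list(c("a", "b"), c("b", "c"))),
               "overlapping")
  # equals exhaustive enumeration for small products
  cl <- list(c("a1", "a2", "a3"), c("b1", "b2"), c("c1", "c2", "c3", "c4"))
  exhaustive <- nrow(expand.grid(lapply(cl, seq_along)))
  expect_equal(enumerate_isoforms(cl), exhaustive)
})

test_that("cassette events are single coding non-terminal exon losses", {
  base <- list(E1 = c(0, 11), E2 = c(20, 31), E3 = c(40, 51),
               E4 = c(60, 71))
  fx <- make_toy_gene(base, list(t1 = c("E1", "E2", "E3", "E4"),
                                 t2 = c("E1", "E2", "E4")))
  ev <- detect_cassette_events(fx$gene)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$lost_exon, fx$gene$transcripts$t1$exons$exon_id[3])

  # terminal-exon difference is not a cassette event
  fx2 <- make_toy_gene(base[1:4], list(t1 = c("E1", "E2", "E3", "E4"),
                                       t2 = c("E1", "E2", "E3")))
  expect_equal(nrow(detect_cassette_events(fx2$gene)), 0)

  # two-exon difference is not, matching a set-difference oracle
  fx3 <- make_toy_gene(base, list(t1 = c("E1", "E2", "E3", "E4"),
                                  t2 = c("E1", "E4")))
  expect_equal(nrow(detect_cassette_events(fx3$gene)), 0)
  diffs <- setdiff(fx3$gene$transcripts$t1$exons$exon_id,
                   fx3$gene$transcripts$t2$exons$exon_id)
  expect_gt(length(diffs), 1)
})

test_that("microexon boundary sits at 27 nt", {
  expect_true(classify_microexon(27)$is_microexon)
  expect_false(classify_microexon(28)$is_microexon)
  expect_true(classify_microexon(3)$is_microexon)
  expect_error(classify_microexon(0), "invalid")
})

test_that("detection is deterministic and no emitted pair co-occurs", {
  gen <- generate_genome_annotation(list(preset = "benchmark"), seed = 17)
  genes <- suppressWarnings(read_annotation(gen$gtf, gen$fasta))
  genome <- attr(genes, "genome")
  for (g in genes) {
    r1 <- suppressWarnings(detect_mxe_pairs(g, genome))
    r2 <- suppressWarnings(detect_mxe_pairs(g, genome))
    expect_identical(r1, r2)
    if (nrow(r1) == 0) next
    for (k in which(r1$pass)) {
      # exhaustive scan: the two exons never share a transcript
      expect_false(any(vapply(g$transcripts, function(t)
        all(c(r1$exon_a[k], r1$exon_b[k]) %in% t$exons$exon_id),
        logical(1))))
    }
  }
})

test_that("planted pairs are recovered and violations rejected by their filter", {
  gen <- generate_genome_annotation(list(preset = "controls"), seed = 13)
  genes <- suppressWarnings(read_annotation(gen$gtf, gen$fasta))
  genome <- attr(genes, "genome")
  pp <- gen$manifest$planted_pairs
  for (k in seq_len(nrow(pp))) {
    g <- genes[[pp$gene_id[k]]]
    ev <- suppressWarnings(detect_mxe_pairs(g, genome))
    row <- ev[ev$exon_a == pp$exon_a[k] & ev$exon_b == pp$exon_b[k], ]
    expect_equal(nrow(row), 1, info = pp$gene_id[k])
    if (pp$detectable[k]) {
      expect_true(row$pass, info = pp$gene_id[k])
    } else {
      expect_false(row$pass, info = pp$gene_id[k])
      failed <- c(cooccurrence = !row$pass_cooccur,
                  graph = !row$pass_graph,
                  frame = !row$pass_frame,
                  length = !row$pass_length,
                  min_len = identical(row$homology_reason, "min_len"),
                  homology = !row$pass_homology &&
                    !identical(row$homology_reason, "min_len"))
      # rejected by exactly the intended filter and no other
      expect_equal(names(which(failed)), pp$violation[k],
                   info = pp$gene_id[k])
    }
  }
})
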