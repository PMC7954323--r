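# Detection of homologous mutually exclusive exon (MXE) pairs, cassette
# exon events and microexons from gene models, plus combinatorial isoform
# counting for genes with MXE clusters (DSCAM-style).

# peptide length of a transcript (0 for non-coding); used for "longest"
.pep_len <- function(t) if (t$coding) sum(t$cds$end - t$cds$start) %/% 3L else 0L

# longest transcript containing an exon; ties broken lexicographically
.host_transcript <- function(gene, exon_id) {
  holders <- Filter(function(t) exon_id %in% t$cds$exon_id, gene$transcripts)
  if (length(holders) == 0) return(NULL)
  lens <- vapply(holders, .pep_len, integer(1))
  ids <- vapply(holders, `[[`, character(1), "id")
  ord <- order(-lens, ids)
  holders[[ord[1]]]
}

#' Exon co-occurrence/overlap graph of a gene
#'
#' Nodes are the gene's coding exons; an undirected edge joins two exons if
#' they genomically overlap or co-occur in any transcript. Exon pairs that
#' are connected (directly or transitively) in this graph cannot be
#' mutually exclusive.
#'
#' @param gene a `gene_model`
#' @return an `igraph` undirected graph over coding exon ids
#' @export
build_cooccurrence_graph <- function(gene) {
  ex <- gene$exons[gene$exons$coding, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(ex), name = ex$exon_id)
  if (nrow(ex) < 2) return(g)
  edges <- character(0); kind <- character(0)
  for (i in seq_len(nrow(ex) - 1)) {
    for (j in seq.int(i + 1, nrow(ex))) {
      overlap <- ex$start[i] < ex$end[j] && ex$start[j] < ex$end[i]
      cooccur <- any(vapply(gene$transcripts, function(t)
        all(c(ex$exon_id[i], ex$exon_id[j]) %in% t$exons$exon_id),
        logical(1)))
      if (overlap || cooccur) {
        edges <- c(edges, ex$exon_id[i], ex$exon_id[j])
        kind <- c(kind, if (overlap && cooccur) "both"
                  else if (overlap) "overlap" else "cooccur")
      }
    }
  }
  if (length(edges))
    g <- igraph::add_edges(g, edges, attr = list(kind = kind))
  g
}

# overlap-chain group membership for each coding exon: exons joined by
# chains of genomic-overlap edges are forms of "the same exon"
.overlap_groups <- function(graph) {
  keep <- igraph::E(graph)[igraph::E(graph)$kind %in% c("overlap", "both")]
  og <- igraph::subgraph_from_edges(graph, keep, delete.vertices = FALSE)
  igraph::components(og)$membership
}

#' Length-ratio filter for candidate MXE exon pairs
#'
#' MXE partners are required to be similar in length: the pair passes iff
#' |log10(len_a/len_b)| <= `max_abs_log_ratio`.
#'
#' @param len_a,len_b exon CDS lengths in nucleotides (> 0)
#' @param max_abs_log_ratio threshold on the absolute log10 ratio
#'   (default 0.25)
#' @return TRUE if the pair passes
#' @export
length_ratio_filter <- function(len_a, len_b, max_abs_log_ratio = 0.25) {
  if (any(c(len_a, len_b) <= 0)) stop("exon lengths must be positive")
  abs(log10(len_a / len_b)) <= max_abs_log_ratio
}

#' Detect candidate MXE pairs in a gene
#'
#' A pair of coding exons (A,B) is a candidate iff they are adjacent in the
#' sorted order of the gene's distinct coding exon intervals, no transcript
#' contains both (`pass_cooccur`), they cannot be linked through the exon
#' graph (`pass_graph`: exons joined by genomic-overlap chains form groups,
#' and the pair is rejected when its two groups are joined by any
#' transcript co-occurrence other than the pair's own direct one), they
#' start in the same reading frame (equal phase), the length-ratio filter
#' passes, and each is contained in at least one coding transcript. The
#' host transcript of each exon is the longest transcript containing it
#' (ties broken lexicographically by id). Terminal exons are allowed;
#' flanking-exon equivalence is recorded but not enforced. The
#' translated-homology filter is applied on the exon peptides.
#'
#' @param gene a `gene_model`
#' @param genome `DNAStringSet` genome store
#' @param apply_homology run the homology filter (default TRUE)
#' @param max_abs_log_ratio,evalue_max,identity_min_pct,min_len thresholds
#' @return data.frame with one row per adjacent never-co-occurring coding
#'   exon pair, per-filter pass columns, peptides, identity/E-value and an
#'   overall `pass`; zero rows when the gene has no candidates
#' @export
detect_mxe_pairs <- function(gene, genome, apply_homology = TRUE,
                             max_abs_log_ratio = 0.25, evalue_max = 0.005,
                             identity_min_pct = 25, min_len = 8) {
  empty <- data.frame(gene_id = character(), exon_a = character(),
                      exon_b = character(), stringsAsFactors = FALSE)
  ex <- gene$exons[gene$exons$coding, , drop = FALSE]
  if (nrow(ex) < 2 || !any(vapply(gene$transcripts, `[[`, logical(1),
                                  "coding")))
    return(empty)
  graph <- build_cooccurrence_graph(gene)
  groups <- .overlap_groups(graph)
  cooccurs <- function(x, y) any(vapply(gene$transcripts, function(t)
    all(c(x, y) %in% t$exons$exon_id), logical(1)))
  ex <- ex[order(ex$start, ex$end), ]
  out <- list()
  for (i in seq_len(nrow(ex) - 1)) {
    a <- ex$exon_id[i]; b <- ex$exon_id[i + 1]
    pass_cooccur <- !cooccurs(a, b)
    ta <- .host_transcript(gene, a); tb <- .host_transcript(gene, b)
    if (is.null(ta) || is.null(tb)) next
    # linked through the graph: same overlap group, or a co-occurrence
    # bridging the two groups other than the pair's own
    ga <- names(groups)[groups == groups[[a]]]
    gb <- names(groups)[groups == groups[[b]]]
    linked <- groups[[a]] == groups[[b]]
    if (!linked) {
      for (x in ga) {
        for (y in gb) {
          if ((x == a && y == b) || (x == b && y == a)) next
          if (cooccurs(x, y)) { linked <- TRUE; break }
        }
        if (linked) break
      }
    }
    pass_graph <- !linked
    sa <- exon_peptide_segment(a, ta, gene, genome)
    sb <- exon_peptide_segment(b, tb, gene, genome)
    pass_frame <- sa$phase == sb$phase
    len_a <- sa$length_nt; len_b <- sb$length_nt
    pass_length <- length_ratio_filter(len_a, len_b, max_abs_log_ratio)
    hom <- if (apply_homology)
      homology_filter(sa$segment, sb$segment, evalue_max,
                      identity_min_pct, min_len)
    else list(pass = NA, identity_pct = NA_real_, evalue = NA_real_,
              reason = NA_character_)
    # flanking exons (by id) around each exon in its host chain
    flank <- function(t, e) {
      k <- match(e, t$exons$exon_id)
      c(if (k > 1) t$exons$exon_id[k - 1] else NA,
        if (k < nrow(t$exons)) t$exons$exon_id[k + 1] else NA)
    }
    flanking_equivalent <- identical(flank(ta, a), flank(tb, b))
    out[[length(out) + 1]] <- data.frame(
      gene_id = gene$id, exon_a = a, exon_b = b,
      host_transcript_a = ta$id, host_transcript_b = tb$id,
      peptide_a = sa$segment, peptide_b = sb$segment,
      len_a = len_a, len_b = len_b, phase_a = sa$phase, phase_b = sb$phase,
      pass_cooccur = pass_cooccur,
      pass_graph = pass_graph, pass_frame = pass_frame,
      pass_length = pass_length,
      pass_homology = isTRUE(hom$pass),
      homology_reason = hom$reason %||% NA_character_,
      identity_pct = hom$identity_pct, evalue = hom$evalue,
      flanking_equivalent = flanking_equivalent,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res$pass <- res$pass_cooccur & res$pass_graph & res$pass_frame &
    res$pass_length & (if (apply_homology) res$pass_homology else TRUE)
  res
}

#' Count combinatorial isoforms of a gene with MXE clusters
#'
#' Given disjoint MXE clusters (each a set of mutually exclusive exons of
#' which exactly one is chosen per transcript), the number of potential
#' splicing isoforms is the product of the cluster sizes; constitutive
#' exons contribute a factor of 1.
#'
#' @param clusters a list of character vectors of exon ids, or a
#'   `gene_model` carrying a `mxe_clusters` attribute
#' @return the isoform count (numeric)
#' @export
enumerate_isoforms <- function(clusters) {
  if (inherits(clusters, "gene_model"))
    clusters <- attr(clusters, "mxe_clusters")
  if (is.null(clusters) || length(clusters) == 0) return(1)
  ids <- unlist(clusters)
  if (anyDuplicated(ids)) stop("overlapping MXE clusters")
  prod(vapply(clusters, length, integer(1)))
}

#' Detect the minimal single-exon-loss cassette event of a gene
#'
#' Takes the longest protein isoform and searches the remaining coding
#' transcripts in decreasing peptide length for one whose exon chain equals
#' the long chain minus exactly one coding, non-terminal exon. At most one
#' event is reported per gene.
#'
#' @param gene a `gene_model`
#' @return data.frame with 0 or 1 rows (gene_id, long/short transcript ids,
#'   lost exon id)
#' @export
detect_cassette_events <- function(gene) {
  empty <- data.frame(gene_id = character(), long_transcript = character(),
                      short_transcript = character(),
                      lost_exon = character(), stringsAsFactors = FALSE)
  coding <- Filter(function(t) t$coding, gene$transcripts)
  if (length(coding) < 2) return(empty)
  lens <- vapply(coding, .pep_len, integer(1))
  ids <- vapply(coding, `[[`, character(1), "id")
  ord <- order(-lens, ids)
  long <- coding[[ord[1]]]
  chain <- long$exons$exon_id
  for (k in ord[-1]) {
    short <- coding[[k]]
    diffs <- setdiff(chain, short$exons$exon_id)
    if (length(diffs) != 1) next
    if (!identical(short$exons$exon_id, setdiff(chain, diffs))) next
    pos <- match(diffs, chain)
    if (pos == 1 || pos == length(chain)) next       # terminal exon
    if (!diffs %in% long$cds$exon_id) next           # must be coding
    return(data.frame(gene_id = gene$id, long_transcript = long$id,
                      short_transcript = short$id, lost_exon = diffs,
                      stringsAsFactors = FALSE))
  }
  empty
}

#' Classify an exon as a microexon
#'
#' Microexons are defined as exons of at most 27 nucleotides.
#'
#' @param length_nt exon length in nucleotides, or an exon row/`gene_model`
#'   exon id
#' @param max_nt microexon length threshold (default 27)
#' @return list(length_nt, is_microexon)
#' @export
classify_microexon <- function(length_nt, max_nt = 27) {
  if (!is.numeric(length_nt) || length_nt <= 0) stop("invalid exon length")
  list(length_nt = as.integer(length_nt),
       is_microexon = length_nt <= max_nt)
}
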