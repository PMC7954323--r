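# Gene / transcript / exon models built from GTF or GFF3 annotation plus a
# genome FASTA. Internal coordinates are 0-based half-open; all file I/O
# converts at the boundary (GTF/GFF3 are 1-based inclusive). Minus-strand
# exon chains are stored in transcription (5'->3') order.

#' Read gene models from annotation and sequence
#'
#' Parses a GTF or GFF3 annotation together with a genome FASTA into a set
#' of in-memory gene models. Coordinates are converted to 0-based half-open
#' internally; minus-strand exon chains are ordered 5'->3' of the
#' transcript. Transcripts without CDS records are flagged non-coding, and
#' transcripts carrying a nonsense-mediated-decay biotype are dropped (with
#' a warning) because NMD transcripts are excluded from event detection.
#'
#' @param annotation_file path to a GTF (or GFF3) file with exon and CDS
#'   features carrying `gene_id`/`transcript_id` attributes
#' @param sequence_file path to the genome FASTA; sequence names must match
#'   the annotation seqids
#' @return a named list of `gene_model` objects; the genome is attached as
#'   attribute `genome` (a `DNAStringSet`)
#' @export
read_annotation <- function(annotation_file, sequence_file) {
  genome <- Biostrings::readDNAStringSet(sequence_file)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(annotation_file)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(df) && "Parent" %in% names(df)) {
    # GFF3: recover gene/transcript from ID/Parent hierarchy
    df$transcript_id <- as.character(unlist(lapply(df$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_)))
    if (!"gene_id" %in% names(df)) df$gene_id <- df$transcript_id
  }
  df <- df[df$type %in% c("exon", "CDS"), ]
  unknown <- setdiff(unique(as.character(df$seqnames)), names(genome))
  if (length(unknown) > 0)
    stop(sprintf("unknown seqid(s) in annotation: %s",
                 paste(unknown, collapse = ",")))
  # 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  biotype <- df$transcript_biotype %||% rep(NA_character_, nrow(df))

  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, ]
    strand <- as.character(gdf$strand[1])
    chrom <- as.character(gdf$seqnames[1])
    transcripts <- list()
    for (tid in unique(gdf$transcript_id)) {
      tdf <- gdf[gdf$transcript_id == tid, ]
      bt <- biotype[df$gene_id == gid][gdf$transcript_id == tid][1]
      nmd <- !is.na(bt) && grepl("nonsense_mediated_decay", bt)
      ex <- tdf[tdf$type == "exon", c("start0", "end0")]
      ex <- ex[order(ex$start0), ]
      if (nrow(ex) > 1 && any(ex$start0[-1] < ex$end0[-nrow(ex)])) {
        warning(sprintf("transcript %s rejected: overlapping exons", tid))
        next
      }
      if (nmd) {
        warning(sprintf("transcript %s dropped: NMD biotype", tid))
        next
      }
      cds <- tdf[tdf$type == "CDS", c("start0", "end0")]
      cds <- cds[order(cds$start0), ]
      # transcription order
      if (strand == "-") {
        ex <- ex[rev(seq_len(nrow(ex))), ]
        cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
      }
      exon_ids <- sprintf("%s:%d-%d", chrom, ex$start0, ex$end0)
      cds_map <- rep(NA_integer_, nrow(cds))
      if (nrow(cds) > 0) {
        for (k in seq_len(nrow(cds))) {
          hit <- which(ex$start0 <= cds$start0[k] & ex$end0 >= cds$end0[k])
          if (length(hit) == 0)
            stop(sprintf("CDS segment outside exons in transcript %s", tid))
          cds_map[k] <- hit[1]
        }
      }
      transcripts[[tid]] <- structure(list(
        id = tid, gene_id = gid,
        exons = data.frame(exon_id = exon_ids, start = ex$start0,
                           end = ex$end0, stringsAsFactors = FALSE),
        cds = if (nrow(cds) > 0)
          data.frame(exon_id = exon_ids[cds_map], start = cds$start0,
                     end = cds$end0, stringsAsFactors = FALSE)
          else data.frame(exon_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE),
        coding = nrow(cds) > 0, nmd_flag = nmd), class = "transcript")
    }
    if (length(transcripts) == 0) next
    exon_universe <- unique(do.call(rbind, lapply(transcripts, `[[`, "exons")))
    exon_universe <- exon_universe[order(exon_universe$start,
                                         exon_universe$end), ]
    rownames(exon_universe) <- NULL
    coding_ids <- unique(unlist(lapply(transcripts, function(t)
      t$cds$exon_id)))
    exon_universe$coding <- exon_universe$exon_id %in% coding_ids
    genes[[gid]] <- structure(list(id = gid, chrom = chrom, strand = strand,
                                   exons = exon_universe,
                                   transcripts = transcripts),
                              class = "gene_model")
  }
  attr(genes, "genome") <- genome
  genes
}

#' Write gene models back to GTF
#'
#' Round-trip writer: emits exon and CDS features (1-based inclusive) for
#' every transcript of every gene, so that re-reading reproduces identical
#' internal coordinates and exon chains.
#'
#' @param genes list of `gene_model` objects
#' @param path output GTF path
#' @return `path`, invisibly
#' @export
write_annotation <- function(genes, path) {
  lines <- character()
  for (g in genes) {
    for (t in g$transcripts) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$id, t$id)
      ex <- t$exons[order(t$exons$start), , drop = FALSE]
      lines <- c(lines, sprintf("%s\tmxestruct\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, ex$start + 1L, ex$end, g$strand,
                                attrs))
      if (t$coding) {
        cds <- t$cds[order(t$cds$start), , drop = FALSE]
        lines <- c(lines, sprintf("%s\tmxestruct\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  g$chrom, cds$start + 1L, cds$end, g$strand,
                                  attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# per-transcript CDS segments in transcription order with cumulative
# nucleotide offsets into the spliced CDS
.cds_segments <- function(transcript) {
  cds <- transcript$cds
  if (nrow(cds) == 0) stop("transcript is non-coding")
  len <- cds$end - cds$start
  cds$nt_start <- cumsum(c(0L, len[-length(len)]))
  cds$nt_end <- cds$nt_start + len
  cds
}

#' Translate the coding region of a transcript
#'
#' Concatenates the CDS segments in transcription order (minus-strand
#' segments are reverse-complemented) and translates with the standard
#' genetic code. A trailing stop codon is removed; an internal stop
#' truncates the peptide and sets attribute `truncated`; a CDS length not
#' divisible by 3 translates `floor(n/3)` codons and sets attribute
#' `partial_codon`. Ambiguity codons translate to `X`.
#'
#' @param transcript a `transcript` object
#' @param gene the owning `gene_model` (for chrom/strand)
#' @param genome a `DNAStringSet` genome store
#' @return the peptide as a character scalar with optional flags
#' @export
extract_cds_peptide <- function(transcript, gene, genome) {
  cds <- .cds_segments(transcript)
  chrom <- genome[[gene$chrom]]
  segs <- lapply(seq_len(nrow(cds)), function(k) {
    s <- Biostrings::subseq(chrom, cds$start[k] + 1L, cds$end[k])
    if (gene$strand == "-") Biostrings::reverseComplement(s) else s
  })
  dna <- do.call(Biostrings::xscat, segs)
  n <- length(dna)
  if (n < 3L) stop("CDS shorter than one codon")
  partial <- (n %% 3L) != 0L
  if (partial) dna <- Biostrings::subseq(dna, 1L, 3L * (n %/% 3L))
  pep <- as.character(suppressWarnings(
    Biostrings::translate(dna, if.fuzzy.codon = "X")))
  truncated <- FALSE
  if (grepl("\\*", sub("\\*$", "", pep))) {
    warning(sprintf("internal stop codon in transcript %s; truncating",
                    transcript$id))
    truncated <- TRUE
    pep <- sub("\\*.*$", "", pep)
  } else {
    pep <- sub("\\*$", "", pep)
  }
  structure(pep, truncated = truncated, partial_codon = partial)
}

#' Peptide segment encoded by one exon of a transcript
#'
#' Returns the residues whose codons are assigned to the exon, the residue
#' interval they occupy in the transcript peptide, and the exon's phase
#' (codon offset at the exon's CDS start). A residue split across a
#' junction belongs to the exon supplying at least 2 of its 3 codon
#' nucleotides; the degenerate 1+1+1 split (microexons) assigns the residue
#' to the exon holding the middle nucleotide.
#'
#' @param exon_id exon identifier within the transcript
#' @param transcript a coding `transcript` containing the exon
#' @param gene owning `gene_model`
#' @param genome `DNAStringSet` genome store
#' @return list with `segment` (character), `span` (c(first,last) 1-based
#'   residue indices), `phase` (0/1/2) and `length_nt`
#' @export
exon_peptide_segment <- function(exon_id, transcript, gene, genome) {
  if (!exon_id %in% transcript$exons$exon_id)
    stop(sprintf("exon %s not in transcript %s", exon_id, transcript$id))
  cds <- .cds_segments(transcript)
  row <- which(cds$exon_id == exon_id)
  if (length(row) == 0)
    stop(sprintf("exon %s is non-coding in transcript %s", exon_id,
                 transcript$id))
  row <- row[1]
  s <- cds$nt_start[row]; e <- cds$nt_end[row]
  phase <- s %% 3L
  codons <- seq.int(s %/% 3L, (e - 1L) %/% 3L)   # 0-based codon indices
  contrib <- vapply(codons, function(i) {
    lo <- max(s, 3L * i); hi <- min(e, 3L * i + 3L)
    hi - lo
  }, integer(1))
  mid_in <- vapply(codons, function(i) {
    m <- 3L * i + 1L; m >= s && m < e
  }, logical(1))
  assigned <- codons[contrib >= 2L | (contrib == 1L & mid_in)]
  pep <- extract_cds_peptide(transcript, gene, genome)
  res <- assigned + 1L
  res <- res[res <= nchar(pep)]   # guard truncated/partial peptides
  seg <- if (length(res)) paste(strsplit(pep, "")[[1]][res], collapse = "")
         else ""
  list(segment = seg,
       span = if (length(res)) c(min(res), max(res)) else c(NA, NA),
       phase = as.integer(phase),
       length_nt = as.integer(e - s))
}
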