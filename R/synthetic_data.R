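# Synthetic-data generators. Every pipeline input can be generated with
# known ground truth (a manifest), so all stages are testable offline:
# genes with planted homologous MXE pairs (and per-filter negative
# controls), cassette exons, microexons, a DSCAM-like combinatorial gene,
# toy protein structures with planted functional sites at controlled
# distances, conserved-column MSAs, and planted mutation sets. Mutation is
# codon-level so the nucleotide-level filters are genuinely exercised.

.codons_by_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

.random_peptide <- function(n) paste(sample(.aa1, n, replace = TRUE),
                                     collapse = "")

.codons_for <- function(pep) {
  tab <- .codons_by_aa()
  vapply(strsplit(pep, "")[[1]], function(a)
    sample(tab[[a]], 1), character(1), USE.NAMES = FALSE)
}

# mutate ~ (1-identity) of the peptide at evenly spread positions so the
# variable residues form a contiguous-ish 3D patch; substitutions always
# change the amino acid
.mutate_peptide <- function(pep, identity) {
  ch <- strsplit(pep, "")[[1]]
  n <- length(ch)
  k <- max(1L, round((1 - identity) * n))
  pos <- unique(round(seq(1, n, length.out = k)))
  for (p in pos) ch[p] <- sample(setdiff(.aa1, ch[p]), 1)
  list(peptide = paste(ch, collapse = ""), positions = pos)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Build one synthetic gene region in local coordinates.
# type: mxe, mxe_cooccur, mxe_frame, mxe_length, mxe_short, mxe_homology,
#       mxe_nmd, cassette, micro, plain, dscam_like
.build_gene <- function(gid, type, identity = 0.67, mxe_len_aa = 36,
                        cluster_sizes = c(12, 48, 33, 2)) {
  intron <- 50L
  feat <- function(tid, ftype, s, e, biotype = NA_character_)
    data.frame(transcript_id = tid, type = ftype, start = s, end = e,
               biotype = biotype, stringsAsFactors = FALSE)
  if (type == "dscam_like") {
    exon_nt <- 36L
    segs <- character(); features <- list(); pos <- 0L
    add_exon <- function(len) {
      s <- pos; segs[[length(segs) + 1]] <<- .rand_dna(len)
      pos <<- pos + len
      segs[[length(segs) + 1]] <<- .rand_dna(intron); pos <<- pos + intron
      c(s, s + len)
    }
    first <- add_exon(48L)
    clusters <- list()
    for (ci in seq_along(cluster_sizes)) {
      cl <- t(vapply(seq_len(cluster_sizes[ci]), function(i) add_exon(exon_nt),
                     numeric(2)))
      clusters[[ci]] <- cl
    }
    last <- add_exon(48L)
    # a few sample transcripts, each choosing one exon per cluster
    n_tx <- 3L
    for (k in seq_len(n_tx)) {
      tid <- sprintf("%s.t%d", gid, k)
      pick <- lapply(clusters, function(cl)
        cl[min(k, nrow(cl)), , drop = TRUE])
      coords <- c(list(first), pick, list(last))
      for (co in coords) {
        features[[length(features) + 1]] <- feat(tid, "exon", co[1], co[2])
        features[[length(features) + 1]] <- feat(tid, "CDS", co[1], co[2])
      }
    }
    return(list(seq = paste(unlist(segs), collapse = ""),
                features = do.call(rbind, features),
                planted = list(type = type,
                               cluster_coords = clusters,
                               cluster_sizes = cluster_sizes)))
  }
  if (type == "plain") {
    pep <- .random_peptide(15)
    cod <- c("ATG", .codons_for(pep))
    e1 <- paste(cod[1:8], collapse = ""); e2 <- paste(cod[9:16], collapse = "")
    seq <- paste0(e1, .rand_dna(intron), e2)
    f <- rbind(feat("t1", "exon", 0, 24), feat("t1", "CDS", 0, 24),
               feat("t1", "exon", 24 + intron, 48 + intron),
               feat("t1", "CDS", 24 + intron, 48 + intron))
    f$transcript_id <- sprintf("%s.t1", gid)
    return(list(seq = seq, features = f, planted = list(type = type)))
  }
  if (type == "micro") {
    peps <- c(.random_peptide(15), .random_peptide(5), .random_peptide(16))
    cods <- lapply(peps, .codons_for)
    lens <- c(3L + 45L, 15L, 48L)   # ATG + 15 aa, 5 aa microexon, 16 aa
    seqs <- c(paste0("ATG", paste(cods[[1]], collapse = "")),
              paste(cods[[2]], collapse = ""),
              paste(cods[[3]], collapse = ""))
    pos <- 0L; coords <- list(); region <- character()
    for (i in 1:3) {
      coords[[i]] <- c(pos, pos + lens[i])
      region <- c(region, seqs[i], .rand_dna(intron))
      pos <- pos + lens[i] + intron
    }
    tid <- sprintf("%s.t1", gid)
    f <- do.call(rbind, lapply(coords, function(co)
      rbind(feat(tid, "exon", co[1], co[2]), feat(tid, "CDS", co[1], co[2]))))
    return(list(seq = paste(region, collapse = ""), features = f,
                planted = list(type = type, micro_coord = coords[[2]])))
  }
  if (type == "cassette") {
    lens <- c(48L, 36L, 36L, 48L)
    peps <- list(NULL, .random_peptide(12), .random_peptide(12),
                 .random_peptide(16))
    seqs <- c(paste0("ATG", paste(.codons_for(.random_peptide(15)),
                                  collapse = "")),
              vapply(peps[2:4], function(p)
                paste(.codons_for(p), collapse = ""), character(1)))
    pos <- 0L; coords <- list(); region <- character()
    for (i in 1:4) {
      coords[[i]] <- c(pos, pos + lens[i])
      region <- c(region, seqs[i], .rand_dna(intron))
      pos <- pos + lens[i] + intron
    }
    t1 <- sprintf("%s.t1", gid); t2 <- sprintf("%s.t2", gid)
    f <- rbind(
      do.call(rbind, lapply(coords, function(co)
        rbind(feat(t1, "exon", co[1], co[2]), feat(t1, "CDS", co[1], co[2])))),
      do.call(rbind, lapply(coords[c(1, 2, 4)], function(co)
        rbind(feat(t2, "exon", co[1], co[2]), feat(t2, "CDS", co[1], co[2])))))
    return(list(seq = paste(region, collapse = ""), features = f,
                planted = list(type = type, lost_coord = coords[[3]],
                               long = t1, short = t2)))
  }

  # --- MXE variants -------------------------------------------------------
  frame_shift <- type == "mxe_frame"
  len_violation <- type == "mxe_length"
  short <- type == "mxe_short"
  unrelated <- type == "mxe_homology"
  aa_len <- if (short) 7L else mxe_len_aa
  pep_a <- .random_peptide(aa_len)
  if (unrelated) {
    pep_b <- .random_peptide(aa_len); mut_pos <- integer(0)
  } else {
    mu <- .mutate_peptide(pep_a, if (len_violation || short) 0.9 else identity)
    pep_b <- mu$peptide; mut_pos <- mu$positions
  }
  e1_cds_nt <- 48L                      # ATG + 15 codons
  e1_pep <- .random_peptide(15)
  e1_seq <- paste0("ATG", paste(.codons_for(e1_pep), collapse = ""))
  e2a_seq <- paste(.codons_for(pep_a), collapse = "")
  e3_pep <- .random_peptide(16)
  e3_seq <- paste(.codons_for(e3_pep), collapse = "")
  if (frame_shift) {
    # T2's CDS on the shared first exon is one nt longer, shifting the
    # alternative exon's phase; the exon bases are chosen so the phase-1
    # translation still yields pep_b (homology intact, frame filter fails)
    spill <- sample(.codons_for(substr(pep_b, 1, 1)), 1)
    e1_seq <- paste0(e1_seq, substr(spill, 1, 1))      # exon is 49 nt
    e2b_seq <- paste0(substr(spill, 2, 3),
                      paste(.codons_for(substr(pep_b, 2, nchar(pep_b))),
                            collapse = ""),
                      .rand_dna(1))                    # still 36 nt
  } else if (len_violation) {
    e2b_seq <- paste0(paste(.codons_for(pep_b), collapse = ""),
                      paste(.codons_for(.random_peptide(aa_len)),
                            collapse = ""))
  } else {
    e2b_seq <- paste(.codons_for(pep_b), collapse = "")
  }
  e1_len <- nchar(e1_seq)
  lens <- c(e1_len, nchar(e2a_seq), nchar(e2b_seq), nchar(e3_seq))
  pos <- 0L; coords <- list(); region <- character()
  for (i in 1:4) {
    coords[[i]] <- c(pos, pos + lens[i])
    region <- c(region,
                list(e1_seq, e2a_seq, e2b_seq, e3_seq)[[i]],
                .rand_dna(intron))
    pos <- pos + lens[i] + intron
  }
  t1 <- sprintf("%s.t1", gid); t2 <- sprintf("%s.t2", gid)
  cds1_e1 <- c(0L, e1_cds_nt)
  cds2_e1 <- if (frame_shift) c(0L, e1_cds_nt + 1L) else cds1_e1
  f <- rbind(
    feat(t1, "exon", coords[[1]][1], coords[[1]][2]),
    feat(t1, "CDS", cds1_e1[1], cds1_e1[2]),
    feat(t1, "exon", coords[[2]][1], coords[[2]][2]),
    feat(t1, "CDS", coords[[2]][1], coords[[2]][2]),
    feat(t1, "exon", coords[[4]][1], coords[[4]][2]),
    feat(t1, "CDS", coords[[4]][1], coords[[4]][2]),
    feat(t2, "exon", coords[[1]][1], coords[[1]][2]),
    feat(t2, "CDS", cds2_e1[1], cds2_e1[2]),
    feat(t2, "exon", coords[[3]][1], coords[[3]][2]),
    feat(t2, "CDS", coords[[3]][1], coords[[3]][2]),
    feat(t2, "exon", coords[[4]][1], coords[[4]][2]),
    feat(t2, "CDS", coords[[4]][1], coords[[4]][2]))
  if (type == "mxe_cooccur") {
    t3 <- sprintf("%s.t3", gid)
    f <- rbind(f, do.call(rbind, lapply(coords, function(co)
      rbind(feat(t3, "exon", co[1], co[2]), feat(t3, "CDS", co[1], co[2])))))
  }
  if (type == "mxe_nmd") {
    t3 <- sprintf("%s.t3", gid)
    f <- rbind(f, do.call(rbind, lapply(coords, function(co)
      rbind(feat(t3, "exon", co[1], co[2], "nonsense_mediated_decay"),
            feat(t3, "CDS", co[1], co[2], "nonsense_mediated_decay")))))
  }
  violation <- switch(type, mxe_cooccur = "cooccurrence",
                      mxe_frame = "frame", mxe_length = "length",
                      mxe_short = "min_len", mxe_homology = "homology",
                      NA_character_)
  list(seq = paste(region, collapse = ""), features = f,
       planted = list(type = type, violation = violation,
                      exon_a_coord = coords[[2]], exon_b_coord = coords[[3]],
                      pep_a = pep_a, pep_b = pep_b,
                      isoform_a = paste0("M", e1_pep, pep_a, e3_pep),
                      variable_isoform_positions = 16L + mut_pos,
                      mutated_positions = mut_pos,
                      identity_target = if (unrelated) NA_real_ else
                        if (len_violation || short) 0.9 else identity,
                      host_a = t1, host_b = t2,
                      detectable = is.na(violation)))
}

.preset_gene_types <- function(preset, n_mxe = 10) {
  switch(preset,
    minimal = "mxe",
    controls = c("mxe", "mxe_cooccur", "mxe_frame", "mxe_length",
                 "mxe_short", "mxe_homology", "micro", "cassette"),
    benchmark = c(rep("mxe", n_mxe - 1), "mxe_nmd", "mxe_cooccur",
                  "mxe_frame", "mxe_length", "mxe_short", "mxe_homology",
                  "cassette", "cassette", "micro", "micro", "plain"),
    dscam_like = "dscam_like",
    stop(sprintf("unknown preset '%s'", preset)))
}

#' Generate a synthetic genome, annotation and manifest
#'
#' Writes a genome FASTA and a GTF containing genes with planted MXE
#' pairs, per-filter negative controls (co-occurrence, frame shift, length
#' ratio, sub-8-residue exons, missing homology), cassette exons,
#' microexons, an NMD-transcript control and (for the "dscam_like" preset)
#' a gene with mutually exclusive exon clusters of sizes 12/48/33/2. The
#' manifest records every planted feature with the exon ids the reader
#' will assign, and fully determines the files given the seed.
#'
#' @param config list: `preset` ("minimal", "controls", "benchmark",
#'   "dscam_like"), and optionally `n_mxe` (benchmark MXE gene count,
#'   default 10), `identity` (target peptide identity of planted pairs,
#'   default 0.67, the study dataset mean), `mxe_len_aa` (planted exon
#'   length in residues, default 36, the study dataset median), `cluster_sizes` (dscam-like preset, default c(12,48,33,2))
#' @param seed RNG seed
#' @param dir output directory (created if needed)
#' @return list(fasta, gtf, manifest)
#' @export
generate_genome_annotation <- function(config = list(preset = "minimal"),
                                       seed = 1, dir = tempfile("synth")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  preset <- config$preset %||% "minimal"
  types <- .preset_gene_types(preset, config$n_mxe %||% 10)
  identity <- config$identity %||% 0.67
  mxe_len_aa <- config$mxe_len_aa %||% 36
  cluster_sizes <- config$cluster_sizes %||% c(12, 48, 33, 2)
  chrom <- "chrS"
  spacer <- 100L
  offset <- 0L
  chrom_seq <- character(); gtf <- character(); manifest_genes <- list()
  clusters_global <- NULL
  exon_id <- function(co) sprintf("%s:%d-%d", chrom, co[1], co[2])
  for (gi in seq_along(types)) {
    gid <- sprintf("g%02d", gi)
    g <- .build_gene(gid, types[gi], identity = identity,
                     mxe_len_aa = mxe_len_aa, cluster_sizes = cluster_sizes)
    f <- g$features
    f$start <- f$start + offset; f$end <- f$end + offset
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s', gid,
                     f$transcript_id,
                     ifelse(is.na(f$biotype), "",
                            sprintf(' transcript_biotype "%s";', f$biotype)))
    gtf <- c(gtf, sprintf("%s\tsynth\t%s\t%d\t%d\t.\t+\t%s\t%s", chrom,
                          f$type, f$start + 1L, f$end,
                          ifelse(f$type == "CDS", "0", "."), attrs))
    p <- g$planted
    shift <- function(co) co + offset
    entry <- list(gene_id = gid, type = p$type)
    if (!is.null(p$exon_a_coord)) {
      entry$exon_a <- exon_id(shift(p$exon_a_coord))
      entry$exon_b <- exon_id(shift(p$exon_b_coord))
      entry$identity_target <- p$identity_target
      entry$violation <- p$violation
      entry$detectable <- p$detectable
      entry$host_a <- p$host_a; entry$host_b <- p$host_b
      entry$mutated_positions <- p$mutated_positions
      entry$isoform_a <- p$isoform_a
      entry$variable_isoform_positions <- p$variable_isoform_positions
    }
    if (!is.null(p$lost_coord)) {
      entry$lost_exon <- exon_id(shift(p$lost_coord))
      entry$long <- p$long; entry$short <- p$short
    }
    if (!is.null(p$micro_coord))
      entry$microexon <- exon_id(shift(p$micro_coord))
    if (!is.null(p$cluster_coords)) {
      clusters_global <- lapply(p$cluster_coords, function(cl)
        vapply(seq_len(nrow(cl)), function(i)
          exon_id(shift(cl[i, ])), character(1)))
      entry$cluster_sizes <- p$cluster_sizes
    }
    entry$n_transcripts <- length(unique(f$transcript_id))
    entry$n_exons <- sum(f$type == "exon" &
                           !duplicated(paste(f$start, f$end)))
    manifest_genes[[gid]] <- entry
    chrom_seq <- c(chrom_seq, g$seq, .rand_dna(spacer))
    offset <- offset + nchar(g$seq) + spacer
  }
  fasta <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "annotation.gtf")
  ss <- Biostrings::DNAStringSet(paste(chrom_seq, collapse = ""))
  names(ss) <- chrom
  Biostrings::writeXStringSet(ss, fasta)
  writeLines(gtf, gtf_path)
  planted <- Filter(function(e) !is.null(e$exon_a), manifest_genes)
  manifest <- list(
    seed = seed, preset = preset,
    genes = manifest_genes,
    planted_pairs = if (length(planted)) data.frame(
      gene_id = vapply(planted, `[[`, character(1), "gene_id"),
      exon_a = vapply(planted, `[[`, character(1), "exon_a"),
      exon_b = vapply(planted, `[[`, character(1), "exon_b"),
      violation = vapply(planted, function(e)
        e$violation %||% NA_character_, character(1)),
      detectable = vapply(planted, `[[`, logical(1), "detectable"),
      row.names = NULL, stringsAsFactors = FALSE) else NULL,
    clusters = clusters_global,
    counts = list(n_genes = length(types)))
  list(fasta = fasta, gtf = gtf_path, manifest = manifest)
}

# helix coordinates: rise 1.5 A/residue, 100 deg/residue, CA radius 2.3 A,
# pseudo side-chain atom 1.5 A further out along the radial direction
.helix_coords <- function(n, rise = 1.5, twist = 100, r_ca = 2.3,
                          r_cb = 3.8, z0 = 0, x0 = 0) {
  ang <- (seq_len(n) - 1) * twist * pi / 180
  z <- z0 + (seq_len(n) - 1) * rise
  list(ca = cbind(x0 + r_ca * cos(ang), r_ca * sin(ang), z),
       cb = cbind(x0 + r_cb * cos(ang), r_cb * sin(ang), z))
}

.write_pdb <- function(path, atoms) {
  # atoms: data.frame(resno, resid3, name, x, y, z)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
    atoms$resid3, atoms$resno, atoms$x, atoms$y, atoms$z,
    substr(atoms$name, 1, 1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a toy protein structure with planted geometry
#'
#' Builds an idealised backbone (helix / extended strand / two-lobe), one
#' pseudo side-chain atom per residue, an optional occluding atom sheath
#' that buries a chosen residue segment, and planted functional sites at
#' controlled distances from a target residue set: "near" sites lie within
#' 6 A of the target set's centre of mass, "far" sites at least 20 A away.
#' The manifest records the exact planted distances.
#'
#' @param config list: `n_res`; `geometry` ("ideal_helix", "extended",
#'   "two_lobe"); optional `sequence` (defaults to a random peptide);
#'   `variable_residues` (target set indices); `sites` list of
#'   list(category=, where="near"/"far", n=); `cage` indices of residues to
#'   bury under the sheath (adds ~8 glycine cage residues)
#' @param seed RNG seed
#' @param dir output directory
#' @return list(pdb, manifest) where the manifest carries the sequence,
#'   planted site residues with their distances, and cage extent
#' @export
generate_toy_structure <- function(config, seed = 1,
                                   dir = tempfile("struct")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_res
  geometry <- config$geometry %||% "ideal_helix"
  sequence <- config$sequence %||% .random_peptide(n)
  stopifnot(nchar(sequence) == n)
  co <- switch(geometry,
    ideal_helix = .helix_coords(n),
    extended = list(ca = cbind(3.8 * (seq_len(n) - 1), 0, 0),
                    cb = cbind(3.8 * (seq_len(n) - 1), 1.5, 0)),
    two_lobe = {
      n1 <- ceiling(n / 2)
      a <- .helix_coords(n1)
      b <- .helix_coords(n - n1, x0 = 30)
      list(ca = rbind(a$ca, b$ca), cb = rbind(a$cb, b$cb))
    },
    stop(sprintf("unknown geometry '%s'", geometry)))
  aa3 <- stats::setNames(bio3d::aa123(.aa1), .aa1)
  ch <- strsplit(sequence, "")[[1]]
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
    data.frame(resno = i, resid3 = aa3[[ch[i]]], name = "CA",
               x = co$ca[i, 1], y = co$ca[i, 2], z = co$ca[i, 3]),
    data.frame(resno = i, resid3 = aa3[[ch[i]]], name = "CB",
               x = co$cb[i, 1], y = co$cb[i, 2], z = co$cb[i, 3]))))
  cage_extent <- NULL
  if (!is.null(config$cage)) {
    if (geometry != "ideal_helix")
      stop("occluding cage is only supported for the ideal_helix geometry")
    zr <- range(co$ca[config$cage, 3]) + c(-3, 3)
    ring_z <- seq(zr[1], zr[2], by = 1.8)
    ring_ang <- seq(0, 2 * pi, length.out = 22)[-22]
    cage_xyz <- do.call(rbind, lapply(ring_z, function(z)
      cbind(6.5 * cos(ring_ang), 6.5 * sin(ring_ang), z)))
    caps <- do.call(rbind, lapply(c(zr[1] - 1.8, zr[2] + 1.8), function(z) {
      rr <- seq(0, 5.2, by = 1.8)
      do.call(rbind, lapply(rr, function(r)
        cbind(r * cos(ring_ang), r * sin(ring_ang), z)))
    }))
    cage_xyz <- rbind(cage_xyz, caps)
    per_res <- ceiling(nrow(cage_xyz) / 8)
    cage_res <- n + rep(seq_len(8), each = per_res)[seq_len(nrow(cage_xyz))]
    within <- stats::ave(seq_len(nrow(cage_xyz)), cage_res,
                         FUN = seq_along)
    atoms <- rbind(atoms, data.frame(resno = cage_res, resid3 = "GLY",
                                     name = sprintf("C%d", within),
                                     x = cage_xyz[, 1], y = cage_xyz[, 2],
                                     z = cage_xyz[, 3]))
    cage_extent <- list(buried = config$cage,
                        cage_residues = sort(unique(cage_res)))
  }
  pdb <- file.path(dir, "structure.pdb")
  .write_pdb(pdb, atoms)
  manifest <- list(seed = seed, n_res = n, geometry = geometry,
                   sequence = sequence, cage = cage_extent)
  if (!is.null(config$variable_residues)) {
    vres <- config$variable_residues
    vat <- atoms[atoms$resno %in% vres, ]
    com <- c(mean(vat$x), mean(vat$y), mean(vat$z))
    d_com <- vapply(seq_len(n), function(i) {
      ai <- atoms[atoms$resno == i, c("x", "y", "z")]
      sqrt(min(.cross_dist2(matrix(com, 1), as.matrix(ai))))
    }, numeric(1))
    manifest$variable_residues <- vres
    manifest$com <- com
    sites <- list()
    for (s in config$sites %||% list()) {
      pool <- if (s$where == "near") {
        # prefer residues outside the target set; sites inside it are
        # legitimate (in-cluster distance is zero by convention)
        cand <- which(d_com <= 6)
        c(setdiff(cand, vres), intersect(cand, vres))
      } else which(d_com >= 20)
      if (length(pool) < s$n)
        stop(sprintf("cannot plant %d '%s' site(s): structure extent too small",
                     s$n, s$where))
      pick <- if (s$where == "near") pool[seq_len(s$n)]
              else pool[order(-d_com[pool])][seq_len(s$n)]
      sites[[length(sites) + 1]] <-
        list(category = s$category, where = s$where, residues = pick,
             distances = d_com[pick])
    }
    manifest$sites <- sites
  }
  list(pdb = pdb, manifest = manifest)
}

#' Write a functional-site TSV from a structure manifest
#'
#' @param manifest a structure manifest from [generate_toy_structure()]
#' @param path output TSV
#' @param structure_id identifier used in the table
#' @return `path`, invisibly
#' @export
write_site_table <- function(manifest, path, structure_id = "synth") {
  rows <- do.call(rbind, lapply(manifest$sites, function(s)
    data.frame(structure_id = structure_id, chain = "A",
               resno = s$residues, category = s$category,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic multiple sequence alignment
#'
#' Planted columns are strictly invariant; background columns draw their
#' residue frequencies from a symmetric Dirichlet (low concentration =
#' high column entropy), emulating a functional-family alignment with
#' conserved functional positions. When a target DOPS band is requested,
#' generation retries up to `max_tries` times and errors if the band is
#' infeasible.
#'
#' @param config list: `n_seq` (default 15), `length` (default 40),
#'   `invariant_cols` (count or explicit positions, default 10),
#'   `concentration` (Dirichlet alpha, default 0.3), `dops_band` optional
#'   c(lo, hi), `max_tries` (default 20)
#' @param seed RNG seed
#' @param dir output directory
#' @return list(fasta, manifest) with realised DOPS in the manifest
#' @export
generate_msa <- function(config = list(), seed = 1, dir = tempfile("msa")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_seq <- config$n_seq %||% 15
  L <- config$length %||% 40
  inv <- config$invariant_cols %||% 10
  if (length(inv) == 1) inv <- sort(sample.int(L, inv))
  conc <- config$concentration %||% 0.3
  band <- config$dops_band
  max_tries <- config$max_tries %||% 20
  for (try in seq_len(max_tries)) {
    mat <- matrix("", n_seq, L)
    for (k in seq_len(L)) {
      if (k %in% inv) {
        mat[, k] <- sample(.aa1, 1)
      } else {
        p <- stats::rgamma(20, conc); p <- p / sum(p)
        mat[, k] <- sample(.aa1, n_seq, replace = TRUE, prob = p)
      }
    }
    prof <- conservation_and_dops(mat)
    if (is.null(band) ||
        (prof$dops > band[1] && prof$dops <= band[2])) {
      seqs <- apply(mat, 1, paste, collapse = "")
      names(seqs) <- sprintf("seq%02d", seq_len(n_seq))
      fasta <- file.path(dir, "alignment.fa")
      Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
      return(list(fasta = fasta,
                  manifest = list(seed = seed, n_seq = n_seq, length = L,
                                  invariant_cols = inv,
                                  concentration = conc,
                                  realised_dops = prof$dops)))
    }
  }
  stop(sprintf("could not reach DOPS band (%s] in %d tries",
               paste(band, collapse = ","), max_tries))
}

#' Generate a planted cancer-mutation table for a toy structure
#'
#' Plants mutation residues inside the variable set, within 4 A of it,
#' and far from it (minimum atom distance at least `far_min`), writing the
#' functional-site CancerMutation TSV schema; the manifest records the
#' true class of every planted mutation.
#'
#' @param structure a `structure_model`
#' @param variable_residues the variable residue indices
#' @param config list(n_inside, n_near, n_far), any may be 0
#' @param seed RNG seed
#' @param dir output directory
#' @param far_min minimum distance for "far" plants (default 20)
#' @param structure_id identifier used in the table
#' @return list(tsv, manifest)
#' @export
generate_mutations <- function(structure, variable_residues,
                               config = list(n_inside = 2, n_near = 2,
                                             n_far = 2),
                               seed = 1, dir = tempfile("mut"),
                               far_min = 20, structure_id = "synth") {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dmat <- residue_distance_matrix(structure)
  d <- apply(dmat[, variable_residues, drop = FALSE], 1, min)
  pools <- list(
    inside = variable_residues,
    near = setdiff(which(d <= 4), variable_residues),
    far = which(d >= far_min))
  counts <- c(inside = config$n_inside %||% 0, near = config$n_near %||% 0,
              far = config$n_far %||% 0)
  picks <- lapply(names(counts), function(cl) {
    k <- counts[[cl]]
    if (k == 0) return(integer(0))
    if (length(pools[[cl]]) < k)
      stop(sprintf("cannot plant %d '%s' mutation(s)", k, cl))
    sample(pools[[cl]], k)
  })
  names(picks) <- names(counts)
  rows <- do.call(rbind, lapply(names(picks), function(cl)
    if (length(picks[[cl]]))
      data.frame(structure_id = structure_id, chain = structure$chain,
                 resno = structure$residues$resno[picks[[cl]]],
                 category = "CancerMutation", true_class = cl,
                 stringsAsFactors = FALSE)))
  tsv <- file.path(dir, "mutations.tsv")
  utils::write.table(rows[, c("structure_id", "chain", "resno", "category")],
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(tsv = tsv,
       manifest = list(seed = seed, classes = rows[, c("resno",
                                                       "true_class")]))
}

#' Generate the default synthetic benchmark bundle
#'
#' Assembles a complete, internally consistent pipeline input set with
#' known ground truth: the "benchmark" gene preset (planted MXE pairs,
#' one per-filter negative control each, cassette exons, microexons, an
#' NMD control), one toy helix structure per structurally analysed event
#' (sequence equal to the event's host isoform, an occluding sheath
#' burying part of the constitutive region, near-planted CSA sites and
#' far-planted PPI sites), cancer-mutation tables (one structure planted
#' in-cluster, one far), disorder scores that gate two structure-less
#' events, and gene sets for the enrichment stage.
#'
#' @param seed RNG seed
#' @param dir output directory
#' @param n_structures number of events given a structure (default 5)
#' @return list(inputs, manifest): `inputs` feeds [run_pipeline()]
#'   directly, `manifest` holds all planted truth
#' @export
generate_benchmark <- function(seed = 1, dir = tempfile("bench"),
                               n_structures = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome_annotation(list(preset = "benchmark"),
                                    seed = seed, dir = dir)
  man <- gen$manifest
  mxe <- Filter(function(e) isTRUE(e$detectable), man$genes)
  stopifnot(length(mxe) >= n_structures)
  with_struct <- mxe[seq_len(n_structures)]
  structures <- list(); sites <- list(); mutations <- list()
  struct_manifests <- list()
  for (k in seq_along(with_struct)) {
    e <- with_struct[[k]]
    iso <- e$isoform_a
    n_iso <- nchar(iso)
    vres <- e$variable_isoform_positions
    cage <- seq(n_iso - 13, n_iso - 4)     # bury part of the last exon
    ts <- generate_toy_structure(
      list(n_res = n_iso, geometry = "ideal_helix", sequence = iso,
           variable_residues = vres, cage = cage,
           sites = list(list(category = "CSA", where = "near", n = 2),
                        list(category = "PPI", where = "far", n = 2))),
      seed = seed + 13 * k, dir = file.path(dir, sprintf("struct%d", k)))
    nm <- e$gene_id
    structures[[nm]] <- ts$pdb
    sites[[nm]] <- write_site_table(ts$manifest,
                                    file.path(dir, sprintf("sites_%s.tsv",
                                                           nm)), nm)
    struct_manifests[[nm]] <- ts$manifest
    if (k <= 2) {
      st <- read_structure(ts$pdb)
      mu <- generate_mutations(
        st, vres,
        config = if (k == 1) list(n_inside = 3) else list(n_far = 3),
        seed = seed + 53 * k, dir = file.path(dir, sprintf("mut%d", k)),
        structure_id = nm)
      mutations[[nm]] <- mu$tsv
      struct_manifests[[nm]]$mutations <- mu$manifest
    }
  }
  gated <- mxe[seq.int(n_structures + 1,
                       min(n_structures + 2, length(mxe)))]
  disorder <- do.call(rbind, lapply(gated, function(e)
    data.frame(protein_id = e$host_a,
               position = seq_len(nchar(e$isoform_a)), score = 0.9,
               stringsAsFactors = FALSE)))
  mxe_ids <- vapply(mxe, `[[`, character(1), "gene_id")
  bg <- sprintf("bg%03d", 1:60)
  gene_sets <- list(
    sets = list(enriched_set = c(mxe_ids[seq_len(min(8, length(mxe_ids)))],
                                 bg[1:2]),
                background_set = bg[11:25]),
    universe = c(vapply(man$genes, `[[`, character(1), "gene_id"), bg))
  list(inputs = list(gtf = gen$gtf, fasta = gen$fasta,
                     structures = structures, sites = sites,
                     mutations = mutations, disorder = disorder,
                     gene_sets = gene_sets),
       manifest = c(man, list(structures = struct_manifests,
                              gated_genes = vapply(gated, `[[`,
                                                   character(1),
                                                   "gene_id"))))
}
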