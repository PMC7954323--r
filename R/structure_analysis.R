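# Protein structure handling: PDB reading (via bio3d), isoform-to-structure
# residue mapping, Shrake-Rupley solvent accessibility with deterministic
# sphere points, inter-residue geometry and single-linkage 3D clustering of
# variable residues.

#' Read a protein structure from a PDB file
#'
#' Keeps heavy atoms of standard ATOM records of one chain: hydrogens,
#' waters and hetero groups are excluded; alternate locations are resolved
#' to the highest occupancy (then alphabetic altloc); insertion codes are
#' preserved in residue identity. Multi-model files use the first model
#' with a warning.
#'
#' @param pdb_file path to a PDB-format file
#' @param chain chain id to read (default: first chain present)
#' @return a `structure_model`: list(chain, residues, atoms, sequence)
#'   where `residues` has one row per residue (residx, resno, icode, aa)
#'   and `atoms` carries residx, name, element and x/y/z in Angstroms
#' @export
read_structure <- function(pdb_file, chain = NULL) {
  pdb <- suppressWarnings(bio3d::read.pdb(pdb_file, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in file")
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1)
    warning("multiple models present; using the first")
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("[0-9]", "", at$elety), 1, 1),
                         at$elesy))
  at <- at[elem != "H", , drop = FALSE]
  elem <- elem[elem != "H"]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # altloc: within (residue, atom name) keep highest occupancy, then
  # alphabetically first altloc
  key <- paste(at$resno, at$insert, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    idx[order(-occ[idx], at$alt[idx])][1]
  }))
  at <- at[sort(keep), , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("[0-9]", "", at$elety), 1, 1),
                         at$elesy))
  rid <- paste0(at$resno, at$insert)
  ures <- unique(rid)
  residx <- match(rid, ures)
  aa <- suppressWarnings(bio3d::aa321(at$resid[match(ures, rid)]))
  aa[is.na(aa)] <- "X"
  residues <- data.frame(residx = seq_along(ures),
                         resno = at$resno[match(ures, rid)],
                         icode = at$insert[match(ures, rid)],
                         aa = aa, stringsAsFactors = FALSE)
  atoms <- data.frame(residx = residx, name = at$elety, element = elem,
                      x = at$x, y = at$y, z = at$z,
                      occ = occ[sort(keep)], stringsAsFactors = FALSE)
  structure(list(chain = chain, residues = residues, atoms = atoms,
                 sequence = paste(residues$aa, collapse = "")),
            class = "structure_model")
}

#' Map an isoform sequence onto a structure
#'
#' Globally aligns the isoform against the structure-derived sequence and
#' maps every column in which both are aligned (identities and
#' substitutions). Coverage is the percentage of structure residues
#' covered; maps covering less than `min_coverage_pct` are flagged
#' unusable. The attribute `identity_pct` records the percent identity of
#' the mapped columns, which callers can use to restrict mapping to
#' homologous templates.
#'
#' @param isoform isoform peptide (>= 8 residues)
#' @param structure a `structure_model`
#' @param min_coverage_pct required structure coverage (default 80)
#' @return a `residue_map`: data.frame(isoform_pos, residx) with attributes
#'   `coverage_pct` and `usable`
#' @export
map_sequence_to_structure <- function(isoform, structure,
                                      min_coverage_pct = 80) {
  if (!nzchar(structure$sequence)) stop("empty structure sequence")
  stopifnot(nchar(isoform) >= 8, nchar(structure$sequence) >= 8)
  aln <- align_isoform_pair(isoform, structure$sequence)
  map <- aln$column_map
  both <- !is.na(map$pos_a) & !is.na(map$pos_b)
  m <- data.frame(isoform_pos = map$pos_a[both], residx = map$pos_b[both])
  coverage <- 100 * nrow(m) / nrow(structure$residues)
  ca <- strsplit(aln$aligned_a, "")[[1]]; cb <- strsplit(aln$aligned_b, "")[[1]]
  identity <- 100 * sum(ca == cb & ca != "-") / max(1, sum(both))
  structure(m, coverage_pct = coverage,
            identity_pct = identity,
            usable = coverage >= min_coverage_pct,
            class = c("residue_map", "data.frame"))
}

.vdw_radii_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      t <- .read_tsv(.extdata("vdw_radii.tsv"))
      cache <<- stats::setNames(t$radius, toupper(t$element))
    }
    cache
  }
})

.max_asa_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      t <- .read_tsv(.extdata("max_asa.tsv"))
      cache <<- stats::setNames(t$max_asa, t$aa)
    }
    cache
  }
})

#' Shrake-Rupley solvent accessibility and relative ASA
#'
#' Computes per-atom solvent-accessible surface area by the Shrake-Rupley
#' method (probe 1.4 A, Bondi van der Waals radii, a deterministic
#' golden-spiral point set), sums to residues, and converts to relative
#' ASA against per-residue-type reference maxima. A residue is exposed iff
#' its rASA is strictly above `exposed_cutoff` percent.
#'
#' @param structure a `structure_model`
#' @param probe probe radius in Angstroms (default 1.4)
#' @param n_points sphere sample points per atom (default 960)
#' @param exposed_cutoff rASA exposure threshold in percent (default 10)
#' @return a `sasa_result`: data.frame(residx, aa, sasa, rasa, exposed);
#'   residue types without a reference max get rASA NA (warned)
#' @export
compute_rasa <- function(structure, probe = 1.4, n_points = 960,
                         exposed_cutoff = 10) {
  at <- structure$atoms
  if (nrow(at) == 0) stop("structure has no atoms")
  radii <- .vdw_radii_table()
  r <- unname(radii[at$element])
  r[is.na(r)] <- radii[["C"]]
  r <- r + probe
  xyz <- cbind(at$x, at$y, at$z)
  pts <- golden_spiral_points(n_points)
  n <- nrow(at)
  d2 <- .cross_dist2(xyz, xyz)
  sasa_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= r[j]^2
    }
    sasa_atom[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  res_sasa <- tapply(sasa_atom, at$residx, sum)
  residues <- structure$residues
  sasa <- as.numeric(res_sasa[as.character(residues$residx)])
  maxasa <- .max_asa_table()[residues$aa]
  if (anyNA(maxasa))
    warning("residue type(s) without reference max ASA; rASA undefined")
  rasa <- 100 * sasa / unname(maxasa)
  data.frame(residx = residues$residx, aa = residues$aa, sasa = sasa,
             rasa = rasa, exposed = !is.na(rasa) & rasa > exposed_cutoff)
}

#' Fraction of exposed residues in a subset
#'
#' @param subset residue indices (residx)
#' @param sasa a `sasa_result` from [compute_rasa()]
#' @return (# exposed in subset) / |subset|
#' @export
exposure_fraction <- function(subset, sasa) {
  if (length(subset) == 0) stop("empty residue subset")
  k <- match(subset, sasa$residx)
  if (anyNA(k)) stop("subset contains residues not in the SASA result")
  if (anyNA(sasa$rasa[k])) stop("subset contains residues with undefined rASA")
  mean(sasa$exposed[k])
}

#' Minimum heavy-atom distance between two residues
#'
#' @param res_i,res_j residue indices (residx)
#' @param structure a `structure_model`
#' @return minimum Euclidean distance over heavy-atom pairs, in Angstroms
#' @export
min_residue_distance <- function(res_i, res_j, structure) {
  ai <- structure$atoms[structure$atoms$residx == res_i, c("x", "y", "z")]
  aj <- structure$atoms[structure$atoms$residx == res_j, c("x", "y", "z")]
  if (nrow(ai) == 0 || nrow(aj) == 0) stop("residue without atoms")
  sqrt(max(0, min(.cross_dist2(as.matrix(ai), as.matrix(aj)))))
}

#' All-against-all minimum inter-residue distance matrix
#'
#' Minimum heavy-atom distances between every residue pair; shared by the
#' clustering, contact-network and null-model code so the geometry is
#' computed once per structure.
#'
#' @param structure a `structure_model`
#' @return a symmetric n x n matrix (Angstroms), zero diagonal
#' @export
residue_distance_matrix <- function(structure) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- .cross_dist2(xyz, xyz)
  n <- nrow(structure$residues)
  out <- matrix(Inf, n, n)
  grp <- at$residx
  for (i in seq_len(n)) {
    ii <- which(grp == i)
    for (j in i:n) {
      m <- min(d2[ii, grp == j])
      out[i, j] <- out[j, i] <- m
    }
  }
  sqrt(pmax(out, 0))
}

#' Single-linkage 3D clustering of variable residues
#'
#' Groups residues into single-linkage connected components under minimum
#' heavy-atom distance <= `link` Angstroms; components smaller than
#' `min_size` are discarded. Each cluster's centre of mass is the mean of
#' its members' heavy-atom coordinates.
#'
#' @param structure a `structure_model`
#' @param residues residue indices (residx) to cluster
#' @param link linkage distance in Angstroms (default 8)
#' @param min_size minimum cluster size (default 3)
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @return list of `residue_cluster` objects: list(members, size,
#'   center_of_mass), ordered by decreasing size
#' @export
cluster_variable_residues <- function(structure, residues, link = 8,
                                      min_size = 3, dmat = NULL) {
  if (length(residues) == 0) return(list())
  residues <- sort(unique(residues))
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  sub <- dmat[residues, residues, drop = FALSE]
  adj <- (sub <= link)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(residues, comp), function(members) {
    if (length(members) < min_size) return(NULL)
    at <- structure$atoms[structure$atoms$residx %in% members, ]
    structure(list(members = members, size = length(members),
                   center_of_mass = c(mean(at$x), mean(at$y), mean(at$z))),
              class = "residue_cluster")
  })
  clusters <- Filter(Negate(is.null), clusters)
  clusters[order(-vapply(clusters, `[[`, numeric(1), "size"))]
}

#' Distance from a cluster's centre of mass to the nearest functional site
#'
#' Minimum over site residues of the minimum heavy-atom distance to the
#' cluster centre of mass; zero when a site residue is itself a cluster
#' member.
#'
#' @param cluster a `residue_cluster`
#' @param sites residue indices (residx) of the functional site set
#' @param structure a `structure_model`
#' @return distance in Angstroms
#' @export
com_to_site_distance <- function(cluster, sites, structure) {
  if (length(sites) == 0) stop("empty site set")
  if (any(sites %in% cluster$members)) return(0)
  com <- matrix(cluster$center_of_mass, nrow = 1)
  at <- structure$atoms[structure$atoms$residx %in% sites, ]
  sqrt(max(0, min(.cross_dist2(com, as.matrix(at[, c("x", "y", "z")])))))
}
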