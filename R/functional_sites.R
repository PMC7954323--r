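# Functional-site annotations and predictions: loading categorised site
# tables, FunSite prediction from MSA conservation (Valdar sum-of-pairs,
# DOPS diversity gate), allosteric-residue prediction by betweenness
# centrality on the residue contact network, and proximity calls of MXE
# variable residues/clusters to sites including cancer mutations.

.site_categories <- c("CSA", "PPI", "PSI", "FunSite", "Allosteric", "PTM",
                      "CancerMutation")

#' Load a functional-site table
#'
#' Reads a TSV with columns structure_id, chain, resno, category and
#' validates against a structure: rows referencing unknown residues are
#' dropped with a warning, duplicates are removed, unknown categories are
#' an error.
#'
#' @param path TSV path (or a data.frame with the same columns)
#' @param structure a `structure_model` to validate residue numbers against
#' @return data.frame(structure_id, chain, resno, category, residx)
#' @export
load_site_table <- function(path, structure) {
  t <- if (is.data.frame(path)) path else .read_tsv(path)
  stopifnot(all(c("structure_id", "chain", "resno", "category") %in%
                names(t)))
  bad <- setdiff(unique(t$category), .site_categories)
  if (length(bad))
    stop(sprintf("unknown site category: %s", paste(bad, collapse = ",")))
  t <- unique(t[, c("structure_id", "chain", "resno", "category")])
  t$residx <- structure$residues$residx[match(t$resno,
                                              structure$residues$resno)]
  if (anyNA(t$residx)) {
    warning(sprintf("%d site row(s) reference residues absent from the structure; dropped",
                    sum(is.na(t$residx))))
    t <- t[!is.na(t$residx), , drop = FALSE]
  }
  rownames(t) <- NULL
  t
}

# Valdar (2002)-style distance-based sequence weights
.valdar_weights <- function(mat) {
  n <- nrow(mat)
  if (n == 1) return(1)
  id <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    id[i, j] <- id[j, i] <- if (any(both))
      mean(mat[i, both] == mat[j, both]) else 0
  }
  w <- vapply(seq_len(n), function(i) mean(1 - id[i, -i]), numeric(1))
  if (all(w == 0)) w <- rep(1, n)
  w / sum(w)
}

#' Per-column conservation and alignment diversity (DOPS)
#'
#' Scores every alignment column with a Valdar-style weighted sum-of-pairs
#' conservation measure: identical residue pairs contribute 1, mismatches
#' and pairs involving a gap contribute 0 (the gap penalty), and sequences
#' are weighted by their mean distance to the rest of the alignment, so
#' redundant sequences do not dominate. An invariant gap-free column
#' scores 1; a column with near-uniform residue usage scores near 0. The
#' diversity-of-positions score (DOPS) summarises how diverse the observed
#' column scores are (distinct score values among columns, scaled to
#' 0-100); predicted FunSites (columns with score >= `funsite_cutoff`)
#' are only emitted when DOPS exceeds `dops_gate`, since conservation is
#' uninformative in low-diversity alignments.
#'
#' @param msa an alignment: FASTA path, named character vector of equal
#'   gapped lengths, or character matrix (rows = sequences)
#' @param funsite_cutoff column-conservation threshold (default 0.7)
#' @param dops_gate DOPS gate (default 70, strict >)
#' @return list(scores, dops, funsite_columns, gated)
#' @export
conservation_and_dops <- function(msa, funsite_cutoff = 0.7,
                                  dops_gate = 70) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    ss <- Biostrings::readAAStringSet(msa)
    msa <- stats::setNames(as.character(ss), names(ss))
  }
  if (is.character(msa) && !is.matrix(msa)) {
    lens <- nchar(msa)
    if (length(unique(lens)) != 1) stop("ragged alignment")
    mat <- do.call(rbind, strsplit(msa, ""))
  } else mat <- msa
  if (nrow(mat) < 5) stop("alignment must contain at least 5 sequences")
  w <- .valdar_weights(mat)
  n <- nrow(mat); L <- ncol(mat)
  pairs <- utils::combn(n, 2)
  pw <- w[pairs[1, ]] * w[pairs[2, ]]
  scores <- vapply(seq_len(L), function(k) {
    a <- mat[pairs[1, ], k]; b <- mat[pairs[2, ], k]
    s <- as.numeric(a == b & a != "-")
    sum(pw * s) / sum(pw)
  }, numeric(1))
  u <- length(unique(round(scores, 10)))
  dops <- if (L <= 1) 0 else 100 * (u - 1) / (L - 1)
  gated <- dops <= dops_gate
  funsites <- if (gated) integer(0) else which(scores >= funsite_cutoff)
  list(scores = scores, dops = dops, funsite_columns = funsites,
       gated = gated)
}

#' Predict allosteric residues by betweenness centrality
#'
#' Builds the residue contact network (edge iff minimum heavy-atom
#' distance <= `cutoff`), computes betweenness centrality (Brandes'
#' algorithm) and returns the residues at or above the given percentile of
#' centrality; ties at the threshold are all included. A disconnected
#' network is computed per component with a warning; a degenerate network
#' where all centralities are equal returns all residues, flagged.
#'
#' @param structure a `structure_model` with at least 10 residues
#' @param cutoff contact distance in Angstroms (default 5)
#' @param percentile centrality percentile (default 95)
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @return residue indices with attributes `centrality` and `degenerate`
#' @export
predict_allosteric_betweenness <- function(structure, cutoff = 5,
                                           percentile = 95, dmat = NULL) {
  n <- nrow(structure$residues)
  if (n < 10) stop("structure must have at least 10 residues")
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  adj <- dmat <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::components(g)$no > 1)
    warning("contact network is disconnected; centrality computed per component")
  bc <- igraph::betweenness(g, directed = FALSE)
  thr <- stats::quantile(bc, percentile / 100, names = FALSE)
  sel <- which(bc >= thr)
  degenerate <- length(unique(bc)) == 1
  structure(structure$residues$residx[sel], centrality = bc,
            degenerate = degenerate)
}

#' Cluster-mode proximity call to a functional-site set
#'
#' The cluster is close iff the distance from its centre of mass to the
#' nearest site residue (zero when a site residue is a member) is at most
#' `cutoff`; all distance cutoffs in the package are inclusive.
#'
#' @param cluster a `residue_cluster`
#' @param sites site residue indices
#' @param structure a `structure_model`
#' @param cutoff call distance in Angstroms (default 6)
#' @param category site category label carried into the output
#' @return a `proximity_call`: list(mode, category, distance, is_close)
#' @export
proximity_call_cluster <- function(cluster, sites, structure, cutoff = 6,
                                   category = NA_character_) {
  d <- com_to_site_distance(cluster, sites, structure)
  list(mode = "cluster_6A", category = category, distance = d,
       is_close = d <= cutoff)
}

#' Residue-mode proximity call to a functional-site set
#'
#' Close iff any variable residue lies within `cutoff` (minimum heavy-atom
#' distance) of any site residue.
#'
#' @param residues variable residue indices
#' @param sites site residue indices
#' @param structure a `structure_model`
#' @param cutoff call distance in Angstroms (default 4)
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @param category site category label
#' @return a `proximity_call`: list(mode, category, distance, is_close)
#' @export
proximity_call_residue <- function(residues, sites, structure, cutoff = 4,
                                   dmat = NULL, category = NA_character_) {
  if (length(residues) == 0 || length(sites) == 0)
    stop("empty residue or site set")
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  d <- min(dmat[residues, sites])
  list(mode = "residue_4A", category = category, distance = d,
       is_close = d <= cutoff)
}

#' Proximity of MXE variable residues to cancer mutation residues
#'
#' Makes the residue-mode (4 A, any-atom) and cluster-mode (6 A, centre of
#' the largest variable-residue cluster) calls against a set of cancer
#' mutation residues, and attaches empirical p-values from the package's
#' randomisation nulls: the residue-spacing-pattern placement null for
#' residue mode and the cluster-growth null for cluster mode. Null
#' distances are raw (continuous), so an observed in-cluster mutation
#' (distance zero by convention) that no null placement matches is
#' reported as p < 1/(n_null), printed as "<1e-04" at the default 10,000
#' resamplings.
#'
#' @param structure a `structure_model`
#' @param variable_residues mapped variable residue indices
#' @param mutation_residues cancer mutation residue indices (non-empty)
#' @param n_null null resamplings (default 10000)
#' @param seed RNG seed for the nulls
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @param residue_cutoff,cluster_cutoff call distances (4 and 6 A)
#' @return list with `residue_mode` and `cluster_mode` calls, each with an
#'   empirical `p_value` and printable `p_label`
#' @export
cancer_proximity <- function(structure, variable_residues,
                             mutation_residues, n_null = 10000, seed = 1,
                             dmat = NULL, residue_cutoff = 4,
                             cluster_cutoff = 6) {
  if (length(mutation_residues) == 0) stop("empty mutation set")
  if (length(variable_residues) == 0) stop("event has no mapped residues")
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  res_call <- proximity_call_residue(variable_residues, mutation_residues,
                                     structure, residue_cutoff, dmat,
                                     "CancerMutation")
  null_res <- residue_pattern_null(structure, variable_residues,
                                   mutation_residues, n = n_null,
                                   seed = seed, cutoff = residue_cutoff,
                                   dmat = dmat, value = "distance")
  p_res <- empirical_pvalue(res_call$distance, null_res,
                            direction = "less")
  clusters <- cluster_variable_residues(structure, variable_residues,
                                        dmat = dmat)
  cl_out <- NULL
  if (length(clusters) > 0) {
    cl <- clusters[[1]]
    cl_call <- proximity_call_cluster(cl, mutation_residues, structure,
                                      cluster_cutoff, "CancerMutation")
    null_cl <- random_cluster_null(structure, cl$size, mutation_residues,
                                   n = n_null, seed = seed, dmat = dmat,
                                   value = "distance")
    p_cl <- empirical_pvalue(cl_call$distance, null_cl, direction = "less")
    cl_out <- c(cl_call, list(p_value = p_cl,
                              p_label = attr(p_cl, "label")))
  }
  list(residue_mode = c(res_call, list(p_value = p_res,
                                       p_label = attr(p_res, "label"))),
       cluster_mode = cl_out)
}
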