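# Variable residues of an MXE isoform pair and their physicochemical
# scoring with the McLachlan similarity table, plus PTM-motif gain/loss
# logic and the intrinsic-disorder gate.

#' The embedded McLachlan physicochemical similarity matrix
#'
#' A 20x20 symmetric integer table of amino-acid physicochemical
#' similarity, scores 0 (no similarity, also used for a deletion) to 6.
#' Validated at load time: symmetry, range [0,6], identity scores in
#' \{5,6\}.
#'
#' @return a named 20x20 integer matrix
#' @export
mclachlan_matrix <- function() {
  m <- as.matrix(.read_tsv(.extdata("mclachlan.tsv"), row.names = 1,
                           check.names = FALSE))
  storage.mode(m) <- "integer"
  stopifnot(identical(rownames(m), colnames(m)),
            isTRUE(all(m == t(m))),
            min(m) >= 0L, max(m) <= 6L,
            all(diag(m) %in% c(5L, 6L)))
  m
}

#' Extract variable residues from a pair alignment
#'
#' Variable residues are alignment columns that differ between the two
#' isoforms: mismatched residues or a gap on either side. Identical
#' columns are excluded.
#'
#' @param aln a `pair_alignment` from [align_isoform_pair()]
#' @return a `variable_set`: data.frame(col, res_a, res_b, pos_a, pos_b)
#'   with attribute `count`
#' @export
extract_variable_residues <- function(aln) {
  stopifnot(inherits(aln, "pair_alignment"))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  keep <- ca != cb
  v <- data.frame(col = which(keep), res_a = ca[keep], res_b = cb[keep],
                  pos_a = aln$column_map$pos_a[keep],
                  pos_b = aln$column_map$pos_b[keep],
                  stringsAsFactors = FALSE)
  structure(v, count = nrow(v), class = c("variable_set", "data.frame"))
}

#' Normalised McLachlan score of a variable-residue set
#'
#' Sums the per-column McLachlan similarity scores (gap columns score 0)
#' and divides by the number of scored columns to normalise. When
#' `mapped_cols` is supplied (columns mapped onto a structure), only those
#' columns enter both the sum and the denominator. A normalised score of
#' at most 2 flags a significant physicochemical change.
#'
#' @param vset a `variable_set`
#' @param matrix McLachlan matrix (default: the embedded table)
#' @param mapped_cols optional integer vector of `col` values to restrict to
#' @return list(score, n, significant_change, per_column)
#' @export
mclachlan_normalized_score <- function(vset, matrix = mclachlan_matrix(),
                                       mapped_cols = NULL) {
  v <- as.data.frame(vset)
  if (!is.null(mapped_cols)) v <- v[v$col %in% mapped_cols, , drop = FALSE]
  if (nrow(v) == 0) stop("no variable residues to score")
  per <- vapply(seq_len(nrow(v)), function(i) {
    a <- v$res_a[i]; b <- v$res_b[i]
    if (a == "-" || b == "-" || !a %in% rownames(matrix) ||
        !b %in% rownames(matrix)) 0 else as.numeric(matrix[a, b])
  }, numeric(1))
  score <- sum(per) / length(per)
  list(score = score, n = length(per), significant_change = score <= 2,
       per_column = per)
}

# sequon (N-glycosylation motif N-[^P]-[S/T]) start positions in a peptide
.sequon_positions <- function(pep) {
  ch <- strsplit(pep, "")[[1]]
  n <- length(ch)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  i[ch[i] == "N" & ch[i + 1] != "P" & (ch[i + 2] == "S" | ch[i + 2] == "T")]
}

#' N-glycosylation sequon gain/loss between two isoforms
#'
#' Scans both peptides for the sequon N-X-S/T (X != P) and reports, mapped
#' through the alignment, motif positions present in exactly one isoform.
#'
#' @param pep_a,pep_b the two peptides
#' @param aln their `pair_alignment`
#' @return data.frame(col, pos_a, pos_b, present_in_a, present_in_b)
#' @export
detect_sequon_change <- function(pep_a, pep_b, aln) {
  stopifnot(inherits(aln, "pair_alignment"))
  sa <- .sequon_positions(pep_a)
  sb <- .sequon_positions(pep_b)
  map <- aln$column_map
  col_a <- map$col[match(sa, map$pos_a)]
  col_b <- map$col[match(sb, map$pos_b)]
  cols <- sort(union(col_a, col_b))
  if (length(cols) == 0)
    return(data.frame(col = integer(), pos_a = integer(), pos_b = integer(),
                      present_in_a = logical(), present_in_b = logical()))
  out <- data.frame(col = cols,
                    pos_a = map$pos_a[match(cols, map$col)],
                    pos_b = map$pos_b[match(cols, map$col)],
                    present_in_a = cols %in% col_a,
                    present_in_b = cols %in% col_b)
  out[xor(out$present_in_a, out$present_in_b), , drop = FALSE]
}

#' Loss of annotated PTM sites across an MXE switch
#'
#' A phosphosite is lost when an annotated S/T/Y position (indexed on
#' isoform a) falls in a variable column whose partner residue is not a
#' phospho-acceptor (S/T/Y). An annotated glycosylation asparagine is lost
#' when the partner residue is not N. Annotations outside the protein are
#' skipped with a warning.
#'
#' @param vset a `variable_set` (positions on isoform a in `pos_a`)
#' @param annotations data.frame(position, ptm_type) with `ptm_type` in
#'   phosphosite / n_glycosylation
#' @param protein_length length of isoform a, for validation
#' @return data.frame of lost sites (position, ptm_type, res_a, res_b)
#' @export
detect_ptm_loss <- function(vset, annotations, protein_length = NULL) {
  empty <- data.frame(position = integer(), ptm_type = character(),
                      res_a = character(), res_b = character(),
                      stringsAsFactors = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0) return(empty)
  v <- as.data.frame(vset)
  out <- empty
  for (i in seq_len(nrow(annotations))) {
    pos <- annotations$position[i]
    type <- annotations$ptm_type[i]
    if (!is.null(protein_length) && (pos < 1 || pos > protein_length)) {
      warning(sprintf("PTM annotation at position %d outside protein", pos))
      next
    }
    k <- which(v$pos_a == pos)
    if (length(k) == 0) next          # position not variable: site retained
    ra <- v$res_a[k[1]]; rb <- v$res_b[k[1]]
    lost <- switch(type,
      phosphosite = ra %in% c("S", "T", "Y") && !rb %in% c("S", "T", "Y"),
      n_glycosylation = ra == "N" && rb != "N",
      stop(sprintf("unknown ptm_type '%s'", type)))
    if (lost)
      out <- rbind(out, data.frame(position = pos, ptm_type = type,
                                   res_a = ra, res_b = rb,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Intrinsic-disorder gate for an isoform
#'
#' A residue is disordered iff its score exceeds 0.5; the isoform is called
#' intrinsically disordered iff strictly more than half of its residues are
#' disordered.
#'
#' @param scores per-residue disorder scores in [0,1]
#' @param protein_length expected length, for validation (optional)
#' @param residue_cutoff per-residue disorder threshold (default 0.5)
#' @param fraction_cutoff disordered-fraction threshold (default 0.5,
#'   strict)
#' @return TRUE if the isoform is intrinsically disordered
#' @export
disorder_gate <- function(scores, protein_length = NULL,
                          residue_cutoff = 0.5, fraction_cutoff = 0.5) {
  if (!is.null(protein_length) && length(scores) != protein_length)
    stop("disorder score length does not match protein length")
  if (any(scores < 0 | scores > 1)) stop("disorder scores must be in [0,1]")
  mean(scores > residue_cutoff) > fraction_cutoff
}
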