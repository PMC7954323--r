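# Pairwise alignment wrappers (Biostrings, BLOSUM62) plus the
# Karlin-Altschul E-value used by the self-contained homology filter.

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global alignment of an MXE isoform peptide pair
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap open 10 and gap
#' extend 0.5 (penalties). Traceback is deterministic (delegated to the
#' Biostrings implementation), so repeated calls give identical alignments.
#'
#' @param pep_a,pep_b peptides (non-empty character scalars)
#' @return a `pair_alignment`: list with `aligned_a`, `aligned_b` (equal
#'   length gapped strings), `score`, and `column_map` (data.frame with
#'   per-column 1-based positions `pos_a`, `pos_b`, NA at gaps)
#' @export
align_isoform_pair <- function(pep_a, pep_b) {
  if (!nzchar(pep_a) || !nzchar(pep_b)) stop("empty sequence")
  .assert_aa(pep_a, "pep_a"); .assert_aa(pep_b, "pep_b")
  aln <- Biostrings::pairwiseAlignment(
    pep_a, pep_b, type = "global", substitutionMatrix = .blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  a <- as.character(Biostrings::alignedPattern(aln))
  b <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(list(aligned_a = a, aligned_b = b,
                 score = Biostrings::score(aln),
                 column_map = data.frame(col = seq_along(ca),
                                         pos_a = pos_a, pos_b = pos_b)),
            class = "pair_alignment")
}

#' Karlin-Altschul E-value for a gapped local alignment score
#'
#' E = K * m * n * exp(-lambda * S) with the gapped BLOSUM62 (11/1)
#' constants lambda = 0.267, K = 0.041 and search space m * n.
#'
#' @param score raw local alignment score
#' @param m,n lengths of the two sequences
#' @param lambda,K Karlin-Altschul constants
#' @return the expected number of chance alignments at this score
#' @export
karlin_altschul_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Translated-homology filter for candidate MXE pairs
#'
#' Rejects immediately when either peptide is shorter than `min_len`
#' residues (too short to assess homology); otherwise runs Smith-Waterman
#' local alignment (BLOSUM62, gap open 11, extend 1), computes percent
#' identity over aligned columns and a Karlin-Altschul E-value, and passes
#' iff identity >= `identity_min_pct` and E <= `evalue_max`.
#'
#' @param pep_a,pep_b exon peptides
#' @param evalue_max maximum E-value (default 0.005)
#' @param identity_min_pct minimum percent identity (default 25)
#' @param min_len minimum peptide length in residues (default 8)
#' @return list with `pass`, `identity_pct`, `evalue`, `score`, `reason`
#' @export
homology_filter <- function(pep_a, pep_b, evalue_max = 0.005,
                            identity_min_pct = 25, min_len = 8) {
  if (!nzchar(pep_a) || !nzchar(pep_b)) stop("empty peptide")
  .assert_aa(pep_a, "pep_a"); .assert_aa(pep_b, "pep_b")
  if (nchar(pep_a) < min_len || nchar(pep_b) < min_len)
    return(list(pass = FALSE, identity_pct = NA_real_, evalue = NA_real_,
                score = NA_real_, reason = "min_len"))
  aln <- Biostrings::pairwiseAlignment(
    pep_a, pep_b, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  s <- Biostrings::score(aln)
  id <- Biostrings::pid(aln, type = "PID1")
  ev <- karlin_altschul_evalue(s, nchar(pep_a), nchar(pep_b))
  pass <- id >= identity_min_pct && ev <= evalue_max
  list(pass = pass, identity_pct = id, evalue = ev, score = s,
       reason = if (pass) NA_character_
                else if (ev > evalue_max) "evalue" else "identity")
}
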