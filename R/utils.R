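# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a bundled data table
#' @noRd
.extdata <- function(file) {
  path <- system.file("extdata", file, package = "mxestruct")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  path
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Deterministic points on the unit sphere (golden-section spiral)
#'
#' Used by the Shrake-Rupley solvent-accessibility routine so that results
#' are reproducible bit-for-bit for a fixed point count.
#'
#' @param n number of points
#' @return an n x 3 matrix of unit vectors
#' @keywords internal
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# squared distances between rows of two coordinate matrices
.cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  outer(an, bn, "+") - 2 * tcrossprod(a, b)
}

.aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.assert_aa <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(.aa1, "X", "*", "-"))
  if (length(bad) > 0)
    stop(sprintf("non-amino-acid characters in %s: %s", what,
                 paste(bad, collapse = ",")))
  invisible(TRUE)
}
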