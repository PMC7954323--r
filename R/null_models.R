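# The randomisation null models (random sequence regions, grown random
# structural clusters, residue-spacing-pattern placement, functional-
# vicinity residue sampling) and the hypothesis-testing machinery
# (Wilcoxon, Mann-Whitney, Z-score, Fisher + Benjamini-Hochberg,
# empirical p-values).

#' Construct a null distribution object
#'
#' @param statistic statistic name
#' @param samples resampled values
#' @param seed seed the samples were drawn with
#' @return a `null_distribution`
#' @export
new_null_distribution <- function(statistic, samples, seed) {
  structure(list(statistic = statistic, samples = samples,
                 n = length(samples), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null distribution '%s': n=%d, mean=%.4g, sd=%.4g (seed %s)\n",
              x$statistic, x$n, mean(x$samples), stats::sd(x$samples),
              format(x$seed)))
  invisible(x)
}

#' Random contiguous-region exposure null
#'
#' Resamples the exposure fraction of uniformly chosen contiguous sequence
#' windows of the same length as the splice region, from the same
#' structure.
#'
#' @param structure a `structure_model`
#' @param region_len window length in residues (<= chain length)
#' @param sasa a `sasa_result` from [compute_rasa()]
#' @param n number of resamplings (default 10000)
#' @param seed RNG seed
#' @return a `null_distribution` of exposure fractions
#' @export
random_region_null <- function(structure, region_len, sasa, n = 10000,
                               seed = 1) {
  L <- nrow(structure$residues)
  if (region_len > L) stop("region longer than the chain")
  exposed <- sasa$exposed[order(sasa$residx)]
  # window means via cumulative sums over residue order
  cs <- c(0, cumsum(as.numeric(exposed)))
  offsets_all <- seq_len(L - region_len + 1)
  frac <- (cs[offsets_all + region_len] - cs[offsets_all]) / region_len
  set.seed(seed)
  new_null_distribution("exposure_fraction",
                        frac[sample.int(length(frac), n, replace = TRUE)],
                        seed)
}

# deterministic cluster growth from one seed residue: residues whose
# minimum atom distance to the current set is <= cutoff are added nearest
# first; when none qualifies before target_size is reached the overall
# nearest residue is added instead (chain-break fallback).
.grow_cluster <- function(seed_res, target_size, dmat) {
  members <- seed_res
  n <- nrow(dmat)
  while (length(members) < target_size) {
    d <- if (length(members) == 1) dmat[members, ]
         else apply(dmat[members, , drop = FALSE], 2, min)
    d[members] <- Inf
    cand <- which(d <= attr(dmat, "growth_cutoff") %||% 2)
    nxt <- if (length(cand) > 0) cand[which.min(d[cand])] else which.min(d)
    members <- c(members, nxt)
  }
  sort(members)
}

#' Grown random structural-cluster null
#'
#' Emulates the splice-region cluster by growing, from a uniformly chosen
#' seed residue, a cluster of the same size as the largest observed
#' variable-residue cluster: residues within `growth_cutoff` (default 2 A,
#' effectively covalent neighbours) of the current set are added nearest
#' first; when growth stalls (chain break, sparse toy structures) the
#' nearest residue overall is added, which is recorded in the attribute
#' `fallback_used`. Growth is deterministic given the seed residue, so the
#' null is computed by resampling precomputed per-seed outcomes.
#'
#' @param structure a `structure_model`
#' @param target_size cluster size to grow (>= 3)
#' @param sites functional-site residue indices
#' @param n resamplings (default 10000)
#' @param seed RNG seed
#' @param growth_cutoff growth distance in Angstroms (default 2)
#' @param com_cutoff proximity call distance for indicators (default 6)
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @param value "indicator" (cluster close to a site, using the in-cluster
#'   zero convention) or "distance" (raw centre-of-mass distance)
#' @return a `null_distribution`
#' @export
random_cluster_null <- function(structure, target_size, sites, n = 10000,
                                seed = 1, growth_cutoff = 2,
                                com_cutoff = 6, dmat = NULL,
                                value = c("indicator", "distance")) {
  value <- match.arg(value)
  if (target_size < 3) stop("target_size must be at least 3")
  L <- nrow(structure$residues)
  if (L < target_size) stop("structure smaller than target cluster size")
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  attr(dmat, "growth_cutoff") <- growth_cutoff
  per_seed <- .cluster_null_per_seed(structure, target_size, sites,
                                     com_cutoff, dmat)
  set.seed(seed)
  pick <- sample.int(L, n, replace = TRUE)
  samples <- if (value == "indicator") per_seed$indicator[pick]
             else per_seed$distance[pick]
  out <- new_null_distribution(paste0("random_cluster_", value), samples,
                               seed)
  attr(out, "fallback_used") <- per_seed$fallback
  out
}

.cluster_null_per_seed <- function(structure, target_size, sites,
                                   com_cutoff, dmat) {
  L <- nrow(structure$residues)
  indicator <- logical(L); distance <- numeric(L); fallback <- FALSE
  at <- structure$atoms
  site_xyz <- as.matrix(at[at$residx %in% sites, c("x", "y", "z")])
  cutoff <- attr(dmat, "growth_cutoff") %||% 2
  for (s in seq_len(L)) {
    members <- .grow_cluster(s, target_size, dmat)
    if (length(members) > 1) {
      step_d <- dmat[members, members]
      if (max(apply(step_d + diag(Inf, length(members)), 1, min)) > cutoff)
        fallback <- TRUE
    }
    m_at <- at[at$residx %in% members, ]
    com <- matrix(c(mean(m_at$x), mean(m_at$y), mean(m_at$z)), nrow = 1)
    raw <- if (nrow(site_xyz) == 0) Inf
           else sqrt(max(0, min(.cross_dist2(com, site_xyz))))
    distance[s] <- raw
    d_call <- if (any(sites %in% members)) 0 else raw
    indicator[s] <- d_call <= com_cutoff
  }
  list(indicator = indicator, distance = distance, fallback = fallback)
}

#' Residue-spacing-pattern placement null
#'
#' Keeps the observed spacing pattern of the variable residues (e.g.
#' X-X---X-X-X along the chain) and slides it to uniformly random offsets
#' within the structure-mapped chain, recording for each placement whether
#' any pattern residue lies within `cutoff` of a site (indicator) or the
#' minimum pattern-to-site atom distance (distance).
#'
#' @param structure a `structure_model`
#' @param pattern_residues observed variable residue indices (the spacing
#'   is taken from these)
#' @param sites site residue indices
#' @param n resamplings (default 10000)
#' @param seed RNG seed
#' @param cutoff residue-mode call distance (default 4)
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @param value "indicator" or "distance"
#' @return a `null_distribution`
#' @export
residue_pattern_null <- function(structure, pattern_residues, sites,
                                 n = 10000, seed = 1, cutoff = 4,
                                 dmat = NULL,
                                 value = c("indicator", "distance")) {
  value <- match.arg(value)
  L <- nrow(structure$residues)
  pat <- sort(unique(pattern_residues))
  span <- max(pat) - min(pat)
  if (span + 1 > L) stop("pattern longer than the chain")
  offsets_rel <- pat - min(pat)
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  starts <- seq_len(L - span)
  per_offset <- vapply(starts, function(s) {
    if (length(sites) == 0) return(Inf)
    min(dmat[s + offsets_rel, sites, drop = FALSE])
  }, numeric(1))
  set.seed(seed)
  pick <- sample.int(length(starts), n, replace = TRUE)
  samples <- if (value == "indicator") per_offset[pick] <= cutoff
             else per_offset[pick]
  new_null_distribution(paste0("residue_pattern_", value), samples, seed)
}

#' Sample residues from the vicinity of functional sites
#'
#' Uniform sampling with replacement from the residues lying within
#' `radius` (minimum atom distance) of any site of the given set; used as
#' the comparison population for McLachlan score distributions.
#'
#' @param structure a `structure_model`
#' @param sites site residue indices
#' @param radius vicinity distance in Angstroms (default 4)
#' @param n sample size
#' @param seed RNG seed
#' @param dmat optional precomputed [residue_distance_matrix()]
#' @return sampled residue indices (with attribute `vicinity`, the pool)
#' @export
functional_vicinity_residue_sample <- function(structure, sites, radius = 4,
                                               n = 1000, seed = 1,
                                               dmat = NULL) {
  if (is.null(dmat)) dmat <- residue_distance_matrix(structure)
  d <- apply(dmat[, sites, drop = FALSE], 1, min)
  vicinity <- which(d <= radius)
  if (length(vicinity) == 0) stop("no residues within radius of the sites")
  set.seed(seed)
  structure(vicinity[sample.int(length(vicinity), n, replace = TRUE)],
            vicinity = vicinity)
}

new_test_result <- function(test, statistic, p, direction, n) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p), direction = direction, n = n),
            class = "test_result")
}

#' Wilcoxon signed-rank test on paired observations
#'
#' Two-sided; exact null enumeration for up to 25 non-zero differences
#' without ties, normal approximation with tie correction otherwise.
#'
#' @param x,y paired observations (or `x` a vector of differences)
#' @return a `test_result`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) stop("all differences are zero (degenerate)")
  if (length(nz) < 5) stop("need at least 5 non-zero differences")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact,
                                            correct = !exact))
  new_test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value,
                  "two-sided", length(nz))
}

#' Mann-Whitney U test on two independent samples
#'
#' Two-sided; exact for combined sample sizes up to 12 without ties,
#' normal approximation with tie correction otherwise.
#'
#' @param sample_a,sample_b numeric samples (each >= 3 values)
#' @return a `test_result`
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop("both samples must contain at least 3 values")
  exact <- (length(sample_a) + length(sample_b)) <= 12 &&
    !any(duplicated(c(sample_a, sample_b)))
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact,
                                            correct = !exact))
  new_test_result("mann_whitney_u", wt$statistic, wt$p.value, "two-sided",
                  length(sample_a) + length(sample_b))
}

#' Z-score test of an observed statistic against a resampling null
#'
#' z = (observed - mean(null)) / sd(null), one-sided towards enrichment
#' (upper tail of the standard normal).
#'
#' @param observed observed statistic (e.g. a proportion)
#' @param null a `null_distribution` with n >= 30
#' @param direction "greater" (enrichment, default) or "less"
#' @return a `test_result` with the z statistic
#' @export
zscore_test <- function(observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(null, "null_distribution"))
  if (null$n < 30) stop("null distribution too small (n < 30)")
  s <- stats::sd(null$samples)
  if (s == 0) stop("null distribution has zero variance; z undefined")
  z <- (observed - mean(null$samples)) / s
  p <- if (direction == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  new_test_result("zscore", z, p, direction, null$n)
}

#' Fisher exact tests with Benjamini-Hochberg correction across units
#'
#' For each unit (e.g. a structural superfamily or gene set) with a 2x2
#' contingency table, computes the two-sided Fisher exact p (hypergeometric
#' enumeration), the sample odds ratio (with a Haldane 0.5 correction only
#' when a zero cell makes it undefined, flagged), and BH q-values across
#' units. A unit is significant iff its odds ratio exceeds 1 and p < alpha.
#'
#' @param tables list of 2x2 matrices, or a data.frame with columns
#'   a, b, c, d (row-major counts)
#' @param alpha significance level (default 0.05)
#' @return data.frame(unit, a, b, c, d, odds_ratio, haldane, p, q,
#'   significant)
#' @export
fisher_bh_enrichment <- function(tables, alpha = 0.05) {
  if (is.data.frame(tables)) {
    units <- rownames(tables) %||% as.character(seq_len(nrow(tables)))
    tables <- stats::setNames(lapply(seq_len(nrow(tables)), function(i)
      matrix(as.numeric(tables[i, c("a", "b", "c", "d")]), 2, 2,
             byrow = TRUE)), units)
  }
  if (is.null(names(tables)))
    names(tables) <- as.character(seq_along(tables))
  rows <- lapply(names(tables), function(u) {
    m <- tables[[u]]
    if (any(m < 0)) stop("negative counts in contingency table")
    p <- stats::fisher.test(m)$p.value
    zero <- any(m == 0)
    mm <- if (zero) m + 0.5 else m
    or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
    data.frame(unit = u, a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
               odds_ratio = or, haldane = zero, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$odds_ratio > 1 & out$p < alpha
  out
}

#' Empirical p-value from a resampling null
#'
#' p = (1 + # samples as or more extreme) / (n + 1); never exactly zero.
#' When no sample is as extreme, the printable label reports "< 1/n".
#'
#' @param observed observed statistic
#' @param null a `null_distribution`
#' @param direction "less", "greater" or "two-sided"
#' @return the p-value, with attribute `label` (printable form)
#' @export
empirical_pvalue <- function(observed, null,
                             direction = c("less", "greater",
                                           "two-sided")) {
  direction <- match.arg(direction)
  s <- as.numeric(null$samples)
  k <- switch(direction,
              less = sum(s <= observed),
              greater = sum(s >= observed),
              `two-sided` = {
                dev <- abs(s - mean(s))
                sum(dev >= abs(observed - mean(s)))
              })
  p <- (1 + k) / (null$n + 1)
  label <- if (k == 0) sprintf("<%g", 1 / null$n) else sprintf("%g", p)
  structure(p, label = label)
}
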