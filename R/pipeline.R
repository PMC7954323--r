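# End-to-end orchestration: detect events, align isoform pairs, map onto
# structures, compute solvent accessibility, cluster variable residues,
# make proximity calls against functional-site categories, run the
# randomisation nulls and tests, and write a machine-readable report. All
# thresholds are carried in a single config and echoed into the report;
# all randomness funnels through the config seed.

#' Default pipeline configuration
#'
#' Thresholds follow the study defaults: identity 25%, E-value 0.005,
#' minimum MXE length 8 residues, |log10 length ratio| 0.25, rASA exposure
#' 10%, 8 A cluster linkage with minimum size 3, 6 A cluster-to-site and
#' 4 A residue-to-site calls, 2 A null-cluster growth, 10,000 null
#' resamplings, 95th betweenness percentile, DOPS gate 70 and disorder
#' gate 0.5 per residue / 50% of residues.
#'
#' @param ... overrides
#' @return a named list of thresholds
#' @export
default_config <- function(...) {
  cfg <- list(identity_min_pct = 25, evalue_max = 0.005, min_len = 8,
              max_abs_log_ratio = 0.25, exposed_cutoff = 10, link = 8,
              min_cluster = 3, com_cutoff = 6, residue_cutoff = 4,
              growth_cutoff = 2, n_null = 10000, percentile = 95,
              dops_gate = 70, disorder_residue = 0.5,
              disorder_fraction = 0.5, min_coverage_pct = 80,
              map_identity_min_pct = 40, seed = 1)
  utils::modifyList(cfg, list(...))
}

# sample one passing pair per MXE cluster of a gene (pairs sharing an exon
# form a cluster), seeded
.sample_one_per_cluster <- function(events, seed) {
  if (nrow(events) == 0) return(events)
  keep <- logical(nrow(events))
  set.seed(seed)
  for (g in unique(events$gene_id)) {
    idx <- which(events$gene_id == g)
    # union-find over shared exons
    grp <- seq_along(idx)
    for (i in seq_along(idx)) for (j in seq_len(i - 1)) {
      share <- length(intersect(
        c(events$exon_a[idx[i]], events$exon_b[idx[i]]),
        c(events$exon_a[idx[j]], events$exon_b[idx[j]]))) > 0
      if (share) grp[grp == grp[i]] <- grp[j]
    }
    for (cl in unique(grp)) {
      members <- idx[grp == cl]
      keep[members[sample.int(length(members), 1)]] <- TRUE
    }
  }
  events[keep, , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Stages: event detection (MXE, cassette, microexon) -> isoform
#' translation and pairwise alignment -> disorder gating -> structure
#' mapping -> solvent accessibility (with the random-region null and a
#' Wilcoxon signed-rank test across events) -> McLachlan physicochemical
#' scoring -> 3D clustering -> proximity calls per functional-site
#' category (with the grown-cluster null and a one-sided Z-test over the
#' event set) -> cancer-mutation proximity -> gene-set enrichment (Fisher
#' + BH). A failing event is logged and skipped, never aborts the run; an
#' empty gene set produces a clean empty report.
#'
#' @param inputs list: `gtf`, `fasta` (required); optionally `structures`
#'   (named list of PDB paths), `sites` (named list of site TSVs or
#'   data.frames, by structure name), `mutations` (ditto, CancerMutation
#'   tables), `disorder` (data.frame protein_id, position, score),
#'   `gene_sets` (list(sets = named list of gene-id vectors,
#'   universe = gene ids))
#' @param config from [default_config()]
#' @param out_dir optional; when given, [write_report()] is called
#' @return a `pipeline_report` list (counts, per-event tables, tests)
#' @export
run_pipeline <- function(inputs, config = default_config(),
                         out_dir = NULL) {
  genes <- read_annotation(inputs$gtf, inputs$fasta)
  genome <- attr(genes, "genome")
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  ## -- detection ---------------------------------------------------------
  ev_list <- lapply(genes, function(g) tryCatch(
    detect_mxe_pairs(g, genome,
                     max_abs_log_ratio = config$max_abs_log_ratio,
                     evalue_max = config$evalue_max,
                     identity_min_pct = config$identity_min_pct,
                     min_len = config$min_len),
    error = function(e) { note("gene %s: detection failed (%s)", g$id,
                               conditionMessage(e)); NULL }))
  candidates <- do.call(rbind, Filter(function(x) !is.null(x) && nrow(x),
                                      ev_list))
  events <- if (!is.null(candidates))
    candidates[candidates$pass, , drop = FALSE] else NULL
  if (is.null(events))
    events <- data.frame(gene_id = character(), exon_a = character(),
                         exon_b = character(), stringsAsFactors = FALSE)
  events <- .sample_one_per_cluster(events, config$seed)
  if (nrow(events)) rownames(events) <- NULL
  cassette <- do.call(rbind, lapply(genes, detect_cassette_events))
  micro <- do.call(rbind, lapply(genes, function(g) {
    ex <- g$exons
    data.frame(gene_id = g$id, exon_id = ex$exon_id,
               length_nt = ex$end - ex$start,
               is_microexon = (ex$end - ex$start) <= 27,
               stringsAsFactors = FALSE)
  }))

  ## -- per-event alignment, disorder gate --------------------------------
  ev_extra <- list(); struct_rows <- list()
  structures <- lapply(inputs$structures %||% list(), read_structure)
  dmats <- lapply(structures, residue_distance_matrix)
  sasas <- lapply(structures, compute_rasa,
                  exposed_cutoff = config$exposed_cutoff)
  site_tabs <- lapply(names(inputs$sites %||% list()), function(nm)
    load_site_table(inputs$sites[[nm]], structures[[nm]]))
  names(site_tabs) <- names(inputs$sites %||% list())
  mut_tabs <- lapply(names(inputs$mutations %||% list()), function(nm)
    load_site_table(inputs$mutations[[nm]], structures[[nm]]))
  names(mut_tabs) <- names(inputs$mutations %||% list())

  for (i in seq_len(nrow(events))) tryCatch({
    ev <- events[i, ]
    gene <- genes[[ev$gene_id]]
    aln <- align_isoform_pair(ev$peptide_a, ev$peptide_b)
    vset <- extract_variable_residues(aln)
    mcl <- mclachlan_normalized_score(vset)
    host <- gene$transcripts[[ev$host_transcript_a]]
    isoform <- as.character(extract_cds_peptide(host, gene, genome))
    disordered <- FALSE
    if (!is.null(inputs$disorder)) {
      d <- inputs$disorder
      sc <- d$score[d$protein_id == ev$host_transcript_a]
      if (length(sc) > 0)
        disordered <- disorder_gate(sc, NULL, config$disorder_residue,
                                    config$disorder_fraction)
    }
    # exon span of exon_a within the host isoform
    seg <- exon_peptide_segment(ev$exon_a, host, gene, genome)
    mapped <- NULL; struct_name <- NA_character_
    if (!disordered) for (nm in names(structures)) {
      m <- map_sequence_to_structure(isoform, structures[[nm]],
                                     config$min_coverage_pct)
      # a usable map must also look homologous, emulating the template
      # search step that precedes mapping in the full protocol
      if (attr(m, "usable") &&
          attr(m, "identity_pct") >= config$map_identity_min_pct) {
        mapped <- m; struct_name <- nm; break
      }
    }
    var_residx <- integer(0)
    if (!is.null(mapped)) {
      iso_pos <- seg$span[1] - 1 + vset$pos_a
      iso_pos <- iso_pos[!is.na(vset$pos_a)]
      var_residx <- mapped$residx[match(iso_pos, mapped$isoform_pos)]
      var_residx <- sort(var_residx[!is.na(var_residx)])
    }
    ev_extra[[i]] <- data.frame(
      n_variable = attr(vset, "count"), mclachlan = mcl$score,
      significant_change = mcl$significant_change,
      disordered = disordered, structure = struct_name,
      n_mapped_variable = length(var_residx),
      variable_residx = paste(var_residx, collapse = ","),
      stringsAsFactors = FALSE)
  }, error = function(e)
    note("event %d (%s): structural stage failed (%s)", i, ev$gene_id,
         conditionMessage(e)))
  if (length(ev_extra) && nrow(events)) {
    filled <- !vapply(ev_extra, is.null, logical(1))
    extra <- do.call(rbind, ev_extra[filled])
    events <- cbind(events[filled, , drop = FALSE], extra)
  }

  ## -- exposure, clusters, proximity, nulls ------------------------------
  exposure_rows <- list(); prox_rows <- list(); cancer_rows <- list()
  null_prox <- list()   # per category: list of per-event indicator samples
  observed_close <- list()
  structural <- which(!is.na(events$structure %||% rep(NA, 0)) &
                        (events$n_mapped_variable %||% 0) >=
                        config$min_cluster)
  for (i in structural) tryCatch({
    ev <- events[i, ]
    nm <- ev$structure
    st <- structures[[nm]]; dm <- dmats[[nm]]; sa <- sasas[[nm]]
    vres <- as.integer(strsplit(ev$variable_residx, ",")[[1]])
    obs_frac <- exposure_fraction(vres, sa)
    rnull <- random_region_null(st, length(vres), sa, n = config$n_null,
                                seed = config$seed + i)
    exposure_rows[[i]] <- data.frame(
      gene_id = ev$gene_id, structure = nm, n_region = length(vres),
      observed_exposure = obs_frac, null_mean = mean(rnull$samples),
      stringsAsFactors = FALSE)
    clusters <- cluster_variable_residues(st, vres, link = config$link,
                                          min_size = config$min_cluster,
                                          dmat = dm)
    cl <- if (length(clusters) > 0) clusters[[1]] else NULL
    sites <- site_tabs[[nm]]
    if (!is.null(cl) && !is.null(sites)) for (cat in unique(sites$category)) {
      sres <- sites$residx[sites$category == cat]
      call <- proximity_call_cluster(cl, sres, st, config$com_cutoff, cat)
      nd <- random_cluster_null(st, cl$size, sres, n = config$n_null,
                                seed = config$seed + 97 * i,
                                growth_cutoff = config$growth_cutoff,
                                com_cutoff = config$com_cutoff, dmat = dm,
                                value = "indicator")
      prox_rows[[length(prox_rows) + 1]] <- data.frame(
        gene_id = ev$gene_id, structure = nm, category = cat,
        mode = call$mode, distance = call$distance,
        is_close = call$is_close, cluster_size = cl$size,
        stringsAsFactors = FALSE)
      null_prox[[cat]] <- c(null_prox[[cat]] %||% list(),
                            list(nd$samples))
      observed_close[[cat]] <- c(observed_close[[cat]] %||% logical(),
                                 call$is_close)
    }
    muts <- mut_tabs[[nm]]
    if (!is.null(muts) && nrow(muts)) {
      cp <- cancer_proximity(st, vres, muts$residx, n_null = config$n_null,
                             seed = config$seed + 31 * i, dmat = dm,
                             residue_cutoff = config$residue_cutoff,
                             cluster_cutoff = config$com_cutoff)
      cancer_rows[[length(cancer_rows) + 1]] <- data.frame(
        gene_id = ev$gene_id, structure = nm,
        residue_close = cp$residue_mode$is_close,
        residue_distance = cp$residue_mode$distance,
        residue_p = cp$residue_mode$p_label,
        cluster_close = cp$cluster_mode$is_close %||% NA,
        cluster_distance = cp$cluster_mode$distance %||% NA_real_,
        cluster_p = cp$cluster_mode$p_label %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }, error = function(e)
    note("event %d: proximity stage failed (%s)", i, conditionMessage(e)))

  ## -- dataset-level tests -----------------------------------------------
  tests <- list()
  exposure <- do.call(rbind, exposure_rows)
  if (!is.null(exposure) && nrow(exposure) >= 5 &&
      any(exposure$observed_exposure != exposure$null_mean)) {
    wt <- tryCatch(wilcoxon_signed_rank(exposure$observed_exposure,
                                        exposure$null_mean),
                   error = function(e) NULL)
    if (!is.null(wt))
      tests$exposure_wilcoxon <- list(statistic = wt$statistic,
                                      p = wt$p_value, n = wt$n)
  }
  for (cat in names(null_prox)) {
    obs <- mean(observed_close[[cat]])
    mat <- do.call(cbind, null_prox[[cat]])      # n_null x n_events
    null_prop <- new_null_distribution(
      sprintf("proportion_close_%s", cat), rowMeans(mat), config$seed)
    zt <- tryCatch(zscore_test(obs, null_prop), error = function(e) NULL)
    tests[[paste0("proximity_", cat)]] <- list(
      observed_proportion = obs, null_mean = mean(null_prop$samples),
      null_sd = stats::sd(null_prop$samples),
      z = if (!is.null(zt)) zt$statistic else NA_real_,
      p = if (!is.null(zt)) zt$p_value else NA_real_,
      n_events = length(observed_close[[cat]]))
  }
  if (!is.null(inputs$gene_sets)) {
    gs <- inputs$gene_sets
    hits <- unique(events$gene_id)
    tabs <- lapply(gs$sets, function(set) {
      a <- length(intersect(set, hits))
      b <- length(setdiff(hits, set))
      cc <- length(setdiff(set, hits))
      d <- length(setdiff(gs$universe, union(set, hits)))
      matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
    })
    tests$enrichment <- fisher_bh_enrichment(tabs)
  }

  report <- structure(list(
    config = config,
    counts = list(n_genes = length(genes), n_events = nrow(events),
                  n_structural = length(structural),
                  n_cassette = if (is.null(cassette)) 0 else nrow(cassette),
                  n_microexons = sum(micro$is_microexon)),
    events = events, cassette = cassette, microexons = micro,
    exposure = exposure, proximity = do.call(rbind, prox_rows),
    cancer = do.call(rbind, cancer_rows), tests = tests, log = log),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' One TSV per stage (events, cassette exons, microexon calls, exposure,
#' proximity calls, cancer proximity) plus a versioned `summary.json`
#' embedding all thresholds, the seed, counts and test results.
#'
#' @param report a `pipeline_report`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name, cols) {
    if (is.null(df) || nrow(df) == 0)
      df <- stats::setNames(data.frame(matrix(ncol = length(cols),
                                              nrow = 0)), cols)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$events, "events.tsv", c("gene_id", "exon_a", "exon_b"))
  wt(report$cassette, "cassette_events.tsv",
     c("gene_id", "long_transcript", "short_transcript", "lost_exon"))
  wt(report$microexons, "microexon_calls.tsv",
     c("gene_id", "exon_id", "length_nt", "is_microexon"))
  wt(report$exposure, "exposure.tsv",
     c("gene_id", "structure", "n_region", "observed_exposure",
       "null_mean"))
  wt(report$proximity, "proximity.tsv",
     c("gene_id", "structure", "category", "mode", "distance", "is_close",
       "cluster_size"))
  wt(report$cancer, "cancer_proximity.tsv",
     c("gene_id", "structure", "residue_close", "residue_distance",
       "residue_p", "cluster_close", "cluster_distance", "cluster_p"))
  summary <- list(schema_version = "1.0", config = report$config,
                  counts = report$counts, tests = report$tests,
                  log = report$log)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
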