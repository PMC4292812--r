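#' Default pipeline configuration
#'
#' A nested list of every tunable of the end-to-end synthetic run: the
#' generator model, the planted-change plan, QC thresholds, fidelity
#' thresholds and resampling sizes. One `seed` governs all stochastic
#' stages via [child_seed()]. Values can be overridden by a YAML config
#' file and/or an `overrides` list; overrides win over the file, the file
#' over the defaults.
#'
#' @return A named list of defaults.
#' @export
default_run_config <- function() {
  list(
    outdir = "pdxmeth_run",
    seed = 1L,
    n_probes = 20000L,
    n_patients = 3L,
    frac_changing = 0.027,
    min_shift = 0.51,
    shared_fraction = 0.86,
    frac_cross_hyb = 0.05,
    detection_p = 0.01,
    bead_min = 3L,
    bead_sample_frac = 0.05,
    drop_sex = TRUE,
    unmeth_upper = 0.31,
    meth_lower = 0.82,
    thresholds_grid = c(0.51, 0.41, 0.31, 0.21),
    enrich_reps = 200L,
    overlap_reps = 1000L)
}

merge_config <- function(base, extra) {
  for (k in names(extra)) base[[k]] <- extra[[k]]
  base
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order — synthesis, probe QC, fidelity
#' statistics, enrichment/overlap — writing every artifact as TSV/BED under
#' `outdir` together with a JSON manifest of all parameters and the master
#' seed, sufficient to regenerate every file. Reruns with the same
#' configuration produce byte-identical numeric outputs.
#'
#' @param config Optional path to a YAML configuration file.
#' @param overrides Named list of configuration overrides (e.g.
#'   `list(n_probes = 5000, seed = 7)`); see [default_run_config()].
#' @return Invisibly, a list with the output paths and the in-memory key
#'   results (`qc`, `pairs`, `reversal`, `enrichment`, `overlap`).
#' @export
run_pipeline <- function(config = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- merge_config(cfg, yaml::read_yaml(config))
  }
  cfg <- merge_config(cfg, overrides)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(cfg$outdir, ...)

  ## synthesis
  ann <- generate_annotation(cfg$n_probes, seed = child_seed(cfg$seed, "ann"))
  model <- methylome_model(n_probes = cfg$n_probes,
                           seed = child_seed(cfg$seed, "pool"))
  patients <- generate_pool(model, cfg$n_patients, ann, sample_prefix = "T")
  colnames(patients) <- paste0("T", seq_len(cfg$n_patients), "P")
  beta <- patients
  planted <- list()
  for (k in seq_len(cfg$n_patients)) {
    plan <- pair_plan(frac_changing = cfg$frac_changing,
                      min_shift = cfg$min_shift,
                      shared_fraction = cfg$shared_fraction,
                      seed = child_seed(cfg$seed, "pair", k))
    pdx <- generate_pdx_pair(patients[, k], plan)
    xid <- paste0("T", k, "X1")
    beta <- cbind(beta, pdx$beta)
    colnames(beta)[ncol(beta)] <- xid
    planted[[xid]] <- pdx$planted
  }
  detp <- generate_detp_matrix(cfg$n_probes, ncol(beta),
                               seed = child_seed(cfg$seed, "detp"),
                               probe_ids = ann$probe_id,
                               sample_ids = colnames(beta))
  beads <- generate_bead_matrix(cfg$n_probes, ncol(beta),
                                seed = child_seed(cfg$seed, "beads"),
                                probe_ids = ann$probe_id,
                                sample_ids = colnames(beta))
  mouse <- generate_mouse_qc(cfg$n_probes, cfg$frac_cross_hyb,
                             seed = child_seed(cfg$seed, "mouse"),
                             probe_ids = ann$probe_id)
  write_annotation_tsv(ann, path("annotation.tsv"))
  write_beta_tsv(beta, path("beta_raw.tsv"))
  write_matrix_tsv(detp, path("detp.tsv"))
  write_matrix_tsv(beads, path("beads.tsv"))
  write_matrix_tsv(cbind(mouse_kidney = mouse), path("mouse_detp.tsv"))

  ## probe QC
  th <- qc_thresholds(detection_p = cfg$detection_p, bead_min = cfg$bead_min,
                      bead_sample_frac = cfg$bead_sample_frac,
                      drop_sex = cfg$drop_sex)
  qc <- apply_qc(beta, detp = detp, beads = beads, detp_mouse = mouse,
                 annotation = ann, thresholds = th)
  fwrite(data.frame(rule = names(qc$report$removed_by_rule),
                    removed = lengths(qc$report$removed_by_rule)),
         path("qc_report.tsv"), sep = "\t")
  writeLines(qc$report$retained, path("retained_probes.txt"))
  for (rule in names(qc$report$removed_by_rule))
    writeLines(qc$report$removed_by_rule[[rule]],
               path(sprintf("removed_%s.txt", rule)))
  write_beta_tsv(qc$beta, path("beta_qc.tsv"))

  ## fidelity
  thr <- reversal_threshold(cfg$unmeth_upper, cfg$meth_lower)
  pair_ids <- data.frame(patient = paste0("T", seq_len(cfg$n_patients), "P"),
                         xenograft = paste0("T", seq_len(cfg$n_patients),
                                            "X1"))
  pairs <- lapply(seq_len(nrow(pair_ids)), function(k)
    delta_beta(qc$beta, pair_ids$patient[k], pair_ids$xenograft[k]))
  rev <- lapply(pairs, reversed_fraction, threshold = thr)
  reversal <- data.frame(patient = pair_ids$patient,
                         xenograft = pair_ids$xenograft,
                         count = vapply(rev, `[[`, numeric(1), "count"),
                         percent = vapply(rev, `[[`, numeric(1), "percent"))
  fwrite(reversal, path("reversal_report.tsv"), sep = "\t")
  fwrite(threshold_sensitivity(pairs, cfg$thresholds_grid),
         path("threshold_sensitivity.tsv"), sep = "\t")
  for (k in seq_along(pairs))
    if (length(rev[[k]]$probes))
      write_bed(rev[[k]]$probes, ann,
                path(sprintf("reversed_%s.bed", pair_ids$xenograft[k])),
                delta = pairs[[k]]$delta)

  ## enrichment & overlap
  target <- rev[[1]]$probes
  enr <- resampling_enrichment(target, qc$report$retained, ann,
                               n_reps = cfg$enrich_reps,
                               seed = child_seed(cfg$seed, "enrich"))
  fwrite(enr, path("enrichment.tsv"), sep = "\t")
  sets <- lapply(rev, `[[`, "probes")
  names(sets) <- pair_ids$xenograft
  ovl_sig <- overlap_significance(sets, qc$report$retained,
                                  n_reps = cfg$overlap_reps,
                                  seed = child_seed(cfg$seed, "overlap"))
  ovl_pct <- overlap_percentages(sets)
  fwrite(cbind(ovl_pct$pairwise,
               full_shared = ovl_pct$full_shared,
               full_percent = ovl_pct$full_percent,
               overlap_p = ovl_sig$empirical_p),
         path("overlap_report.tsv"), sep = "\t")

  ## provenance manifest
  jsonlite::write_json(
    list(package = "pdxmeth",
         version = as.character(utils::packageVersion("pdxmeth")),
         config = cfg),
    path("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(outdir = cfg$outdir, config = cfg, qc = qc, pairs = pairs,
                 reversal = reversal, enrichment = enr,
                 overlap = list(significance = ovl_sig,
                                percentages = ovl_pct),
                 planted = planted, annotation = ann))
}
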