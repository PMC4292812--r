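#' @useDynLib pdxmeth, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif plogis qlogis quantile sd setNames
#' @importFrom utils head
NULL

GENOMIC_FEATURES <- c("TSS1500", "TSS200", "5UTR", "1stExon",
                      "Body", "3UTR", "IGR")
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "None")
PROMOTER_FEATURES <- c("TSS1500", "TSS200", "5UTR", "1stExon")

#' Default per-category methylation-state mixture
#'
#' One row per (genomic feature, CpG-island relation) combination, giving the
#' mixture weights of the three probe states (unmethylated, intermediate,
#' methylated). The defaults emulate the canonical 450K picture: CpG islands —
#' especially at promoters — are predominantly unmethylated, while gene bodies
#' and intergenic open-sea probes are predominantly methylated.
#'
#' @return A data.frame with columns `feature`, `island`, `w_unmeth`,
#'   `w_inter`, `w_meth`; weights sum to 1 in every row.
#' @export
default_feature_mix <- function() {
  grid <- expand.grid(feature = GENOMIC_FEATURES, island = ISLAND_RELATIONS,
                      stringsAsFactors = FALSE)
  w <- t(vapply(seq_len(nrow(grid)), function(i) {
    prom <- grid$feature[i] %in% PROMOTER_FEATURES
    switch(grid$island[i],
      Island = if (prom) c(0.95, 0.03, 0.02) else c(0.80, 0.10, 0.10),
      Shore  = if (prom) c(0.70, 0.15, 0.15) else c(0.35, 0.20, 0.45),
      if (prom) c(0.40, 0.15, 0.45) else c(0.10, 0.10, 0.80))
  }, numeric(3)))
  data.frame(grid, w_unmeth = w[, 1], w_inter = w[, 2], w_meth = w[, 3])
}

#' Synthetic 450K methylome model
#'
#' Parameters of the beta-value generator. Probes are assigned a methylation
#' state (unmethylated / intermediate / methylated) from the per-category
#' mixture in `feature_mix`; each probe gets a logit-scale baseline centred on
#' the state mode with between-probe spread `probe_sd`, and each sample adds
#' logit-scale Gaussian noise with `sample_noise_sd` before mapping back
#' through the inverse logit. Working on the logit scale keeps every value
#' strictly inside (0, 1) without clipping artefacts.
#'
#' @param n_probes Number of probes.
#' @param feature_mix Data.frame as returned by [default_feature_mix()].
#' @param unmeth_mode,meth_mode,inter_mode Beta-scale modes of the three
#'   probe states.
#' @param probe_sd Between-probe logit-scale SD around the state mode.
#' @param sample_noise_sd Per-sample logit-scale noise SD, governing
#'   cross-sample variability at a probe.
#' @param seed Integer RNG seed; the generator is a pure function of
#'   (parameters, seed).
#' @return An object of class `methylome_model`.
#' @export
methylome_model <- function(n_probes = 20000L,
                            feature_mix = default_feature_mix(),
                            unmeth_mode = 0.10, meth_mode = 0.90,
                            inter_mode = 0.50,
                            probe_sd = 0.7, sample_noise_sd = 0.3,
                            seed = 1L) {
  check_count(n_probes, "n_probes", min = 1)
  for (nm in c("unmeth_mode", "meth_mode", "inter_mode"))
    check_fraction(get(nm), nm, lo = 1e-6, hi = 1 - 1e-6)
  if (!is.numeric(probe_sd) || !is.finite(probe_sd) || probe_sd < 0)
    stop("'probe_sd' must be a finite non-negative number")
  if (!is.numeric(sample_noise_sd) || !is.finite(sample_noise_sd) ||
      sample_noise_sd < 0)
    stop("'sample_noise_sd' must be a finite non-negative number")
  stopifnot(is.data.frame(feature_mix),
            all(c("feature", "island", "w_unmeth", "w_inter", "w_meth") %in%
                  names(feature_mix)))
  wsum <- feature_mix$w_unmeth + feature_mix$w_inter + feature_mix$w_meth
  if (any(abs(wsum - 1) > 1e-9))
    stop("feature_mix mixture weights must sum to 1 in every row")
  structure(list(n_probes = as.integer(n_probes), feature_mix = feature_mix,
                 unmeth_mode = unmeth_mode, meth_mode = meth_mode,
                 inter_mode = inter_mode, probe_sd = probe_sd,
                 sample_noise_sd = sample_noise_sd, seed = as.integer(seed)),
            class = "methylome_model")
}

#' Generate a synthetic probe annotation manifest
#'
#' Emulates a 450K-style manifest: chromosome and 1-based position, genomic
#' feature (TSS1500, TSS200, 5UTR, 1stExon, Body, 3UTR, IGR) and CpG-island
#' relation (Island, Shore, Shelf, None). Island relation is sampled
#' conditionally on the feature so that islands concentrate at promoters, as
#' on the real array.
#'
#' @param n_probes Number of probes.
#' @param seed RNG seed.
#' @param include_sex If `TRUE` a small fraction of probes is placed on
#'   chrX/chrY.
#' @return A data.frame with columns `probe_id`, `chrom`, `pos`, `feature`,
#'   `island_relation`.
#' @export
generate_annotation <- function(n_probes = 20000L, seed = 1L,
                                include_sex = TRUE) {
  check_count(n_probes, "n_probes", min = 1)
  set.seed(seed)
  autosomes <- paste0("chr", 1:22)
  chroms <- c(autosomes, if (include_sex) c("chrX", "chrY"))
  chrom_w <- c(seq(2.5, 0.6, length.out = 22), if (include_sex) c(0.8, 0.06))
  chrom <- sample(chroms, n_probes, replace = TRUE, prob = chrom_w)
  pos <- sample.int(2.4e8, n_probes, replace = TRUE)
  feat_w <- c(TSS1500 = 0.14, TSS200 = 0.13, `5UTR` = 0.08, `1stExon` = 0.06,
              Body = 0.31, `3UTR` = 0.03, IGR = 0.25)
  feature <- sample(GENOMIC_FEATURES, n_probes, replace = TRUE, prob = feat_w)
  island <- character(n_probes)
  prom <- feature %in% PROMOTER_FEATURES
  island[prom] <- sample(ISLAND_RELATIONS, sum(prom), replace = TRUE,
                         prob = c(0.55, 0.25, 0.07, 0.13))
  island[!prom] <- sample(ISLAND_RELATIONS, sum(!prom), replace = TRUE,
                          prob = c(0.14, 0.19, 0.11, 0.56))
  data.frame(probe_id = sprintf("cg%08d", seq_len(n_probes)),
             chrom = chrom, pos = pos, feature = feature,
             island_relation = island, stringsAsFactors = FALSE)
}

#' Generate a pool of synthetic methylomes
#'
#' Draws `n_samples` beta-value columns from a [methylome_model()], using the
#' annotation to pick each probe's state mixture. Identical seed and
#' parameters reproduce the matrix bit-for-bit. The per-probe state
#' assignment is attached as attribute `"probe_state"` (levels `"unmeth"`,
#' `"inter"`, `"meth"`) so downstream tests can assert on the generating
#' truth.
#'
#' @param model A `methylome_model`.
#' @param n_samples Number of samples (columns).
#' @param annotation Manifest covering `model$n_probes` probes, as from
#'   [generate_annotation()].
#' @param sample_prefix Prefix for column names.
#' @return A numeric matrix (probes x samples) with values in (0, 1), probe
#'   ids as rownames.
#' @export
generate_pool <- function(model, n_samples, annotation,
                          sample_prefix = "S") {
  stopifnot(inherits(model, "methylome_model"))
  check_count(n_samples, "n_samples", min = 1)
  if (nrow(annotation) != model$n_probes)
    stop("annotation must cover exactly model$n_probes probes")
  set.seed(model$seed)
  mix <- model$feature_mix
  key <- paste(annotation$feature, annotation$island_relation)
  mixkey <- paste(mix$feature, mix$island)
  row <- match(key, mixkey)
  if (anyNA(row))
    stop("annotation contains feature/island combinations absent from ",
         "feature_mix: ", paste(unique(key[is.na(row)]), collapse = ", "))
  w <- as.matrix(mix[row, c("w_unmeth", "w_inter", "w_meth")])
  u <- runif(model$n_probes)
  state <- ifelse(u < w[, 1], "unmeth",
                  ifelse(u < w[, 1] + w[, 2], "inter", "meth"))
  mode_logit <- qlogis(c(unmeth = model$unmeth_mode, inter = model$inter_mode,
                         meth = model$meth_mode))[state]
  # intermediate probes get a tighter spread so they stay mid-range
  psd <- ifelse(state == "inter", model$probe_sd * 0.6, model$probe_sd)
  baseline <- mode_logit + rnorm(model$n_probes, sd = psd)
  out <- matrix(NA_real_, model$n_probes, n_samples,
                dimnames = list(annotation$probe_id,
                                paste0(sample_prefix, seq_len(n_samples))))
  # fill in fixed-size column blocks to bound peak memory at full scale
  block <- 250L
  for (j0 in seq(1L, n_samples, by = block)) {
    j <- j0:min(j0 + block - 1L, n_samples)
    noise <- if (model$sample_noise_sd > 0)
      matrix(rnorm(model$n_probes * length(j), sd = model$sample_noise_sd),
             model$n_probes, length(j))
    else 0
    out[, j] <- plogis(baseline + noise)
  }
  attr(out, "probe_state") <- setNames(state, annotation$probe_id)
  out
}

#' Plan of planted xenografting-associated methylation changes
#'
#' Describes how a synthetic PDX methylome is derived from its patient
#' tumour: a tumour-specific random fraction of probes (default 2.7%) is
#' shifted by at least `min_shift` in beta (default 0.51, the reversed
#' methylation threshold), split between gains and losses by
#' `direction_balance`. `shared_fraction` controls how much of the changed
#' set is common between sibling PDXs grown from the same patient tumour
#' (default 0.86).
#'
#' @param frac_changing Fraction of probes planted as changed.
#' @param min_shift Minimum planted absolute beta shift, in (0, 1].
#' @param direction_balance Fraction of planted changes that are up-shifts
#'   (methylation gains in the xenograft).
#' @param shared_fraction Fraction of changed probes shared between sibling
#'   PDXs of one tumour.
#' @param seed RNG seed.
#' @return An object of class `pair_plan`.
#' @export
pair_plan <- function(frac_changing = 0.027, min_shift = 0.51,
                      direction_balance = 0.5, shared_fraction = 0.86,
                      seed = 1L) {
  check_fraction(frac_changing, "frac_changing")
  check_fraction(min_shift, "min_shift", lo = 1e-12)
  check_fraction(direction_balance, "direction_balance")
  check_fraction(shared_fraction, "shared_fraction")
  structure(list(frac_changing = frac_changing, min_shift = min_shift,
                 direction_balance = direction_balance,
                 shared_fraction = shared_fraction, seed = as.integer(seed)),
            class = "pair_plan")
}

# Plant n_change shifts of >= min_shift into a beta vector. Direction
# feasibility is decided before drawing (up-shifts only where
# beta <= 1 - min_shift, down where beta >= min_shift) so every planted
# change genuinely reaches the threshold without clipping. Assumes the RNG
# has been seeded by the caller.
plant_changes <- function(beta, n_change, min_shift, direction_balance,
                          exclude = integer(0)) {
  n_up <- round(direction_balance * n_change)
  n_down <- n_change - n_up
  up_cand <- setdiff(which(beta <= 1 - min_shift), exclude)
  down_cand <- setdiff(which(beta >= min_shift), exclude)
  if (length(up_cand) < n_up || length(down_cand) < n_down)
    stop(sprintf(paste0("infeasible plan: need %d up and %d down shifts but ",
                        "only %d and %d feasible probes are available"),
                 n_up, n_down, length(up_cand), length(down_cand)),
         call. = FALSE)
  up_idx <- if (n_up > 0) sample(up_cand, n_up) else integer(0)
  down_cand <- setdiff(down_cand, up_idx)
  if (length(down_cand) < n_down)
    stop(sprintf("infeasible plan: %d down-shift candidates for %d required",
                 length(down_cand), n_down), call. = FALSE)
  down_idx <- if (n_down > 0) sample(down_cand, n_down) else integer(0)
  out <- beta
  if (n_up > 0)
    out[up_idx] <- beta[up_idx] +
      runif(n_up, min_shift, 1 - beta[up_idx])
  if (n_down > 0)
    out[down_idx] <- beta[down_idx] -
      runif(n_down, min_shift, beta[down_idx])
  planted <- data.frame(
    probe = c(up_idx, down_idx),
    probe_id = names(beta)[c(up_idx, down_idx)] %||% NA_character_,
    direction = rep(c(1L, -1L), c(n_up, n_down)),
    stringsAsFactors = FALSE)
  list(beta = out, planted = planted[order(planted$probe), ])
}

#' Derive a synthetic PDX methylome from a patient tumour column
#'
#' Copies the patient beta vector and plants `round(frac_changing * n)`
#' changes of at least `min_shift`, returning the modified vector together
#' with the planted probe set as ground truth. Unplanted probes are left
#' exactly unchanged, so threshold-based reversal detection recovers the
#' planted set exactly.
#'
#' @param patient Named numeric vector of patient beta values in \[0, 1\].
#' @param plan A [pair_plan()].
#' @return A list with elements `beta` (the xenograft column) and `planted`
#'   (data.frame `probe`, `probe_id`, `direction` where direction +1 means a
#'   methylation gain in the xenograft).
#' @export
generate_pdx_pair <- function(patient, plan) {
  stopifnot(inherits(plan, "pair_plan"), is.numeric(patient))
  if (any(patient < 0 | patient > 1, na.rm = TRUE))
    stop("patient beta values must lie in [0, 1]")
  set.seed(plan$seed)
  n_change <- round(plan$frac_changing * length(patient))
  if (n_change == 0)
    return(list(beta = patient,
                planted = data.frame(probe = integer(0),
                                     probe_id = character(0),
                                     direction = integer(0))))
  plant_changes(patient, n_change, plan$min_shift, plan$direction_balance)
}

#' Generate sibling PDXs sharing most of their planted changes
#'
#' Sibling xenografts grown from the same patient tumour share a common core
#' of `shared_fraction` of their changed probes (tumour-specific changes);
#' the remainder is private to each sibling. All siblings carry the same
#' number of planted changes.
#'
#' @inheritParams generate_pdx_pair
#' @param n_siblings Number of sibling PDXs (>= 2).
#' @return A list of `n_siblings` elements, each as in [generate_pdx_pair()].
#' @export
generate_pdx_siblings <- function(patient, plan, n_siblings = 2L) {
  stopifnot(inherits(plan, "pair_plan"))
  check_count(n_siblings, "n_siblings", min = 2)
  set.seed(plan$seed)
  n_change <- round(plan$frac_changing * length(patient))
  n_shared <- round(plan$shared_fraction * n_change)
  shared <- plant_changes(patient, n_shared, plan$min_shift,
                          plan$direction_balance)
  lapply(seq_len(n_siblings), function(i) {
    priv <- plant_changes(shared$beta, n_change - n_shared, plan$min_shift,
                          plan$direction_balance,
                          exclude = shared$planted$probe)
    planted <- rbind(shared$planted, priv$planted)
    list(beta = priv$beta, planted = planted[order(planted$probe), ])
  })
}

#' Generate a mouse-only detection p-value vector
#'
#' Emulates the 450K quality-control sample from mouse tissue used to flag
#' probes that cross-hybridise to host DNA: exactly
#' `round(frac_cross_hyb * n_probes)` probes receive a detection p-value
#' below 0.01 (detected in mouse), all others at or above 0.01.
#'
#' @param n_probes Number of probes.
#' @param frac_cross_hyb Fraction of probes detectable in the mouse sample.
#' @param seed RNG seed.
#' @param probe_ids Optional probe names for the result.
#' @return A named numeric vector of detection p-values in \[0, 1\].
#' @export
generate_mouse_qc <- function(n_probes, frac_cross_hyb, seed = 1L,
                              probe_ids = sprintf("cg%08d",
                                                  seq_len(n_probes))) {
  check_count(n_probes, "n_probes", min = 1)
  check_fraction(frac_cross_hyb, "frac_cross_hyb")
  set.seed(seed)
  n_flag <- round(frac_cross_hyb * n_probes)
  p <- runif(n_probes, min = 0.011, max = 1)
  if (n_flag > 0) {
    idx <- sample.int(n_probes, n_flag)
    p[idx] <- runif(n_flag, min = 0, max = 0.0099)
  }
  setNames(p, probe_ids)
}

#' Generate a clean-ish human detection p-value matrix
#'
#' Most entries are well below the 0.01 detection cutoff; a small fraction of
#' probes fail detection in one random sample. Plumbing for exercising the
#' quality-control stage.
#'
#' @param n_probes,n_samples Matrix dimensions.
#' @param frac_fail Fraction of probes given one failing sample.
#' @param seed RNG seed.
#' @param probe_ids,sample_ids Dimension names.
#' @return Numeric matrix of detection p-values.
#' @export
generate_detp_matrix <- function(n_probes, n_samples, frac_fail = 0.002,
                                 seed = 1L,
                                 probe_ids = sprintf("cg%08d",
                                                     seq_len(n_probes)),
                                 sample_ids = paste0("S",
                                                     seq_len(n_samples))) {
  check_fraction(frac_fail, "frac_fail")
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0, 0.005), n_probes, n_samples,
              dimnames = list(probe_ids, sample_ids))
  n_fail <- round(frac_fail * n_probes)
  if (n_fail > 0) {
    rows <- sample.int(n_probes, n_fail)
    cols <- sample.int(n_samples, n_fail, replace = TRUE)
    m[cbind(rows, cols)] <- runif(n_fail, 0.011, 1)
  }
  m
}

#' Generate a bead-count matrix
#'
#' Bead counts around 8-20 with a small fraction of probes given a low-bead
#' (< 3) sample; plumbing for the bead-cutoff quality-control rule.
#'
#' @inheritParams generate_detp_matrix
#' @param frac_low Fraction of probes given one low-bead sample.
#' @return Integer matrix of bead counts.
#' @export
generate_bead_matrix <- function(n_probes, n_samples, frac_low = 0.002,
                                 seed = 1L,
                                 probe_ids = sprintf("cg%08d",
                                                     seq_len(n_probes)),
                                 sample_ids = paste0("S",
                                                     seq_len(n_samples))) {
  check_fraction(frac_low, "frac_low")
  set.seed(seed)
  m <- matrix(sample(8:20, n_probes * n_samples, replace = TRUE),
              n_probes, n_samples, dimnames = list(probe_ids, sample_ids))
  n_low <- round(frac_low * n_probes)
  if (n_low > 0) {
    rows <- sample.int(n_probes, n_low)
    cols <- sample.int(n_samples, n_low, replace = TRUE)
    m[cbind(rows, cols)] <- sample(0:2, n_low, replace = TRUE)
  }
  m
}

#' Lazy methylome column sampler
#'
#' Builds the per-probe state and baseline of a [methylome_model()] once
#' (consuming the model seed) and returns a function that materialises any
#' number of fresh sample columns on demand from the current RNG stream.
#' Columns drawn this way are distributed exactly as columns of
#' [generate_pool()]; the sampler exists so that very large probe universes
#' can be simulated without holding a full methylome pool in memory —
#' drawing n fresh columns is equivalent to drawing n distinct samples from
#' an arbitrarily large pool.
#'
#' Callers are responsible for seeding the RNG before each draw if
#' reproducibility is required.
#'
#' @inheritParams generate_pool
#' @return A function `f(n)` returning a probes x n beta matrix.
#' @export
methylome_sampler <- function(model, annotation) {
  stopifnot(inherits(model, "methylome_model"))
  if (nrow(annotation) != model$n_probes)
    stop("annotation must cover exactly model$n_probes probes")
  set.seed(model$seed)
  mix <- model$feature_mix
  key <- paste(annotation$feature, annotation$island_relation)
  row <- match(key, paste(mix$feature, mix$island))
  if (anyNA(row))
    stop("annotation contains feature/island combinations absent from ",
         "feature_mix")
  w <- as.matrix(mix[row, c("w_unmeth", "w_inter", "w_meth")])
  u <- runif(model$n_probes)
  state <- ifelse(u < w[, 1], "unmeth",
                  ifelse(u < w[, 1] + w[, 2], "inter", "meth"))
  mode_logit <- qlogis(c(unmeth = model$unmeth_mode, inter = model$inter_mode,
                         meth = model$meth_mode))[state]
  psd <- ifelse(state == "inter", model$probe_sd * 0.6, model$probe_sd)
  baseline <- mode_logit + rnorm(model$n_probes, sd = psd)
  n_probes <- model$n_probes
  noise_sd <- model$sample_noise_sd
  ids <- annotation$probe_id
  function(n) {
    out <- matrix(NA_real_, n_probes, n,
                  dimnames = list(ids, paste0("S", seq_len(n))))
    for (j in seq_len(n))
      out[, j] <- plogis(baseline +
                           if (noise_sd > 0) rnorm(n_probes, sd = noise_sd)
                           else 0)
    out
  }
}

READ_CLASSES <- c("human_only", "mouse_only", "both", "neither")

#' Generate synthetic dual-genome read-pair records
#'
#' Draws `n_pairs` read pairs with multinomially distributed alignment
#' classes over human-only, mouse-only, both-genomes and neither-genome.
#' Fixtures for the xenograft read filter; they can be written as two
#' name-matched SAM files with [write_read_records_sam()].
#'
#' @param n_pairs Number of read pairs.
#' @param class_probs Numeric 4-vector of probabilities over
#'   `c("human_only", "mouse_only", "both", "neither")`; must sum to 1
#'   (tolerance 1e-9).
#' @param seed RNG seed.
#' @return A data.frame with columns `read_id`, `class`, `human_aligned`,
#'   `mouse_aligned`.
#' @export
generate_read_records <- function(n_pairs,
                                  class_probs = c(0.7, 0.1, 0.15, 0.05),
                                  seed = 1L) {
  check_count(n_pairs, "n_pairs", min = 1)
  if (length(class_probs) != 4L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop("'class_probs' must be 4 non-negative probabilities summing to 1")
  set.seed(seed)
  cls <- sample(READ_CLASSES, n_pairs, replace = TRUE, prob = class_probs)
  data.frame(read_id = sprintf("rp%07d", seq_len(n_pairs)),
             class = cls,
             human_aligned = cls %in% c("human_only", "both"),
             mouse_aligned = cls %in% c("mouse_only", "both"),
             stringsAsFactors = FALSE)
}

# One SAM line per mate. Aligned pairs get proper-pair primary alignments;
# pairs not aligned to the genome are emitted as both-mates-unmapped records
# so every read name appears in both files, as real dual alignments do.
sam_pair_lines <- function(id, i, aligned, ref) {
  seq1 <- strrep("A", 50)
  if (aligned) {
    pos1 <- 1000 + 10 * i
    pos2 <- pos1 + 150
    c(paste(id, 99L, ref, pos1, 60L, "50M", "=", pos2, 200, seq1, "*",
            sep = "\t"),
      paste(id, 147L, ref, pos2, 60L, "50M", "=", pos1, -200, seq1, "*",
            sep = "\t"))
  } else {
    c(paste(id, 77L, "*", 0L, 0L, "*", "*", 0L, 0L, seq1, "*", sep = "\t"),
      paste(id, 141L, "*", 0L, 0L, "*", "*", 0L, 0L, seq1, "*", sep = "\t"))
  }
}

#' Write read-pair records as two name-matched SAM files
#'
#' Produces one SAM file per genome (graft = human, host = mouse). A record
#' aligned to a genome is written as a properly paired primary alignment;
#' otherwise the pair is written as unmapped so the read name still appears
#' in both files. The files round-trip through [ingest_alignments()] to the
#' same classes.
#'
#' @param records As from [generate_read_records()].
#' @param graft_path,host_path Output SAM paths.
#' @return Invisibly, `c(graft_path, host_path)`.
#' @export
write_read_records_sam <- function(records, graft_path, host_path) {
  stopifnot(all(c("read_id", "human_aligned", "mouse_aligned") %in%
                  names(records)))
  hdr <- function(ref) c("@HD\tVN:1.6\tSO:queryname",
                         sprintf("@SQ\tSN:%s\tLN:100000000", ref))
  graft <- unlist(lapply(seq_len(nrow(records)), function(i)
    sam_pair_lines(records$read_id[i], i, records$human_aligned[i], "chrH")))
  host <- unlist(lapply(seq_len(nrow(records)), function(i)
    sam_pair_lines(records$read_id[i], i, records$mouse_aligned[i], "chrM")))
  writeLines(c(hdr("chrH"), graft), graft_path)
  writeLines(c(hdr("chrM"), host), host_path)
  invisible(c(graft_path, host_path))
}
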