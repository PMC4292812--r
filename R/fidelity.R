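#' Reversed-methylation threshold
#'
#' The minimum change in beta expected when a CpG goes from fully
#' unmethylated to fully methylated or vice versa. With the published
#' bounds — 95% of fully unmethylated probes at beta <= 0.31 and fully
#' methylated probes at beta >= 0.82 — the threshold is
#' 0.82 - 0.31 = 0.51.
#'
#' @param unmeth_upper Upper beta bound of the fully unmethylated state.
#' @param meth_lower Lower beta bound of the fully methylated state.
#' @return An object of class `reversal_threshold` with fields
#'   `unmeth_upper`, `meth_lower` and `threshold`.
#' @examples
#' reversal_threshold()$threshold # 0.51
#' @export
reversal_threshold <- function(unmeth_upper = 0.31, meth_lower = 0.82) {
  check_fraction(unmeth_upper, "unmeth_upper")
  check_fraction(meth_lower, "meth_lower")
  if (meth_lower <= unmeth_upper)
    stop("degenerate calibration: methylated lower bound (", meth_lower,
         ") must exceed unmethylated upper bound (", unmeth_upper, ")",
         call. = FALSE)
  structure(list(unmeth_upper = unmeth_upper, meth_lower = meth_lower,
                 threshold = meth_lower - unmeth_upper),
            class = "reversal_threshold")
}

#' Calibrate the reversal threshold from reference beta distributions
#'
#' Given beta values of probes known to be fully unmethylated and fully
#' methylated, takes the `coverage` quantile of the unmethylated values and
#' the `1 - coverage` quantile of the methylated values (nearest-rank,
#' type-1 quantiles, unambiguous on small vectors) and returns their
#' difference as the minimum beta change for a full methylation reversal.
#'
#' @param unmeth_betas,meth_betas Non-empty numeric vectors in \[0, 1\].
#' @param coverage Coverage fraction (default 0.95).
#' @return A [reversal_threshold()].
#' @export
calibrate_threshold <- function(unmeth_betas, meth_betas, coverage = 0.95) {
  if (!length(unmeth_betas) || !length(meth_betas))
    stop("both calibration vectors must be non-empty")
  stopifnot(all(unmeth_betas >= 0 & unmeth_betas <= 1),
            all(meth_betas >= 0 & meth_betas <= 1))
  check_fraction(coverage, "coverage", lo = 0.5, hi = 1)
  # nearest-rank quantile x_(ceil(p n)), with a fuzz guarding against
  # floating-point products like 0.05 * 100 landing just above the integer
  nearest_rank <- function(x, p) {
    s <- sort(x)
    s[min(length(s), max(1L, as.integer(ceiling(p * length(s) - 1e-9))))]
  }
  reversal_threshold(unmeth_upper = nearest_rank(unmeth_betas, coverage),
                     meth_lower = nearest_rank(meth_betas, 1 - coverage))
}

#' Per-probe beta difference for one patient/xenograft pair
#'
#' Computes delta-beta = beta(patient) - beta(xenograft) at every probe of
#' the (QC-retained) matrix. The sign convention is fixed as patient minus
#' xenograft; swapping the two samples negates the vector.
#'
#' @param beta Beta matrix with both samples as columns.
#' @param patient_id,xenograft_id Column names of the two samples.
#' @return An object of class `pair_delta` with fields `patient_id`,
#'   `xenograft_id` and the named `delta` vector.
#' @export
delta_beta <- function(beta, patient_id, xenograft_id) {
  stopifnot(is.matrix(beta))
  for (id in c(patient_id, xenograft_id))
    if (!id %in% colnames(beta))
      stop(sprintf("sample '%s' not found in the beta matrix", id),
           call. = FALSE)
  structure(list(patient_id = patient_id, xenograft_id = xenograft_id,
                 delta = beta[, patient_id] - beta[, xenograft_id]),
            class = "pair_delta")
}

as_threshold_value <- function(threshold) {
  if (inherits(threshold, "reversal_threshold")) threshold <- threshold$threshold
  check_fraction(threshold, "threshold", lo = 1e-12)
  threshold
}

#' Probes reversing their methylation state in a xenograft
#'
#' Counts probes whose absolute beta change between patient and xenograft
#' meets or exceeds the reversal threshold (boundary inclusive: a change of
#' exactly the threshold counts). The percentage is relative to the number
#' of retained probes in the pair.
#'
#' @param pair A [delta_beta()] result.
#' @param threshold A [reversal_threshold()] or a bare numeric in (0, 1].
#' @return A list with `count`, `percent` and `probes` (ids, or indices for
#'   unnamed deltas).
#' @export
reversed_fraction <- function(pair, threshold = reversal_threshold()) {
  stopifnot(inherits(pair, "pair_delta"))
  thr <- as_threshold_value(threshold)
  hit <- abs(pair$delta) >= thr
  probes <- names(pair$delta)[hit] %||% which(hit)
  list(count = sum(hit), percent = 100 * sum(hit) / length(pair$delta),
       probes = probes)
}

#' Histogram of absolute beta differences
#'
#' Bins |delta-beta| into `bin_width` increments (default 1%) over \[0, 1\].
#' Bins are half-open \[lo, hi) with the final bin closed; counts sum to the
#' number of retained probes.
#'
#' @param pair A [delta_beta()] result.
#' @param bin_width Bin width; must divide 1 evenly.
#' @return A data.frame with `bin_lo`, `bin_hi`, `count`, `percent`.
#' @export
delta_histogram <- function(pair, bin_width = 0.01) {
  stopifnot(inherits(pair, "pair_delta"))
  n_bins <- round(1 / bin_width)
  idx <- beta_bin_index(abs(pair$delta), bin_width)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lo = (seq_len(n_bins) - 1) * bin_width,
             bin_hi = seq_len(n_bins) * bin_width,
             count = counts,
             percent = 100 * counts / length(pair$delta))
}

#' Mean changing-probe percentage across pairs at several thresholds
#'
#' For each threshold, the mean over pairs of the reversed-probe percentage
#' together with its standard error of the mean. Used to assess how
#' sensitive the changing-probe estimate is to the choice of the reversal
#' threshold.
#'
#' @param pairs Non-empty list of [delta_beta()] results.
#' @param thresholds Numeric vector of thresholds.
#' @return A data.frame with `threshold`, `mean_percent`, `sem`.
#' @export
threshold_sensitivity <- function(pairs,
                                  thresholds = c(0.51, 0.41, 0.31, 0.21)) {
  if (!length(pairs)) stop("'pairs' must contain at least one pair")
  res <- lapply(thresholds, function(thr) {
    pct <- vapply(pairs, function(p) reversed_fraction(p, thr)$percent,
                  numeric(1))
    c(mean = mean(pct),
      sem = if (length(pct) > 1) sd(pct) / sqrt(length(pct)) else 0)
  })
  data.frame(threshold = thresholds,
             mean_percent = vapply(res, `[[`, numeric(1), "mean"),
             sem = vapply(res, `[[`, numeric(1), "sem"))
}

#' Per-sample, per-feature beta-value distributions
#'
#' Bins each sample's beta values into `bin_width` increments, separately
#' for every genomic feature, every CpG-island relation, and a
#' "Whole Genome" category covering all probes. Percentages within each
#' (sample, category) histogram sum to 100.
#'
#' @param beta Beta matrix restricted to the retained probes.
#' @param annotation Manifest covering the matrix rows.
#' @param bin_width Bin width; must divide 1 evenly.
#' @return A data.frame with `sample`, `category`, `bin_lo`, `bin_hi`,
#'   `count`, `percent`.
#' @export
feature_histograms <- function(beta, annotation, bin_width = 0.01) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("annotation does not cover all retained probes")
  bad <- setdiff(unique(ann$feature), GENOMIC_FEATURES)
  if (length(bad))
    stop("unknown genomic feature label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$island_relation), ISLAND_RELATIONS)
  if (length(bad))
    stop("unknown island relation label(s): ", paste(bad, collapse = ", "))
  n_bins <- round(1 / bin_width)
  groups <- c(list(`Whole Genome` = rep(TRUE, nrow(beta))),
              lapply(setNames(nm = GENOMIC_FEATURES),
                     function(f) ann$feature == f),
              lapply(setNames(nm = ISLAND_RELATIONS),
                     function(r) ann$island_relation == r))
  out <- list()
  for (s in colnames(beta)) {
    idx_all <- beta_bin_index(beta[, s], bin_width)
    for (g in names(groups)) {
      sel <- groups[[g]]
      if (!any(sel)) next
      counts <- tabulate(idx_all[sel], nbins = n_bins)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, category = g,
        bin_lo = (seq_len(n_bins) - 1) * bin_width,
        bin_hi = seq_len(n_bins) * bin_width,
        count = counts, percent = 100 * counts / sum(sel))
    }
  }
  do.call(rbind, out)
}

#' Substitute-tumour concordance (delta-delta-beta)
#'
#' Tests whether a xenograft can stand in for its matched patient tumour in
#' an inter-tumour comparison: for a reference pair (patient A vs patient B)
#' and a test pair (patient A vs xenograft of B), computes per probe
#' ddb = |delta-beta(ref)| - |delta-beta(test)|. Values near zero indicate
#' that the xenograft captures the same inter-tumour differences; the
#' summary reports the fraction of probes with |ddb| below `tol`.
#'
#' @param ref_pair,test_pair [delta_beta()] results on the same probe
#'   universe.
#' @param tol Concordance tolerance on |ddb| (no field-standard value
#'   exists; 0.1 — ten histogram bins — is this package's default).
#' @param bin_width Histogram bin width over \[-1, 1\].
#' @return A list with the `ddb` vector, a binned `histogram` data.frame,
#'   `concordant_fraction` and `tol`.
#' @export
substitute_concordance <- function(ref_pair, test_pair, tol = 0.1,
                                   bin_width = 0.01) {
  stopifnot(inherits(ref_pair, "pair_delta"),
            inherits(test_pair, "pair_delta"))
  if (length(ref_pair$delta) != length(test_pair$delta) ||
      !identical(names(ref_pair$delta), names(test_pair$delta)))
    stop("the two pairs are not on the same probe universe")
  check_fraction(tol, "tol", lo = 1e-12, hi = 2)
  ddb <- abs(ref_pair$delta) - abs(test_pair$delta)
  n_bins <- 2 * round(1 / bin_width)
  idx <- pmin.int(floor((ddb + 1) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  hist <- data.frame(bin_lo = -1 + (seq_len(n_bins) - 1) * bin_width,
                     bin_hi = -1 + seq_len(n_bins) * bin_width,
                     count = counts, percent = 100 * counts / length(ddb))
  list(ddb = ddb, histogram = hist,
       concordant_fraction = mean(abs(ddb) < tol), tol = tol)
}

#' Directional concordance between two signed probe or region sets
#'
#' Intersects two sets of differentially methylated elements by identifier
#' and reports how many are shared and what fraction of the shared elements
#' agree in direction of change (methylation gain vs loss). Used, e.g., to
#' compare array-derived reversed probes with regions called from an
#' orthogonal assay such as MeDIP-seq.
#'
#' @param set_a,set_b Data.frames with columns `id` and `direction`
#'   (positive = gain, negative = loss).
#' @return A list with `shared` (count) and `concordance` (fraction in
#'   \[0, 1\], or `NA` when no element is shared).
#' @export
set_concordance <- function(set_a, set_b) {
  stopifnot(all(c("id", "direction") %in% names(set_a)),
            all(c("id", "direction") %in% names(set_b)))
  shared <- intersect(set_a$id, set_b$id)
  if (!length(shared))
    return(list(shared = 0L, concordance = NA_real_))
  da <- sign(set_a$direction[match(shared, set_a$id)])
  db <- sign(set_b$direction[match(shared, set_b$id)])
  list(shared = length(shared), concordance = mean(da == db))
}
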