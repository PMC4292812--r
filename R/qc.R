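#' Probe quality-control thresholds
#'
#' Bundles the probe-level QC parameters: a probe passes detection in a
#' sample when its detection p-value is strictly below `detection_p`
#' (signal distinguishable from background); a probe fails the bead rule
#' when fewer than `bead_min` beads back it in at least `bead_sample_frac`
#' of samples (the ChAMP convention for a "bead cutoff of 0.05");
#' sex-chromosome probes are dropped when `drop_sex` is set.
#'
#' @param detection_p Detection p-value cutoff, in (0, 1).
#' @param bead_min Minimum bead count.
#' @param bead_sample_frac Sample-fraction tolerance for the bead rule.
#' @param drop_sex Drop chrX/chrY probes?
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(detection_p = 0.01, bead_min = 3L,
                          bead_sample_frac = 0.05, drop_sex = TRUE) {
  check_fraction(detection_p, "detection_p", lo = 1e-12, hi = 1 - 1e-12)
  check_count(bead_min, "bead_min", min = 0)
  check_fraction(bead_sample_frac, "bead_sample_frac")
  structure(list(detection_p = detection_p, bead_min = as.integer(bead_min),
                 bead_sample_frac = bead_sample_frac,
                 drop_sex = isTRUE(drop_sex)),
            class = "qc_thresholds")
}

check_detp_range <- function(detp) {
  bad <- which(detp < 0 | detp > 1 | !is.finite(detp), arr.ind = TRUE)
  if (length(bad)) {
    if (is.matrix(bad)) {
      pr <- rownames(detp)[bad[1, 1]] %||% bad[1, 1]
      sm <- colnames(detp)[bad[1, 2]] %||% bad[1, 2]
      stop(sprintf("detection p-value out of [0, 1] at probe %s, sample %s",
                   pr, sm), call. = FALSE)
    }
    stop(sprintf("detection p-value out of [0, 1] at position %d", bad[1]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Probes failing the detection p-value rule
#'
#' A probe is removed when any sample has detection p at or above the cutoff
#' — i.e. when it fails detection (p >= `detection_p`; passing requires
#' p strictly below the cutoff) in at least one sample.
#'
#' @param detp Matrix of detection p-values (probes x samples), probe ids as
#'   rownames.
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of probe ids to remove.
#' @export
filter_detection <- function(detp, thresholds = qc_thresholds()) {
  stopifnot(is.matrix(detp))
  check_detp_range(detp)
  fail <- rowSums(detp >= thresholds$detection_p) > 0
  rownames(detp)[fail] %||% which(fail)
}

#' Probes detectable in the mouse-only sample
#'
#' Probes whose detection p-value in a host (mouse) tissue sample falls
#' strictly below the cutoff hybridise to mouse DNA and would carry host
#' signal in xenografts; they are masked from all downstream analysis.
#' At the boundary (p equal to the cutoff) a probe counts as not detected
#' in mouse and is retained.
#'
#' @param detp_mouse Named numeric vector, one detection p per probe.
#' @param thresholds A [qc_thresholds()].
#' @param probe_universe Optional probe-id vector to validate length against.
#' @return Character vector of probe ids to mask.
#' @export
mouse_mask <- function(detp_mouse, thresholds = qc_thresholds(),
                       probe_universe = NULL) {
  check_detp_range(detp_mouse)
  if (!is.null(probe_universe) &&
      length(detp_mouse) != length(probe_universe))
    stop(sprintf("mouse detection vector has %d probes; universe has %d",
                 length(detp_mouse), length(probe_universe)), call. = FALSE)
  hit <- detp_mouse < thresholds$detection_p
  names(detp_mouse)[hit] %||% which(hit)
}

#' Probes failing the bead-count rule
#'
#' Removes probes backed by fewer than `bead_min` beads in at least
#' `bead_sample_frac` of samples (boundary inclusive: a probe with exactly
#' that fraction of low-bead samples is removed).
#'
#' @param beads Matrix of non-negative integer bead counts.
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of probe ids to remove.
#' @export
filter_beads <- function(beads, thresholds = qc_thresholds()) {
  stopifnot(is.matrix(beads))
  if (any(beads < 0 | !is.finite(beads)))
    stop("bead counts must be non-negative", call. = FALSE)
  fail <- rowMeans(beads < thresholds$bead_min) >= thresholds$bead_sample_frac
  rownames(beads)[fail] %||% which(fail)
}

#' Apply the full probe QC pipeline
#'
#' Applies the probe-removal rules in fixed order — detection p-value, bead
#' cutoff, sex chromosomes, mouse mask — and restricts the beta matrix to
#' the retained probes. A probe removed by several rules is attributed to
#' the first one in that order, so the per-rule sets plus the retained set
#' partition the input universe; the retained set itself is order-invariant
#' (a union of removals).
#'
#' @param beta Beta-value matrix (probes x samples), probe ids as rownames.
#' @param detp,beads Optional matching detection-p and bead-count matrices.
#' @param detp_mouse Optional named mouse detection-p vector.
#' @param annotation Manifest data.frame with `probe_id` and `chrom`;
#'   required when `thresholds$drop_sex`.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `beta` (the filtered matrix) and `report`, an object
#'   of class `qc_report` holding per-rule removal sets, counts and the
#'   retained probe ids.
#' @export
apply_qc <- function(beta, detp = NULL, beads = NULL, detp_mouse = NULL,
                     annotation = NULL, thresholds = qc_thresholds()) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  universe <- rownames(beta)
  same_universe <- function(x, what) {
    ids <- if (is.matrix(x)) rownames(x) else names(x)
    if (is.null(ids) || !identical(sort(ids), sort(universe)))
      stop(sprintf("'%s' does not share the beta matrix probe universe",
                   what), call. = FALSE)
  }
  removed <- list()
  if (!is.null(detp)) {
    same_universe(detp, "detp")
    removed$detection <- filter_detection(detp[universe, , drop = FALSE],
                                          thresholds)
  } else removed$detection <- character(0)
  if (!is.null(beads)) {
    same_universe(beads, "beads")
    removed$beads <- setdiff(filter_beads(beads[universe, , drop = FALSE],
                                          thresholds),
                             removed$detection)
  } else removed$beads <- character(0)
  gone <- c(removed$detection, removed$beads)
  if (thresholds$drop_sex) {
    if (is.null(annotation))
      stop("'annotation' is required to drop sex-chromosome probes")
    sex <- annotation$probe_id[annotation$chrom %in% c("chrX", "chrY")]
    removed$sex <- setdiff(intersect(sex, universe), gone)
  } else removed$sex <- character(0)
  gone <- c(gone, removed$sex)
  if (!is.null(detp_mouse)) {
    same_universe(detp_mouse, "detp_mouse")
    removed$mouse <- setdiff(mouse_mask(detp_mouse[universe], thresholds),
                             gone)
  } else removed$mouse <- character(0)
  retained <- setdiff(universe, unlist(removed))
  report <- structure(
    list(removed_by_rule = removed,
         counts = c(vapply(removed, length, integer(1)),
                    retained = length(retained),
                    input = length(universe)),
         retained = retained),
    class = "qc_report")
  list(beta = beta[retained, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC report\n")
  cat(sprintf("  input probes:   %d\n", x$counts[["input"]]))
  for (rule in names(x$removed_by_rule))
    cat(sprintf("  removed (%s): %d\n", rule, length(x$removed_by_rule[[rule]])))
  cat(sprintf("  retained:       %d\n", length(x$retained)))
  invisible(x)
}
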