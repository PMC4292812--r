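#' Combined (epi)genomic category per probe
#'
#' Each probe's genomic feature and CpG-island relation are combined into a
#' single category (e.g. `"TSS200:Island"`), so that every annotated probe
#' maps to exactly one combined category.
#'
#' @param probe_ids Probe ids to annotate.
#' @param annotation Manifest data.frame.
#' @return A character vector of combined categories, `NA` where the probe
#'   is missing from the manifest.
#' @export
combined_category <- function(probe_ids, annotation) {
  i <- match(probe_ids, annotation$probe_id)
  ifelse(is.na(i), NA_character_,
         paste(annotation$feature[i], annotation$island_relation[i],
               sep = ":"))
}

#' Resampling enrichment of a probe set across combined categories
#'
#' Compares the combined (epi)genomic category composition of a target probe
#' set (e.g. the probes reversing methylation after xenografting) with its
#' expectation under random selection: in each of `n_reps` repetitions,
#' `|target|` probes are drawn uniformly without replacement from the
#' universe and tallied per category. Fold is observed over resampled mean;
#' the two-sided empirical p-value is the add-one estimator
#' `(r + 1) / (n_reps + 1)` on the more extreme tail, doubled and capped at
#' 1, so p is never zero and never below `1 / (n_reps + 1)`.
#'
#' Probes missing from the manifest are excluded from both target and
#' universe (with a message).
#'
#' @param target Character vector of probe ids, a subset of `universe`.
#' @param universe Character vector of probe ids (the QC-retained set).
#' @param annotation Manifest data.frame.
#' @param n_reps Number of resampling repetitions (default 1000).
#' @param seed Optional RNG seed.
#' @return A data.frame (class `enrichment_result`) with one row per
#'   category present in the universe: `category`, `observed`,
#'   `expected_mean`, `expected_sd`, `fold`, `empirical_p`, `n_reps`.
#' @export
resampling_enrichment <- function(target, universe, annotation,
                                  n_reps = 1000L, seed = NULL) {
  check_count(n_reps, "n_reps", min = 1)
  if (!all(target %in% universe))
    stop("'target' must be a subset of 'universe'")
  cat_u <- combined_category(universe, annotation)
  n_miss <- sum(is.na(cat_u))
  if (n_miss > 0) {
    message(n_miss, " probe(s) without annotation excluded from universe ",
            "and target")
    universe <- universe[!is.na(cat_u)]
    cat_u <- cat_u[!is.na(cat_u)]
    target <- intersect(target, universe)
  }
  if (length(target) > length(universe))
    stop("'target' is larger than 'universe'")
  if (!is.null(seed)) set.seed(seed)
  lev <- sort(unique(cat_u))
  cat_i <- match(cat_u, lev)
  observed <- tabulate(cat_i[universe %in% target], nbins = length(lev))
  k <- length(target)
  reps <- matrix(0L, length(lev), n_reps)
  for (r in seq_len(n_reps))
    reps[, r] <- tabulate(cat_i[sample.int(length(universe), k)],
                          nbins = length(lev))
  exp_mean <- rowMeans(reps)
  exp_sd <- apply(reps, 1, sd)
  r_hi <- rowSums(reps >= observed)
  r_lo <- rowSums(reps <= observed)
  p <- pmin(1, 2 * pmin(r_hi + 1, r_lo + 1) / (n_reps + 1))
  out <- data.frame(category = lev, observed = observed,
                    expected_mean = exp_mean, expected_sd = exp_sd,
                    fold = ifelse(exp_mean > 0, observed / exp_mean,
                                  ifelse(observed == 0, NA_real_, Inf)),
                    empirical_p = p, n_reps = n_reps,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Resampling significance of a multi-set probe overlap
#'
#' Observed statistic: the size of the intersection of all sets. Null: in
#' each repetition every set is redrawn at its own size uniformly without
#' replacement from the universe and the null intersection size recorded.
#' The empirical p-value is `(r + 1) / (n_reps + 1)` with `r` the number of
#' repetitions whose null intersection is at least the observed one.
#'
#' @param sets List (>= 2) of probe-id vectors, all subsets of `universe`.
#' @param universe Probe-id vector.
#' @param n_reps Repetitions (default 10000).
#' @param seed Optional RNG seed.
#' @param keep_null Return the null intersection sizes?
#' @return A list with `observed_shared`, `empirical_p`, `n_reps`, and
#'   optionally `null`.
#' @export
overlap_significance <- function(sets, universe, n_reps = 10000L,
                                 seed = NULL, keep_null = FALSE) {
  if (length(sets) < 2) stop("need at least two sets")
  check_count(n_reps, "n_reps", min = 1)
  for (i in seq_along(sets))
    if (!all(sets[[i]] %in% universe))
      stop(sprintf("set %d is not a subset of the universe", i))
  if (!is.null(seed)) set.seed(seed)
  observed <- length(Reduce(intersect, sets))
  sizes <- lengths(sets)
  n_u <- length(universe)
  null <- vapply(seq_len(n_reps), function(r) {
    length(Reduce(intersect,
                  lapply(sizes, function(s) sample.int(n_u, s))))
  }, integer(1))
  res <- list(observed_shared = observed,
              empirical_p = (sum(null >= observed) + 1) / (n_reps + 1),
              n_reps = n_reps)
  if (keep_null) res$null <- null
  res
}

#' Overlap percentages between changing-probe sets
#'
#' All percentages use one denominator: the size of the smallest set (the
#' sample with the fewest changing probes), so 100% means "everything the
#' most conservative sample calls changing is also called by the others".
#' Reports every pairwise overlap and the full intersection.
#'
#' @param sets Named list (>= 2) of non-empty probe-id vectors.
#' @return A list with `denominator_set`, `denominator` (its size),
#'   `pairwise` (data.frame `set_a`, `set_b`, `shared`, `percent`),
#'   `full_shared` and `full_percent`.
#' @export
overlap_percentages <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    stop("empty set(s): ", paste(empty, collapse = ", "))
  sizes <- lengths(sets)
  denom_set <- names(sets)[which.min(sizes)]
  denom <- min(sizes)
  cmb <- utils::combn(names(sets), 2)
  pairwise <- data.frame(
    set_a = cmb[1, ], set_b = cmb[2, ],
    shared = apply(cmb, 2, function(ab)
      length(intersect(sets[[ab[1]]], sets[[ab[2]]]))),
    stringsAsFactors = FALSE)
  pairwise$percent <- 100 * pairwise$shared / denom
  full <- length(Reduce(intersect, sets))
  list(denominator_set = denom_set, denominator = denom,
       pairwise = pairwise, full_shared = full,
       full_percent = 100 * full / denom)
}
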