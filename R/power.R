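#' Configuration of the perturb-and-test sample-size simulation
#'
#' The simulation asks how many probes would falsely appear differentially
#' methylated between two groups of n samples when every sample in one group
#' carries tumour-specific xenografting-associated changes: for each group
#' size n, n methylomes are drawn from a pool, each is independently
#' perturbed at `n_perturb` random probes by +/- `delta` (`n_up` gains,
#' `n_down` losses), and every probe is tested original-group vs
#' modified-group with a two-sided Wilcoxon rank-sum test at the
#' non-adjusted level `alpha`.
#'
#' @param n_grid Group sizes to evaluate (default 5 to 50).
#' @param n_perturb Probes perturbed per sample (default 11110).
#' @param n_up,n_down Split of the perturbations into gains and losses
#'   (default 5555 each); must sum to `n_perturb`.
#' @param delta Shift magnitude in beta (default 0.51, the reversal
#'   threshold).
#' @param alpha Per-probe significance level, non-adjusted (default 0.05,
#'   inclusive: p <= alpha counts).
#' @param n_reps Repetitions of the whole model per group size (default 5).
#' @param pool_size Number of methylomes in the sampling pool
#'   (default 2000).
#' @param clip If `TRUE`, perturbed probes are drawn without regard to
#'   feasibility and the shifted values clipped to \[0, 1\] (sensitivity
#'   mode); by default only probes where the full shift fits are eligible.
#' @param seed Master seed; expanded per (n, repetition) via
#'   [child_seed()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_grid = 5:50, n_perturb = 11110L, n_up = 5555L,
                       n_down = 5555L, delta = 0.51, alpha = 0.05,
                       n_reps = 5L, pool_size = 2000L, clip = FALSE,
                       seed = 1L) {
  stopifnot(length(n_grid) >= 1, all(n_grid >= 1))
  check_count(n_perturb, "n_perturb", min = 0)
  check_count(n_up, "n_up", min = 0)
  check_count(n_down, "n_down", min = 0)
  if (n_up + n_down != n_perturb)
    stop("'n_up' + 'n_down' must equal 'n_perturb'")
  check_fraction(delta, "delta", lo = 1e-12)
  check_fraction(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  check_count(n_reps, "n_reps", min = 1)
  check_count(pool_size, "pool_size", min = max(n_grid))
  structure(list(n_grid = as.integer(n_grid),
                 n_perturb = as.integer(n_perturb),
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 delta = delta, alpha = alpha, n_reps = as.integer(n_reps),
                 pool_size = as.integer(pool_size), clip = isTRUE(clip),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Scale the simulation to a smaller probe universe
#'
#' Rescales `n_perturb` (and its up/down split) by `n_probes / n_probes_ref`
#' so the per-probe perturbation probability — the quantity that drives the
#' per-probe test — is preserved on a smaller universe. Significant-probe
#' counts from the scaled run estimate the full-scale counts after
#' multiplying by the returned `count_rescale` factor (probes behave
#' independently, so expected counts scale linearly with universe size).
#'
#' @param config A [sim_config()].
#' @param n_probes Size of the scaled probe universe.
#' @param n_probes_ref Reference full-scale universe (default 463558, the
#'   QC-retained 450K probe count).
#' @return The scaled `sim_config`, with attribute `count_rescale`.
#' @export
scale_sim_config <- function(config, n_probes, n_probes_ref = 463558L) {
  stopifnot(inherits(config, "sim_config"))
  check_count(n_probes, "n_probes", min = 1)
  ratio <- n_probes / n_probes_ref
  n_up <- round(config$n_up * ratio)
  n_down <- round(config$n_down * ratio)
  out <- sim_config(n_grid = config$n_grid, n_perturb = n_up + n_down,
                    n_up = n_up, n_down = n_down, delta = config$delta,
                    alpha = config$alpha, n_reps = config$n_reps,
                    pool_size = config$pool_size, clip = config$clip,
                    seed = config$seed)
  attr(out, "count_rescale") <- n_probes_ref / n_probes
  out
}

#' Perturb one methylome at tumour-specific random probes
#'
#' Shifts exactly `n_up` probes up and `n_down` probes down by `delta`,
#' choosing probes uniformly at random and independently of any other
#' sample (the changes are tumour-specific, so no prediction of which
#' probes move can be made). By default only probes where the full-magnitude
#' shift stays inside \[0, 1\] are eligible (up-shifts where
#' beta <= 1 - delta, down-shifts where beta >= delta), so every planted
#' difference is exactly `delta`; with `config$clip` the shifted values are
#' clipped instead.
#'
#' @param beta Numeric beta vector in \[0, 1\].
#' @param config A [sim_config()].
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A list with `beta` (perturbed vector) and `record` (data.frame
#'   `probe`, `direction`).
#' @export
perturb_sample <- function(beta, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (config$n_perturb == 0)
    return(list(beta = beta,
                record = data.frame(probe = integer(0),
                                    direction = integer(0))))
  n <- length(beta)
  if (config$clip) {
    idx <- sample.int(n, config$n_perturb)
    up <- idx[seq_len(config$n_up)]
    down <- idx[config$n_up + seq_len(config$n_down)]
    beta[up] <- pmin(1, beta[up] + config$delta)
    beta[down] <- pmax(0, beta[down] - config$delta)
  } else {
    up_cand <- which(beta <= 1 - config$delta)
    if (length(up_cand) < config$n_up)
      stop(sprintf("only %d probes can take a +%g shift; %d required",
                   length(up_cand), config$delta, config$n_up),
           call. = FALSE)
    up <- if (config$n_up) sample(up_cand, config$n_up) else integer(0)
    down_cand <- setdiff(which(beta >= config$delta), up)
    if (length(down_cand) < config$n_down)
      stop(sprintf("only %d probes can take a -%g shift; %d required",
                   length(down_cand), config$delta, config$n_down),
           call. = FALSE)
    down <- if (config$n_down) sample(down_cand, config$n_down)
            else integer(0)
    beta[up] <- beta[up] + config$delta
    beta[down] <- beta[down] - config$delta
  }
  list(beta = beta,
       record = data.frame(probe = c(up, down),
                           direction = rep(c(1L, -1L),
                                           c(length(up), length(down)))))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Wrapper with the conventions used throughout the simulation: the exact
#' enumeration p-value when the combined size is at most 20 and there are
#' no ties, the tie-corrected normal approximation with continuity
#' correction otherwise, and p = 1 when all values are tied (zero rank
#' variance).
#'
#' @param group_a,group_b Non-empty finite numeric vectors.
#' @return The two-sided p-value.
#' @export
rank_sum_pvalue <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  v <- c(group_a, group_b)
  if (!all(is.finite(v))) stop("values must be finite")
  if (length(unique(v)) == 1L) return(1)
  exact <- length(v) <= 20 && !anyDuplicated(v)
  stats::wilcox.test(group_a, group_b, exact = exact,
                     correct = TRUE)$p.value
}

#' One repetition of the perturbation model
#'
#' Draws `n` samples without replacement from the pool, perturbs each
#' independently, and counts probes whose original-group vs modified-group
#' rank-sum p-value is at or below `config$alpha`. Probes perturbed in no
#' sample are skipped without testing: their two groups are identical, so
#' their p-value is exactly 1 — a pure optimisation with no effect on the
#' count.
#'
#' @param pool Beta matrix (probes x pool samples), or a function `f(n)`
#'   returning n fresh methylome columns (see [methylome_sampler()]) —
#'   equivalent to drawing from an arbitrarily large pool.
#' @param n Group size.
#' @param config A [sim_config()].
#' @param seed Optional seed for this repetition.
#' @return The number of significant probes (integer).
#' @export
run_one_rep <- function(pool, n, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_count(n, "n", min = 1)
  if (is.matrix(pool) && n > ncol(pool))
    stop(sprintf("n = %d exceeds the pool size %d", n, ncol(pool)))
  if (!is.null(seed)) set.seed(seed)
  orig <- if (is.function(pool)) pool(n)
          else pool[, sample.int(ncol(pool), n), drop = FALSE]
  mod <- orig
  touched <- vector("list", n)
  for (j in seq_len(n)) {
    p <- perturb_sample(orig[, j], config)
    mod[, j] <- p$beta
    touched[[j]] <- p$record$probe
  }
  touched <- sort(unique(unlist(touched)))
  if (!length(touched)) return(0L)
  pv <- wilcox_rows_pvalue(orig[touched, , drop = FALSE],
                           mod[touched, , drop = FALSE])
  sum(pv <= config$alpha)
}

#' Run the full sample-size simulation
#'
#' For every group size in `config$n_grid`, runs `config$n_reps`
#' independent repetitions of [run_one_rep()] — fresh sample selection and
#' fresh tumour-specific perturbations each time — and summarises the
#' significant-probe counts by their mean and standard error of the mean.
#' Each (group size, repetition) cell gets its own child seed from the
#' master seed, so a fixed master seed reproduces the whole curve.
#'
#' @param pool Beta matrix (probes x pool samples), e.g. from
#'   [generate_pool()], or a column-sampler function from
#'   [methylome_sampler()].
#' @param config A [sim_config()].
#' @return An object of class `power_curve`: a data.frame with `n`,
#'   `mean_count`, `sem`, plus attributes `counts` (n_grid x n_reps matrix
#'   of raw counts) and `count_rescale` (carried over from
#'   [scale_sim_config()], 1 otherwise).
#' @export
run_simulation <- function(pool, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.matrix(pool) && ncol(pool) < max(config$n_grid))
    stop("pool has fewer samples than the largest group size")
  counts <- matrix(NA_integer_, length(config$n_grid), config$n_reps,
                   dimnames = list(config$n_grid, NULL))
  for (i in seq_along(config$n_grid)) {
    n <- config$n_grid[i]
    for (r in seq_len(config$n_reps))
      counts[i, r] <- run_one_rep(
        pool, n, config,
        seed = child_seed(config$seed, "power", n * 1000L + r))
  }
  out <- data.frame(
    n = config$n_grid,
    mean_count = rowMeans(counts),
    sem = apply(counts, 1, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else 0))
  attr(out, "counts") <- counts
  attr(out, "count_rescale") <- attr(config, "count_rescale") %||% 1
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Two-tier sample-size study at the full array scale
#'
#' Runs the perturbation model over the whole group-size grid with a fixed
#' computational budget, split by cost: small group sizes (default 5-15,
#' where significant-probe counts are largest and repetitions are cheap)
#' are simulated at the full probe universe via a lazy [methylome_sampler()],
#' and the remaining sizes on a scaled-down universe with the perturbation
#' density preserved and counts rescaled by the probe ratio
#' ([scale_sim_config()]). All other parameters are the [sim_config()]
#' defaults: 11,110 perturbed probes per sample (5,555 up, 5,555 down) at
#' the full scale, shifts of 0.51, alpha 0.05 non-adjusted, 5 repetitions
#' per group size.
#'
#' @param seed Master seed; all stages derive child seeds from it.
#' @param full_n Group sizes run at full scale.
#' @param scaled_n Group sizes run at the scaled universe.
#' @param n_probes Full probe universe size (default 463558).
#' @param n_probes_scaled Scaled universe size (default 50000).
#' @param pool_size Methylome pool size for the scaled tier (default 2000).
#' @return A `power_curve` data.frame over the combined grid with columns
#'   `n`, `mean_count`, `sem` (already on the full-array count scale) and
#'   `tier`.
#' @export
power_study <- function(seed = 1L, full_n = 5:15, scaled_n = 16:50,
                        n_probes = 463558L, n_probes_scaled = 50000L,
                        pool_size = 2000L) {
  ann <- generate_annotation(n_probes, seed = child_seed(seed, "ann"))
  model <- methylome_model(n_probes = n_probes,
                           seed = child_seed(seed, "pool"))
  sampler <- methylome_sampler(model, ann)
  cfg_full <- sim_config(n_grid = full_n, pool_size = pool_size,
                         seed = child_seed(seed, "power-full"))
  full <- run_simulation(sampler, cfg_full)
  rm(sampler)
  ann_s <- generate_annotation(n_probes_scaled,
                               seed = child_seed(seed, "ann-scaled"))
  model_s <- methylome_model(n_probes = n_probes_scaled,
                             seed = child_seed(seed, "pool-scaled"))
  pool_s <- generate_pool(model_s, pool_size, ann_s)
  cfg_s <- scale_sim_config(
    sim_config(n_grid = scaled_n, pool_size = pool_size,
               seed = child_seed(seed, "power-scaled")),
    n_probes_scaled, n_probes_ref = n_probes)
  scaled <- run_simulation(pool_s, cfg_s)
  rs <- attr(scaled, "count_rescale")
  out <- data.frame(
    n = c(full$n, scaled$n),
    mean_count = c(full$mean_count, scaled$mean_count * rs),
    sem = c(full$sem, scaled$sem * rs),
    tier = rep(c("full", "scaled"), c(nrow(full), nrow(scaled))))
  attr(out, "counts") <- rbind(attr(full, "counts"),
                               attr(scaled, "counts") * rs)
  attr(out, "count_rescale") <- 1
  class(out) <- c("power_curve", "data.frame")
  out
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve over %d group sizes (%d repetitions each)\n",
              nrow(x), ncol(attr(x, "counts"))))
  rs <- attr(x, "count_rescale")
  if (!is.null(rs) && rs != 1)
    cat(sprintf("  scaled run: multiply counts by %.3f for the full array\n",
                rs))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.power_curve <- function(x, ...) {
  graphics::plot(x$n, x$mean_count, type = "b", pch = 16,
                 xlab = "samples per group (n)",
                 ylab = "significant probes (mean over runs)", ...)
  graphics::arrows(x$n, x$mean_count - x$sem, x$n, x$mean_count + x$sem,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
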