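small_cfg <- function(...) {
  defaults <- list(n_grid = c(5L, 8L), n_perturb = 40L, n_up = 20L,
                   n_down = 20L, n_reps = 2L, pool_size = 20L, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("rank_sum_pvalue matches exact enumeration and handles ties", {
  expect_equal(rank_sum_pvalue(1:3, 4:6), 0.1) # 2/20 partitions as extreme
  expect_equal(rank_sum_pvalue(c(2, 2, 2), c(2, 2, 2)), 1)
  # exact enumeration oracle on all no-tie cases at small sizes
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(100, n1 + n2) / 10
    a <- x[1:n1]; b <- x[-(1:n1)]
    # brute force: permutation distribution of the rank sum
    W <- sum(rank(x)[1:n1])
    perms <- combn(n1 + n2, n1)
    Wnull <- apply(perms, 2, function(ix) sum(rank(x)[ix]))
    mu <- n1 * (n1 + n2 + 1) / 2
    p_exact <- mean(abs(Wnull - mu) >= abs(W - mu))
    expect_equal(rank_sum_pvalue(a, b), p_exact, tolerance = 1e-10)
  }
  expect_error(rank_sum_pvalue(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation stays close to the exact p-value", {
  set.seed(33)
  for (i in 1:200) {
    x <- sample(1000, 18) / 7
    a <- x[1:9]; b <- x[10:18]
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_approx <- pdxmeth:::wilcox_rows_pvalue(matrix(a, 1), matrix(b, 1))
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("row-wise kernel agrees with wilcox.test under heavy ties", {
  set.seed(44)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    a <- sample(round(runif(4), 2), n, replace = TRUE)
    b <- a
    k <- sample(0:3, 1)
    if (k > 0) b[sample(n, k)] <- b[sample(n, k)] + 0.51
    p_ref <- if (length(unique(c(a, b))) == 1) 1 else
      suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                   correct = TRUE)$p.value)
    p_row <- pdxmeth:::wilcox_rows_pvalue(matrix(a, 1), matrix(b, 1))
    expect_equal(p_row, p_ref, tolerance = 1e-12)
  }
})

test_that("perturbation shifts exactly the planned probes by exactly delta", {
  set.seed(2)
  beta <- runif(5000)
  cfg <- small_cfg(n_perturb = 200L, n_up = 120L, n_down = 80L)
  res <- perturb_sample(beta, cfg, seed = 5)
  diffs <- res$beta - beta
  expect_equal(sum(diffs != 0), 200)
  expect_equal(sum(diffs > 0), 120)
  expect_equal(sum(diffs < 0), 80)
  expect_true(all(abs(diffs[res$record$probe]) == 0.51))
  expect_true(all(res$beta >= 0 & res$beta <= 1))
  # zero-perturbation config is the identity
  none <- perturb_sample(beta, small_cfg(n_perturb = 0L, n_up = 0L,
                                         n_down = 0L))
  expect_identical(none$beta, beta)
  # infeasible: everything mid-range blocks no direction, but all low blocks down
  low <- rep(0.1, 100)
  expect_error(perturb_sample(low, small_cfg(n_perturb = 20L, n_up = 0L,
                                             n_down = 20L)),
               "-0.51 shift")
})

test_that("zero perturbations give zero significant probes at every n", {
  pool <- tiny_pool(800, 20, seed = 6)
  cfg <- small_cfg(n_perturb = 0L, n_up = 0L, n_down = 0L,
                   n_grid = c(3L, 5L, 9L), n_reps = 2L)
  pc <- run_simulation(pool, cfg)
  expect_true(all(pc$mean_count == 0))
  expect_true(all(pc$sem == 0))
})

test_that("a probe perturbed in one of 15 samples cannot reach significance", {
  # enumerate structured extremes: n-1 duplicated pairs plus one shifted value
  set.seed(12)
  for (i in 1:40) {
    a <- sample(round(runif(6), 1), 15, replace = TRUE)
    b <- a
    j <- sample(15, 1)
    b[j] <- min(a[j] + 0.51, 1)
    p <- pdxmeth:::wilcox_rows_pvalue(matrix(a, 1), matrix(b, 1))
    expect_gt(p, 0.05)
  }
})

test_that("one repetition is reproducible and invariant to column order", {
  pool <- tiny_pool(1500, 12, seed = 7)
  cfg <- small_cfg(n_perturb = 100L, n_up = 50L, n_down = 50L)
  c1 <- run_one_rep(pool, 6, cfg, seed = 31)
  expect_identical(c1, run_one_rep(pool, 6, cfg, seed = 31))
  perm <- pool[, sample(ncol(pool))]
  # same seed, permuted pool columns: different draw, but the count metric
  # applied to identical group pairs is symmetric
  a <- pool[, 1:6]; b <- a
  for (j in 1:6) b[, j] <- perturb_sample(a[, j], cfg, seed = j)$beta
  p1 <- pdxmeth:::wilcox_rows_pvalue(a, b)
  shuf <- sample(6)
  p2 <- pdxmeth:::wilcox_rows_pvalue(a[, shuf], b[, shuf])
  expect_equal(p1, p2)
  expect_error(run_one_rep(pool, 13, cfg), "exceeds")
})

test_that("the power curve is reproducible and decreasing from n=5 to n=50", {
  ann <- tiny_annotation(4000, seed = 15)
  pool <- generate_pool(methylome_model(n_probes = 4000, seed = 15), 60, ann)
  cfg <- sim_config(n_grid = c(5L, 50L), n_perturb = 96L, n_up = 48L,
                    n_down = 48L, n_reps = 5L, pool_size = 60L, seed = 3L)
  pc <- run_simulation(pool, cfg)
  pc2 <- run_simulation(pool, cfg)
  expect_identical(as.data.frame(pc), as.data.frame(pc2))
  expect_lte(pc$mean_count[pc$n == 50], pc$mean_count[pc$n == 5])
  # single repetition: SEM identically zero
  pc1 <- run_simulation(pool, sim_config(n_grid = 5L, n_perturb = 96L,
                                         n_up = 48L, n_down = 48L,
                                         n_reps = 1L, pool_size = 60L))
  expect_equal(pc1$sem, 0)
})

test_that("scaled configs preserve perturbation density and report the rescale", {
  cfg <- scale_sim_config(sim_config(), 50000)
  expect_equal(cfg$n_perturb, 2 * round(5555 * 50000 / 463558))
  expect_equal(cfg$n_up, cfg$n_down)
  expect_equal(attr(cfg, "count_rescale"), 463558 / 50000)
  expect_error(sim_config(n_up = 3L, n_down = 3L, n_perturb = 7L), "equal")
})
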