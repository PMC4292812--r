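test_that("threshold calibration reproduces the published bounds and the quantile oracle", {
  thr <- reversal_threshold()
  expect_equal(thr$threshold, 0.51)
  expect_equal(reversal_threshold(0, 1)$threshold, 1)
  # quantile oracle by explicit sort (nearest-rank)
  set.seed(17)
  u <- runif(1000, 0, 0.4); m <- runif(1000, 0.7, 1)
  cal <- calibrate_threshold(u, m, coverage = 0.95)
  su <- sort(u); sm <- sort(m)
  expect_equal(cal$unmeth_upper, su[ceiling(0.95 * 1000)])
  expect_equal(cal$meth_lower, sm[ceiling(0.05 * 1000)])
  expect_equal(cal$threshold, cal$meth_lower - cal$unmeth_upper)
  # degenerate calibration rejected
  expect_error(calibrate_threshold(runif(50, 0.5, 1), runif(50, 0, 0.5)),
               "degenerate")
  expect_error(calibrate_threshold(numeric(0), m), "non-empty")
})

test_that("delta_beta is an exact antisymmetric difference", {
  fix <- tiny_pair(1000)
  d <- delta_beta(fix$beta, "P", "X")
  expect_equal(unname(d$delta), unname(fix$beta[, "P"] - fix$beta[, "X"]))
  expect_equal(delta_beta(fix$beta, "X", "P")$delta, -d$delta)
  same <- delta_beta(cbind(fix$beta, P2 = fix$beta[, "P"]), "P", "P2")
  expect_true(all(same$delta == 0))
  expect_error(delta_beta(fix$beta, "P", "nope"), "nope")
  expect_true(all(abs(d$delta[fix$planted$probe]) >= fix$plan$min_shift))
})

test_that("reversed_fraction counts inclusively and recovers planted truth exactly", {
  pd <- structure(list(patient_id = "a", xenograft_id = "b",
                       delta = c(0.6, -0.52, 0.50, 0.51, -0.3)),
                  class = "pair_delta")
  rf <- reversed_fraction(pd, 0.51)
  expect_equal(rf$count, 3)
  expect_equal(rf$probes, c(1L, 2L, 4L))
  expect_equal(rf$percent, 60)
  zero <- structure(list(patient_id = "a", xenograft_id = "b",
                         delta = rep(0, 10)), class = "pair_delta")
  expect_equal(reversed_fraction(zero, 0.51)$count, 0)
  # planted 2.7% recovered exactly, count and identity
  fix <- tiny_pair(10000, frac_changing = 0.027)
  rf <- reversed_fraction(delta_beta(fix$beta, "P", "X"),
                          reversal_threshold())
  expect_equal(rf$percent, 2.7)
  expect_setequal(rf$probes, fix$planted$probe_id)
})

test_that("delta histograms conserve probe counts", {
  fix <- tiny_pair(3000)
  d <- delta_beta(fix$beta, "P", "X")
  h <- delta_histogram(d)
  expect_equal(nrow(h), 100)
  expect_equal(sum(h$count), 3000)
  expect_equal(sum(h$percent), 100)
  zero <- structure(list(patient_id = "a", xenograft_id = "b",
                         delta = rep(0, 7)), class = "pair_delta")
  hz <- delta_histogram(zero)
  expect_equal(hz$count[1], 7)
  expect_equal(sum(hz$count[-1]), 0)
  expect_error(delta_histogram(d, bin_width = 0.03), "bin_width")
})

test_that("threshold sensitivity is monotone and exact on uniform planted shifts", {
  fix1 <- tiny_pair(4000, seed = 1)
  fix2 <- tiny_pair(4000, seed = 2)
  pairs <- list(delta_beta(fix1$beta, "P", "X"),
                delta_beta(fix2$beta, "P", "X"))
  ts <- threshold_sensitivity(pairs)
  expect_equal(ts$threshold, c(0.51, 0.41, 0.31, 0.21))
  expect_true(all(diff(ts$mean_percent) >= 0)) # grows as threshold drops
  # single pair: SEM identically zero
  expect_true(all(threshold_sensitivity(pairs[1])$sem == 0))
  # planted shifts all >= 0.51, unplanted all 0: identical percent everywhere
  expect_true(all(ts$mean_percent == ts$mean_percent[1]))
  expect_error(threshold_sensitivity(list()), "at least one")
})

test_that("feature histograms normalise per sample and category", {
  ann <- tiny_annotation(2000, seed = 3)
  pool <- tiny_pool(2000, 2, 3, ann)
  fh <- feature_histograms(pool, ann, bin_width = 0.05)
  sums <- tapply(fh$percent, paste(fh$sample, fh$category), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true("Whole Genome" %in% fh$category)
  # island probes sit lower than gene-body probes
  med <- function(cat, s) {
    sub <- fh[fh$category == cat & fh$sample == s, ]
    w <- sub$count / sum(sub$count)
    sum(w * (sub$bin_lo + sub$bin_hi) / 2)
  }
  for (s in unique(fh$sample)) expect_lt(med("Island", s), med("Body", s))
  bad_ann <- ann; bad_ann$feature[1] <- "Exotic"
  expect_error(feature_histograms(pool, bad_ann), "Exotic")
  cst <- matrix(0.5, 10, 1, dimnames = list(ann$probe_id[1:10], "s"))
  hc <- feature_histograms(cst, ann[1:10, ], bin_width = 0.25)
  expect_true(all(hc$percent %in% c(0, 100)))
})

test_that("substitute concordance is zero on identical pairs and elementwise exact", {
  fix <- tiny_pair(500)
  ref <- delta_beta(fix$beta, "P", "X")
  sc <- substitute_concordance(ref, ref)
  expect_true(all(sc$ddb == 0))
  expect_equal(sc$concordant_fraction, 1)
  other <- delta_beta(fix$beta, "P", "S2")
  sc2 <- substitute_concordance(ref, other)
  expect_true(all(abs(sc2$ddb) <= 2))
  expect_equal(sum(sc2$histogram$count), 500)
  # elementwise oracle on random probes
  set.seed(8)
  for (i in sample(500, 100))
    expect_equal(sc2$ddb[[i]],
                 abs(ref$delta[[i]]) - abs(other$delta[[i]]))
  short <- structure(list(patient_id = "a", xenograft_id = "b",
                          delta = ref$delta[1:10]), class = "pair_delta")
  expect_error(substitute_concordance(ref, short), "universe")
})

test_that("signed set concordance counts direction agreement", {
  a <- data.frame(id = paste0("r", 1:10), direction = rep(c(1, -1), 5))
  expect_equal(set_concordance(a, a),
               list(shared = 10L, concordance = 1.0))
  b <- a; b$direction[1] <- -b$direction[1]
  expect_equal(set_concordance(a, b)$concordance, 0.9)
  dis <- data.frame(id = paste0("q", 1:3), direction = 1)
  res <- set_concordance(a, dis)
  expect_equal(res$shared, 0L)
  expect_true(is.na(res$concordance))
})
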