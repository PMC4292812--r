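test_that("generated beta values are bounded, bimodal and reproducible", {
  ann <- tiny_annotation(5000)
  model <- methylome_model(n_probes = 5000, seed = 9)
  pool <- generate_pool(model, 6, ann)
  expect_true(all(pool >= 0 & pool <= 1))
  # column-wise bimodality: mid-range mass stays low under the default model
  mid <- colMeans(pool > 0.2 & pool < 0.8)
  expect_true(all(mid < 0.35))
  # CpG-island promoter probes are overwhelmingly unmethylated
  st <- attr(pool, "probe_state")
  sel <- ann$island_relation == "Island" & ann$feature == "TSS200"
  expect_gt(mean(st[sel] == "unmeth"), 0.90)
  # Island median beta below Body median beta, per sample
  isl <- ann$island_relation == "Island"
  body <- ann$feature == "Body"
  for (j in seq_len(ncol(pool)))
    expect_lt(median(pool[isl, j]), median(pool[body, j]))
  # determinism
  pool2 <- generate_pool(methylome_model(n_probes = 5000, seed = 9), 6, ann)
  expect_identical(pool, pool2)
})

test_that("zero sample noise collapses all samples onto the probe baseline", {
  ann <- tiny_annotation(500)
  model <- methylome_model(n_probes = 500, sample_noise_sd = 0, seed = 3)
  pool <- generate_pool(model, 3, ann)
  expect_identical(unname(pool[, 1]), unname(pool[, 2]))
  expect_identical(unname(pool[, 1]), unname(pool[, 3]))
})

test_that("methylome_sampler draws columns from the same distribution as generate_pool", {
  ann <- tiny_annotation(3000)
  model <- methylome_model(n_probes = 3000, seed = 5)
  pool <- generate_pool(model, 2, ann)
  sampler <- methylome_sampler(model, ann)
  set.seed(11)
  a <- sampler(2)
  expect_equal(dim(a), dim(pool))
  expect_true(all(a > 0 & a < 1))
  # same probe baseline: probe-wise means across draws correlate strongly
  set.seed(12)
  b <- sampler(8)
  expect_gt(cor(rowMeans(b), rowMeans(pool)), 0.95)
  # deterministic under the ambient RNG seed
  set.seed(11)
  expect_identical(a, sampler(2))
})

test_that("model parameter validation names the offending field", {
  expect_error(methylome_model(sample_noise_sd = NA), "sample_noise_sd")
  expect_error(methylome_model(probe_sd = Inf), "probe_sd")
  expect_error(methylome_model(unmeth_mode = 2), "unmeth_mode")
  bad_mix <- default_feature_mix()
  bad_mix$w_meth[1] <- bad_mix$w_meth[1] + 0.5
  expect_error(methylome_model(feature_mix = bad_mix), "sum to 1")
})

test_that("planted PDX changes respect count, magnitude and feasibility", {
  fix <- tiny_pair(10000, frac_changing = 0.027)
  expect_equal(nrow(fix$planted), round(0.027 * 10000))
  d <- fix$beta[, "P"] - fix$beta[, "X"]
  expect_true(all(abs(d[fix$planted$probe]) >= fix$plan$min_shift))
  expect_true(all(d[-fix$planted$probe] == 0))
  expect_true(all(fix$beta[, "X"] >= 0 & fix$beta[, "X"] <= 1))
  # direction sign: +1 means methylation gain in the xenograft
  up <- fix$planted$probe[fix$planted$direction == 1]
  expect_true(all(fix$beta[up, "X"] > fix$beta[up, "P"]))
})

test_that("a zero-change plan returns the input untouched", {
  pool <- tiny_pool(300, 1)
  res <- generate_pdx_pair(pool[, 1], pair_plan(frac_changing = 0))
  expect_identical(res$beta, pool[, 1])
  expect_equal(nrow(res$planted), 0)
})

test_that("an infeasible plan is rejected with the shortfall", {
  beta <- setNames(rep(0.5, 50), paste0("p", 1:50))
  expect_error(
    generate_pdx_pair(beta, pair_plan(frac_changing = 1, min_shift = 0.6)),
    "infeasible")
})

test_that("sibling PDXs share the planned fraction of changed probes", {
  pool <- tiny_pool(20000, 1)
  plan <- pair_plan(frac_changing = 0.027, shared_fraction = 0.86, seed = 13)
  sibs <- generate_pdx_siblings(pool[, 1], plan, n_siblings = 3)
  sets <- lapply(sibs, function(s) s$planted$probe_id)
  expect_true(all(lengths(sets) == round(0.027 * 20000)))
  ov <- overlap_percentages(setNames(sets, c("A", "B", "C")))
  expect_true(all(abs(ov$pairwise$percent - 86) < 3))
})

test_that("mouse QC vector flags exactly the requested probe fraction", {
  p <- generate_mouse_qc(485512, 0.0947, seed = 2)
  expect_equal(sum(p < 0.01), 45978) # round(0.0947 * 485512)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, generate_mouse_qc(485512, 0.0947, seed = 2))
  expect_equal(sum(generate_mouse_qc(1000, 0, seed = 1) < 0.01), 0)
})

test_that("read-record classes follow the multinomial and round-trip via SAM", {
  probs <- c(0.7, 0.1, 0.15, 0.05)
  rec <- generate_read_records(1000, probs, seed = 8)
  counts <- table(factor(rec$class, levels = c("human_only", "mouse_only",
                                               "both", "neither")))
  # each class count inside its 99.75% binomial envelope
  for (k in 1:4) {
    expect_gte(counts[k], qbinom(0.00125, 1000, probs[k]))
    expect_lte(counts[k], qbinom(0.99875, 1000, probs[k]))
  }
  expect_true(all(rec$class[rec$human_aligned & rec$mouse_aligned] == "both"))
  graft <- tempfile(fileext = ".sam"); host <- tempfile(fileext = ".sam")
  write_read_records_sam(rec[1:200, ], graft, host)
  back <- ingest_alignments(graft, host)
  expect_equal(nrow(back), 200)
  m <- match(rec$read_id[1:200], back$read_id)
  expect_equal(back$human_aligned[m], rec$human_aligned[1:200])
  expect_equal(back$mouse_aligned[m], rec$mouse_aligned[1:200])
})

test_that("degenerate class probabilities produce a single class", {
  rec <- generate_read_records(50, c(1, 0, 0, 0), seed = 1)
  expect_true(all(rec$class == "human_only"))
  expect_error(generate_read_records(10, c(0.5, 0.5, 0.1, 0)), "sum")
})
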