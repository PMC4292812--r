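mk <- function(v, nr, nc, ids = sprintf("p%d", seq_len(nr)))
  matrix(v, nr, nc, dimnames = list(ids, paste0("s", seq_len(nc))))

test_that("detection filter removes probes failing in any sample, boundary inclusive", {
  detp <- mk(0.0001, 3, 2)
  expect_length(filter_detection(detp), 0)
  detp[2, 1] <- 0.02
  expect_equal(filter_detection(detp), "p2")
  # p exactly at the cutoff fails detection (pass requires p < 0.01)
  detp[3, 2] <- 0.01
  expect_setequal(filter_detection(detp), c("p2", "p3"))
  detp[1, 1] <- 1.2
  expect_error(filter_detection(detp), "p1.*s1")
})

test_that("mouse mask keeps boundary probes and matches the generator", {
  expect_length(mouse_mask(setNames(rep(0.5, 4), paste0("p", 1:4))), 0)
  v <- setNames(c(0.001, 0.2, 0.009), paste0("p", 1:3))
  expect_equal(mouse_mask(v), c("p1", "p3"))
  # boundary: p == 0.01 counts as not detected in mouse
  expect_length(mouse_mask(setNames(0.01, "p1")), 0)
  g <- generate_mouse_qc(5000, 0.1, seed = 3)
  expect_length(mouse_mask(g), round(0.1 * 5000))
  expect_error(mouse_mask(v, probe_universe = paste0("p", 1:5)), "3.*5")
})

test_that("bead rule uses the low-bead sample fraction with inclusive boundary", {
  expect_length(filter_beads(mk(10, 2, 5)), 0)
  b20 <- mk(10, 1, 20); b20[1, 7] <- 2
  expect_equal(filter_beads(b20), "p1")   # 1/20 = 0.05 >= 0.05
  b21 <- mk(10, 1, 21); b21[1, 7] <- 2
  expect_length(filter_beads(b21), 0)     # 1/21 < 0.05
  bad <- mk(10, 2, 2); bad[1, 1] <- -1
  expect_error(filter_beads(bad), "non-negative")
})

test_that("apply_qc partitions removals in rule order and retains the complement", {
  n <- 400
  ann <- tiny_annotation(n, seed = 21)
  pool <- tiny_pool(n, 3, 21, ann)
  detp <- mk(0.001, n, 3, rownames(pool))
  beads <- mk(10, n, 3, rownames(pool))
  detp[1:10, 2] <- 0.5                       # detection failures
  beads[5:20, ] <- 1                         # bead failures (5:10 overlap)
  mouse <- setNames(rep(0.9, n), rownames(pool))
  mouse[c(15, 30:40)] <- 0.0001              # mouse mask (15 overlaps beads)
  res <- apply_qc(pool, detp, beads, mouse, ann)
  rm_ <- res$report$removed_by_rule
  expect_setequal(rm_$detection, rownames(pool)[1:10])
  expect_setequal(rm_$beads, rownames(pool)[11:20])
  sex <- ann$probe_id[ann$chrom %in% c("chrX", "chrY")]
  expect_setequal(rm_$sex, setdiff(sex, rownames(pool)[1:20]))
  expect_setequal(rm_$mouse,
                  setdiff(rownames(pool)[30:40], sex))
  # partition: rule sets + retained = universe, pairwise disjoint
  all_ids <- c(unlist(rm_), res$report$retained)
  expect_setequal(all_ids, rownames(pool))
  expect_equal(length(all_ids), n)
  expect_false(any(sex %in% res$report$retained))
  expect_equal(rownames(res$beta), res$report$retained)
})

test_that("clean inputs pass through and QC is idempotent", {
  n <- 300
  ann <- tiny_annotation(n, seed = 4, include_sex = FALSE)
  pool <- tiny_pool(n, 2, 4, ann)
  detp <- mk(0.001, n, 2, rownames(pool))
  beads <- mk(10, n, 2, rownames(pool))
  mouse <- setNames(rep(0.9, n), rownames(pool))
  res <- apply_qc(pool, detp, beads, mouse, ann)
  expect_equal(res$report$retained, rownames(pool))
  # idempotence on a filtered result
  detp[1:5, 1] <- 0.9
  res1 <- apply_qc(pool, detp, beads, mouse, ann)
  keep <- res1$report$retained
  res2 <- apply_qc(res1$beta, detp[keep, ], beads[keep, ], mouse[keep], ann)
  expect_equal(res2$report$retained, keep)
  expect_identical(res2$beta, res1$beta)
})

test_that("retained set shrinks monotonically as thresholds tighten", {
  n <- 500
  set.seed(31)
  ann <- tiny_annotation(n, seed = 31)
  pool <- tiny_pool(n, 4, 31, ann)
  detp <- mk(runif(n * 4, 0, 0.05), n, 4, rownames(pool))
  beads <- mk(sample(1:10, n * 4, TRUE), n, 4, rownames(pool))
  mouse <- setNames(runif(n), rownames(pool))
  kept <- function(dp, bf) {
    th <- qc_thresholds(detection_p = dp, bead_sample_frac = bf)
    apply_qc(pool, detp, beads, mouse, ann, th)$report$retained
  }
  base <- kept(0.01, 0.5)
  expect_true(all(kept(0.005, 0.5) %in% base))
  expect_true(all(kept(0.01, 0.25) %in% base))
})

test_that("mismatched probe universes are rejected", {
  pool <- tiny_pool(100, 2)
  detp <- matrix(0.001, 99, 2,
                 dimnames = list(rownames(pool)[1:99], c("a", "b")))
  expect_error(apply_qc(pool, detp = detp, annotation = NULL,
                        thresholds = qc_thresholds(drop_sex = FALSE)),
               "universe")
})
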