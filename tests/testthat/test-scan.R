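make_contig_window <- function(seed = 1, L = 1e5, S = 300) {
  set.seed(seed)
  X <- matrix(sample(0:1, 12 * S, TRUE), 12)
  pop_window(X, positions = sort(sample(0:(L - 1), S)), L = L,
             n1 = 6, n2 = 6)
}

test_that("window extraction counts and mask filtering follow the rules", {
  cw <- make_contig_window()
  ew <- extract_windows(cw, size = 1e4, step = 1e4)
  expect_equal(nrow(ew$table), 10L)
  expect_true(all(ew$table$retained))
  slid <- extract_windows(cw, size = 1e4, step = 1e3)
  expect_equal(nrow(slid$table), 91L)
  ## a window with 26% masked is excluded, 25% is kept
  mask <- rbind(c(0, 2600), c(10000, 12500))
  ewm <- extract_windows(cw, size = 1e4, step = 1e4, mask = mask)
  expect_false(ewm$table$retained[1])
  expect_true(ewm$table$retained[2])
  expect_equal(ewm$table$masked_fraction[1:2], c(0.26, 0.25))
  expect_null(ewm$windows[[1]])
  expect_equal(ewm$windows[[2]]$L_u, 7500)
  expect_error(extract_windows(cw, size = 1e6), "larger than contig")
})

test_that("region clustering applies the run and peak rules", {
  calls <- data.frame(contig = "c1", start = (0:2) * 1e4,
                      end = (1:3) * 1e4, retained = TRUE,
                      p_intro = c(0.96, 0.92, 0.50),
                      direction = c("mig12", "mig12", NA))
  r <- cluster_regions(calls, step = 1e4)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0, 2e4))
  expect_equal(r$direction, "mig12")
  ## no member above the peak threshold: no region
  calls$p_intro <- c(0.92, 0.93, 0.5)
  expect_equal(nrow(cluster_regions(calls, step = 1e4)), 0L)
  ## excluded windows break runs
  calls2 <- data.frame(contig = "c1", start = (0:4) * 1e4,
                       end = (1:5) * 1e4,
                       retained = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                       p_intro = c(0.96, 0.99, NA, 0.99, 0.91),
                       direction = c("mig12", "mig21", NA, "mig21",
                                     "mig21"))
  r2 <- cluster_regions(calls2, step = 1e4)
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$start, c(0, 3e4))
  ## tie in direction votes resolved by the max-posterior window
  expect_equal(r2$direction[1], "mig21")
})

test_that("region clustering matches the run-scan oracle on random inputs", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    p <- round(runif(n), 3)
    retained <- runif(n) > 0.15
    calls <- data.frame(contig = "c1", start = (seq_len(n) - 1) * 1000,
                        end = seq_len(n) * 1000, retained = retained,
                        p_intro = ifelse(retained, p, NA),
                        direction = ifelse(retained & p > 0.5, "mig12",
                                           NA))
    got <- cluster_regions(calls, step = 1000)
    member_ok <- c(FALSE, rep(TRUE, n - 1))  # all steps adjacent
    want <- o_cluster_runs(ifelse(retained, p, NA), member_ok)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, vapply(want, function(x) (x[1] - 1) * 1000,
                                     numeric(1)))
      expect_equal(got$end, vapply(want, function(x) x[2] * 1000,
                                   numeric(1)))
    }
  }
})

test_that("clustering is idempotent under reordering of the call table", {
  set.seed(62)
  n <- 20
  p <- runif(n)
  calls <- data.frame(contig = "c1", start = (seq_len(n) - 1) * 1000,
                      end = seq_len(n) * 1000, retained = TRUE,
                      p_intro = p, direction = "mig12")
  r1 <- cluster_regions(calls, step = 1000)
  r2 <- cluster_regions(calls[sample(n), ], step = 1000)
  expect_equal(r1, r2)
})

test_that("genome classification equals per-window prediction", {
  toy <- toy_features(40, seed = 71)
  fit <- train_classifier(toy$features, toy$labels, seed = 2, tune = FALSE)
  cw <- make_contig_window(seed = 7)
  ew <- extract_windows(cw, size = 2e4, step = 2e4)
  calls <- classify_genome(fit, ew, contig = "cX")
  feats <- feature_matrix(ew$windows)
  direct <- predict(fit, feats)
  expect_equal(calls$p_intro, direct$p_intro)
  expect_equal(calls$call, direct$call)
  ## zero retained windows -> empty call set
  mask_all <- cbind(0, cw$L)
  ew0 <- extract_windows(cw, size = 2e4, step = 2e4, mask = mask_all)
  calls0 <- classify_genome(fit, ew0)
  expect_false(any(calls0$retained))
  expect_true(all(is.na(calls0$p_intro)))
})

test_that("refined intervals stay inside their coarse regions", {
  toy <- toy_features(40, seed = 81)
  fit <- train_classifier(toy$features, toy$labels, seed = 2, tune = FALSE)
  cw <- make_contig_window(seed = 8, L = 4e4, S = 400)
  coarse <- data.frame(start = c(5000, 25000), end = c(15000, 35000))
  fine <- refine_regions(fit, cw, coarse, size = 1000, step = 500,
                         cutoff = 0.2)
  if (nrow(fine) > 0) {
    inside <- vapply(seq_len(nrow(fine)), function(i) {
      any(fine[i, 1] >= coarse$start & fine[i, 2] <= coarse$end)
    }, logical(1))
    expect_true(all(inside))
  }
  expect_equal(nrow(refine_regions(fit, cw, coarse[0, ])), 0L)
})

test_that("permutation enrichment matches exhaustive enumeration on a toy", {
  ## 3 accessible slots of 10 bp; 1 region of 10 bp; 1 feature overlapping
  ## slot 1 only: placements are uniform over 3 slots (the region fills a
  ## slot exactly), so P(overlap) = 1/3
  accessible <- rbind(c(0, 10), c(20, 30), c(40, 50))
  feature <- cbind(0, 10)
  region <- cbind(20, 30)  # observed overlap 0
  res <- permutation_enrichment(region, feature, accessible,
                                n_perm = 3000, seed = 5, side = "greater")
  expect_equal(res$observed, 0L)
  ## observed 0 so every permutation has stat >= 0: p = 1
  expect_equal(res$p, 1)
  expect_lt(abs(res$permuted_mean - 1 / 3), 0.03)
  ## deficit side: P(stat <= 0) = 2/3
  res2 <- permutation_enrichment(region, feature, accessible,
                                 n_perm = 3000, seed = 5, side = "less")
  expect_equal(res2$p, 2 / 3, tolerance = 0.03)
  ## saturation: regions covering everything overlap all features
  res3 <- permutation_enrichment(accessible, feature, accessible,
                                 n_perm = 100, seed = 1, side = "less")
  expect_equal(res3$observed, 1L)
  expect_equal(res3$p, 1)
  ## zero regions
  res4 <- permutation_enrichment(NULL, feature, accessible, n_perm = 10,
                                 seed = 1)
  expect_equal(res4$observed, 0L)
  expect_error(
    permutation_enrichment(cbind(0, 100), feature, accessible,
                           n_perm = 10, seed = 1),
    "longer than any accessible")
})

test_that("called windows merge into base-pair intervals", {
  calls <- data.frame(start = c(0, 1000, 2000, 20000),
                      end = c(10000, 11000, 12000, 30000),
                      retained = c(TRUE, TRUE, TRUE, TRUE),
                      call = c(TRUE, TRUE, FALSE, TRUE))
  iv <- called_intervals(calls)
  expect_equal(iv, cbind(start = c(0, 20000), end = c(11000, 30000)))
})
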