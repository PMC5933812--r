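test_that("pairwise divergence matrix matches direct counting", {
  w <- pop_window(rbind(c(0, 1, 0, 1), c(0, 0, 1, 1),
                        c(0, 1, 0, 1), c(0, 0, 1, 1)),
                  positions = c(10, 20, 30, 40), L = 100, L_u = 100,
                  n1 = 2, n2 = 2)
  D <- pairwise_diff_matrix(w)
  expect_equal(D[1, 2], 2 / 100)
  expect_equal(D[1, 3], 0)
  expect_equal(diag(D), rep(0, 4))
  for (i in 1:30) {
    ww <- random_small_window(1000 + i)
    expect_equal(pairwise_diff_matrix(ww),
                 o_diff_counts(ww$haplotypes) / ww$L_u, tolerance = 1e-12)
  }
  wfull <- make_window(seed = 1, mask_fraction = 1)
  expect_error(pairwise_diff_matrix(wfull), "fully masked")
})

test_that("every statistic matches its brute-force oracle on random windows", {
  for (i in 1:100) {
    w <- random_small_window(i)
    fv <- feature_vector(w)
    X1 <- w$haplotypes[1:w$n1, , drop = FALSE]
    X2 <- w$haplotypes[w$n1 + 1:w$n2, , drop = FALSE]
    expect_equal(fv[["pi_1"]], o_pi_sum(X1) / w$L_u, tolerance = 1e-9)
    expect_equal(fv[["pi_2"]], o_pi_sum(X2) / w$L_u, tolerance = 1e-9)
    expect_equal(fv[["thetaH_1"]], o_thetaH_sum(X1) / w$L_u,
                 tolerance = 1e-9)
    expect_equal(fv[["fayWuH_1"]],
                 (o_pi_sum(X1) - o_thetaH_sum(X1)) / w$L_u,
                 tolerance = 1e-9)
    expect_equal(fv[["segSiteDensity_1"]], o_n_poly(X1) / w$L_u,
                 tolerance = 1e-9)
    expect_equal(fv[["tajimaD_1"]], o_tajima_d(X1), tolerance = 1e-9)
    expect_equal(fv[["tajimaD_2"]], o_tajima_d(X2), tolerance = 1e-9)
    expect_equal(fv[["ZnS_1"]], o_zns(X1), tolerance = 1e-9)
    expect_equal(fv[["ZnS_2"]], o_zns(X2), tolerance = 1e-9)
    ## cross-population block
    K <- o_diff_counts(w$haplotypes)
    cross <- K[1:w$n1, w$n1 + 1:w$n2, drop = FALSE] / w$L_u
    expect_equal(fv[["d_xy"]], mean(cross), tolerance = 1e-9)
    expect_equal(fv[["d_min"]], min(cross), tolerance = 1e-9)
    if (mean(cross) > 0) {
      expect_equal(fv[["G_min"]], min(cross) / mean(cross),
                   tolerance = 1e-9)
    }
    within1 <- (K / w$L_u)[1:w$n1, 1:w$n1]
    expect_equal(fv[["d_dRank1"]],
                 o_dd_rank(within1[upper.tri(within1)], min(cross)),
                 tolerance = 1e-9)
    ibs <- o_ibs(w)
    expect_equal(fv[["IBS_MaxB"]], ibs$IBS_MaxB, tolerance = 1e-9)
    expect_equal(fv[["IBS_Mean1"]], ibs$IBS_Mean1, tolerance = 1e-9)
    expect_equal(fv[["IBS_Mean2"]], ibs$IBS_Mean2, tolerance = 1e-9)
    expect_equal(fv[["Snn"]], o_snn(w), tolerance = 1e-9)
    ## bounds that must hold everywhere
    expect_lte(fv[["d_min"]], fv[["d_xy"]])
    expect_gte(fv[["G_min"]], 0); expect_lte(fv[["G_min"]], 1)
    expect_gte(fv[["d_dRank1"]], 0); expect_lte(fv[["d_dRank1"]], 1)
    expect_gte(fv[["d_dRank2"]], 0); expect_lte(fv[["d_dRank2"]], 1)
    expect_lte(fv[["Fst"]], 1)
    expect_lte(fv[["IBS_MaxB"]], w$L)
    expect_gte(fv[["nHaplotypes_1"]], 1)
    expect_lte(fv[["nHaplotypes_1"]], w$n1)
  }
})

test_that("monomorphic populations yield the documented sentinels", {
  X <- rbind(matrix(0L, 3, 4), matrix(c(0L, 1L), 3, 4))
  X[4:6, ] <- matrix(sample(0:1, 12, TRUE), 3)
  w <- pop_window(X, positions = c(5, 10, 15, 20), L = 100, n1 = 3, n2 = 3)
  s1 <- single_pop_stats(w, 1)
  expect_equal(s1$pi, 0)
  expect_equal(s1$segSiteDensity, 0)
  expect_equal(s1$thetaH, 0)
  expect_equal(s1$fayWuH, 0)
  expect_equal(s1$tajimaD, 0)
  expect_equal(s1$ZnS, 0)
  expect_equal(s1$nHaplotypes, 1)
})

test_that("simple algebraic identities hold", {
  ## n = 2 haplotypes differing at k sites: pi = k / L_u
  X <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L),
             c(0L, 1L, 0L), c(0L, 1L, 1L))
  w <- pop_window(X, positions = c(1, 2, 3), L = 50, n1 = 2, n2 = 2)
  expect_equal(single_pop_stats(w, 1)$pi, 3 / 50)
  ## cross divergences {0.03, 0.05} -> d_xy 0.04, G_min 0.75
  cd <- list(d_xy = mean(c(0.03, 0.05)), d_min = 0.03)
  expect_equal(cd$d_min / cd$d_xy, 0.75)
  ## d_d1 by direct substitution
  dd <- dd_stats(w, pi1 = 0.06, pi2 = 0.06, d_min = 0.03)
  expect_equal(dd$d_d1, 0.5)
  ## d_min below every within-pop divergence -> rank 0
  w2 <- make_window(seed = 9, n1 = 4, n2 = 4, S = 12)
  K <- o_diff_counts(w2$haplotypes) / w2$L_u
  dd2 <- dd_stats(w2, 0.01, 0.01, d_min = -1)
  expect_equal(dd2$d_dRank1, 0)
  expect_equal(dd2$d_dRank2, 0)
})

test_that("IBS tract rule matches the hand-computed example", {
  ## one pair with differences at bp 10 and 60 in a 100 bp window:
  ## tracts {10, 50, 40}, mean 33.33
  X <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  w <- pop_window(X, positions = c(10, 60), L = 100, n1 = 2, n2 = 2)
  ibs <- ibs_stats(w)
  expect_equal(ibs$IBS_Mean1, mean(c(10, 50, 40)))
  ## identical cross pair: max tract spans the window
  w2 <- make_window(seed = 3, identical_cross_pair = TRUE)
  expect_equal(ibs_stats(w2)$IBS_MaxB, w2$L)
})

test_that("F_ST hits its boundary cases", {
  w <- make_window(seed = 4, n1 = 5, n2 = 5, S = 15, fixed_columns = 15)
  expect_equal(feature_vector(w)[["Fst"]], 1)
  ## two independent samples from one population: F_ST about 0
  set.seed(42)
  S <- 500
  freq <- runif(S, 0.2, 0.8)
  X <- matrix(rbinom(16 * S, 1, rep(freq, each = 16)), 16)
  w2 <- pop_window(X, positions = sort(sample.int(10000, S)) - 1,
                   L = 10000, n1 = 8, n2 = 8)
  expect_lt(abs(feature_vector(w2)[["Fst"]]), 0.05)
})

test_that("Z_X components follow the stated formula", {
  for (i in 1:25) {
    w <- random_small_window(300 + i)
    z <- zx(w)
    Xg <- w$haplotypes
    expect_equal(z$ZnSG, o_zns(Xg), tolerance = 1e-9)
    if (z$ZnSG > 0) {
      expect_equal(z$Z_X, (z$ZnS1 + z$ZnS2) / (2 * z$ZnSG),
                   tolerance = 1e-12)
    } else {
      expect_equal(z$Z_X, 0)
    }
  }
  ## fewer than 2 pooled SNPs: sentinel 0
  X <- rbind(c(0L), c(1L), c(0L), c(1L))
  w1 <- pop_window(X, positions = 7, L = 100, n1 = 2, n2 = 2)
  expect_equal(zx(w1)$Z_X, 0)
})

test_that("S_nn separates distinct populations and splits ties", {
  w <- make_window(seed = 5, n1 = 4, n2 = 4, S = 20, fixed_columns = 20)
  expect_equal(snn(w), 1)
  ## 4-haplotype example with one tie, enumerated by hand:
  ## h1 = 00, h2 = 01, h3 = 00, h4 = 11 (pop1 = {h1,h2}, pop2 = {h3,h4})
  ## nearest sets: h1 -> {h3} (0 diffs): 0 same; h2 -> {h1,h3,h4} tie at 1
  ## diff: 1/3 same; h3 -> {h1}: 0 same; h4 -> {h2}: 0 same
  X <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 0L), c(1L, 1L))
  w2 <- pop_window(X, positions = c(3, 8), L = 10, n1 = 2, n2 = 2)
  expect_equal(snn(w2), mean(c(0, 1 / 3, 0, 0)))
  ## random labels on identical data give S_nn near the same-population
  ## expectation (permutation oracle)
  set.seed(99)
  vals <- replicate(200, {
    X <- matrix(sample(0:1, 8 * 15, TRUE), 8)
    X <- X[sample(8), ]
    snn(pop_window(X, positions = sort(sample(0:499, 15)), L = 500,
                   n1 = 4, n2 = 4))
  })
  expect_gt(mean(vals), 0.3)
  expect_lt(mean(vals), 0.6)
})

test_that("the feature vector is complete, symmetric, and masking-consistent", {
  w <- make_window(seed = 6, n1 = 6, n2 = 5, S = 25)
  fv <- feature_vector(w)
  expect_length(fv, 31L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  ## swapping the populations swaps paired entries and fixes symmetric ones
  ws <- pop_window(rbind(w$haplotypes[w$n1 + 1:w$n2, ],
                         w$haplotypes[1:w$n1, ]),
                   positions = w$positions, L = w$L, L_u = w$L_u,
                   n1 = w$n2, n2 = w$n1)
  fs <- feature_vector(ws)
  single <- c("pi", "varPairDist", "segSiteDensity", "privateDensity",
              "fayWuH", "thetaH", "tajimaD", "ZnS", "nHaplotypes")
  for (s in single) {
    expect_equal(fs[[paste0(s, "_1")]], fv[[paste0(s, "_2")]])
    expect_equal(fs[[paste0(s, "_2")]], fv[[paste0(s, "_1")]])
  }
  expect_equal(fs[["d_d1"]], fv[["d_d2"]])
  expect_equal(fs[["d_dRank1"]], fv[["d_dRank2"]])
  expect_equal(fs[["IBS_Mean1"]], fv[["IBS_Mean2"]])
  for (s in c("Fst", "Snn", "d_xy", "d_min", "G_min", "Z_X", "IBS_MaxB")) {
    expect_equal(fs[[s]], fv[[s]])
  }
  ## duplicating masked sites as missing-everywhere columns changes nothing
  S <- ncol(w$haplotypes)
  extra <- matrix(NA_integer_, nrow = nrow(w$haplotypes), ncol = 3)
  Xa <- cbind(w$haplotypes, extra)
  pos_a <- c(w$positions, w$L - 3:1)
  ord <- order(pos_a)
  wa <- pop_window(Xa[, ord], positions = pos_a[ord], L = w$L, L_u = w$L_u,
                   n1 = w$n1, n2 = w$n2)
  expect_equal(feature_vector(wa), fv)
})
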