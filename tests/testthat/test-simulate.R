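test_that("the pulse parameter grid has the stated structure", {
  g <- training_grid(td = 0.25, n_per_class = 1e4)
  expect_equal(nrow(g), 2 * 361)           # 19 x 19 per direction
  expect_equal(sum(g$n[g$direction == "mig12"]), 1e4)
  expect_equal(sum(g$n[g$direction == "mig21"]), 1e4)
  expect_lte(diff(range(g$n)), 1)          # as equal as possible
  gt <- training_grid(td = 0.25, test = TRUE, directions = "mig12")
  expect_equal(nrow(gt), 380)              # adds T_M = 0.001 x T_D
  expect_equal(min(gt$tm), 0.001 * 0.25)
  specs <- expand_grid_specs(g[1:3, ], condition = TRUE)
  expect_equal(nrow(specs), sum(g$n[1:3]))
  expect_true(all(specs$condition))
})

test_that("conditioned introgression examples always contain migrants and carry tracts", {
  m <- demographic_model(td = 0.25)
  g <- data.frame(direction = rep(c("mig12", "mig21"), each = 2),
                  tm = 0.25 * c(0.01, 0.45), pm = c(0.05, 0.5), n = 3)
  ex <- simulate_windows(m, expand_grid_specs(g, condition = TRUE),
                         seed = 101)
  for (e in ex) {
    expect_gte(e$n_migrant, 1L)
    expect_gte(nrow(e$tracts), 1L)
    expect_true(all(e$tracts[, 1] >= 0 & e$tracts[, 2] <= m$L))
    expect_true(all(e$migrants >= 1 & e$migrants <= 30))
    ## recipient haplotypes carry the migrant material
    if (e$label == "mig12") expect_true(all(e$migrants > 15))
    if (e$label == "mig21") expect_true(all(e$migrants <= 15))
  }
})

test_that("no-migration replicates have no migrant truth", {
  m <- demographic_model(td = 0.25)
  ex <- simulate_windows(m, null_specs(5), seed = 11)
  for (e in ex) {
    expect_equal(e$n_migrant, 0L)
    expect_equal(nrow(e$tracts), 0L)
  }
})

test_that("simulation is deterministic given the seed", {
  m <- demographic_model(td = 0.25)
  s <- expand_grid_specs(
    data.frame(direction = "mig12", tm = 0.025, pm = 0.3, n = 2))
  a <- simulate_windows(m, s, seed = 77)
  b <- simulate_windows(m, s, seed = 77)
  expect_equal(a, b)
  c2 <- simulate_windows(m, s, seed = 78)
  expect_false(identical(a, c2))
})

test_that("neutral simulations match coalescent expectations", {
  ## panmictic single population: E[S] = theta * sum(1/i), E[pi] = theta/L
  m <- demographic_model(td = NULL, theta = 50, rho = 250,
                         n1 = 15, n2 = 15)
  res <- simulate_features(m, null_specs(300), seed = 5)
  a_n <- sum(1 / seq_len(29))
  exp_S <- 50 * a_n
  obs_S <- mean(res$truth$segsites)
  se_S <- stats::sd(res$truth$segsites) / sqrt(300)
  expect_lt(abs(obs_S - exp_S), 3 * se_S + 1)
  ## pooled per-bp pi on a panmictic model (population labels arbitrary):
  ## E = theta / L = 0.005
  pi_pool <- (res$features$pi_1 + res$features$pi_2) / 2
  se_pi <- stats::sd(pi_pool) / sqrt(300)
  expect_lt(abs(mean(pi_pool) - 0.005), 3 * se_pi + 2e-4)
})

test_that("continuous migration produces monotone migrant fractions", {
  m <- demographic_model(td = 0.25)
  f0 <- simulate_continuous(m, m = 0, reps = 20, seed = 2)
  expect_equal(mean(f0$migrant), 0)
  f1 <- simulate_continuous(m, m = 0.05, reps = 150, seed = 3)
  f2 <- simulate_continuous(m, m = 1, reps = 150, seed = 4)
  expect_lte(mean(f1$migrant), mean(f2$migrant))
})

test_that("ghost-donor windows contain only the sampled haplotypes", {
  m <- demographic_model(td = 0.25)
  g <- data.frame(tm = 0.025, pm = 0.5, n = 3)
  ex <- simulate_ghost(m, g, recipient = 1, seed = 13)
  for (e in ex) {
    expect_equal(nrow(e$window$haplotypes), 30L)
    expect_equal(e$label, "ghost1")
    ## recipient population 1 receives the material
    if (e$n_migrant > 0) expect_true(all(e$migrants <= 15))
  }
})

test_that("contig simulation confines introgression to the centre", {
  m <- demographic_model(td = 0.25, L = 1e6, theta = 5000, rho = 25000)
  ex <- simulate_contig(m, data.frame(tm = c(0.05, NA), pm = c(0.7, NA)),
                        seed = 21)
  e <- ex[[1]]
  expect_gte(nrow(e$tracts), 1L)
  expect_true(all(e$tracts[, 1] >= 450000 & e$tracts[, 2] <= 550000))
  expect_equal(nrow(ex[[2]]$tracts), 0L)
  expect_equal(ex[[2]]$label, "noMig")
})

test_that("parameter-draw models stay within the stated ranges", {
  pe <- list(Nanc = 5e5, N1_0 = 1e6, N1 = 9e6, N2_0 = 1e4, N2 = 2.6e4,
             Td_gen = 1.3e6, L = 1e4)
  for (s in 1:20) {
    d <- draw_drosophila_model(pe, seed = s)
    dr <- d$draws
    for (nm in c("Nanc", "N1_0", "N1", "N2_0", "N2", "Td_gen")) {
      expect_gte(dr[[nm]], pe[[nm]] / 2)
      expect_lte(dr[[nm]], 3 * pe[[nm]] / 2)
    }
    expect_equal(dr$rho, dr$theta / 0.2)
    tm_gen <- d$tm * 4 * d$model$N0
    expect_gt(tm_gen, 0)
    expect_lte(tm_gen, dr$Td_gen / 4)
    expect_gt(d$pm, 0); expect_lte(d$pm, 1)
  }
  expect_equal(draw_drosophila_model(pe, seed = 4),
               draw_drosophila_model(pe, seed = 4))
})

test_that("the simplified island model inverts the diversity formulas", {
  mu <- 3.5e-9
  ## pi = 4 mu N -> N recovered exactly
  m <- misspecified_island_model(pi1 = 4 * mu * 1e6, pi2 = 4 * mu * 2e4,
                                 d_xy = 0.017, mu = mu)
  expect_equal(m$sizes$p1, 1e6)
  expect_equal(m$sizes$p2, 2e4)
  expect_equal(m$sizes$anc, 1e6)
  T_gen <- m$td * 4 * m$N0
  expect_equal(T_gen, 0.017 / (2 * mu) - 2e6)
  ## d_xy = 4 mu N_anc puts the split at T = 0
  expect_error(
    misspecified_island_model(pi1 = 4 * mu * 1e6, pi2 = 4 * mu * 1e4,
                              d_xy = 4 * mu * 1e6 * 0.9, mu = mu),
    "negative")
  m0 <- misspecified_island_model(pi1 = 4 * mu * 1e6, pi2 = 4 * mu * 1e4,
                                  d_xy = 4 * mu * 1e6, mu = mu)
  expect_null(m0$td)  # T = 0 generations: the split vanishes
})

test_that("real-mask mirroring updates sites and unmasked length", {
  lib <- make_mask_library(10, L = 1e4, fractions = c(0, 0.3), seed = 8)
  expect_equal(lib, make_mask_library(10, L = 1e4, fractions = c(0, 0.3),
                                      seed = 8))
  fracs <- vapply(lib, function(m) ivl_length(m) / 1e4, numeric(1))
  expect_equal(fracs, rep(c(0, 0.3), 5), tolerance = 0.01)
  w <- make_window(seed = 12, S = 50)
  wm <- apply_real_mask(w, lib, seed = 3)
  idx <- attr(wm, "mask_index")
  expect_equal(wm$L_u, w$L_u - ivl_length(lib[[idx]]))
  ## empty mask leaves the window unchanged
  w0 <- apply_real_mask(w, lib[1], seed = 3)
  expect_equal(w0$L_u, w$L_u)
  expect_equal(ncol(w0$haplotypes), ncol(w$haplotypes))
  expect_error(apply_real_mask(w, list(), seed = 1), "empty")
})
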