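# Independent brute-force implementations of every statistic, written as
# direct loops over the textbook formulas. These exist solely as oracles for
# the vectorized/compiled implementations in the package.

o_diff_counts <- function(X) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) K[i, j] <- sum(X[i, ] != X[j, ], na.rm = TRUE)
  }
  K
}

o_pi_sum <- function(X) {
  tot <- 0
  for (s in seq_len(ncol(X))) {
    col <- X[, s]
    nk <- sum(!is.na(col)); dk <- sum(col, na.rm = TRUE)
    if (nk >= 2 && dk > 0 && dk < nk) {
      tot <- tot + 2 * dk * (nk - dk) / (nk * (nk - 1))
    }
  }
  tot
}

o_thetaH_sum <- function(X) {
  tot <- 0
  for (s in seq_len(ncol(X))) {
    col <- X[, s]
    nk <- sum(!is.na(col)); dk <- sum(col, na.rm = TRUE)
    if (nk >= 2 && dk > 0 && dk < nk) {
      tot <- tot + 2 * dk^2 / (nk * (nk - 1))
    }
  }
  tot
}

o_n_poly <- function(X) {
  cnt <- 0
  for (s in seq_len(ncol(X))) {
    col <- X[, s]
    dk <- sum(col, na.rm = TRUE)
    if (dk > 0 && dk < sum(!is.na(col))) cnt <- cnt + 1
  }
  cnt
}

o_tajima_d <- function(X) {
  n <- nrow(X)
  S <- o_n_poly(X)
  if (S == 0) return(0)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(0)  # n = 2: variance terms vanish
  (o_pi_sum(X) - S / a1) / denom
}

o_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  (sum((x - mean(x)) * (y - mean(y))))^2 / (sx * sy)
}

o_zns <- function(X) {
  poly <- vapply(seq_len(ncol(X)), function(s) {
    dk <- sum(X[, s], na.rm = TRUE)
    dk > 0 && dk < sum(!is.na(X[, s]))
  }, logical(1))
  Xp <- X[, poly, drop = FALSE]
  S <- ncol(Xp)
  if (S < 2) return(0)
  vals <- c()
  for (a in seq_len(S - 1)) for (b in (a + 1):S) {
    vals <- c(vals, o_r2(Xp[, a], Xp[, b]))
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(0)
  mean(vals)
}

o_ibs_tracts <- function(xi, xj, pos, L) {
  d <- which(xi != xj)  # NA-safe: NA comparisons are dropped by which()
  if (length(d) == 0) return(L)
  p <- pos[d]
  c(p[1], diff(p), L - p[length(p)])
}

o_ibs <- function(w) {
  X <- w$haplotypes; pos <- w$positions; L <- w$L
  within_mean <- function(rows) {
    vals <- c()
    for (i in seq_along(rows)) for (j in seq_along(rows)) {
      if (i < j) {
        vals <- c(vals, mean(o_ibs_tracts(X[rows[i], ], X[rows[j], ],
                                          pos, L)))
      }
    }
    mean(vals)
  }
  mx <- 0
  for (i in 1:w$n1) for (j in (w$n1 + 1):(w$n1 + w$n2)) {
    mx <- max(mx, max(o_ibs_tracts(X[i, ], X[j, ], pos, L)))
  }
  list(IBS_MaxB = mx, IBS_Mean1 = within_mean(1:w$n1),
       IBS_Mean2 = within_mean(w$n1 + 1:w$n2))
}

o_snn <- function(w) {
  K <- o_diff_counts(w$haplotypes)
  n <- nrow(K)
  popid <- rep(1:2, c(w$n1, w$n2))
  fr <- numeric(n)
  for (i in 1:n) {
    d <- K[i, -i]; pp <- popid[-i]
    nn <- which(d == min(d))
    fr[i] <- sum(pp[nn] == popid[i]) / length(nn)
  }
  mean(fr)
}

o_dd_rank <- function(within_divs, d_min) {
  s <- sort(within_divs)
  (sum(s < d_min) + 0.5 * sum(s == d_min)) / length(s)
}

o_auc_rank <- function(scores, labels) {
  # Mann-Whitney U identity
  labels <- as.logical(labels)
  r <- rank(scores)
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

o_cluster_runs <- function(p, step_ok, p_run = 0.9, p_peak = 0.95) {
  # run-scan over a posterior sequence; step_ok[i] TRUE if window i is
  # adjacent to window i-1; returns list of index ranges of kept regions
  member <- !is.na(p) & p > p_run
  out <- list()
  i <- 1
  while (i <= length(p)) {
    if (!member[i]) { i <- i + 1; next }
    j <- i
    while (j < length(p) && member[j + 1] && step_ok[j + 1]) j <- j + 1
    if (max(p[i:j]) > p_peak) out[[length(out) + 1]] <- c(i, j)
    i <- j + 1
  }
  out
}

o_bp_metrics <- function(pred, truth, L) {
  # boolean-vector comparison on an integer grid
  pv <- rep(FALSE, L); tv <- rep(FALSE, L)
  if (NROW(pred) > 0) for (i in seq_len(NROW(pred))) {
    pv[(pred[i, 1] + 1):pred[i, 2]] <- TRUE
  }
  if (NROW(truth) > 0) for (i in seq_len(NROW(truth))) {
    tv[(truth[i, 1] + 1):truth[i, 2]] <- TRUE
  }
  list(sensitivity = if (sum(tv) > 0) sum(pv & tv) / sum(tv) else NA_real_,
       fpr = if (sum(!tv) > 0) sum(pv & !tv) / sum(!tv) else NA_real_,
       ppv = if (sum(pv) > 0) sum(pv & tv) / sum(pv) else 0)
}

# small random windows for property tests
random_small_window <- function(seed) {
  set.seed(seed)
  make_window(seed = seed,
              n1 = sample(2:8, 1), n2 = sample(2:8, 1),
              S = sample(2:30, 1), L = 1000L,
              missing_rate = sample(c(0, 0, 0.1), 1))
}
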