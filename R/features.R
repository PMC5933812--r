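#' Construct a two-population haplotype window
#'
#' The container consumed by all summary statistics: a haplotype matrix for
#' `n1 + n2` sampled chromosomes (population 1 rows first) over the
#' segregating sites of a genomic window, with base-pair site positions and
#' masking-aware length bookkeeping.
#'
#' @param haplotypes integer matrix, `n1 + n2` rows by S sites; entries 0/1
#'   (`0` = ancestral when `polarized`) or `NA` for missing alleles.
#' @param positions numeric vector of strictly increasing site positions in
#'   bp, in `[0, L)`.
#' @param L window length in bp.
#' @param L_u unmasked window length in bp (denominator of all per-bp
#'   statistics); defaults to `L`.
#' @param n1,n2 haplotype counts of populations 1 and 2.
#' @param polarized logical: is allele 0 the ancestral state? Fay and Wu's
#'   statistics are only meaningful when `TRUE`.
#' @param validate check invariants (default `TRUE`).
#' @return an object of class `pop_window`.
#' @export
pop_window <- function(haplotypes, positions, L, L_u = L, n1, n2,
                       polarized = TRUE, validate = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  ## sites masked everywhere carry no information; drop them
  if (ncol(haplotypes) > 0L) {
    informative <- colSums(!is.na(haplotypes)) > 0L
    haplotypes <- haplotypes[, informative, drop = FALSE]
    positions <- positions[informative]
  }
  w <- structure(list(haplotypes = haplotypes, positions = as.numeric(positions),
                      L = as.numeric(L), L_u = as.numeric(L_u),
                      n1 = as.integer(n1), n2 = as.integer(n2),
                      polarized = isTRUE(polarized)),
                 class = "pop_window")
  if (validate) validate_pop_window(w)
  w
}

validate_pop_window <- function(w) {
  if (w$n1 < 2L || w$n2 < 2L) stop("need at least 2 haplotypes per population")
  if (nrow(w$haplotypes) != w$n1 + w$n2) {
    stop("haplotype matrix must have n1 + n2 rows")
  }
  if (length(w$positions) != ncol(w$haplotypes)) {
    stop("positions length must equal number of sites")
  }
  if (length(w$positions) > 1L && any(diff(w$positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (length(w$positions) > 0L &&
      (min(w$positions) < 0 || max(w$positions) >= w$L)) {
    stop("positions must lie in [0, L)")
  }
  if (w$L_u > w$L || w$L_u < 0) stop("L_u must lie in [0, L]")
  bad <- !(is.na(w$haplotypes) | w$haplotypes == 0L | w$haplotypes == 1L)
  if (any(bad)) stop("alleles must be 0, 1, or NA")
  invisible(w)
}

#' @export
print.pop_window <- function(x, ...) {
  cat(sprintf(
    "pop_window: %d + %d haplotypes, %d segregating sites, L = %g bp (L_u = %g)%s\n",
    x$n1, x$n2, ncol(x$haplotypes), x$L, x$L_u,
    if (x$polarized) "" else " [unpolarized]"))
  invisible(x)
}

pop_rows <- function(w, pop) {
  if (pop == 1L) seq_len(w$n1) else w$n1 + seq_len(w$n2)
}

#' Pairwise difference counts between all haplotypes
#'
#' Entry (i, j) is the number of sites at which haplotypes i and j are both
#' non-missing and carry different alleles.
#' @keywords internal
pair_diff_counts <- function(w) {
  X <- w$haplotypes
  n <- nrow(X)
  if (ncol(X) == 0L) return(matrix(0, n, n))
  cpp_pair_diff_counts(X)
}

#' Matrix of per-bp divergences between all haplotype pairs
#'
#' @param window a [pop_window()].
#' @return symmetric `(n1+n2) x (n1+n2)` matrix; entry (i, j) is the number
#'   of sites where i and j are both non-missing and differ, divided by the
#'   unmasked window length.
#' @export
pairwise_diff_matrix <- function(window) {
  if (window$L_u <= 0) stop("window fully masked")
  pair_diff_counts(window) / window$L_u
}

## Per-site allele counts within a set of rows: list(n = non-missing count,
## d = count of allele 1)
site_counts <- function(X) {
  if (ncol(X) == 0L) return(list(n = integer(0), d = integer(0)))
  nm <- colSums(!is.na(X))
  d <- colSums(X, na.rm = TRUE)
  list(n = nm, d = d)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

## Mean r^2 over all pairs of the given columns (haplotype rows x sites),
## pairwise-complete over missing data; 0 when < 2 usable sites.
mean_r2 <- function(X) {
  if (ncol(X) < 2L) return(0)
  cpp_mean_r2(X)
}

## Distinct rows with NA treated as a wildcard: a row matches an earlier
## representative if every column is equal or missing in either. Greedy
## first-match scan (deterministic).
n_distinct_haps <- function(X) {
  n <- nrow(X)
  if (n == 0L) return(0L)
  if (ncol(X) == 0L) return(1L)
  if (!anyNA(X)) {
    return(nrow(unique(X)))
  }
  reps <- list(X[1L, ])
  for (i in seq_len(n)[-1L]) {
    xi <- X[i, ]
    matched <- FALSE
    for (r in reps) {
      cmp <- xi == r
      if (all(cmp | is.na(cmp))) { matched <- TRUE; break }
    }
    if (!matched) reps[[length(reps) + 1L]] <- xi
  }
  length(reps)
}

#' Single-population summary statistics
#'
#' The nine per-population statistics of the feature vector: nucleotide
#' diversity `pi`, the variance of per-bp pairwise distances, the densities
#' of segregating and private sites, Fay and Wu's H and theta_H, Tajima's D,
#' `ZnS` (mean r^2 over SNP pairs, Kelly 1997), and the number of distinct
#' haplotypes. Per-bp statistics are normalized by the unmasked length
#' `L_u`; degenerate cases (monomorphic windows) return the documented
#' sentinel values.
#'
#' @param window a [pop_window()].
#' @param pop 1 or 2.
#' @param diff_matrix optional precomputed [pairwise_diff_matrix()].
#' @return named list of the 9 statistics.
#' @export
single_pop_stats <- function(window, pop, diff_matrix = NULL) {
  if (window$L_u <= 0) stop("window fully masked")
  rows <- pop_rows(window, pop)
  other <- pop_rows(window, if (pop == 1L) 2L else 1L)
  X <- window$haplotypes[rows, , drop = FALSE]
  n <- length(rows)
  sc <- site_counts(X)
  poly <- sc$d > 0L & sc$d < sc$n
  nn <- sc$n[poly]; dd <- sc$d[poly]
  ok <- nn >= 2L
  ## pi as a sum of per-site heterozygosities (sample-size aware per site)
  pi_sum <- sum(2 * dd[ok] * (nn[ok] - dd[ok]) / (nn[ok] * (nn[ok] - 1)))
  pi <- pi_sum / window$L_u
  ## theta_H: doubly weighted by derived-allele count (polarized data)
  thetaH_sum <- sum(2 * dd[ok]^2 / (nn[ok] * (nn[ok] - 1)))
  thetaH <- thetaH_sum / window$L_u
  fayWuH <- pi - thetaH
  S <- sum(poly)
  segSiteDensity <- S / window$L_u
  sco <- site_counts(window$haplotypes[other, , drop = FALSE])
  mono_other <- !(sco$d > 0L & sco$d < sco$n)
  privateDensity <- sum(poly & mono_other) / window$L_u
  if (S == 0L) {
    tajD <- 0
  } else {
    tc <- tajima_constants(n)
    denom <- sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
    tajD <- if (denom > 0) (pi_sum - S / tc$a1) / denom else 0
  }
  if (is.null(diff_matrix)) diff_matrix <- pairwise_diff_matrix(window)
  d_sub <- diff_matrix[rows, rows]
  pair_d <- d_sub[upper.tri(d_sub)]
  varPairDist <- if (length(pair_d) > 1L) stats::var(pair_d) else 0
  ZnS <- mean_r2(X[, poly, drop = FALSE])
  nHap <- n_distinct_haps(X[, poly, drop = FALSE])
  list(pi = pi, varPairDist = varPairDist, segSiteDensity = segSiteDensity,
       privateDensity = privateDensity, fayWuH = fayWuH, thetaH = thetaH,
       tajimaD = tajD, ZnS = ZnS, nHaplotypes = nHap)
}

#' Cross-population divergence statistics
#'
#' `d_xy` is the mean and `d_min` the minimum per-bp divergence over all
#' `n1 x n2` cross-population haplotype pairs; `G_min = d_min / d_xy`
#' (sentinel 0 when `d_xy = 0`).
#'
#' @inheritParams single_pop_stats
#' @return named list with `d_xy`, `d_min`, `G_min`.
#' @export
cross_divergence <- function(window, diff_matrix = NULL) {
  if (is.null(diff_matrix)) diff_matrix <- pairwise_diff_matrix(window)
  cross <- diff_matrix[pop_rows(window, 1L), pop_rows(window, 2L), drop = FALSE]
  d_xy <- mean(cross)
  d_min <- min(cross)
  list(d_xy = d_xy, d_min = d_min,
       G_min = if (d_xy > 0) d_min / d_xy else 0)
}

#' d_min scaled by within-population diversity, and its percentile ranks
#'
#' `d_d1 = d_min / pi_1` (and analogously `d_d2`): under recent introgression
#' from population p the closest cross-population pair coalesces within the
#' donor, so `d_min` falls to the order of `pi_p`. `d_dRank_p` is the
#' midrank percentile (fraction in `[0, 1]`) of `d_min` within the multiset
#' of within-population-p pairwise divergences. When `pi_p = 0` it is
#' replaced by the smallest attainable nonzero value,
#' `1 / (L_u * choose(n_p, 2))`.
#'
#' @inheritParams single_pop_stats
#' @param pi1,pi2 per-bp nucleotide diversities (from [single_pop_stats()]).
#' @param d_min per-bp minimum cross-population divergence.
#' @return named list with `d_d1`, `d_d2`, `d_dRank1`, `d_dRank2`.
#' @export
dd_stats <- function(window, pi1, pi2, d_min, diff_matrix = NULL) {
  if (is.null(diff_matrix)) diff_matrix <- pairwise_diff_matrix(window)
  res <- list()
  for (p in 1:2) {
    rows <- pop_rows(window, p)
    n_p <- length(rows)
    pi_p <- if (p == 1L) pi1 else pi2
    if (pi_p <= 0) pi_p <- 1 / (window$L_u * choose(n_p, 2))
    res[[paste0("d_d", p)]] <- d_min / pi_p
    sub <- diff_matrix[rows, rows]
    within <- sub[upper.tri(sub)]
    res[[paste0("d_dRank", p)]] <-
      (sum(within < d_min) + 0.5 * sum(within == d_min)) / length(within)
  }
  res
}

#' Within- versus pooled-population linkage disequilibrium contrast
#'
#' `Z_X = (ZnS1 + ZnS2) / (2 ZnSG)` where `ZnS_p` is the mean r^2 over pairs
#' of sites polymorphic within population p and `ZnSG` the same over sites
#' polymorphic in the pooled sample. Introgression inflates within-population
#' LD relative to pooled LD, lowering `Z_X`'s complement; sentinel 0 when
#' `ZnSG` is undefined.
#'
#' @inheritParams single_pop_stats
#' @param ZnS1,ZnS2 optional precomputed within-population values.
#' @return named list with `ZnS1`, `ZnS2`, `ZnSG`, `Z_X`.
#' @export
zx <- function(window, ZnS1 = NULL, ZnS2 = NULL) {
  pop_znS <- function(p) {
    X <- window$haplotypes[pop_rows(window, p), , drop = FALSE]
    sc <- site_counts(X)
    mean_r2(X[, sc$d > 0L & sc$d < sc$n, drop = FALSE])
  }
  if (is.null(ZnS1)) ZnS1 <- pop_znS(1L)
  if (is.null(ZnS2)) ZnS2 <- pop_znS(2L)
  X <- window$haplotypes
  sc <- site_counts(X)
  ZnSG <- mean_r2(X[, sc$d > 0L & sc$d < sc$n, drop = FALSE])
  list(ZnS1 = ZnS1, ZnS2 = ZnS2, ZnSG = ZnSG,
       Z_X = if (ZnSG > 0) (ZnS1 + ZnS2) / (2 * ZnSG) else 0)
}

#' Identity-by-state tract length statistics
#'
#' For a pair of haplotypes the IBS tracts are the gaps between consecutive
#' difference positions plus the two window flanks (a pair with no
#' differences yields a single tract of length L). `IBS_Mean1`/`IBS_Mean2`
#' are the mean tract lengths over all within-population pairs, and
#' `IBS_MaxB` is the maximum tract length over all cross-population pairs.
#'
#' @inheritParams single_pop_stats
#' @return named list with `IBS_MaxB`, `IBS_Mean1`, `IBS_Mean2`.
#' @export
ibs_stats <- function(window, diff_matrix = NULL) {
  K <- pair_diff_counts(window)
  L <- window$L
  means <- numeric(2)
  for (p in 1:2) {
    rows <- pop_rows(window, p)
    sub <- K[rows, rows]
    k <- sub[upper.tri(sub)]
    ## a pair with k differences partitions [0, L) into k + 1 tracts
    means[p] <- mean(L / (k + 1))
  }
  max_b <- cpp_ibs_max_cross(window$haplotypes, window$positions,
                             window$n1, L)
  list(IBS_MaxB = max_b, IBS_Mean1 = means[1], IBS_Mean2 = means[2])
}

#' Hudson-style F_ST from within- and between-population diversity
#'
#' `F_ST = 1 - mean(pi_1, pi_2) / d_xy`; sentinel 0 when `d_xy = 0`;
#' negative values are retained.
#'
#' @param pi1,pi2,d_xy per-bp diversities and mean cross-population
#'   divergence.
#' @export
hudson_fst <- function(pi1, pi2, d_xy) {
  if (d_xy <= 0) return(0)
  1 - ((pi1 + pi2) / 2) / d_xy
}

#' Hudson's nearest-neighbour statistic S_nn
#'
#' For each haplotype, the fraction of its nearest neighbours (haplotypes at
#' minimal distance, ties sharing credit equally) that belong to its own
#' population; `S_nn` is the mean of this fraction over all haplotypes.
#'
#' @inheritParams single_pop_stats
#' @export
snn <- function(window, diff_matrix = NULL) {
  K <- pair_diff_counts(window)
  n <- nrow(K)
  if (n < 4L) stop("S_nn requires at least 4 haplotypes")
  popid <- rep(1:2, c(window$n1, window$n2))
  fr <- numeric(n)
  for (i in seq_len(n)) {
    d <- K[i, -i]
    same <- popid[-i] == popid[i]
    nn <- d == min(d)
    fr[i] <- sum(nn & same) / sum(nn)
  }
  mean(fr)
}

#' Canonical feature order of the 31-statistic vector
#'
#' @return character vector of length 31: the 9 single-population statistics
#'   for population 1, the same for population 2, then the 13
#'   cross-population statistics.
#' @export
feature_names <- function() {
  single <- c("pi", "varPairDist", "segSiteDensity", "privateDensity",
              "fayWuH", "thetaH", "tajimaD", "ZnS", "nHaplotypes")
  c(paste0(single, "_1"), paste0(single, "_2"),
    "Fst", "Snn", "d_xy", "d_min", "G_min", "d_d1", "d_d2",
    "d_dRank1", "d_dRank2", "Z_X", "IBS_MaxB", "IBS_Mean1", "IBS_Mean2")
}

#' Compute the full 31-statistic feature vector for a window
#'
#' @param window a [pop_window()].
#' @return named numeric vector of length 31 in the canonical
#'   [feature_names()] order; all values finite (degenerate statistics take
#'   their documented sentinel values).
#' @export
feature_vector <- function(window) {
  dm <- pairwise_diff_matrix(window)
  s1 <- single_pop_stats(window, 1L, dm)
  s2 <- single_pop_stats(window, 2L, dm)
  cd <- cross_divergence(window, dm)
  dd <- dd_stats(window, s1$pi, s2$pi, cd$d_min, dm)
  z <- zx(window, ZnS1 = s1$ZnS, ZnS2 = s2$ZnS)
  ibs <- ibs_stats(window, dm)
  v <- c(unlist(s1, use.names = FALSE), unlist(s2, use.names = FALSE),
         hudson_fst(s1$pi, s2$pi, cd$d_xy), snn(window, dm),
         cd$d_xy, cd$d_min, cd$G_min,
         dd$d_d1, dd$d_d2, dd$d_dRank1, dd$d_dRank2,
         z$Z_X, ibs$IBS_MaxB, ibs$IBS_Mean1, ibs$IBS_Mean2)
  names(v) <- feature_names()
  stopifnot(all(is.finite(v)))
  v
}

#' Feature matrix for a list of windows or simulated examples
#'
#' @param windows list of [pop_window()] objects or simulated examples
#'   (lists with a `window` element).
#' @return data.frame with 31 feature columns in canonical order.
#' @export
feature_matrix <- function(windows) {
  rows <- lapply(windows, function(w) {
    if (!inherits(w, "pop_window")) w <- w$window
    feature_vector(w)
  })
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- feature_names()
  out
}
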