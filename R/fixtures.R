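#' Deterministic toy haplotype windows for tests and examples
#'
#' Generates a small [pop_window()] from a seed, optionally planting exact
#' structures used by tests: an identical cross-population haplotype pair
#' (forcing `d_min = 0`), columns fixed for alternative alleles between the
#' populations (forcing `F_ST = 1` when all columns are fixed), random
#' missingness, and a masked fraction (reducing `L_u`).
#'
#' @param seed integer seed (fixture randomness is independent of the
#'   simulation module's seed stream).
#' @param n1,n2 haplotype counts per population.
#' @param S number of segregating sites.
#' @param L window length in bp.
#' @param identical_cross_pair plant haplotype 1 of each population as
#'   identical.
#' @param fixed_columns number of columns fixed for alternative alleles
#'   between populations (`S` for complete fixation).
#' @param missing_rate per-allele missingness probability.
#' @param mask_fraction fraction of the window masked (reduces `L_u`).
#' @return a [pop_window()].
#' @export
make_window <- function(seed = 1L, n1 = 5L, n2 = 5L, S = 20L, L = 10000L,
                        identical_cross_pair = FALSE, fixed_columns = 0L,
                        missing_rate = 0, mask_fraction = 0) {
  if (identical_cross_pair && fixed_columns > 0L) {
    stop("cannot plant an identical cross pair and fixed columns at once")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 77L))
  n <- n1 + n2
  freq <- stats::runif(S, 0.1, 0.9)
  X <- matrix(stats::rbinom(n * S, 1L, rep(freq, each = n)), nrow = n)
  if (fixed_columns > 0L) {
    idx <- seq_len(min(fixed_columns, S))
    X[seq_len(n1), idx] <- 0L
    X[n1 + seq_len(n2), idx] <- 1L
  }
  if (identical_cross_pair) X[n1 + 1L, ] <- X[1L, ]
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * S) < missing_rate, nrow = n)
    ## keep >= 1 non-missing allele per population per site
    for (p in list(seq_len(n1), n1 + seq_len(n2))) {
      allmiss <- colSums(!miss[p, , drop = FALSE]) == 0L
      if (any(allmiss)) miss[p[1L], allmiss] <- FALSE
    }
    if (identical_cross_pair) miss[c(1L, n1 + 1L), ] <- FALSE
    X[miss] <- NA_integer_
  }
  ## ensure sites are polymorphic in the pooled sample where possible
  pos <- sort(sample.int(L, S)) - 1L
  pop_window(X, positions = pos, L = L, L_u = round(L * (1 - mask_fraction)),
             n1 = n1, n2 = n2, polarized = TRUE)
}

#' Library of per-window mask interval sets
#'
#' Stand-in for the per-window masked-site patterns of a real data set, used
#' by [apply_real_mask()]. Each mask is a set of intervals covering
#' approximately the requested fraction of the window.
#'
#' @param n number of masks.
#' @param L window length in bp.
#' @param fractions vector of target masked fractions, recycled over masks.
#' @param seed integer seed.
#' @param n_blocks number of masked blocks per window.
#' @return list of interval matrices (possibly empty).
#' @export
make_mask_library <- function(n, L, fractions = 0.1, seed = 1L,
                              n_blocks = 5L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 101L))
  fractions <- rep_len(fractions, n)
  lapply(seq_len(n), function(i) {
    f <- fractions[i]
    if (f <= 0) return(as_ivl(NULL))
    total <- round(L * f)
    sizes <- rep(floor(total / n_blocks), n_blocks)
    sizes[1L] <- sizes[1L] + total - sum(sizes)
    ## place blocks without overlap by splitting the window into slots
    slot <- floor(L / n_blocks)
    starts <- (seq_len(n_blocks) - 1L) * slot +
      vapply(sizes, function(s) sample.int(max(slot - s, 1L), 1L) - 1L,
             integer(1))
    ivl_normalize(cbind(starts, starts + sizes))
  })
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
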