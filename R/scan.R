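#' Extract (sliding) windows from a long haplotype region
#'
#' Cuts a contig-scale [pop_window()] into fixed-size windows (optionally
#' sliding), applying an accessibility mask: a window whose masked fraction
#' exceeds `max_masked` (default 0.25) is flagged excluded and carries no
#' evidence downstream.
#'
#' @param contig_window a [pop_window()] spanning the contig.
#' @param size window size in bp (default 10 kb).
#' @param step step size in bp (default `size`: non-overlapping windows).
#' @param mask interval matrix of masked regions on the contig (bp).
#' @param max_masked maximum tolerated masked fraction.
#' @return list with `windows` (list of [pop_window()]s, `NULL` where
#'   excluded) and `table` (data.frame: start, end, masked_fraction,
#'   retained).
#' @export
extract_windows <- function(contig_window, size = 1e4, step = size,
                            mask = NULL, max_masked = 0.25) {
  L <- contig_window$L
  if (size > L) stop("window larger than contig")
  starts <- seq(0, L - size, by = step)
  mask <- ivl_normalize(if (is.null(mask)) NULL else mask)
  pos <- contig_window$positions
  windows <- vector("list", length(starts))
  tab <- data.frame(start = starts, end = starts + size,
                    masked_fraction = 0, retained = TRUE)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + size
    m_here <- ivl_intersect(mask, cbind(s, e))
    m_len <- ivl_length(m_here)
    tab$masked_fraction[i] <- m_len / size
    if (m_len / size > max_masked) {
      tab$retained[i] <- FALSE
      next
    }
    keep <- pos >= s & pos < e
    w <- pop_window(contig_window$haplotypes[, keep, drop = FALSE],
                    positions = pos[keep] - s, L = size, L_u = size - m_len,
                    n1 = contig_window$n1, n2 = contig_window$n2,
                    polarized = contig_window$polarized, validate = FALSE)
    if (nrow(m_here) > 0L) {
      w <- mask_pop_window(w, m_here - s)
      w$L_u <- size - m_len
    }
    windows[[i]] <- w
  }
  list(windows = windows, table = tab)
}

#' Classify every retained window of a contig
#'
#' @param model an `introscan_model`.
#' @param extraction result of [extract_windows()].
#' @param contig contig name for the output table.
#' @param cutoff posterior cutoff (defaults to the model's).
#' @return data.frame of window calls: coordinates, masked fraction,
#'   retained flag, class posteriors, `p_intro`, `call`, `direction`
#'   (`NA` posteriors for excluded windows).
#' @export
classify_genome <- function(model, extraction, contig = "contig1",
                            cutoff = NULL) {
  tab <- extraction$table
  out <- data.frame(contig = contig, tab,
                    p_intro = NA_real_, call = FALSE,
                    direction = NA_character_, stringsAsFactors = FALSE)
  idx <- which(tab$retained)
  if (length(idx) > 0L) {
    feats <- feature_matrix(extraction$windows[idx])
    pred <- stats::predict(model, feats, cutoff = cutoff)
    out$p_intro[idx] <- pred$p_intro
    out$call[idx] <- pred$call
    out$direction[idx] <- pred$direction
  }
  out
}

#' Cluster window calls into introgressed regions
#'
#' Finds maximal runs of consecutive retained windows whose posterior
#' probability of introgression exceeds `p_run` (default 0.90) and keeps
#' those runs containing at least one window above `p_peak` (default 0.95).
#' Excluded (masked-out) windows break runs. The region direction is the
#' majority of member-window directions (ties resolved by the
#' highest-posterior window).
#'
#' @param calls data.frame from [classify_genome()] (columns start, end,
#'   retained, p_intro, direction), sorted by coordinate.
#' @param p_run run-membership posterior threshold (strict inequality).
#' @param p_peak retention threshold: max member posterior must exceed it.
#' @param step expected distance between consecutive window starts;
#'   defaults to the observed spacing.
#' @return data.frame of regions: contig, start, end, n_windows, direction,
#'   max_posterior.
#' @export
cluster_regions <- function(calls, p_run = 0.90, p_peak = 0.95,
                            step = NULL) {
  calls <- calls[order(calls$start), , drop = FALSE]
  if (is.null(step)) {
    step <- if (nrow(calls) > 1L) min(diff(calls$start)) else 0
  }
  member <- calls$retained & !is.na(calls$p_intro) & calls$p_intro > p_run
  regions <- NULL
  i <- 1L
  n <- nrow(calls)
  while (i <= n) {
    if (!member[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && member[j + 1L] &&
           isTRUE(all.equal(calls$start[j + 1L] - calls$start[j], step))) {
      j <- j + 1L
    }
    run <- calls[i:j, , drop = FALSE]
    if (max(run$p_intro) > p_peak) {
      dirs <- run$direction[!is.na(run$direction)]
      if (length(dirs) == 0L) {
        direction <- NA_character_
      } else {
        tt <- sort(table(dirs), decreasing = TRUE)
        if (length(tt) > 1L && tt[1] == tt[2]) {
          direction <- run$direction[which.max(run$p_intro)]
        } else {
          direction <- names(tt)[1]
        }
      }
      regions <- rbind(regions, data.frame(
        contig = run$contig[1] %||% "contig1",
        start = min(run$start), end = max(run$end),
        n_windows = nrow(run), direction = direction,
        max_posterior = max(run$p_intro), stringsAsFactors = FALSE))
    }
    i <- j + 1L
  }
  if (is.null(regions)) {
    regions <- data.frame(contig = character(0), start = numeric(0),
                          end = numeric(0), n_windows = integer(0),
                          direction = character(0),
                          max_posterior = numeric(0))
  }
  regions
}

#' Refine coarse introgressed regions with a fine-scale classifier
#'
#' Applies a classifier trained on small windows (default 1 kb, 100 bp
#' step) inside each coarse region, retaining fine windows whose posterior
#' probability of introgression exceeds 0.5 (introgression more probable
#' than not; lenient because the region already passed the coarse
#' classifier), and merges retained windows into intervals.
#'
#' @param fine_model an `introscan_model` trained at the fine window size.
#' @param contig_window the contig-scale [pop_window()].
#' @param coarse_regions data.frame from [cluster_regions()] (or predicted
#'   coarse intervals with start/end columns).
#' @param size,step fine window size and step in bp.
#' @param cutoff posterior cutoff on `p_intro` (default 0.5).
#' @param mask optional contig mask intervals.
#' @return interval matrix of refined introgressed intervals (bp).
#' @export
refine_regions <- function(fine_model, contig_window, coarse_regions,
                           size = 1e3, step = 100, cutoff = 0.5,
                           mask = NULL) {
  if (NROW(coarse_regions) == 0L) return(as_ivl(NULL))
  out <- NULL
  for (i in seq_len(NROW(coarse_regions))) {
    s0 <- max(0, coarse_regions$start[i])
    e0 <- min(contig_window$L, coarse_regions$end[i])
    if (e0 - s0 < size) next
    starts <- seq(s0, e0 - size, by = step)
    pos <- contig_window$positions
    wins <- lapply(starts, function(s) {
      keep <- pos >= s & pos < s + size
      pop_window(contig_window$haplotypes[, keep, drop = FALSE],
                 positions = pos[keep] - s, L = size, L_u = size,
                 n1 = contig_window$n1, n2 = contig_window$n2,
                 polarized = contig_window$polarized, validate = FALSE)
    })
    feats <- feature_matrix(wins)
    pred <- stats::predict(fine_model, feats)
    hit <- pred$p_intro > cutoff
    if (any(hit)) {
      out <- rbind(out, cbind(starts[hit], starts[hit] + size))
    }
  }
  ## clip to coarse spans and merge
  ivl_intersect(ivl_normalize(out),
                cbind(coarse_regions$start, coarse_regions$end))
}

#' Permutation test for overlap between regions and annotation features
#'
#' Randomly reassigns each region to a new location such that its full span
#' lies within the accessible portion of the genome (uniform over valid
#' placements, independently per region), and compares the observed number
#' of annotation features overlapped by at least one region with the
#' permuted distribution. Add-one correction avoids zero p-values.
#'
#' @param regions interval matrix/data.frame of called regions (bp).
#' @param annotations interval matrix of annotation features.
#' @param accessible interval matrix of accessible windows.
#' @param n_perm number of permutations (default 1e4).
#' @param seed integer seed.
#' @param side `"greater"` for enrichment, `"less"` for deficit.
#' @return list with `observed`, `permuted_mean`, `p`.
#' @export
permutation_enrichment <- function(regions, annotations, accessible,
                                   n_perm = 1e4, seed = 1L,
                                   side = c("greater", "less")) {
  side <- match.arg(side)
  regions <- ivl_normalize(regions)
  annotations <- ivl_normalize(annotations)
  accessible <- ivl_normalize(accessible)
  count_overlap <- function(reg) {
    if (nrow(reg) == 0L || nrow(annotations) == 0L) return(0L)
    hits <- vapply(seq_len(nrow(annotations)), function(i) {
      any(reg[, 1] < annotations[i, 2] & reg[, 2] > annotations[i, 1])
    }, logical(1))
    sum(hits)
  }
  observed <- count_overlap(regions)
  if (nrow(regions) == 0L) {
    return(list(observed = 0L, permuted_mean = 0, p = 1))
  }
  lens <- regions[, 2] - regions[, 1]
  ## valid start offsets per region within each accessible run
  placements <- lapply(lens, function(len) {
    ok <- accessible[, 2] - accessible[, 1] >= len
    if (!any(ok)) stop("region longer than any accessible stretch")
    runs <- accessible[ok, , drop = FALSE]
    cbind(runs[, 1], runs[, 2] - len + 0)  # start range [a, b] inclusive
  })
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 41L))
  stat <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- matrix(0, nrow(regions), 2L)
    for (r in seq_len(nrow(regions))) {
      pl <- placements[[r]]
      n_opts <- pl[, 2] - pl[, 1] + 1
      run <- sample.int(nrow(pl), 1L, prob = n_opts)
      s <- pl[run, 1] + sample.int(n_opts[run], 1L) - 1
      perm[r, ] <- c(s, s + lens[r])
    }
    stat[p] <- count_overlap(perm)
  }
  cmp <- if (side == "greater") stat >= observed else stat <= observed
  list(observed = observed, permuted_mean = mean(stat),
       p = (1 + sum(cmp)) / (n_perm + 1))
}

#' Predicted introgressed intervals from a sliding-window scan
#'
#' Union of all retained windows called introgressed at the given cutoff;
#' the standard way to turn sliding-window calls into base-pair-level
#' predictions for [bp_metrics()].
#'
#' @param calls data.frame from [classify_genome()].
#' @return interval matrix (bp).
#' @export
called_intervals <- function(calls) {
  hit <- calls$retained & calls$call
  ivl_normalize(cbind(calls$start[hit], calls$end[hit]))
}
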