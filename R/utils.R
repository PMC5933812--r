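#' @keywords internal
#' @useDynLib introscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Interval helpers. All intervals are 0-based, half-open [start, end),
## represented as two-column matrices or data.frames with columns
## start, end in bp.

as_ivl <- function(x) {
  if (is.null(x) || NROW(x) == 0L) {
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.data.frame(x)) {
    cn <- intersect(c("start", "end"), names(x))
    if (length(cn) == 2L) x <- cbind(x$start, x$end)
    x <- as.matrix(x)
  }
  matrix(as.numeric(x[, 1:2]), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a set of intervals: sort and merge overlapping or abutting ones
#' @param ivl matrix/data.frame with start, end columns (0-based half-open)
#' @return matrix with columns start, end; sorted, non-overlapping
#' @keywords internal
ivl_normalize <- function(ivl) {
  m <- as_ivl(ivl)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Total length covered by a set of intervals
#' @keywords internal
ivl_length <- function(ivl) {
  m <- ivl_normalize(ivl)
  if (nrow(m) == 0L) return(0)
  sum(m[, 2] - m[, 1])
}

#' Intersection of two interval sets
#' @keywords internal
ivl_intersect <- function(a, b) {
  a <- ivl_normalize(a); b <- ivl_normalize(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(as_ivl(NULL))
  out <- NULL
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- e > s
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  ivl_normalize(out)
}

#' Set difference a \ b of two interval sets
#' @keywords internal
ivl_subtract <- function(a, b) {
  a <- ivl_normalize(a); b <- ivl_normalize(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    segs <- a[i, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      nxt <- NULL
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) {
          nxt <- rbind(nxt, c(s, e))
        } else {
          if (bs > s) nxt <- rbind(nxt, c(s, bs))
          if (be < e) nxt <- rbind(nxt, c(be, e))
        }
      }
      segs <- if (is.null(nxt)) {
        matrix(numeric(0), ncol = 2L)
      } else {
        nxt
      }
      if (nrow(segs) == 0L) break
    }
    if (nrow(segs) > 0L) out <- rbind(out, segs)
  }
  ivl_normalize(out)
}

## Bounded integer seeds for downstream RNG consumers (R and msprime both
## want seeds below 2^31).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + k * 12820163) %% 2147483629 + 1
}
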