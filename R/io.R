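#' Read ms-format coalescent simulator output
#'
#' Parses the text format emitted by Hudson's `ms` and compatible simulators:
#' replicates are delimited by `//` lines, each followed by a
#' `segsites:` line, a `positions:` line with site positions as fractions of
#' the locus in `[0, 1)`, and one 0/1 string per sampled chromosome. Any
#' lines before the first `//` (the command-line echo and seeds) are
#' ignored.
#'
#' @param con path to an ms-format file, or a character vector of lines.
#' @return A list of replicates, each a list with elements `segsites`
#'   (integer), `positions` (numeric vector of fractions), and `haplotypes`
#'   (integer matrix, one row per chromosome, entries 0/1).
#' @export
read_ms <- function(con) {
  lines <- if (length(con) == 1L && file.exists(con)) readLines(con) else con
  starts <- which(lines == "//")
  if (length(starts) == 0L) stop("no '//' replicate delimiters found")
  bounds <- c(starts, length(lines) + 1L)
  reps <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    block <- block[block != ""]
    seg_line <- grep("^segsites:", block, value = TRUE)
    if (length(seg_line) != 1L) {
      stop(sprintf("replicate %d: missing segsites line", r))
    }
    segsites <- as.integer(sub("^segsites:\\s*", "", seg_line))
    if (segsites == 0L) {
      reps[[r]] <- list(segsites = 0L, positions = numeric(0),
                        haplotypes = matrix(integer(0), nrow = 0, ncol = 0))
      next
    }
    pos_line <- grep("^positions:", block, value = TRUE)
    if (length(pos_line) != 1L) {
      stop(sprintf("replicate %d: missing positions line", r))
    }
    positions <- as.numeric(strsplit(
      sub("^positions:\\s*", "", pos_line), "\\s+")[[1]])
    hap_lines <- block[grepl("^[01]+$", block)]
    if (length(hap_lines) == 0L) {
      stop(sprintf("replicate %d: no haplotype rows", r))
    }
    if (any(nchar(hap_lines) != segsites)) {
      stop(sprintf(
        "replicate %d: haplotype length does not match segsites (%d)",
        r, segsites))
    }
    if (length(positions) != segsites) {
      stop(sprintf("replicate %d: positions length != segsites", r))
    }
    haps <- matrix(
      as.integer(unlist(strsplit(hap_lines, "", fixed = TRUE), use.names = FALSE)),
      nrow = length(hap_lines), byrow = TRUE)
    reps[[r]] <- list(segsites = segsites, positions = positions,
                      haplotypes = haps)
  }
  n_hap <- vapply(reps, function(x) nrow(x$haplotypes), integer(1))
  n_hap <- n_hap[n_hap > 0L]
  if (length(unique(n_hap)) > 1L) {
    stop("haplotype count differs across replicates")
  }
  reps
}

#' Write replicates in ms format
#'
#' @param reps list of replicates as returned by [read_ms()].
#' @param file output path.
#' @param header optional first line (command echo); a placeholder is
#'   written if omitted.
#' @export
write_ms <- function(reps, file, header = NULL) {
  out <- c(header %||% sprintf("introscan %d replicates", length(reps)), "")
  for (r in reps) {
    out <- c(out, "//", sprintf("segsites: %d", r$segsites))
    if (r$segsites > 0L) {
      out <- c(out,
               paste("positions:",
                     paste(sprintf("%.8f", r$positions), collapse = " ")),
               apply(r$haplotypes, 1L, paste, collapse = ""))
    }
    out <- c(out, "")
  }
  writeLines(out, file)
  invisible(file)
}

#' Map fractional site positions to distinct base-pair coordinates
#'
#' Multiplies positions in `[0, 1)` by the window length and rounds; when
#' two sites round to the same integer, the later site is shifted to the
#' nearest free integer to the right (a deterministic left-to-right scan),
#' preserving order.
#'
#' @param positions numeric vector of non-decreasing fractions in `[0, 1)`.
#' @param window_length_bp window length L in bp.
#' @return strictly increasing integer positions in `[0, L)`.
#' @export
positions_to_bp <- function(positions, window_length_bp) {
  L <- as.integer(window_length_bp)
  if (L < 1L) stop("window length must be >= 1")
  S <- length(positions)
  if (S == 0L) return(integer(0))
  if (S > L) stop("more segregating sites than base pairs")
  bp <- as.integer(round(positions * L))
  bp[bp >= L] <- L - 1L
  for (i in seq_len(S)) {
    if (i > 1L && bp[i] <= bp[i - 1L]) bp[i] <- bp[i - 1L] + 1L
  }
  ## if we ran off the right edge, push back from the end
  if (bp[S] >= L) {
    bp[S] <- L - 1L
    for (i in rev(seq_len(S - 1L))) {
      if (bp[i] >= bp[i + 1L]) bp[i] <- bp[i + 1L] - 1L
    }
    if (bp[1L] < 0L) stop("cannot place sites in window")
  }
  bp
}

#' Read a BED3 accessibility/mask file for one contig
#'
#' @param file BED path (contig, start, end; 0-based half-open).
#' @param contig optional contig filter.
#' @return list with `contig` and `intervals` (normalized matrix).
#' @export
read_mask_bed <- function(file, contig = NULL) {
  bed <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(contig)) bed <- bed[bed[[1]] == contig, , drop = FALSE]
  list(contig = if (is.null(contig)) bed[1, 1] else contig,
       intervals = ivl_normalize(bed[, 2:3]))
}

#' Read a window of phased biallelic genotypes from a VCF file
#'
#' Builds a two-population haplotype window from phased diploid (or haploid)
#' genotypes. Indel and multiallelic records are skipped (counted in the
#' `skipped` attribute); sites inside the mask are excluded; missing alleles
#' become `NA`. VCF coordinates are 1-based; the returned window is 0-based
#' half-open.
#'
#' @param vcf path to a VCF file (requires the `vcfR` package).
#' @param contig,start,end window coordinates (0-based half-open).
#' @param pop1,pop2 character vectors of sample names.
#' @param mask optional mask intervals for this contig (matrix/data.frame).
#' @param polarized logical; if `FALSE` (default for real data) the REF
#'   allele is treated as ancestral and the window is flagged unpolarized.
#' @return a [pop_window()].
#' @export
read_vcf_window <- function(vcf, contig, start, end, pop1, pop2,
                            mask = NULL, polarized = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_window requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- fix[, "CHROM"] == contig &
    as.numeric(fix[, "POS"]) >= start + 1 & as.numeric(fix[, "POS"]) <= end
  skipped <- 0L
  L <- end - start
  mask_iv <- ivl_normalize(if (is.null(mask)) NULL else mask)
  mask_here <- ivl_intersect(mask_iv, cbind(start, end))
  L_u <- L - ivl_length(mask_here)
  samples <- c(pop1, pop2)
  empty <- function() {
    w <- pop_window(matrix(integer(0), nrow = 2 * length(samples), ncol = 0),
                    positions = numeric(0), L = L, L_u = L_u,
                    n1 = 2 * length(pop1), n2 = 2 * length(pop2),
                    polarized = polarized, validate = FALSE)
    attr(w, "skipped") <- skipped
    w
  }
  if (!any(keep)) return(empty())
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v)[keep, samples, drop = FALSE]
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "ALT"] != "."
  skipped <- sum(!biallelic)
  if (skipped > 0L) {
    message(sprintf("read_vcf_window: skipped %d non-SNP/multiallelic records",
                    skipped))
  }
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]
  pos0 <- as.numeric(fix[, "POS"]) - 1  # 0-based
  in_mask <- rep(FALSE, length(pos0))
  if (nrow(mask_here) > 0L) {
    for (i in seq_len(nrow(mask_here))) {
      in_mask <- in_mask | (pos0 >= mask_here[i, 1] & pos0 < mask_here[i, 2])
    }
  }
  fix <- fix[!in_mask, , drop = FALSE]
  gt <- gt[!in_mask, , drop = FALSE]
  pos0 <- pos0[!in_mask]
  if (length(pos0) == 0L) return(empty())
  unphased <- grepl("/", gt) & !gt %in% c("0/0", "1/1", "./.")
  dim(unphased) <- dim(gt)  # grepl drops matrix dims
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)
    stop(sprintf("unphased heterozygote at %s:%s sample %s",
                 contig, fix[idx[1, 1], "POS"], samples[idx[1, 2]]))
  }
  split_alleles <- function(g) {
    a <- strsplit(g, "[|/]")
    vapply(a, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (length(x) == 1L) x <- c(x, NA_integer_)  # haploid: second NA
      x[1:2]
    }, integer(2))
  }
  S <- nrow(gt)
  haps <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = S)
  ploidy2 <- any(grepl("[|/]", gt))
  for (j in seq_along(samples)) {
    al <- split_alleles(gt[, j])
    haps[2L * j - 1L, ] <- al[1, ]
    haps[2L * j, ] <- al[2, ]
  }
  if (!ploidy2) haps <- haps[seq(1L, nrow(haps), by = 2L), , drop = FALSE]
  n1 <- if (ploidy2) 2L * length(pop1) else length(pop1)
  n2 <- if (ploidy2) 2L * length(pop2) else length(pop2)
  ## drop sites where a population has no called allele
  ok <- colSums(!is.na(haps[seq_len(n1), , drop = FALSE])) >= 1L &
    colSums(!is.na(haps[n1 + seq_len(n2), , drop = FALSE])) >= 1L
  w <- pop_window(haps[, ok, drop = FALSE], positions = pos0[ok] - start,
                  L = L, L_u = L_u, n1 = n1, n2 = n2, polarized = polarized)
  attr(w, "skipped") <- skipped
  w
}

#' Write (and read back) a feature table
#'
#' TSV with a header naming every feature in the canonical 31-statistic
#' order; extra leading columns (e.g. window coordinates or labels) are
#' preserved.
#'
#' @param x data.frame whose feature columns are the canonical 31.
#' @param file output path.
#' @export
write_feature_table <- function(x, file) {
  fn <- feature_names()
  if (!all(fn %in% colnames(x))) {
    stop("feature table must contain all 31 canonical feature columns")
  }
  meta <- setdiff(colnames(x), fn)
  utils::write.table(x[, c(meta, fn), drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(file) {
  x <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  fn <- feature_names()
  if (!all(fn %in% colnames(x))) {
    stop("file does not contain the 31 canonical feature columns")
  }
  x
}

#' Write called introgressed regions as BED
#'
#' Columns: contig, start, end, direction, maximum posterior probability of
#' introgression among member windows.
#'
#' @param regions data.frame with columns contig, start, end, direction,
#'   max_posterior.
#' @param file output path.
#' @export
write_region_bed <- function(regions, file) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  utils::write.table(
    data.frame(regions$contig, as.integer(regions$start),
               as.integer(regions$end), regions$direction,
               regions$max_posterior),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
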