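#' Two-population demographic model
#'
#' Describes the isolation(-with-migration) model under which training and
#' test windows are simulated. Times are in units of `4 N0` generations and
#' population-scaled rates follow the ms convention (`theta = 4 N0 mu L`,
#' `rho = 4 N0 r L`, migration `4 N0 m`), for a diploid reference size `N0`.
#' Sampled chromosomes are haploid genomes.
#'
#' @param td split time in units of `4 N0` generations (0 or `NULL` for a
#'   panmictic control population).
#' @param L window length in bp.
#' @param theta,rho locus-wide population mutation and recombination rates.
#' @param n1,n2 sampled haplotypes per population.
#' @param N0 diploid reference population size (default 1e4; affects only
#'   the internal rescaling to generations, not the sampled distributions).
#' @param sizes optional named list of population sizes overriding `N0`:
#'   entries `p1`, `p2`, `anc`, `ghost`, each either a single diploid size
#'   or `c(present, at_split)` for exponential size change.
#' @param m12,m21 continuous (population-scaled) migration rates, forward in
#'   time from population 1 to 2 and 2 to 1.
#' @param ghost include an unsampled ghost population splitting from the
#'   ancestor at `td` (used as an introgression donor).
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(td = 0.25, L = 1e4, theta = 50, rho = 250,
                              n1 = 15L, n2 = 15L, N0 = 1e4, sizes = NULL,
                              m12 = 0, m21 = 0, ghost = FALSE) {
  stopifnot(theta > 0, rho >= 0, n1 >= 2L, n2 >= 2L, L >= 1,
            m12 >= 0, m21 >= 0)
  structure(list(td = if (is.null(td) || td <= 0) NULL else td,
                 L = L, theta = theta, rho = rho,
                 n1 = as.integer(n1), n2 = as.integer(n2), N0 = N0,
                 sizes = sizes, m12 = m12, m21 = m21, ghost = isTRUE(ghost)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf(
    "demographic_model: td = %s x4N, theta = %g, rho = %g, L = %g bp, n = %d + %d%s%s\n",
    if (is.null(x$td)) "panmictic" else format(x$td), x$theta, x$rho, x$L,
    x$n1, x$n2,
    if (x$m12 > 0 || x$m21 > 0)
      sprintf(", m = (%g, %g)", x$m12, x$m21) else "",
    if (x$ghost) ", +ghost" else ""))
  invisible(x)
}

#' Training/test grid of pulse-introgression parameters
#'
#' The pulse time `T_M` is drawn from `{0.01, 0.05, 0.10, ..., 0.90} x T_D`
#' (19 values; the test grid adds `0.001 x T_D`) and the per-lineage
#' migration probability `P_M` from `{0.05, 0.10, ..., 0.95}` (19 values).
#' Replicates are allocated as equally as possible over the cells of each
#' direction, remainder to the lexicographically first cells.
#'
#' @param td split time (same units as the model).
#' @param n_per_class total replicates per introgression class (default
#'   1e4).
#' @param directions introgression directions to include (`"mig12"` is
#'   forward-time population 1 into 2).
#' @param test use the test grid (adds `T_M = 0.001 x T_D`).
#' @return data.frame with columns `direction`, `tm`, `pm`, `n`.
#' @export
training_grid <- function(td, n_per_class = 1e4,
                          directions = c("mig12", "mig21"), test = FALSE) {
  tm_frac <- c(if (test) 0.001, 0.01, seq(0.05, 0.9, by = 0.05))
  pm <- seq(0.05, 0.95, by = 0.05)
  out <- NULL
  for (dir in directions) {
    cells <- expand.grid(pm = pm, tm = tm_frac * td,
                         KEEP.OUT.ATTRS = FALSE)[, c("tm", "pm")]
    cells <- cells[order(cells$tm, cells$pm), ]
    n_cells <- nrow(cells)
    ## as-equal-as-possible quota allocation; any remainder is spread
    ## uniformly across the ordered grid (clumping it into the first cells
    ## would bias small sets toward the most recent pulses)
    q <- floor(seq_len(n_cells) * n_per_class / n_cells)
    n <- diff(c(0L, q))
    out <- rbind(out, data.frame(direction = dir, cells, n = n))
  }
  rownames(out) <- NULL
  out
}

#' Expand a grid of cells into one row per replicate
#' @param grid data.frame from [training_grid()] (columns direction, tm,
#'   pm, n).
#' @param label class label to attach; defaults to the direction.
#' @param condition require at least one migrant lineage per replicate.
#' @return data.frame with one row per replicate (columns label, direction,
#'   tm, pm, condition).
#' @export
expand_grid_specs <- function(grid, label = NULL, condition = FALSE) {
  idx <- rep(seq_len(nrow(grid)), grid$n)
  data.frame(label = if (is.null(label)) grid$direction[idx] else label,
             direction = grid$direction[idx], tm = grid$tm[idx],
             pm = grid$pm[idx], condition = condition,
             stringsAsFactors = FALSE)
}

#' Specs for no-migration replicates
#' @param n number of replicates.
#' @export
null_specs <- function(n) {
  data.frame(label = "noMig", direction = NA_character_, tm = NA_real_,
             pm = NA_real_, condition = FALSE, stringsAsFactors = FALSE)[
               rep(1L, n), , drop = FALSE]
}

python_bin <- function() {
  getOption("introscan.python", Sys.which("python"))
}

model_to_job <- function(model) {
  job <- list(N0 = model$N0, L = model$L, theta = model$theta,
              rho = model$rho, n1 = model$n1, n2 = model$n2,
              m12 = model$m12, m21 = model$m21, ghost = model$ghost)
  if (!is.null(model$td)) job$td <- model$td
  if (!is.null(model$sizes)) job$sizes <- model$sizes
  job
}

run_coalsim <- function(model, specs, seed, type = NULL) {
  driver <- system.file("python", "coalsim.py", package = "introscan")
  tmp <- tempfile("coalsim")
  job_file <- paste0(tmp, ".json")
  ms_file <- paste0(tmp, ".ms")
  truth_file <- paste0(tmp, ".truth")
  on.exit(unlink(c(job_file, ms_file, truth_file)))
  reps <- lapply(seq_len(nrow(specs)), function(i) {
    r <- list(label = specs$label[i])
    if (!is.na(specs$direction[i])) r$direction <- specs$direction[i]
    if (!is.null(specs$tm) && !is.na(specs$tm[i])) r$tm <- specs$tm[i]
    if (!is.null(specs$pm) && !is.na(specs$pm[i])) r$pm <- specs$pm[i]
    if (isTRUE(specs$condition[i])) r$condition <- TRUE
    if (!is.null(type)) r$type <- type
    if (!is.null(specs$center)) r$center <- specs$center[[i]]
    r
  })
  job <- list(seed = as.integer(seed) %% 2147483647L,
              model = model_to_job(model), reps = reps,
              out_ms = ms_file, out_truth = truth_file)
  jsonlite::write_json(job, job_file, auto_unbox = TRUE, digits = NA)
  status <- system2(python_bin(), c(driver, job_file),
                    stdout = "", stderr = "")
  if (status != 0L) {
    stop(sprintf("coalescent simulation failed (exit %d, seed %d)",
                 status, seed))
  }
  list(reps = read_ms(ms_file),
       truth = utils::read.table(truth_file, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE,
                                 colClasses = c(
                                   "integer", "character", "numeric",
                                   "numeric", "integer", "character",
                                   "character", "integer")))
}

parse_tracts <- function(s) {
  if (is.na(s) || s == ".") return(as_ivl(NULL))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  ivl_normalize(do.call(rbind, lapply(parts, as.numeric)))
}

ms_to_window <- function(rep, model) {
  pos_bp <- positions_to_bp(rep$positions, model$L)
  haps <- rep$haplotypes
  if (nrow(haps) == 0L) {
    haps <- matrix(integer(0), nrow = model$n1 + model$n2, ncol = 0L)
  }
  pop_window(haps, positions = pos_bp, L = model$L, L_u = model$L,
             n1 = model$n1, n2 = model$n2, polarized = TRUE)
}

#' Simulate labelled two-population windows
#'
#' Runs the bundled msprime driver once for the whole batch of replicate
#' specifications, returning one simulated example per spec: the haplotype
#' window, the class label, and the migrant truth (which sampled haplotypes
#' carry introgressed material, and the tract intervals in bp). Fully
#' reproducible from `seed`.
#'
#' @param model a [demographic_model()].
#' @param specs data.frame of replicate specs ([expand_grid_specs()],
#'   [null_specs()]), columns label, direction, tm, pm, condition.
#' @param seed integer seed.
#' @return list of simulated examples: each a list with `window`
#'   ([pop_window()]), `label`, `tm`, `pm`, `n_migrant`, `migrants`
#'   (1-based haplotype indices), and `tracts` (interval matrix, bp).
#' @export
simulate_windows <- function(model, specs, seed) {
  res <- run_coalsim(model, specs, seed)
  lapply(seq_along(res$reps), function(i) {
    tr <- res$truth[i, ]
    migrants <- if (tr$migrants == ".") integer(0) else
      as.integer(strsplit(tr$migrants, ",", fixed = TRUE)[[1]]) + 1L
    list(window = ms_to_window(res$reps[[i]], model),
         label = tr$label, tm = tr$tm, pm = tr$pm,
         n_migrant = tr$n_migrant, migrants = migrants,
         tracts = parse_tracts(tr$tracts))
  })
}

#' Simulate windows and return their feature vectors (chunked)
#'
#' Memory-friendly driver for large batches: simulates in chunks, computes
#' the 31-statistic feature vector per window, and discards the haplotypes.
#'
#' @inheritParams simulate_windows
#' @param chunk replicates per driver invocation.
#' @return list with `features` (data.frame, canonical order) and `truth`
#'   (data.frame with label, tm, pm, n_migrant, segsites).
#' @export
simulate_features <- function(model, specs, seed, chunk = 2000L) {
  n <- nrow(specs)
  splits <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  feats <- vector("list", length(splits))
  truths <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    res <- run_coalsim(model, specs[splits[[k]], , drop = FALSE],
                       derive_seed(seed, k))
    feats[[k]] <- do.call(rbind, lapply(res$reps, function(r) {
      feature_vector(ms_to_window(r, model))
    }))
    truths[[k]] <- res$truth[, c("label", "tm", "pm", "n_migrant",
                                 "segsites")]
  }
  features <- as.data.frame(do.call(rbind, feats))
  colnames(features) <- feature_names()
  rownames(features) <- NULL
  list(features = features, truth = do.call(rbind, truths))
}

#' Simulate windows under continuous bidirectional migration
#'
#' Used both to measure the fraction of windows whose sample contains at
#' least one migrant lineage at a given migration rate and to build test
#' sets for classifier sensitivity under continuous gene flow.
#'
#' @param model a [demographic_model()] (its `m12`/`m21` are overridden).
#' @param m symmetric population-scaled migration rate (ms convention,
#'   `4 N0 m`).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param features also compute feature vectors (default `FALSE`: migrant
#'   flags only).
#' @return list with `migrant` (logical vector: sample contains at least
#'   one migrant lineage) and, if requested, `features`.
#' @export
simulate_continuous <- function(model, m, reps, seed, features = FALSE) {
  stopifnot(m >= 0)
  model$m12 <- m
  model$m21 <- m
  specs <- null_specs(reps)
  specs$label <- "continuous"
  if (features) {
    res <- simulate_features(model, specs, seed)
    list(migrant = res$truth$n_migrant > 0L, features = res$features)
  } else {
    res <- run_coalsim(model, specs, seed)
    list(migrant = res$truth$n_migrant > 0L)
  }
}

#' Simulate test windows with an unsampled ghost donor
#'
#' As [simulate_windows()], but the introgression pulse originates from a
#' third, unsampled population that split from the two sampled populations
#' at `td`. Only the `n1 + n2` sampled haplotypes appear in the windows;
#' labels are `ghost1`/`ghost2` (recipient population) for evaluation only.
#'
#' @inheritParams simulate_windows
#' @param recipient 1 or 2: population receiving the ghost material.
#' @param grid data.frame of (tm, pm) cells with counts (e.g. from
#'   [training_grid()] with `directions = "ghost1"`).
#' @export
simulate_ghost <- function(model, grid, recipient = 1L, seed) {
  model$ghost <- TRUE
  grid$direction <- paste0("ghost", recipient)
  specs <- expand_grid_specs(grid)
  simulate_windows(model, specs, seed)
}

#' Draw a concrete model from point estimates (parameter-draw training)
#'
#' Emulates training-set generation under an uncertain demographic model:
#' every parameter is drawn uniformly from `[x/2, 3x/2]` around its point
#' estimate `x`, the pulse time `T_M` uniformly from `(0, T_D/4]`
#' generations ago, and `P_M` uniformly from `(0, 1]`. The ratio of `theta`
#' to `rho` is held at 0.2 and continuous migration is zero (all migrants
#' arise from the pulse).
#'
#' @param point_estimates named list: `Nanc`, `N1_0`, `N1`, `N2_0`, `N2`
#'   (diploid sizes; `*_0` are the sizes at the split for exponential
#'   change), `Td_gen` (split time in generations), `L` (bp), and
#'   optionally `mu` (default 3.5e-9 per bp per generation).
#' @param seed integer seed.
#' @return list with `model` (a [demographic_model()] in rescaled units),
#'   `tm`, `pm` (pulse parameters in the model's `4 N0`-generation units),
#'   and `draws` (the drawn parameter values).
#' @export
draw_drosophila_model <- function(point_estimates, seed) {
  pe <- point_estimates
  mu <- pe$mu %||% 3.5e-9
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 13L))
  draw <- function(x) {
    repeat {
      v <- stats::runif(1, x / 2, 3 * x / 2)
      if (v > 0) return(v)
    }
  }
  d <- list(Nanc = draw(pe$Nanc), N1_0 = draw(pe$N1_0), N1 = draw(pe$N1),
            N2_0 = draw(pe$N2_0), N2 = draw(pe$N2),
            Td_gen = draw(pe$Td_gen),
            theta = draw(4 * pe$Nanc * mu * pe$L))
  d$rho <- d$theta / 0.2
  tm_gen <- stats::runif(1, 0, d$Td_gen / 4)
  pm <- stats::runif(1, .Machine$double.eps, 1)
  N0 <- d$Nanc  # reference size for rescaling
  model <- demographic_model(
    td = d$Td_gen / (4 * N0), L = pe$L,
    theta = d$theta * N0 / pe$Nanc, rho = d$rho * N0 / pe$Nanc,
    n1 = pe$n1 %||% 15L, n2 = pe$n2 %||% 15L, N0 = N0,
    sizes = list(p1 = c(d$N1, d$N1_0), p2 = c(d$N2, d$N2_0), anc = d$Nanc))
  list(model = model, tm = tm_gen / (4 * N0), pm = pm, draws = d)
}

#' Two-epoch island model recovered from observed summaries
#'
#' Constructs a deliberately simplified (misspecified) isolation model from
#' observed diversity and divergence: `N1 = pi_1 / (4 mu)`,
#' `N2 = pi_2 / (4 mu)`, `N_anc = N1`, and a split
#' `T = d_xy / (2 mu) - 2 N_anc` generations ago (the expected
#' cross-population TMRCA minus the expected ancestral coalescence time).
#' No size change, no migration.
#'
#' @param pi1,pi2 mean per-bp diversities of the two populations.
#' @param d_xy mean per-bp cross-population divergence.
#' @param mu mutation rate per bp per generation.
#' @param L window length in bp.
#' @param n1,n2 sample sizes.
#' @return a [demographic_model()].
#' @export
misspecified_island_model <- function(pi1, pi2, d_xy, mu, L = 1e4,
                                      n1 = 15L, n2 = 15L) {
  stopifnot(pi1 > 0, pi2 > 0, d_xy > 0, mu > 0)
  N1 <- pi1 / (4 * mu)
  N2 <- pi2 / (4 * mu)
  Nanc <- N1
  T_gen <- d_xy / (2 * mu) - 2 * Nanc
  if (T_gen < 0) stop("d_xy/(2 mu) < 2 N_anc: negative split time")
  N0 <- Nanc
  demographic_model(td = T_gen / (4 * N0), L = L, theta = 4 * N0 * mu * L,
                    rho = 4 * N0 * mu * L / 0.2, n1 = n1, n2 = n2, N0 = N0,
                    sizes = list(p1 = N1, p2 = N2, anc = Nanc))
}

#' Mask a simulated window like a randomly chosen real window
#'
#' Mirrors real-data masking onto simulations: draws one mask from a
#' library of per-window masked interval sets, removes the sites it covers,
#' and reduces the unmasked length accordingly.
#'
#' @param window a [pop_window()].
#' @param mask_library list of interval matrices ([make_mask_library()]).
#' @param seed integer seed (selection is recorded in attribute
#'   `mask_index`).
#' @return the masked [pop_window()].
#' @export
apply_real_mask <- function(window, mask_library, seed) {
  if (length(mask_library) == 0L) stop("empty mask library")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, 29L))
  idx <- sample.int(length(mask_library), 1L)
  mask <- ivl_intersect(mask_library[[idx]], cbind(0, window$L))
  out <- mask_pop_window(window, mask)
  attr(out, "mask_index") <- idx
  out
}

## Apply interval mask to a window: drop covered sites, reduce L_u.
mask_pop_window <- function(window, mask) {
  mask <- ivl_normalize(mask)
  keep <- rep(TRUE, length(window$positions))
  if (nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      keep <- keep & !(window$positions >= mask[i, 1] &
                         window$positions < mask[i, 2])
    }
  }
  pop_window(window$haplotypes[, keep, drop = FALSE],
             positions = window$positions[keep], L = window$L,
             L_u = window$L_u - ivl_length(mask), n1 = window$n1,
             n2 = window$n2, polarized = window$polarized,
             validate = FALSE)
}

#' Simulate a long chromosome with introgression confined to its centre
#'
#' Simulates contigs (default 1 Mb, `theta = 5000`, `rho = 25000`) where a
#' pulse of gene flow (population 2 into 1 by default) affects only the
#' central segment (default the central 100 kb), with introgressed tract
#' truth recorded in bp. Used for base-pair-level benchmarking of
#' sliding-window scans.
#'
#' @param model a [demographic_model()] (use `L = 1e6`, `theta = 5000`,
#'   `rho = 25000` for the standard setting).
#' @param specs data.frame with columns tm, pm (`NA` for no-introgression
#'   replicates); one contig per row.
#' @param seed integer seed.
#' @param center length-2 vector: bounds of the central segment in bp.
#' @return list of examples as in [simulate_windows()]; truth tracts fall
#'   within `center`.
#' @export
simulate_contig <- function(model, specs, seed, center = NULL) {
  if (is.null(center)) center <- c(0.45, 0.55) * model$L
  sp <- data.frame(label = ifelse(is.na(specs$tm), "noMig", "mig21"),
                   direction = ifelse(is.na(specs$tm), NA, "mig21"),
                   tm = specs$tm, pm = specs$pm, condition = FALSE,
                   stringsAsFactors = FALSE)
  sp$center <- rep(list(as.numeric(center)), nrow(sp))
  res <- run_coalsim(model, sp, seed, type = "contig")
  lapply(seq_along(res$reps), function(i) {
    tr <- res$truth[i, ]
    migrants <- if (tr$migrants == ".") integer(0) else
      as.integer(strsplit(tr$migrants, ",", fixed = TRUE)[[1]]) + 1L
    list(window = ms_to_window(res$reps[[i]], model),
         label = tr$label, tm = tr$tm, pm = tr$pm,
         n_migrant = tr$n_migrant, migrants = migrants,
         tracts = parse_tracts(tr$tracts))
  })
}
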