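#' Fuzzy Dice similarity coefficient
#'
#' Dice overlap generalised to probabilistic maps: the intersection is the
#' voxel-wise minimum and `|.|` integrates voxel values over the image,
#' `DSC = 2 sum(min(S, M)) / (sum(S) + sum(M))`. On binary inputs this equals
#' the classic Dice coefficient. When both inputs are identically zero the
#' coefficient is 1 by convention (the 0/0 case).
#'
#' @param S,M arrays (or `fused_map`/`saliency_map`) with values in `[0, 1]`
#'   on the same grid; probability maps should be percentile-normalised first
#'   (see [normalize_map()]).
#' @return A value in `[0, 1]`.
#' @export
fuzzy_dice <- function(S, M) {
  S <- prob_values(S)
  M <- prob_values(M)
  if (!all(dim(S) == dim(M)))
    stop("S and M are on different grids", call. = FALSE)
  denom <- sum(S) + sum(M)
  if (denom == 0) return(1)
  2 * sum(pmin(S, M)) / denom
}

prob_values <- function(x) {
  if (inherits(x, "fused_map")) x <- x$phi
  if (inherits(x, "saliency_map")) x <- x$s
  if (is.logical(x)) x <- x + 0
  if (any(x < 0) || any(x > 1))
    stop("values must lie in [0, 1]; normalise probability maps first",
         call. = FALSE)
  x
}

#' Consensus of multiple rater masks by voting
#'
#' A voxel belongs to the consensus iff at least `threshold` of the binary
#' masks mark it; the default threshold is a majority, `ceiling(n / 2)`.
#'
#' @param masks list of >= 2 binary (logical or 0/1) arrays on one grid.
#' @param threshold vote count in `1..length(masks)`; `NULL` for majority.
#' @return Logical array.
#' @export
consensus_mask <- function(masks, threshold = NULL) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("need at least two rater masks", call. = FALSE)
  d <- dim(masks[[1]])
  for (m in masks) if (!all(dim(m) == d))
    stop("rater masks are on different grids", call. = FALSE)
  n <- length(masks)
  if (is.null(threshold)) threshold <- ceiling(n / 2)
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > n)
    stop("threshold must be in 1..", n, call. = FALSE)
  votes <- Reduce(`+`, lapply(masks, function(m) (m > 0) + 0L))
  votes >= threshold
}

#' Otsu threshold of a probability volume
#'
#' Single global Otsu threshold over all voxels (values expected in
#' `[0, 1]`); [binarize_map()] applies it.
#'
#' @param x array, `fused_map` or `saliency_map` with values in `[0, 1]`.
#' @param levels histogram levels passed to [EBImage::otsu()].
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, levels = 256) {
  v <- prob_values(x)
  EBImage::otsu(matrix(as.vector(v), ncol = 1), range = c(0, 1),
                levels = levels)
}

#' @rdname otsu_threshold
#' @param threshold explicit threshold; `NULL` (default) uses Otsu.
#' @return `binarize_map`: logical array.
#' @export
binarize_map <- function(x, threshold = NULL) {
  v <- prob_values(x)
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  v > threshold
}

#' Compare initialisation strategies and fusion operators on phantoms
#'
#' Runs the full extraction pipeline on a synthetic multi-modal phantom for
#' every combination of token-initialisation strategy and fusion operator,
#' over one or more seeds, and reports the fuzzy and Otsu-binarised Dice
#' coefficients against the phantom's ground truth. Fusion operator
#' `"single"` expands to one row per modality (no fusion). Deterministic
#' under a fixed seed set.
#'
#' @param spec a [phantom_spec()]; its `seed` is replaced by each element of
#'   `seeds` in turn.
#' @param strategies character vector of [init_tokens()] strategy names.
#' @param fusion_ops subset of `"cosine"`, `"min"`, `"max"`, `"single"`.
#' @param config a [vessel_config()]; its `init` field is overridden by
#'   `strategies`.
#' @param seeds integer vector of phantom seeds.
#' @return `data.frame` with one row per (strategy, fusion) combination:
#'   `strategy`, `fusion`, `n_seeds`, `dsc_mean`, `dsc_sd`,
#'   `dsc_otsu_mean`, `dsc_otsu_sd`.
#' @export
run_comparison <- function(spec,
                           strategies = c("hessian_vesselness",
                                          "ball_vesselness"),
                           fusion_ops = "cosine",
                           config = vessel_config(),
                           seeds = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  bad <- setdiff(fusion_ops, c("cosine", "min", "max", "single"))
  if (length(bad)) stop("unknown fusion operator(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  acc <- list()
  for (seed in seeds) {
    spec$seed <- seed
    ph <- generate_phantom(spec)
    truth <- ph$truth + 0
    L <- length(ph$modalities)
    for (strat in strategies) {
      cfg <- config
      cfg$init <- strat
      smaps <- lapply(ph$modalities, function(v) {
        normalize_map(compute_saliency_map(v, cfg)$S)
      })
      for (op in fusion_ops) {
        if (op == "single") {
          for (m in seq_len(L)) {
            phi <- normalize_map(smaps[[m]]$s)
            acc[[length(acc) + 1L]] <- data.frame(
              strategy = strat, fusion = paste0("single_m", m), seed = seed,
              dsc = fuzzy_dice(phi, truth),
              dsc_otsu = fuzzy_dice(binarize_map(phi), truth))
          }
          next
        }
        fm <- switch(op,
                     cosine = if (L == 2L) fuse_pair(smaps[[1]], smaps[[2]])
                              else fuse_multi(smaps),
                     min = fuse_min(smaps),
                     max = fuse_max(smaps))
        phi <- normalize_map(fm$phi)
        acc[[length(acc) + 1L]] <- data.frame(
          strategy = strat, fusion = op, seed = seed,
          dsc = fuzzy_dice(phi, truth),
          dsc_otsu = fuzzy_dice(binarize_map(phi), truth))
      }
    }
  }
  rows <- do.call(rbind, acc)
  agg <- unique(rows[c("strategy", "fusion")])
  res <- do.call(rbind, lapply(seq_len(nrow(agg)), function(r) {
    sel <- rows$strategy == agg$strategy[r] & rows$fusion == agg$fusion[r]
    data.frame(strategy = agg$strategy[r], fusion = agg$fusion[r],
               n_seeds = sum(sel), dsc_mean = mean(rows$dsc[sel]),
               dsc_sd = if (sum(sel) > 1) sd(rows$dsc[sel]) else NA_real_,
               dsc_otsu_mean = mean(rows$dsc_otsu[sel]),
               dsc_otsu_sd = if (sum(sel) > 1) sd(rows$dsc_otsu[sel])
                             else NA_real_)
  }))
  rownames(res) <- NULL
  res
}
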