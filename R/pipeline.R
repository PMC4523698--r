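#' Pipeline configuration
#'
#' Bundles and validates the settings of every stage of the extraction
#' pipeline. Defaults follow the validated operating point: 10 log-spaced
#' scales between 1.0 and 4.5 mm, smooth (Manniesing-style) vesselness,
#' Hessian-orientation tokens with vesselness saliency, 45 degree vote
#' cutoff, cosine fusion, 99.9th-percentile saliency normalisation.
#'
#' @param sigma_min,sigma_max,n_scales scale ladder (mm / count).
#' @param init token initialisation strategy (see [init_tokens()]).
#' @param vesselness a [vesselness_params()].
#' @param voting a [vote_params()].
#' @param fusion `"cosine"`, `"min"` or `"max"`.
#' @param normalize_pct percentile for saliency normalisation before fusion
#'   (and of the fused map); `NULL` disables normalisation.
#' @param invert set `TRUE` for dark-vessel inputs.
#' @return A `vessel_config`.
#' @export
vessel_config <- function(sigma_min = 1.0, sigma_max = 4.5, n_scales = 10L,
                          init = "hessian_vesselness",
                          vesselness = vesselness_params(),
                          voting = vote_params(),
                          fusion = c("cosine", "min", "max"),
                          normalize_pct = 99.9, invert = FALSE) {
  fusion <- match.arg(fusion)
  init <- match.arg(init, c("hessian_vesselness", "ball_vesselness",
                            "ball_k", "ball_intensity", "hessian_kappa",
                            "structure_tensor"))
  stopifnot(inherits(vesselness, "vesselness_params"),
            inherits(voting, "vote_params"),
            is.null(normalize_pct) ||
              (normalize_pct > 0 && normalize_pct <= 100))
  ladder <- make_scale_ladder(sigma_min, sigma_max, n_scales)
  structure(list(ladder = ladder, init = init, vesselness = vesselness,
                 voting = voting, fusion = fusion,
                 normalize_pct = normalize_pct, invert = isTRUE(invert)),
            class = "vessel_config")
}

#' Single-modality saliency maps
#'
#' Runs scale-space analysis, token selection, tensor initialisation, tensor
#' voting and voting analysis on one volume, returning the S/C/J maps.
#'
#' @param volume a [scalar_volume()] (or 3-D array / `niftiImage`).
#' @param config a [vessel_config()].
#' @param mask optional binary region mask applied before token selection.
#' @param verbose log stage timings to stderr.
#' @return The [extract_maps()] result with an added `n_tokens` element.
#' @export
compute_saliency_map <- function(volume, config = vessel_config(),
                                 mask = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "vessel_config"))
  t0 <- proc.time()[3]
  stage <- function(msg) {
    if (verbose) message(sprintf("[%7.2fs] %s", proc.time()[3] - t0, msg))
  }
  ss <- build_scale_space(volume, config$ladder, config$vesselness,
                          invert = config$invert)
  stage("scale space built")
  tokens <- select_tokens(ss, mask)
  stage(sprintf("%d tokens selected", length(tokens$index)))
  tt <- init_tokens(tokens, config$init, ss = ss)
  field <- cast_all_votes(tt, config$voting)
  stage("votes cast")
  maps <- extract_maps(field)
  stage("saliency maps extracted")
  maps$n_tokens <- length(tokens$index)
  maps
}

#' End-to-end multi-modal vessel extraction
#'
#' Computes the per-modality S-maps, normalises their saliencies (so no
#' modality dominates by intensity units), resamples them onto the grid of
#' the first modality if needed, and fuses them with the configured
#' operator into a single vessel-probability map. With a single input volume
#' the S-map is passed through (with a warning if cosine fusion was
#' requested, which is degenerate at L = 1).
#'
#' @param volumes list of [scalar_volume()]s (or paths / arrays), assumed
#'   affinely co-registered.
#' @param mask optional binary mask on the first modality's grid.
#' @param config a [vessel_config()].
#' @param verbose log stage timings.
#' @return A `fused_map` (`phi` normalised to `[0, 1]` when
#'   `config$normalize_pct` is set), with the per-modality `smaps` attached.
#' @export
vessel_extract <- function(volumes, mask = NULL, config = vessel_config(),
                           verbose = FALSE) {
  if (inherits(volumes, "scalar_volume") || is.character(volumes) ||
      (is.array(volumes) && length(dim(volumes)) == 3L))
    volumes <- list(volumes)
  if (!length(volumes)) stop("need at least one input volume", call. = FALSE)
  volumes <- lapply(volumes, function(v) {
    if (is.character(v)) read_volume(v) else as_scalar_volume(v)
  })
  smaps <- vector("list", length(volumes))
  for (m in seq_along(volumes)) {
    use_mask <- if (m == 1L) mask else NULL
    maps <- compute_saliency_map(volumes[[m]], config, mask = use_mask,
                                 verbose = verbose)
    smaps[[m]] <- maps$S
  }
  if (!is.null(config$normalize_pct))
    smaps <- lapply(smaps, normalize_map, pct = config$normalize_pct)
  ref_dim <- dim(smaps[[1]]$s)
  ref_sp <- smaps[[1]]$spacing
  for (m in seq_along(smaps)[-1]) {
    if (!all(dim(smaps[[m]]$s) == ref_dim) ||
        !isTRUE(all.equal(smaps[[m]]$spacing, ref_sp))) {
      smaps[[m]] <- resample_saliency_map(smaps[[m]], ref_dim, ref_sp)
    }
  }
  if (length(smaps) == 1L) {
    if (config$fusion == "cosine")
      warning("cosine fusion with a single modality is degenerate; ",
              "passing the S-map through", call. = FALSE)
    fused <- new_fused_map(smaps[[1]]$s, ref_sp, "identity", 1L)
  } else {
    fused <- switch(config$fusion,
                    cosine = if (length(smaps) == 2L)
                               fuse_pair(smaps[[1]], smaps[[2]])
                             else fuse_multi(smaps),
                    min = fuse_min(smaps),
                    max = fuse_max(smaps))
  }
  if (!is.null(config$normalize_pct))
    fused$phi <- normalize_map(fused$phi, config$normalize_pct)
  fused$smaps <- smaps
  fused
}
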