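#' @name fusion
#' @title Multi-modality fusion of saliency maps
#'
#' @description Per-modality S-maps (saliency `s_i`, unit direction `w_i`)
#' on a common grid are fused into one vessel-probability map. The cosine
#' operator rewards directional consensus and punishes discord:
#' for two modalities
#' `phi(p) = 0.5 |w1 . w2| (s1 + s2)`,
#' and for `L` modalities
#' `phi(p) = (1/L) sum_i s_i sum_{j != i} |w_i . w_j|`,
#' which reduces exactly to the pairwise form at `L = 2`. With complete
#' directional agreement the output is the average of the saliencies; with
#' perpendicular directions it drops to zero. Sentinel (zero) directions —
#' voxels where a modality found nothing — contribute zero alignment by
#' construction. The `min`/`max` operators are the probabilistic analogues
#' of logical AND/OR baselines and ignore directions.
#'
#' @param map1,map2 `saliency_map`s on the same grid.
#' @param maps list of >= 2 `saliency_map`s on the same grid.
#' @return A `fused_map`: list with `phi` (non-negative array), `spacing`,
#'   and `provenance` (operator and number of modalities).
NULL

check_same_grid <- function(maps) {
  d <- dim(maps[[1]]$s)
  for (m in maps[-1]) {
    if (!all(dim(m$s) == d))
      stop("saliency maps are on different grids (",
           paste(d, collapse = "x"), " vs ",
           paste(dim(m$s), collapse = "x"),
           "); resample them to a common grid first ",
           "(see resample_saliency_map())", call. = FALSE)
  }
  d
}

new_fused_map <- function(phi, spacing, op, L) {
  structure(list(phi = phi, spacing = spacing,
                 provenance = list(op = op, n_modalities = L)),
            class = "fused_map")
}

#' @export
print.fused_map <- function(x, ...) {
  cat(sprintf("<fused_map> op '%s' over %d modalities, %s voxels, max %.4g\n",
              x$provenance$op, x$provenance$n_modalities,
              paste(dim(x$phi), collapse = "x"), max(x$phi)))
  invisible(x)
}

#' @rdname fusion
#' @export
fuse_pair <- function(map1, map2) {
  stopifnot(inherits(map1, "saliency_map"), inherits(map2, "saliency_map"))
  d <- check_same_grid(list(map1, map2))
  w1 <- matrix(map1$w, ncol = 3)
  w2 <- matrix(map2$w, ncol = 3)
  align <- abs(rowSums(w1 * w2))
  phi <- 0.5 * align * (as.vector(map1$s) + as.vector(map2$s))
  dim(phi) <- d
  new_fused_map(phi, map1$spacing, "cosine", 2L)
}

#' @rdname fusion
#' @export
fuse_multi <- function(maps) {
  if (!is.list(maps) || length(maps) < 2L)
    stop("cosine fusion needs at least two modalities", call. = FALSE)
  lapply(maps, function(m) stopifnot(inherits(m, "saliency_map")))
  d <- check_same_grid(maps)
  L <- length(maps)
  w <- lapply(maps, function(m) matrix(m$w, ncol = 3))
  s <- lapply(maps, function(m) as.vector(m$s))
  phi <- 0
  for (i in seq_len(L)) {
    align_i <- 0
    for (j in seq_len(L)) {
      if (j == i) next
      align_i <- align_i + abs(rowSums(w[[i]] * w[[j]]))
    }
    phi <- phi + s[[i]] * align_i
  }
  phi <- phi / L
  dim(phi) <- d
  new_fused_map(phi, maps[[1]]$spacing, "cosine", L)
}

#' @rdname fusion
#' @export
fuse_min <- function(maps) {
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  d <- check_same_grid(maps)
  phi <- Reduce(pmin, lapply(maps, function(m) m$s))
  dim(phi) <- d
  new_fused_map(phi, maps[[1]]$spacing, "min", length(maps))
}

#' @rdname fusion
#' @export
fuse_max <- function(maps) {
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  d <- check_same_grid(maps)
  phi <- Reduce(pmax, lapply(maps, function(m) m$s))
  dim(phi) <- d
  new_fused_map(phi, maps[[1]]$spacing, "max", length(maps))
}

#' Percentile normalisation of a saliency or probability volume
#'
#' Rescales a non-negative volume to `[0, 1]` by its `pct`-th percentile over
#' positive voxels (values above it are clipped to 1). Used before fusion so
#' one modality cannot dominate by intensity units, and before fuzzy-Dice
#' comparison of probability maps to binary references.
#'
#' @param x array, `saliency_map` or `fused_map`.
#' @param pct percentile in (0, 100]; default 99.9.
#' @return Same type as `x` with rescaled values.
#' @export
normalize_map <- function(x, pct = 99.9) {
  if (inherits(x, "saliency_map")) {
    x$s <- normalize_map(x$s, pct)
    return(x)
  }
  if (inherits(x, "fused_map")) {
    x$phi <- normalize_map(x$phi, pct)
    return(x)
  }
  normalize_saliency(x, pct)
}

#' Resample a saliency map onto another grid by linear interpolation
#'
#' Trilinear interpolation of the saliency and the three direction
#' components, with directions renormalised to unit length afterwards (zero
#' where the interpolated direction vanishes). Grids are assumed to share
#' their physical origin at the centre of voxel (1,1,1), i.e. the inputs are
#' already co-registered.
#'
#' @param map a `saliency_map`.
#' @param target_dim integer length-3 target grid size.
#' @param target_spacing numeric length-3 target spacing in mm.
#' @return A `saliency_map` on the target grid.
#' @export
resample_saliency_map <- function(map, target_dim, target_spacing) {
  stopifnot(inherits(map, "saliency_map"))
  src_d <- dim(map$s)
  tg <- lapply(1:3, function(a) {
    (seq_len(target_dim[a]) - 1) * target_spacing[a] / map$spacing[a] + 1
  })
  grid <- expand.grid(x = tg[[1]], y = tg[[2]], z = tg[[3]])
  interp <- function(vol) trilinear(vol, grid$x, grid$y, grid$z)
  s <- interp(map$s)
  s[s < 0] <- 0
  dim(s) <- target_dim
  w <- vapply(1:3,
              function(cc) interp(map$w[, , , cc]),
              numeric(prod(target_dim)))
  nrm <- sqrt(rowSums(w^2))
  pos <- nrm > 0
  w[pos, ] <- w[pos, , drop = FALSE] / nrm[pos]
  dim(w) <- c(target_dim, 3L)
  structure(list(s = s, w = w, kind = map$kind, spacing = target_spacing),
            class = "saliency_map")
}

# Vectorised trilinear interpolation at fractional 1-based voxel coordinates,
# clamped to the volume.
trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(x, d[1]); y <- cl(y, d[2]); z <- cl(z, d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);     v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1); v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}
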