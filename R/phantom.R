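#' @name phantom
#' @title Synthetic multi-modal vascular phantoms
#'
#' @description Generates co-registered multi-modality volumes of bright
#' tubular structures on a dark background, with ground truth. Tube
#' centerlines are polylines (straight, helical or bifurcating); the
#' intensity profile is a Gaussian radial falloff (default sd = radius / 2),
#' emulating partial-volume boundaries rather than hard discs. Geometry is
#' identical across modalities; each modality adds its own signal gain,
#' additive Gaussian noise, optional smoothing, and optional signal-dropout
#' segments (a fraction of the centerline with attenuated signal), emulating
#' the modality-specific weak responses and discontinuities seen in clinical
#' angiography. All randomness is fixed by the spec's seed.
NULL

#' Tube descriptors for phantoms
#'
#' `tube()` takes an explicit polyline; `tube_straight()`, `tube_helix()` and
#' `tube_bifurcation()` build common geometries (the bifurcation returns a
#' list of three tubes sharing the junction).
#'
#' @param points n x 3 matrix of centerline coordinates in mm (physical
#'   coordinates; voxel (1,1,1) is at the origin).
#' @param radius tube radius in mm (truth mask = voxels within `radius` of
#'   the centerline).
#' @param intensity peak centerline intensity (default 1).
#' @param profile_sd sd of the Gaussian radial intensity falloff in mm;
#'   default `radius / 2`.
#' @param from,to straight tube endpoints (mm).
#' @param center xy centre of the helix axis (mm); the helix runs along z.
#' @param z_range helix z extent (mm).
#' @param coil_radius,turns helix coil radius (mm) and number of turns.
#' @param root,junction,tip1,tip2 bifurcation node coordinates (mm).
#' @param child_radius radius of the two child branches (default
#'   `0.75 * radius`).
#' @return A `phantom_tube` (or list of them for the bifurcation).
#' @export
tube <- function(points, radius, intensity = 1, profile_sd = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L, radius > 0,
            intensity > 0)
  if (is.null(profile_sd)) profile_sd <- radius / 2
  stopifnot(profile_sd > 0)
  structure(list(points = points, radius = radius, intensity = intensity,
                 profile_sd = profile_sd), class = "phantom_tube")
}

#' @rdname tube
#' @export
tube_straight <- function(from, to, radius, intensity = 1,
                          profile_sd = NULL) {
  tube(rbind(from, to), radius, intensity, profile_sd)
}

#' @rdname tube
#' @export
tube_helix <- function(center, z_range, coil_radius, turns, radius,
                       intensity = 1, profile_sd = NULL) {
  t <- seq(0, 1, length.out = max(64L, round(64 * turns)))
  pts <- cbind(center[1] + coil_radius * cos(2 * pi * turns * t),
               center[2] + coil_radius * sin(2 * pi * turns * t),
               z_range[1] + t * diff(z_range))
  tube(pts, radius, intensity, profile_sd)
}

#' @rdname tube
#' @export
tube_bifurcation <- function(root, junction, tip1, tip2, radius,
                             child_radius = 0.75 * radius, intensity = 1) {
  list(tube(rbind(root, junction), radius, intensity),
       tube(rbind(junction, tip1), child_radius, intensity),
       tube(rbind(junction, tip2), child_radius, intensity))
}

#' Phantom specification
#'
#' @param dim integer length-3 grid size (each >= 8).
#' @param spacing voxel spacing in mm.
#' @param tubes list of [tube()] objects (nested lists, e.g. from
#'   [tube_bifurcation()], are flattened); may be empty for a
#'   background-only phantom.
#' @param modalities list of per-modality settings, each a list with fields
#'   `gain` (default 1), `noise_sd` (additive Gaussian noise sd, default
#'   0.02), `smooth_sd` (Gaussian smoothing in mm, default 0) and `dropout`
#'   (`NULL`, or a list / list-of-lists with `start`, `end` in `[0, 1)`
#'   — centerline arc-length fractions — and `attenuation` in `[0, 1)`).
#' @param seed integer seed fixing all randomness.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dim, spacing = c(1, 1, 1), tubes = list(),
                         modalities = list(list(noise_sd = 0.02),
                                           list(noise_sd = 0.06)),
                         seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L), all(spacing > 0),
            is.list(tubes), is.list(modalities), length(modalities) >= 1L)
  flat <- list()
  for (tb in tubes) {
    if (inherits(tb, "phantom_tube")) flat[[length(flat) + 1L]] <- tb
    else for (t2 in tb) flat[[length(flat) + 1L]] <- t2
  }
  extent <- (dim - 1L) * spacing
  for (tb in flat) {
    if (any(tb$points < -1e-9) ||
        any(sweep(tb$points, 2, extent) > 1e-9))
      stop("tube centerline exits the grid extent [0, ",
           paste(signif(extent, 4), collapse = " x "), "] mm", call. = FALSE)
    if (tb$radius < min(spacing) / 2)
      warning("tube radius ", tb$radius, " mm is below half a voxel; ",
              "the tube is severely under-resolved", call. = FALSE)
  }
  mods <- lapply(modalities, function(m) {
    m <- utils::modifyList(list(gain = 1, noise_sd = 0.02, smooth_sd = 0,
                                dropout = NULL), m)
    if (!is.null(m$dropout) && !is.null(m$dropout$start))
      m$dropout <- list(m$dropout)
    for (dseg in m$dropout) {
      stopifnot(dseg$start >= 0, dseg$start < dseg$end, dseg$end <= 1,
                dseg$attenuation >= 0, dseg$attenuation < 1)
    }
    m
  })
  structure(list(dim = dim, spacing = spacing, tubes = flat,
                 modalities = mods, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Densify a polyline to roughly `step` mm segments; returns points, unit
# tangents and cumulative arc-length fractions.
densify_polyline <- function(points, step) {
  segs <- diff(points)
  len <- sqrt(rowSums(segs^2))
  keep <- len > 0
  if (!any(keep)) stop("degenerate tube centerline", call. = FALSE)
  pts <- list()
  for (i in which(keep)) {
    n <- max(2L, ceiling(len[i] / step) + 1L)
    f <- seq(0, 1, length.out = n)
    if (i < max(which(keep))) f <- f[-length(f)]
    pts[[length(pts) + 1L]] <-
      cbind(points[i, 1] + f * segs[i, 1],
            points[i, 2] + f * segs[i, 2],
            points[i, 3] + f * segs[i, 3])
  }
  p <- do.call(rbind, pts)
  d <- diff(p)
  tans <- rbind(d, d[nrow(d), , drop = FALSE])
  nrm <- sqrt(rowSums(tans^2))
  nrm[nrm == 0] <- 1
  tans <- tans / nrm
  arc <- c(0, cumsum(sqrt(rowSums(d^2))))
  frac <- if (max(arc) > 0) arc / max(arc) else arc
  list(points = p, tangents = tans, frac = frac)
}

#' Generate a synthetic multi-modal phantom
#'
#' @param spec a [phantom_spec()].
#' @return List with `modalities` (list of [scalar_volume()]s), `truth`
#'   (logical array, voxels within a tube radius of a centerline —
#'   invariant to all modality settings), `centerline` (data.frame `i, j, k,
#'   tx, ty, tz`: centerline voxels with true unit tangents), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  sp <- spec$spacing
  nvox <- prod(d)
  set.seed(spec$seed)
  truth <- array(FALSE, d)
  nmod <- length(spec$modalities)
  amp <- lapply(seq_len(nmod), function(m) array(0, d))
  cl_rows <- list()
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  step <- 0.25 * min(sp)
  for (tb in spec$tubes) {
    poly <- densify_polyline(tb$points, step)
    reach <- max(4 * tb$profile_sd, tb$radius) + 2 * max(sp)
    lo <- apply(poly$points, 2, min) - reach
    hi <- apply(poly$points, 2, max) + reach
    sub <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
    if (any(lengths(sub) == 0L)) next
    g <- expand.grid(x = ax[[1]][sub[[1]]], y = ax[[2]][sub[[2]]],
                     z = ax[[3]][sub[[3]]])
    nb <- nrow(g)
    best_d2 <- rep(Inf, nb)
    best_pt <- rep(1L, nb)
    for (pidx in seq_len(nrow(poly$points))) {
      p <- poly$points[pidx, ]
      d2 <- (g$x - p[1])^2 + (g$y - p[2])^2 + (g$z - p[3])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_pt[upd] <- pidx
    }
    box_idx <- as.matrix(expand.grid(i = sub[[1]], j = sub[[2]],
                                     k = sub[[3]]))
    lin <- box_idx[, 1] + d[1] * (box_idx[, 2] - 1L) +
      d[1] * d[2] * (box_idx[, 3] - 1L)
    truth[lin] <- truth[lin] | (best_d2 <= tb$radius^2)
    base_amp <- tb$intensity * exp(-best_d2 / (2 * tb$profile_sd^2))
    frac_at <- poly$frac[best_pt]
    for (m in seq_len(nmod)) {
      mod <- spec$modalities[[m]]
      w <- rep(1, nb)
      for (dseg in mod$dropout) {
        inseg <- frac_at >= dseg$start & frac_at < dseg$end
        w[inseg] <- pmin(w[inseg], dseg$attenuation)
      }
      contrib <- mod$gain * w * base_amp
      amp[[m]][lin] <- pmax(amp[[m]][lin], contrib)
    }
    # centerline voxels: nearest voxel of each densified point
    vi <- pmin(pmax(round(sweep(poly$points, 2, sp, "/")) + 1L, 1L),
               matrix(d, nrow(poly$points), 3, byrow = TRUE))
    dup <- duplicated(vi)
    cl_rows[[length(cl_rows) + 1L]] <-
      data.frame(i = vi[!dup, 1], j = vi[!dup, 2], k = vi[!dup, 3],
                 tx = poly$tangents[!dup, 1], ty = poly$tangents[!dup, 2],
                 tz = poly$tangents[!dup, 3])
  }
  modalities <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    mod <- spec$modalities[[m]]
    vol <- amp[[m]]
    if (mod$smooth_sd > 0) {
      vol <- scalar_volume(vol, sp)
      vol <- gaussian_derivative(vol, mod$smooth_sd, c(0, 0, 0))
    }
    vol <- vol + rnorm(nvox, 0, mod$noise_sd)
    dim(vol) <- d
    modalities[[m]] <- scalar_volume(vol, sp)
  }
  centerline <- if (length(cl_rows)) do.call(rbind, cl_rows)
                else data.frame(i = integer(), j = integer(), k = integer(),
                                tx = numeric(), ty = numeric(),
                                tz = numeric())
  list(modalities = modalities, truth = truth, centerline = centerline,
       spec = spec)
}

#' Phantom presets
#'
#' Ready-made phantom specifications used throughout the documentation and
#' tests: `"straight"` (one straight tube, two modalities of unequal noise),
#' `"helix"`, `"bifurcation"`, and `"dropout_pair"` (a straight tube with
#' complementary dropout segments: the first modality loses signal over
#' arc fractions 0.15--0.40, the second over 0.60--0.85).
#'
#' @param name preset name.
#' @param dim grid size (default `c(32, 32, 48)`).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param radius tube radius in mm (default 2).
#' @param seed phantom seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("straight", "helix", "bifurcation",
                                    "dropout_pair"),
                           dim = c(32, 32, 48), spacing = c(1, 1, 1),
                           radius = 2, seed = 1L) {
  name <- match.arg(name)
  ext <- (dim - 1) * spacing
  cx <- ext[1] / 2
  cy <- ext[2] / 2
  mods_plain <- list(list(noise_sd = 0.02), list(noise_sd = 0.06))
  tubes <- switch(name,
    straight = ,
    dropout_pair = list(tube_straight(c(cx, cy, 0), c(cx, cy, ext[3]),
                                      radius)),
    helix = list(tube_helix(c(cx, cy), c(0, ext[3]),
                            coil_radius = min(cx, cy) / 2, turns = 1.5,
                            radius = radius)),
    bifurcation = list(tube_bifurcation(
      root = c(cx, cy, 0), junction = c(cx, cy, ext[3] * 0.45),
      tip1 = c(cx * 0.45, cy, ext[3]), tip2 = c(cx * 1.55, cy, ext[3]),
      radius = radius)))
  mods <- if (name == "dropout_pair") {
    list(list(noise_sd = 0.02,
              dropout = list(start = 0.15, end = 0.40, attenuation = 0.1)),
         list(noise_sd = 0.06,
              dropout = list(start = 0.60, end = 0.85, attenuation = 0.1)))
  } else mods_plain
  phantom_spec(dim, spacing, tubes, mods, seed = seed)
}
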