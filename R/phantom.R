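# Voxel phantom of left-breast anatomy: torso plus two breast bulges,
# lungs and heart as carved ellipsoids, target volumes per protocol
# (CTV = whole ipsilateral breast; PTV = 5 mm expansion kept 5 mm off the
# skin). World axes: x towards patient left, y anterior, z superior,
# origin at the torso centre; all lengths in mm.

#' Phantom geometry specification
#'
#' @param spacing_mm voxel spacing, scalar or length-3 (mm).
#' @param body_semiaxes torso ellipsoid semi-axes (mm).
#' @param breast_center,breast_semiaxes ipsilateral (left) breast
#'   ellipsoid; the contralateral breast is its mirror in x.
#' @param heart_center,heart_semiaxes heart ellipsoid (mm).
#' @param lung_center,lung_semiaxes left lung ellipsoid; the right lung
#'   is its mirror in x.
#' @param ptv_margin_mm isotropic CTV-to-PTV expansion (default 5).
#' @param skin_clearance_mm minimum PTV distance from non-body (default 5).
#' @param pad_voxels empty voxel layers around the body.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing_mm = 5,
                         body_semiaxes = c(150, 100, 180),
                         breast_center = c(70, 85, 20),
                         breast_semiaxes = c(55, 50, 50),
                         heart_center = c(20, 10, -40),
                         heart_semiaxes = c(55, 50, 55),
                         lung_center = c(60, -15, 30),
                         lung_semiaxes = c(45, 60, 110),
                         ptv_margin_mm = 5,
                         skin_clearance_mm = 5,
                         pad_voxels = 2L) {
  spacing <- rep(as.numeric(spacing_mm), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(c(body_semiaxes, breast_semiaxes, heart_semiaxes,
            lung_semiaxes) <= 0))
    stop("all semi-axes must be positive")
  if (ptv_margin_mm < 0 || skin_clearance_mm < 0)
    stop("PTV construction margins must be >= 0")
  structure(list(spacing = spacing, body_semiaxes = body_semiaxes,
                 breast_center = breast_center,
                 breast_semiaxes = breast_semiaxes,
                 heart_center = heart_center, heart_semiaxes = heart_semiaxes,
                 lung_center = lung_center, lung_semiaxes = lung_semiaxes,
                 ptv_margin_mm = ptv_margin_mm,
                 skin_clearance_mm = skin_clearance_mm,
                 pad_voxels = as.integer(pad_voxels)),
            class = "phantom_spec")
}

scale_phantom_spec <- function(spec, factor) {
  for (f in c("body_semiaxes", "breast_center", "breast_semiaxes",
              "heart_center", "heart_semiaxes", "lung_center",
              "lung_semiaxes"))
    spec[[f]] <- spec[[f]] * factor
  spec
}

# membership of an axis-aligned ellipsoid, via separable outer sums of the
# normalised squared coordinate terms
ellipsoid_mask <- function(coords, center, semi) {
  t1 <- ((coords$x - center[1]) / semi[1])^2
  t2 <- ((coords$y - center[2]) / semi[2])^2
  t3 <- ((coords$z - center[3]) / semi[3])^2
  outer(outer(t1, t2, "+"), t3, "+") <= 1
}

#' Build the six-structure voxel phantom
#'
#' Constructs Body (torso plus both breast bulges), CTVp (whole
#' ipsilateral breast), PTVp-Skin05 (CTV expanded by `ptv_margin_mm`,
#' restricted to voxels strictly more than `skin_clearance_mm` from
#' non-body), Lungs, Heart and BreastCL on one grid. Structures are
#' pairwise disjoint except PTV with CTV.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `structures` (named list of
#'   [struct_mask()]s), `spacing`, `origin`, `shape`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  ext_lo <- c(-spec$body_semiaxes[1], -spec$body_semiaxes[2],
              -spec$body_semiaxes[3])
  ext_hi <- c(spec$body_semiaxes[1],
              max(spec$body_semiaxes[2],
                  spec$breast_center[2] + spec$breast_semiaxes[2]),
              spec$body_semiaxes[3])
  pad <- spec$pad_voxels * sp
  origin <- ext_lo - pad
  shape <- ceiling((ext_hi + pad - origin) / sp) + 1L
  coords <- list(x = origin[1] + (seq_len(shape[1]) - 1) * sp[1],
                 y = origin[2] + (seq_len(shape[2]) - 1) * sp[2],
                 z = origin[3] + (seq_len(shape[3]) - 1) * sp[3])
  mirror <- function(v) v * c(-1, 1, 1)

  torso <- ellipsoid_mask(coords, c(0, 0, 0), spec$body_semiaxes)
  breast_i <- ellipsoid_mask(coords, spec$breast_center, spec$breast_semiaxes)
  breast_c <- ellipsoid_mask(coords, mirror(spec$breast_center),
                             spec$breast_semiaxes)
  heart <- ellipsoid_mask(coords, spec$heart_center, spec$heart_semiaxes)
  lung_l <- ellipsoid_mask(coords, spec$lung_center, spec$lung_semiaxes)
  lung_r <- ellipsoid_mask(coords, mirror(spec$lung_center),
                           spec$lung_semiaxes)
  body <- torso | breast_i | breast_c
  heart <- heart & torso
  lungs <- (lung_l | lung_r) & torso & !heart
  ctv <- breast_i & !heart & !lungs
  breast_cl <- breast_c & !heart & !lungs & !ctv

  d_ctv <- distance_to_set(ctv, sp)
  d_skin <- distance_to_set(!body, sp)
  ptv <- d_ctv <= spec$ptv_margin_mm & d_skin > spec$skin_clearance_mm &
    !lungs & !heart & !breast_cl
  if (!any(ptv))
    stop("phantom spec produces an empty PTV (margins vs anatomy)")

  mk <- function(m, name) struct_mask(m, sp, origin, name = name)
  structure(list(
    structures = list(
      "Body" = mk(body, "Body"),
      "CTVp" = mk(ctv, "CTVp"),
      "PTVp-Skin05" = mk(ptv, "PTVp-Skin05"),
      "Lungs" = mk(lungs, "Lungs"),
      "Heart" = mk(heart, "Heart"),
      "BreastCL" = mk(breast_cl, "BreastCL")),
    spacing = sp, origin = origin, shape = shape, spec = spec),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s @ %s mm>\n", paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  for (s in x$structures) print(s)
  invisible(x)
}

# ---- band-limited Gaussian noise -------------------------------------

# smooth random field: white noise on a coarse lattice of pitch corr_mm,
# trilinearly interpolated to the fine grid, normalised to zero mean and
# unit sd
smooth_noise <- function(shape, spacing, corr_mm) {
  tpos <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a] / corr_mm)
  cn <- vapply(tpos, function(t) as.integer(floor(max(t))) + 2L, integer(1))
  C <- array(stats::rnorm(prod(cn)), cn)
  i0 <- lapply(tpos, function(t) floor(t) + 1L)
  fr <- lapply(1:3, function(a) tpos[[a]] - (i0[[a]] - 1L))
  out <- array(0, shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    ix <- pmin(i0[[1]] + dx, cn[1])
    iy <- pmin(i0[[2]] + dy, cn[2])
    iz <- pmin(i0[[3]] + dz, cn[3])
    lin <- outer(outer(ix, (iy - 1L) * cn[1], "+"),
                 (iz - 1L) * cn[1] * cn[2], "+")
    out <- out + array(C[lin], shape) *
      outer(outer(wx, wy), wz)
  }
  (out - mean(out)) / stats::sd(out)
}

# ---- dose painting ----------------------------------------------------

#' Paint a plan-like dose field onto a phantom
#'
#' Emulates a tangential-field breast dose: plateau inside the PTV with
#' multiplicative band-limited Gaussian heterogeneity, exponential
#' distance falloff outside, an optional cold-spot defect, then exact
#' calibration of the PTV mean to `plateau_gy` (global scale) and of each
#' requested OAR mean to its target (per-organ scale).
#'
#' @param phantom a [build_phantom()] result.
#' @param quality list with `plateau_gy` (Gy), `heterogeneity`
#'   (fractional sd of the plateau, 0 disables), `falloff_mm`
#'   (exponential decay length outside the PTV; 0 means no dose outside),
#'   `oar_targets` (named mean-dose targets in Gy for `Lungs`, `Heart`,
#'   `BreastCL`; omit or NA to leave uncalibrated), `cold_spot` (NULL or
#'   list `depth_gy`, `frac_volume`), `het_corr_mm` (heterogeneity
#'   correlation length, default 30).
#' @param seed RNG seed for the heterogeneity field and cold-spot site.
#' @return a [dose_grid()].
#' @export
paint_dose <- function(phantom, quality, seed = 1) {
  stopifnot(inherits(phantom, "phantom"))
  set.seed(seed)
  q <- quality
  plateau <- q$plateau_gy
  if (is.null(plateau) || plateau <= 0) stop("plateau_gy must be positive")
  ptv <- phantom$structures[["PTVp-Skin05"]]$membership
  sp <- phantom$spacing
  dist <- distance_to_set(ptv, sp)
  dose <- if (is.null(q$falloff_mm) || q$falloff_mm <= 0)
    plateau * (dist == 0)
  else
    plateau * exp(-dist / q$falloff_mm)
  het <- if (is.null(q$heterogeneity)) 0 else q$heterogeneity
  if (het > 0) {
    corr <- if (is.null(q$het_corr_mm)) 30 else q$het_corr_mm
    dose <- dose * (1 + het * smooth_noise(phantom$shape, sp, corr))
  }
  if (!is.null(q$cold_spot)) {
    cs <- q$cold_spot
    vox <- which(ptv)
    centre_idx <- arrayInd(vox[sample.int(length(vox), 1L)], phantom$shape)
    centre <- voxel_coords(centre_idx, sp, phantom$origin)
    r <- (3 * cs$frac_volume * length(vox) * prod(sp) / (4 * pi))^(1 / 3)
    coords <- list(x = phantom$origin[1] + (seq_len(phantom$shape[1]) - 1) * sp[1],
                   y = phantom$origin[2] + (seq_len(phantom$shape[2]) - 1) * sp[2],
                   z = phantom$origin[3] + (seq_len(phantom$shape[3]) - 1) * sp[3])
    d2 <- outer(outer((coords$x - centre[1])^2, (coords$y - centre[2])^2, "+"),
                (coords$z - centre[3])^2, "+")
    # linear ramp over 5 mm at the cold-spot edge
    w <- pmin(pmax((sqrt(d2) - r) / 5, 0), 1)
    dose <- dose * (1 - (1 - w) * cs$depth_gy / plateau)
  }
  dose <- pmax(dose, 0)
  # exact PTV mean, then exact OAR means (regions are disjoint from PTV)
  dose <- dose * plateau / mean(dose[ptv])
  if (!is.null(q$oar_targets)) {
    for (org in names(q$oar_targets)) {
      tgt <- q$oar_targets[[org]]
      if (is.null(tgt) || is.na(tgt)) next
      if (tgt > plateau)
        stop(sprintf("requested %s mean dose %.2f Gy exceeds the plateau", org, tgt))
      om <- phantom$structures[[org]]$membership
      cur <- mean(dose[om])
      if (cur <= 0 && tgt > 0)
        stop(sprintf("%s receives no dose; target %.2f Gy unreachable (falloff 0?)",
                     org, tgt))
      if (cur > 0) dose[om] <- dose[om] * tgt / cur
    }
  }
  dose_grid(dose, sp, phantom$origin)
}

# ---- contour perturbation --------------------------------------------

#' Perturb a mask towards target contour-similarity values
#'
#' Displaces the mask boundary by a smooth random field: the perturbed
#' mask is the sublevel set `sdf(x) <= amp * noise(x)` of the signed
#' distance field, with band-limited unit-variance noise and the
#' amplitude `amp` solved by bisection so the volumetric Dice against the
#' original hits `target_vdsc`. The noise correlation length is tied to
#' `target_hd95` (larger tolerated surface distances need coherent,
#' longer-range displacements).
#'
#' @param mask a non-empty [struct_mask()].
#' @param target_vdsc desired VDSC in (0, 1]; 1 returns the mask
#'   unchanged.
#' @param target_hd95 desired HD95 in mm (guides the correlation length;
#'   achieved value is approximate).
#' @param seed RNG seed.
#' @param sdf optional precomputed [signed_distance()] of `mask` (re-used
#'   across seeds for speed).
#' @param corr_mm noise correlation length override (mm).
#' @param tol VDSC bisection tolerance (default 0.005).
#' @return perturbed `struct_mask`.
#' @export
perturb_mask <- function(mask, target_vdsc, target_hd95 = NA, seed = 1,
                         sdf = NULL, corr_mm = NULL, tol = 0.005) {
  stopifnot(inherits(mask, "struct_mask"))
  if (mask$empty) stop("cannot perturb an empty mask")
  if (target_vdsc <= 0 || target_vdsc > 1)
    stop("target_vdsc must lie in (0, 1]")
  if (target_vdsc >= 1 - 1e-12) return(mask)
  set.seed(seed)
  if (is.null(sdf)) sdf <- signed_distance(mask)
  if (is.null(corr_mm))
    corr_mm <- max(3 * mean(mask$spacing),
                   if (is.finite(target_hd95)) 2.5 * target_hd95 else 0)
  noise <- smooth_noise(mask$shape, mask$spacing, corr_mm)
  orig <- mask$membership
  n_orig <- sum(orig)
  vdsc_at <- function(amp) {
    m2 <- sdf <= amp * noise
    n2 <- sum(m2)
    if (n2 == 0L) return(0)
    2 * sum(m2 & orig) / (n_orig + n2)
  }
  lo <- 0; hi <- mean(mask$spacing)
  v_hi <- vdsc_at(hi)
  while (v_hi > target_vdsc && hi < 500) {
    hi <- hi * 2
    v_hi <- vdsc_at(hi)
  }
  if (v_hi > target_vdsc)
    stop(sprintf("cannot reach VDSC %.3f: amplitude %.0f mm still gives %.3f",
                 target_vdsc, hi, v_hi))
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    v <- vdsc_at(mid)
    if (abs(v - target_vdsc) <= tol) { lo <- hi <- mid; break }
    if (v > target_vdsc) lo <- mid else hi <- mid
  }
  amp <- (lo + hi) / 2
  struct_mask(sdf <= amp * noise, mask$spacing, mask$origin,
              name = mask$name)
}

# apply the configured contour targets to a phantom's structures
perturb_structures <- function(phantom, contour_targets, seed = 1) {
  out <- list()
  for (r in seq_len(nrow(contour_targets))) {
    sname <- contour_targets$structure[r]
    m <- phantom$structures[[sname]]
    if (is.null(m)) next
    out[[sname]] <- perturb_mask(m, contour_targets$vdsc[r],
                                 contour_targets$hd95_mm[r],
                                 seed = seed + r)
  }
  out
}
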