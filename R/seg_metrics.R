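#' Surface voxel centres of a mask
#'
#' A member voxel is a surface voxel iff at least one of its six
#' face-neighbours is a non-member or lies outside the array (array-edge
#' members therefore count as surface). Returned as voxel-centre world
#' coordinates in mm.
#'
#' @param m a non-empty [struct_mask()].
#' @return numeric n x 3 matrix of mm coordinates.
#' @export
surface_points <- function(m) {
  stopifnot(inherits(m, "struct_mask"))
  if (m$empty || !any(m$membership))
    stop(sprintf("mask '%s' is empty; no surface", m$name))
  idx <- which(surface_voxels(m$membership), arr.ind = TRUE)
  voxel_coords(idx, m$spacing, m$origin)
}

# logical array marking boundary member voxels under 6-connectivity
surface_voxels <- function(a) {
  dm <- dim(a)
  # padded neighbour lookup: outside counts as non-member
  shift_nonmember <- function(axis, by) {
    out <- array(TRUE, dm)  # TRUE = neighbour is non-member/outside
    n <- dm[axis]
    if (n < 1L + abs(by)) return(out)
    src <- seq_len(n - abs(by))
    if (by > 0) {
      dst <- src + by
    } else {
      dst <- src
      src <- src - by
    }
    ix <- function(which_idx) switch(axis,
      `1` = list(which_idx, TRUE, TRUE),
      `2` = list(TRUE, which_idx, TRUE),
      `3` = list(TRUE, TRUE, which_idx))
    do.call(`[<-`, c(list(out), ix(dst),
                     list(value = !do.call(`[`, c(list(a), ix(src))))))
  }
  any_bg <- array(FALSE, dm)
  for (axis in 1:3) for (by in c(-1L, 1L))
    any_bg <- any_bg | shift_nonmember(axis, by)
  a & any_bg
}

# for each row of A, Euclidean distance (mm) to the nearest row of B;
# chunked vectorised nearest-neighbour
nn_distances <- function(A, B) {
  if (!nrow(A) || !nrow(B)) stop("empty point set")
  b2 <- rowSums(B * B)
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e7 / nrow(B)))
  for (i0 in seq.int(1L, nrow(A), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(A))
    Ai <- A[ii, , drop = FALSE]
    d2 <- outer(rowSums(Ai * Ai), b2, "+") - 2 * tcrossprod(Ai, B)
    jmin <- max.col(-d2, ties.method = "first")
    out[ii] <- sqrt(pmax(d2[cbind(seq_along(ii), jmin)], 0))
  }
  out
}

check_mask_pair <- function(a, b) {
  stopifnot(inherits(a, "struct_mask"), inherits(b, "struct_mask"))
  stop_if_misaligned(a, b, "masks")
}

#' Volumetric Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` over member-voxel counts. Two empty
#' masks are defined as perfectly similar (1, with a warning).
#'
#' @param a,b aligned [struct_mask()]s.
#' @return value in `[0, 1]`.
#' @export
vdsc <- function(a, b) {
  check_mask_pair(a, b)
  na <- sum(a$membership); nb <- sum(b$membership)
  if (na + nb == 0L) {
    warning("both masks empty; VDSC defined as 1")
    return(1)
  }
  2 * sum(a$membership & b$membership) / (na + nb)
}

#' Surface Dice similarity coefficient at tolerance tau
#'
#' Fraction of the two surfaces lying within `tau` mm of the other
#' surface: `(|S_A within tau of S_B| + |S_B within tau of S_A|) /
#' (|S_A| + |S_B|)`, Euclidean distances between surface-voxel centres.
#'
#' @param a,b aligned non-empty [struct_mask()]s.
#' @param tau distance tolerance in mm (default 3).
#' @return value in `[0, 1]`.
#' @export
sdsc <- function(a, b, tau = 3) {
  check_mask_pair(a, b)
  if (tau < 0) stop("tau must be >= 0")
  sa <- surface_points(a)
  sb <- surface_points(b)
  dab <- nn_distances(sa, sb)
  dba <- nn_distances(sb, sa)
  tol <- tau + 1e-9  # absorb floating-point noise at the tolerance boundary
  (sum(dab <= tol) + sum(dba <= tol)) / (nrow(sa) + nrow(sb))
}

#' 95th-percentile Hausdorff distance
#'
#' The maximum of the two directed 95th-percentile surface distances, each
#' the 95th percentile (linear interpolation between order statistics) of
#' the nearest-surface distances over one surface.
#'
#' @param a,b aligned non-empty [struct_mask()]s.
#' @param p percentile (default 95).
#' @return distance in mm.
#' @export
hd95 <- function(a, b, p = 95) {
  check_mask_pair(a, b)
  sa <- surface_points(a)
  sb <- surface_points(b)
  max(stats::quantile(nn_distances(sa, sb), p / 100, type = 7, names = FALSE),
      stats::quantile(nn_distances(sb, sa), p / 100, type = 7, names = FALSE))
}

#' All three contour-comparison metrics at once
#'
#' @param a,b aligned non-empty [struct_mask()]s (reference, test).
#' @param tau surface-Dice tolerance in mm.
#' @return one-row data.frame `structure, vdsc, sdsc_3mm, hd95_mm`.
#' @export
compare_masks <- function(a, b, tau = 3) {
  data.frame(structure = a$name,
             vdsc = vdsc(a, b),
             sdsc_3mm = sdsc(a, b, tau),
             hd95_mm = hd95(a, b),
             stringsAsFactors = FALSE)
}
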