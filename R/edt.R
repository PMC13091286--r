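# Exact Euclidean distance transform, separable (parabola-envelope) form,
# with anisotropic voxel spacing. Pure R; distances are voxel-centre based
# and returned in mm. Infinities are encoded as a large finite cost so the
# envelope arithmetic stays defined.

EDT_BIG <- 1e12  # mm^2, far above any realistic squared extent

# 1D squared-distance transform of one line of costs f (mm^2) on a grid
# with squared step s2 (mm^2)
dt1d_sq <- function(f, s2) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  d <- numeric(n)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2L:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q * s2) - (f[p] + p * p * s2)) / (2 * s2 * (q - p))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1L:n) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- s2 * (q - p)^2 + f[p]
  }
  d
}

# apply dt1d_sq along the first axis of a 3D cost array
dt_axis1 <- function(g, s) {
  dm <- dim(g)
  m <- matrix(g, nrow = dm[1])
  s2 <- s * s
  for (j in seq_len(ncol(m))) m[, j] <- dt1d_sq(m[, j], s2)
  array(m, dim = dm)
}

#' Euclidean distance to a voxel set
#'
#' Exact distance (mm, voxel-centre to voxel-centre, anisotropic spacing
#' respected) from every grid voxel to the nearest `TRUE` voxel of
#' `member`. All-`FALSE` input gives a large sentinel distance everywhere.
#'
#' @param member logical 3D array.
#' @param spacing mm per axis.
#' @return numeric 3D array of distances in mm.
#' @export
distance_to_set <- function(member, spacing) {
  stopifnot(length(dim(member)) == 3L, length(spacing) == 3L)
  g <- array(ifelse(member, 0, EDT_BIG), dim = dim(member))
  g <- dt_axis1(g, spacing[1])
  g <- aperm(dt_axis1(aperm(g, c(2, 1, 3)), spacing[2]), c(2, 1, 3))
  g <- aperm(dt_axis1(aperm(g, c(3, 2, 1)), spacing[3]), c(3, 2, 1))
  sqrt(pmin(g, EDT_BIG))
}

#' Signed distance field of a mask
#'
#' Negative inside the mask, positive outside; magnitude is the Euclidean
#' distance (mm) to the nearest voxel of the opposite membership. The zero
#' level sits between the boundary voxel layers.
#'
#' @param mask a [struct_mask()].
#' @return numeric 3D array, mm.
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "struct_mask"))
  m <- mask$membership
  d_in <- distance_to_set(m, mask$spacing)       # 0 inside
  d_out <- distance_to_set(!m, mask$spacing)     # 0 outside
  d_in - d_out
}
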