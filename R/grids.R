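#' Construct a dose grid
#'
#' A `dose_grid` is an axis-aligned 3D voxel field of absorbed dose in Gy,
#' with per-axis spacing (mm) and the world position (mm) of the centre of
#' voxel `[1,1,1]` as origin. Index order is `[i, j, k]` with world
#' coordinate `origin + (index - 1) * spacing`.
#'
#' @param values numeric 3D array of doses in Gy; finite and non-negative.
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param origin numeric length-3, mm; world position of voxel (1,1,1) centre.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("dose values must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  bad <- sum(!is.finite(values) | values < 0)
  if (bad > 0L)
    stop(sprintf("dose grid contains %d negative or non-finite voxel(s)", bad))
  structure(
    list(values = values, spacing = spacing, origin = origin,
         shape = dim(values)),
    class = "dose_grid"
  )
}

#' Construct a structure mask
#'
#' Boolean voxel membership on the same geometry convention as [dose_grid()].
#' A voxel belongs to the structure iff its centre lies inside it.
#'
#' @param membership logical (or 0/1) 3D array.
#' @param spacing,origin geometry as in [dose_grid()].
#' @param name structure label (e.g. `"CTVp"`, `"Heart"`).
#' @param allow_empty if `FALSE` (default) an all-false mask is an error;
#'   if `TRUE` the returned mask carries `empty = TRUE`.
#' @return An object of class `struct_mask`.
#' @export
struct_mask <- function(membership, spacing, origin = c(0, 0, 0),
                        name = "structure", allow_empty = FALSE) {
  membership <- as.array(membership)
  if (length(dim(membership)) != 3L) stop("mask must be a 3D array")
  storage.mode(membership) <- "logical"
  if (anyNA(membership)) stop("mask contains NA voxels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)")
  empty <- !any(membership)
  if (empty && !allow_empty)
    stop(sprintf("mask '%s' has no member voxels", name))
  structure(
    list(membership = membership, spacing = spacing, origin = origin,
         shape = dim(membership), name = name, empty = empty),
    class = "struct_mask"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid %s, spacing %s mm, dose %.2f-%.2f Gy>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.struct_mask <- function(x, ...) {
  cat(sprintf("<struct_mask '%s' %s, %d voxels, %.1f cm3>\n",
              x$name, paste(x$shape, collapse = "x"),
              sum(x$membership), mask_volume(x)))
  invisible(x)
}

#' Test geometric alignment of two volumes
#'
#' Pure predicate gating every cross-volume operation: `TRUE` iff shape is
#' identical and spacing and origin agree within `tol` mm on every axis.
#'
#' @param a,b `dose_grid` or `struct_mask` objects.
#' @param tol alignment tolerance in mm (default 1e-6).
#' @return logical scalar.
#' @export
check_aligned <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!check_aligned(a, b))
    stop(sprintf("%s are not geometrically aligned (shape/spacing/origin)", what))
  invisible(TRUE)
}

#' Structure volume in cm3
#'
#' Member-voxel count times voxel volume (product of spacings), mm3 to cm3.
#'
#' @param m a `struct_mask`.
#' @return volume in cm3; 0 with a warning for an empty mask.
#' @export
mask_volume <- function(m) {
  stopifnot(inherits(m, "struct_mask"))
  n <- sum(m$membership)
  if (n == 0L) {
    warning(sprintf("mask '%s' is empty; volume 0", m$name))
    return(0)
  }
  n * prod(m$spacing) / 1000
}

#' Voxel-centre world coordinates of a set of voxels
#'
#' @param idx integer matrix (n x 3) of array indices.
#' @param spacing,origin grid geometry (mm).
#' @return numeric n x 3 matrix of mm coordinates.
#' @keywords internal
voxel_coords <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}
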