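#' Fit an arc through the apical surface, nucleus center, and basal end
#'
#' Hair-cell nuclear position is quantified along an arc fitted through
#' three landmarks in 3D: the apical surface (cuticular plate) `A`, the
#' nucleus centroid `N`, and the basal end `B`. The fitted circle is the
#' circumcircle of the three points in their common plane; arc lengths are
#' measured along the arc from `A` to `B` that passes through `N`. When
#' the three points are (nearly) collinear — triangle area below
#' `1e-9 * |AB|^2`, a scale-free tolerance that prevents the circumradius
#' from blowing up — the fit falls back to straight segments and lengths
#' are Euclidean distances.
#'
#' @param a,n,b Numeric length-3 coordinates of the apical landmark,
#'   nucleus centroid, and basal landmark, in voxel indices (or in
#'   micrometres if `voxel_size = c(1, 1, 1)`).
#' @param voxel_size Physical voxel spacing `(dx, dy, dz)` in micrometres;
#'   points are scaled to micrometres before fitting.
#' @return An object of class `oto_arc`: a list with the scaled points,
#'   `collinear` flag, circle `center`, `radius` and plane `normal` (NA
#'   when collinear), and arc lengths `len_an` (apical to nucleus) and
#'   `len_ab` (apical to basal), in micrometres.
#' @examples
#' fit <- fit_arc(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
#' fit$len_an  # pi/2: quarter of the unit circle
#' nucleus_position(fit)
#' @export
fit_arc <- function(a, n, b, voxel_size = c(1, 1, 1)) {
  pts <- lapply(list(a = a, n = n, b = b), function(p) {
    if (!is.numeric(p) || length(p) != 3L || anyNA(p)) {
      abort("landmarks must be numeric length-3 coordinates")
    }
    as.numeric(p) * voxel_size
  })
  if (any(voxel_size <= 0)) abort("`voxel_size` must be strictly positive")
  a <- pts$a; n <- pts$n; b <- pts$b
  if (identical_point(a, n) || identical_point(a, b) || identical_point(n, b)) {
    abort("landmarks must be three distinct points")
  }

  u <- n - a
  v <- b - a
  cr <- cross3(u, v)
  area2 <- sqrt(sum(cr^2))          # twice the triangle area
  ab2 <- sum(v^2)

  if (area2 / 2 < 1e-9 * ab2) {
    fit <- list(
      a = a, n = n, b = b, collinear = TRUE,
      center = rep(NA_real_, 3), radius = NA_real_, normal = rep(NA_real_, 3),
      len_an = sqrt(sum(u^2)), len_ab = sqrt(ab2)
    )
    class(fit) <- "oto_arc"
    return(fit)
  }

  # circumcenter: a + (|v|^2 (w x u) x w? ) -- use the standard barycentric
  # formula in the plane of the triangle
  uu <- sum(u^2); vv <- sum(v^2); uv <- sum(u * v)
  denom <- 2 * (uu * vv - uv^2)
  s <- (vv * (uu - uv)) / denom
  t <- (uu * (vv - uv)) / denom
  center <- a + s * u + t * v
  radius <- sqrt(sum((a - center)^2))
  normal <- cr / area2

  # angles around the circle, measured from A
  e1 <- (a - center) / radius
  e2 <- cross3(normal, e1)
  ang <- function(p) {
    d <- p - center
    th <- atan2(sum(d * e2), sum(d * e1))
    if (th < 0) th + 2 * pi else th
  }
  th_n <- ang(n)
  th_b <- ang(b)
  # the arc A -> B passing through N
  if (th_n <= th_b) {
    len_an <- radius * th_n
    len_ab <- radius * th_b
  } else {
    len_an <- radius * (2 * pi - th_n)
    len_ab <- radius * (2 * pi - th_b)
  }

  fit <- list(
    a = a, n = n, b = b, collinear = FALSE,
    center = center, radius = radius, normal = normal,
    len_an = len_an, len_ab = len_ab
  )
  class(fit) <- "oto_arc"
  fit
}

identical_point <- function(p, q) all(p == q)

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Nuclear position along the fitted arc
#'
#' @param fit An [fit_arc()] result.
#' @return A one-row tibble with `distance_um` (arc length from the apical
#'   landmark to the nucleus) and `normalized` (fraction of the total
#'   apical-to-basal arc length, in `[0, 1]`).
#' @export
nucleus_position <- function(fit) {
  stopifnot(inherits(fit, "oto_arc"))
  if (fit$len_ab == 0) abort("total arc length is zero; cannot normalize")
  tibble(distance_um = fit$len_an, normalized = fit$len_an / fit$len_ab)
}

#' @export
print.oto_arc <- function(x, ...) {
  kind <- if (x$collinear) "collinear (straight-segment fallback)" else
    sprintf("circular, radius %.3f um", x$radius)
  cat("<oto_arc> ", kind, "\n", sep = "")
  cat(sprintf("  apical->nucleus %.4f um, apical->basal %.4f um\n",
              x$len_an, x$len_ab))
  invisible(x)
}

#' @rdname fit_arc
#' @param x An `oto_arc` object.
#' @param ... Unused.
#' @export
tidy.oto_arc <- function(x, ...) {
  tibble(
    collinear = x$collinear,
    radius_um = if (x$collinear) NA_real_ else x$radius,
    distance_um = x$len_an,
    arc_length_um = x$len_ab,
    normalized = x$len_an / x$len_ab
  )
}

#' Arc morphometry for a detection table
#'
#' Applies [fit_arc()] and [nucleus_position()] to every row of a cell
#' detection table, using its landmark columns (`apical_*`, `nucleus_*`,
#' `basal_*`, in micrometres).
#'
#' @param detections A tibble as returned by [classify_cells()] (or a
#'   manual-landmark table with the same columns).
#' @param voxel_size Voxel spacing in micrometres; defaults to
#'   `c(1, 1, 1)` because detection tables already carry micrometre
#'   coordinates.
#' @return The input with `distance_um`, `normalized`, `arc_length_um`,
#'   and `collinear` columns appended.
#' @export
measure_nuclei <- function(detections, voxel_size = c(1, 1, 1)) {
  need <- c(paste0("apical_", c("x", "y", "z")),
            paste0("nucleus_", c("x", "y", "z")),
            paste0("basal_", c("x", "y", "z")))
  missing_cols <- setdiff(need, names(detections))
  if (length(missing_cols)) {
    abort(paste0("detections lack landmark columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  res <- purrr::pmap_dfr(
    detections[need],
    function(apical_x, apical_y, apical_z, nucleus_x, nucleus_y, nucleus_z,
             basal_x, basal_y, basal_z) {
      fit <- fit_arc(c(apical_x, apical_y, apical_z),
                     c(nucleus_x, nucleus_y, nucleus_z),
                     c(basal_x, basal_y, basal_z),
                     voxel_size = voxel_size)
      tibble(distance_um = fit$len_an,
             normalized = fit$len_an / fit$len_ab,
             arc_length_um = fit$len_ab,
             collinear = fit$collinear)
    }
  )
  dplyr::bind_cols(as_tibble(detections), res)
}
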