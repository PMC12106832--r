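#' Surface morphometry: areas and the 3D gyrification index
#'
#' `mesh_surface_area` sums triangle areas (half cross-product magnitude).
#' `convex_hull_area` is the surface area of the convex hull of the vertex
#' set. `gyrification_index` is their ratio: 1 for convex surfaces, larger the
#' more folded the surface is. The index is invariant to rigid motion and to
#' uniform scaling, and requires a closed, consistently oriented mesh.
#'
#' @param mesh a `perigyri_mesh` (or, for `convex_hull_area`, a numeric
#'   `n x 3` point matrix).
#' @return A single non-negative number; `gyrification_index` is `>= 1` up to
#'   floating-point error.
#' @examples
#' gyrification_index(cube_mesh())   # exactly 1: the cube is convex
#' @export
mesh_surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "perigyri_mesh"))
  sum(triangle_areas(mesh))
}

#' @rdname mesh_surface_area
#' @export
convex_hull_area <- function(mesh) {
  pts <- if (inherits(mesh, "perigyri_mesh")) mesh$vertices else as.matrix(mesh)
  if (nrow(pts) < 4L) stop("convex hull needs at least 4 points")
  .hull3d_cpp(pts)$area
}

#' @rdname mesh_surface_area
#' @export
gyrification_index <- function(mesh) {
  stopifnot(inherits(mesh, "perigyri_mesh"))
  be <- boundary_edges(mesh)
  if (length(be))
    stop("mesh is not closed; boundary edges (vertex pairs): ",
         paste(head(be, 10L), collapse = ", "),
         if (length(be) > 10L) " ..." else "")
  mesh_surface_area(mesh) / convex_hull_area(mesh)
}

# Band-limited smooth scalar field on the unit sphere: a superposition of
# plane waves cos(k (u . d) + phase) with angular frequencies in a fixed band
# (spherical-harmonic degree 12-24 equivalent), softly saturated with a tanh
# so excursions stay bounded (~1.2 sd); bounded excursions let the radial
# deformation fold deeply before the positive-radius (star-shape) limit on
# the amplitude. The band and saturation are constants of the generator;
# amplitude is the only dial. Returns a function of an n x 3 matrix of unit
# directions, standardized to zero mean / unit sd over the template
# directions it is first evaluated on.
sphere_field <- function(seed, n_waves = 48L, band = c(12, 24)) {
  waves <- with_seed(seed, {
    d <- matrix(rnorm(3L * n_waves), n_waves, 3L)
    d <- d / sqrt(rowSums(d^2))
    list(d = d,
         k = runif(n_waves, band[1], band[2]),
         phase = runif(n_waves, 0, 2 * pi))
  })
  mu <- NULL; sdv <- NULL; mu2 <- NULL; sd2 <- NULL
  function(u) {
    raw <- cos(sweep(u %*% t(waves$d), 2L, waves$k, `*`) +
               matrix(waves$phase, nrow(u), length(waves$phase), byrow = TRUE))
    s <- rowSums(raw) / sqrt(length(waves$k) / 2)
    if (is.null(mu)) {
      mu <<- mean(s); sdv <<- max(sd(s), 1e-12)
    }
    s <- 1.2 * tanh((s - mu) / (1.2 * sdv))
    if (is.null(mu2)) {
      mu2 <<- mean(s); sd2 <<- max(sd(s), 1e-12)
    }
    (s - mu2) / sd2
  }
}

#' Synthetic folded surfaces with a prescribed gyrification index
#'
#' Generates a star-shaped surface by radially perturbing an icosphere,
#' `r(u) = radius * (1 + a * s(u))`, where `s` is a seeded band-limited smooth
#' field with unit standard deviation and the amplitude `a` is calibrated by
#' bisection so the measured gyrification index hits `target_gi`. These
#' surfaces stand in for extracted cortical meshes in tests and simulations;
#' they share the real surfaces' area/hull structure but none of their
#' anatomy.
#'
#' @param target_gi desired gyrification index, `>= 1`.
#' @param radius sphere radius (mm).
#' @param subdivision icosphere subdivision level (`>= 3`).
#' @param seed integer seed for the perturbation field.
#' @param tol calibration tolerance on the achieved index.
#' @return `simulate_folded_mesh` returns a `perigyri_mesh` with attribute
#'   `"amplitude"`; `calibrate_fold_amplitude` returns the amplitude alone.
#' @export
simulate_folded_mesh <- function(target_gi, radius = 60, subdivision = 4,
                                 seed = 1, tol = 0.005) {
  stopifnot(target_gi >= 1, subdivision >= 3)
  base <- icosphere(subdivision, radius = 1)
  u <- base$vertices
  field <- sphere_field(seed)
  s <- field(u)
  a <- calibrate_fold_amplitude(target_gi, base, s, tol = tol)
  out <- mesh(u * radius * (1 + a * s), base$faces)
  out <- orient_mesh(out)
  attr(out, "amplitude") <- a
  out
}

#' @rdname simulate_folded_mesh
#' @param template unit icosphere `perigyri_mesh` used as deformation support.
#' @param field_values field values `s` at the template vertices.
#' @param max_iter bisection iteration cap.
#' @export
calibrate_fold_amplitude <- function(target_gi, template, field_values,
                                     tol = 0.005, max_iter = 60L) {
  stopifnot(target_gi >= 1)
  if (target_gi == 1) return(0)
  u <- template$vertices
  gi_at <- function(a)
    gyrification_index(mesh(u * (1 + a * field_values), template$faces,
                            validate = FALSE))
  a_max <- 0.95 / max(abs(field_values))  # keep radii positive, star-shaped
  lo <- 0; hi <- a_max
  if (gi_at(hi) < target_gi)
    stop("target gyrification index ", target_gi,
         " unreachable before the star-shape bound on the amplitude")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g <- gi_at(mid)
    if (abs(g - target_gi) < tol) return(mid)
    if (g < target_gi) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Canonical tissue labels for volumetric features (mm^3).
tissue_labels <- c("eCSF", "cGM", "WM", "dGM", "lateral_ventricles",
                   "cerebellum", "brainstem", "hippocampus")

#' Aggregate raw morphometric measures into analysis features
#'
#' Derived features follow the study definitions: CSF is external CSF plus the
#' lateral ventricles; intracranial volume is the sum of all eight tissue
#' volumes; the gyrification index is surface area over convex-hull area.
#'
#' @param volumes named numeric vector with entries `eCSF`, `cGM`, `WM`,
#'   `dGM`, `lateral_ventricles`, `cerebellum`, `brainstem`, `hippocampus`
#'   (mm^3, all positive).
#' @param surface_area_mm2,hull_area_mm2 optional surface measures (mm^2).
#' @return A one-row `data.frame` with the tissue volumes, `csf_mm3`,
#'   `icv_mm3` and, when areas are given, `surface_area_mm2`, `hull_area_mm2`
#'   and `gyrification_index`.
#' @export
aggregate_features <- function(volumes, surface_area_mm2 = NULL,
                               hull_area_mm2 = NULL) {
  missing_t <- setdiff(tissue_labels, names(volumes))
  if (length(missing_t))
    stop("missing tissue volume(s): ", paste(missing_t, collapse = ", "))
  volumes <- volumes[tissue_labels]
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("tissue volumes must be positive and finite")
  out <- as.data.frame(as.list(volumes))
  names(out) <- paste0(tissue_labels, "_mm3")
  out$csf_mm3 <- volumes[["eCSF"]] + volumes[["lateral_ventricles"]]
  out$icv_mm3 <- sum(volumes)
  if (!is.null(surface_area_mm2) && !is.null(hull_area_mm2)) {
    if (surface_area_mm2 <= 0 || hull_area_mm2 <= 0)
      stop("areas must be positive")
    out$surface_area_mm2 <- surface_area_mm2
    out$hull_area_mm2 <- hull_area_mm2
    out$gyrification_index <- surface_area_mm2 / hull_area_mm2
  }
  out
}

#' Standardize a positive outcome series to maximum one
#'
#' Divides each value by the series maximum, the scale on which the
#' standardized gyrification index is analysed (maximum set to 1). The map is
#' monotone, so order statistics and growth fractions are unchanged.
#'
#' @param values positive numeric vector.
#' @return Numeric vector with maximum exactly 1.
#' @export
standardize_feature <- function(values) {
  if (!length(values)) stop("empty series")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive and finite")
  values / max(values)
}
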