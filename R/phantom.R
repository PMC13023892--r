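# Phantom generation: randomized two-layer (skull shell + brain interior)
# elliptical head models with 0, 1 or 2 elliptical hemorrhagic inclusions,
# rasterized onto the solver grid as relative-permittivity / conductivity maps.

#' Coupling-medium dielectric properties
#'
#' The antenna--head gap is filled with a lossy matching medium with relative
#' permittivity 45 and conductivity 0.5 S/m; every grid cell outside the head
#' holds exactly these values.
#'
#' @return Named numeric vector with elements `eps_r` and `sigma`.
#' @export
coupling_medium <- function() c(eps_r = 45, sigma = 0.5)

#' Default tissue dielectric table
#'
#' Approximate tissue properties near 1--2 GHz: skull (cortical bone), average
#' brain, and whole blood for the hemorrhagic inclusions.  Only the contrast
#' between lesion and background matters for confocal imaging; all values are
#' configurable through [phantom_config()].
#'
#' @return Named list of `c(eps_r, sigma)` pairs for `skull`, `brain`, `blood`.
#' @export
tissue_table_default <- function() {
  list(skull = c(eps_r = 13, sigma = 0.9),
       brain = c(eps_r = 45, sigma = 0.8),
       blood = c(eps_r = 61, sigma = 1.6))
}

#' Square simulation grid specification
#'
#' Cell centers run from `-half + dx/2` to `half - dx/2` in both axes;
#' `origin` is the physical coordinate of cell (1,1)'s center.
#'
#' @param dx Grid spacing (m).
#' @param half Half-width of the square domain (m).
#' @return List with `dx`, `n` (cells per side), `origin`, and center
#'   coordinate vectors `xc`, `yc`.
#' @export
grid_spec <- function(dx = 2.5e-3, half = 0.125) {
  stopifnot(dx > 0, half > dx)
  n <- round(2 * half / dx)
  xc <- -half + (seq_len(n) - 0.5) * dx
  list(dx = dx, n = n, origin = c(xc[1], xc[1]), xc = xc, yc = xc)
}

#' Lesion (hemorrhage) specification
#'
#' @param center Length-2 numeric, ellipse center (m).
#' @param semi_axes Length-2 numeric, semi-axes `(a, b)` (m), both positive.
#' @param angle Orientation (rad).
#' @param eps_r,sigma Lesion dielectric properties.
#' @return Object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, semi_axes, angle = 0,
                        eps_r = tissue_table_default()$blood[["eps_r"]],
                        sigma = tissue_table_default()$blood[["sigma"]]) {
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop("lesion semi-axes must be positive")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 angle = as.numeric(angle), eps_r = eps_r, sigma = sigma),
            class = "lesion_spec")
}

#' Phantom generation configuration
#'
#' Randomization ranges for the head model (rotation, per-axis deformation,
#' global scale) and for lesion geometry.  With `class_label` 0/1/2 the
#' phantom carries that many non-overlapping elliptical hemorrhages.
#'
#' @param class_label Lesion count, one of 0, 1, 2.
#' @param seed Integer seed; phantom generation is a pure function of the
#'   configuration including this seed.
#' @param grid Grid from [grid_spec()].
#' @param head_radius_range Base head radius range (m) before deformation.
#' @param rotation_range Head/lesion orientation range (rad).
#' @param deform_range Per-axis scale factor range.
#' @param scale_range Global scale factor range.
#' @param skull_thickness Skull shell thickness (m).
#' @param lesion_semi_axis_range Lesion semi-axis range (m).
#' @param tissue_table Named list as in [tissue_table_default()].
#' @param max_attempts Rejection-sampling cap for non-overlapping placement.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(class_label, seed = 1L, grid = grid_spec(),
                           head_radius_range = c(0.070, 0.080),
                           rotation_range = c(0, 2 * pi),
                           deform_range = c(0.9, 1.1),
                           scale_range = c(0.95, 1.05),
                           skull_thickness = 0.007,
                           lesion_semi_axis_range = c(0.005, 0.015),
                           tissue_table = tissue_table_default(),
                           max_attempts = 1000L) {
  if (!class_label %in% 0:2) stop("class_label must be 0, 1 or 2")
  structure(list(class_label = as.integer(class_label), seed = as.integer(seed),
                 grid = grid, head_radius_range = head_radius_range,
                 rotation_range = rotation_range, deform_range = deform_range,
                 scale_range = scale_range, skull_thickness = skull_thickness,
                 lesion_semi_axis_range = lesion_semi_axis_range,
                 tissue_table = tissue_table,
                 max_attempts = as.integer(max_attempts)),
            class = "phantom_config")
}

#' Dielectric map container
#'
#' Per-cell relative permittivity and conductivity on a square grid, with the
#' interior-brain mask used for lesion placement.
#'
#' @param eps_r,sigma Numeric matrices (same dimensions).
#' @param dx Grid spacing (m).
#' @param origin Physical coordinates of cell (1,1)'s center (m).
#' @param mask_brain Logical matrix, `TRUE` inside the brain interior.
#' @return Object of class `dielectric_map`.
#' @export
dielectric_map <- function(eps_r, sigma, dx, origin, mask_brain) {
  stopifnot(is.matrix(eps_r), all(dim(eps_r) == dim(sigma)),
            all(dim(eps_r) == dim(mask_brain)))
  if (any(eps_r < 1)) stop("eps_r must be >= 1 everywhere")
  if (any(sigma < 0)) stop("sigma must be >= 0 everywhere")
  structure(list(eps_r = eps_r, sigma = sigma, dx = dx,
                 origin = as.numeric(origin), mask_brain = mask_brain),
            class = "dielectric_map")
}

#' @export
print.dielectric_map <- function(x, ...) {
  cat(sprintf("<dielectric_map> %d x %d cells, dx = %.4g m\n",
              nrow(x$eps_r), ncol(x$eps_r), x$dx))
  cat(sprintf("  eps_r in [%.3g, %.3g], sigma in [%.3g, %.3g] S/m, brain cells: %d\n",
              min(x$eps_r), max(x$eps_r), min(x$sigma), max(x$sigma),
              sum(x$mask_brain)))
  invisible(x)
}

# cell-center coordinate matrices for a map/grid
grid_coords <- function(grid) {
  list(X = matrix(grid$xc, grid$n, grid$n),
       Y = matrix(grid$yc, grid$n, grid$n, byrow = TRUE))
}

# squared elliptical radius of points (x,y) w.r.t. a rotated ellipse;
# value <= 1 means inside
ellipse_q <- function(x, y, center, semi_axes, angle) {
  dxp <- x - center[1]; dyp <- y - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * dxp + sa * dyp
  v <- -sa * dxp + ca * dyp
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2
}

# points on an ellipse boundary (for containment / separation tests)
ellipse_boundary <- function(center, semi_axes, angle, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  u <- semi_axes[1] * cos(th); v <- semi_axes[2] * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1] + ca * u - sa * v, center[2] + sa * u + ca * v)
}

# TRUE if ellipse A lies entirely inside ellipse B (boundary sampling)
ellipse_inside <- function(A, B, margin = 0) {
  pts <- ellipse_boundary(A$center, A$semi_axes + margin, A$angle)
  all(ellipse_q(pts[, 1], pts[, 2], B$center, B$semi_axes, B$angle) <= 1)
}

# TRUE if two ellipses overlap or touch (boundary sampling + center checks)
ellipses_overlap <- function(A, B, margin = 0) {
  if (ellipse_q(A$center[1], A$center[2], B$center, B$semi_axes, B$angle) <= 1)
    return(TRUE)
  if (ellipse_q(B$center[1], B$center[2], A$center, A$semi_axes, A$angle) <= 1)
    return(TRUE)
  pa <- ellipse_boundary(A$center, A$semi_axes + margin, A$angle)
  if (any(ellipse_q(pa[, 1], pa[, 2], B$center, B$semi_axes, B$angle) <= 1))
    return(TRUE)
  pb <- ellipse_boundary(B$center, B$semi_axes + margin, B$angle)
  any(ellipse_q(pb[, 1], pb[, 2], A$center, A$semi_axes, A$angle) <= 1)
}

#' Paint a rotated ellipse onto a dielectric map
#'
#' Cells whose centers fall inside the ellipse take the lesion's dielectric
#' values; all other cells are unchanged.
#'
#' @param map A [dielectric_map()].
#' @param lesion A [lesion_spec()].
#' @param grid The grid the map was built on (for cell-center coordinates).
#' @return The updated `dielectric_map`.
#' @export
rasterize_ellipse <- function(map, lesion, grid) {
  if (any(lesion$semi_axes <= 0)) stop("ellipse semi-axes must be positive")
  co <- grid_coords(grid)
  inside <- ellipse_q(co$X, co$Y, lesion$center, lesion$semi_axes,
                      lesion$angle) <= 1
  map$eps_r[inside] <- lesion$eps_r
  map$sigma[inside] <- lesion$sigma
  map
}

#' Generate a randomized dielectric head phantom
#'
#' Builds a two-layer head (skull shell around a brain interior, both ellipses
#' after random rotation, per-axis deformation and global scaling of a base
#' circle) immersed in the coupling medium, then places `class_label`
#' non-overlapping elliptical hemorrhages fully inside the brain by rejection
#' sampling.  Deterministic given the configuration (including its seed).
#'
#' @param cfg A [phantom_config()].
#' @return List with `map` (a [dielectric_map()]) and `lesions`
#'   (list of [lesion_spec()], length `cfg$class_label`).
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    grid <- cfg$grid
    cm <- coupling_medium()
    n <- grid$n
    eps <- matrix(cm[["eps_r"]], n, n)
    sig <- matrix(cm[["sigma"]], n, n)

    r0 <- runif(1, cfg$head_radius_range[1], cfg$head_radius_range[2])
    rot <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
    def <- runif(2, cfg$deform_range[1], cfg$deform_range[2])
    gsc <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
    head_ax <- r0 * def * gsc
    brain_ax <- pmax(head_ax - cfg$skull_thickness, 0.01)
    head_el <- list(center = c(0, 0), semi_axes = head_ax, angle = rot)
    brain_el <- list(center = c(0, 0), semi_axes = brain_ax, angle = rot)

    co <- grid_coords(grid)
    q_head <- ellipse_q(co$X, co$Y, head_el$center, head_el$semi_axes, head_el$angle)
    q_brain <- ellipse_q(co$X, co$Y, brain_el$center, brain_el$semi_axes, brain_el$angle)
    in_head <- q_head <= 1
    in_brain <- q_brain <= 1
    tt <- cfg$tissue_table
    eps[in_head] <- tt$skull[["eps_r"]]; sig[in_head] <- tt$skull[["sigma"]]
    eps[in_brain] <- tt$brain[["eps_r"]]; sig[in_brain] <- tt$brain[["sigma"]]

    lesions <- list()
    if (cfg$class_label > 0) {
      attempts <- 0L
      while (length(lesions) < cfg$class_label) {
        attempts <- attempts + 1L
        if (attempts > cfg$max_attempts)
          stop(sprintf("could not place %d non-overlapping lesions in %d attempts",
                       cfg$class_label, cfg$max_attempts))
        ax <- runif(2, cfg$lesion_semi_axis_range[1], cfg$lesion_semi_axis_range[2])
        ang <- runif(1, 0, 2 * pi)
        # center uniform over the brain bounding box, then containment check
        rmax <- max(brain_ax)
        ctr <- runif(2, -rmax, rmax)
        cand <- lesion_spec(ctr, ax, ang,
                            eps_r = tt$blood[["eps_r"]], sigma = tt$blood[["sigma"]])
        if (!ellipse_inside(cand, brain_el)) next
        if (length(lesions) > 0 &&
            ellipses_overlap(cand, lesions[[1]], margin = 1e-3)) next
        lesions <- c(lesions, list(cand))
      }
    }

    map <- dielectric_map(eps, sig, grid$dx, grid$origin, in_brain)
    for (les in lesions) map <- rasterize_ellipse(map, les, grid)
    list(map = map, lesions = lesions)
  })
}

#' Validate dielectric-map invariants
#'
#' Checks that permittivity/conductivity are physically admissible, that all
#' grids share dimensions, and that cells outside the head carry exactly the
#' coupling-medium values.
#'
#' @param map A [dielectric_map()].
#' @param head_mask Optional logical matrix marking head cells; when `NULL`,
#'   any cell differing from the coupling medium is taken as head, so only the
#'   admissibility and shape invariants are checked.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_dielectric_map <- function(map, head_mask = NULL) {
  stopifnot(inherits(map, "dielectric_map"))
  cm <- coupling_medium()
  if (any(map$eps_r < 1) || any(map$sigma < 0))
    stop("dielectric map fails admissibility (eps_r >= 1, sigma >= 0)")
  if (!all(dim(map$eps_r) == dim(map$sigma)) ||
      !all(dim(map$eps_r) == dim(map$mask_brain)))
    stop("grid dimension mismatch")
  if (!is.null(head_mask)) {
    out <- !head_mask
    if (any(map$eps_r[out] != cm[["eps_r"]]) || any(map$sigma[out] != cm[["sigma"]]))
      stop("cells outside the head must equal the coupling medium exactly")
  }
  invisible(TRUE)
}
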