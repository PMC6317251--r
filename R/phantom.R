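#' Specify a synthetic thoracic phantom
#'
#' Describes a simplified axial thorax used to exercise the whole pipeline
#' with known ground truth: low-intensity background air, a high-intensity
#' elliptical body, two low-intensity lung fields inside the body, a thin
#' high-intensity scanner-bed slab separated from the body by an air gap, and
#' optional spherical soft-tissue lesions. Geometry is given as fractions of
#' the slice shape so one spec scales to any resolution.
#'
#' @param n_slices Number of axial slices.
#' @param shape Slice shape `c(rows, cols)`; the conventional CT matrix is
#'   512 x 512.
#' @param body_center,body_semiaxes Body ellipse center / semi-axes as
#'   fractions of `(rows, cols)`.
#' @param lung_centers 2 x 2 matrix of lung ellipse centers (fractions),
#'   one row per lung.
#' @param lung_semiaxes 2 x 2 matrix of lung semi-axes (fractions).
#' @param lung_taper Coefficient in `[0, 1)` shrinking the lung cross-section
#'   towards the first and last slice (`0` = cylindrical lungs).
#' @param bed Named list `list(rows = c(top, bottom), cols = c(left, right))`
#'   as fractions; the bed must be separated from the body by at least one
#'   background row. `NULL` drops the bed.
#' @param lesions List of lesions, each
#'   `list(center = c(row, col, slice) fractions, radius = fraction of rows,
#'   intensity = HU)`; spherical in voxel units.
#' @param tissue_intensities Named HU vector for `air`, `parenchyma`, `body`,
#'   `bed`, `lesion`.
#' @param noise_sigma Additive Gaussian noise standard deviation in HU.
#' @param seed Integer seed for the noise field.
#' @return A `phantom_spec` object.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(n_slices = 20,
                         shape = c(512, 512),
                         body_center = c(0.50, 0.50),
                         body_semiaxes = c(0.40, 0.46),
                         lung_centers = rbind(c(0.48, 0.28), c(0.48, 0.72)),
                         lung_semiaxes = rbind(c(0.24, 0.12), c(0.24, 0.12)),
                         lung_taper = 0.3,
                         bed = list(rows = c(0.93, 0.96), cols = c(0.10, 0.90)),
                         lesions = list(),
                         tissue_intensities = c(air = -1000, parenchyma = -850,
                                                body = 40, bed = 100,
                                                lesion = 30),
                         noise_sigma = 20,
                         seed = 1L) {
  spec <- structure(
    list(n_slices = as.integer(n_slices), shape = as.integer(shape),
         body_center = body_center, body_semiaxes = body_semiaxes,
         lung_centers = rbind(lung_centers), lung_semiaxes = rbind(lung_semiaxes),
         lung_taper = lung_taper, bed = bed, lesions = lesions,
         tissue_intensities = tissue_intensities,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$n_slices < 1) stop("n_slices must be positive")
  if (any(spec$shape < 32)) stop("slice shape too small")
  need <- c("air", "parenchyma", "body", "bed", "lesion")
  if (!all(need %in% names(spec$tissue_intensities)))
    stop("tissue_intensities must name: ", paste(need, collapse = ", "))
  if (spec$lung_taper < 0 || spec$lung_taper >= 1)
    stop("lung_taper must be in [0, 1)")
  # lungs strictly inside the body ellipse: check a dense boundary sample
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  for (l in 1:nrow(spec$lung_centers)) {
    br <- spec$lung_centers[l, 1] + spec$lung_semiaxes[l, 1] * cos(th)
    bc <- spec$lung_centers[l, 2] + spec$lung_semiaxes[l, 2] * sin(th)
    inside <- ((br - spec$body_center[1]) / spec$body_semiaxes[1])^2 +
      ((bc - spec$body_center[2]) / spec$body_semiaxes[2])^2
    if (any(inside >= 1))
      stop("lung ellipse ", l, " is not strictly inside the body ellipse")
  }
  if (!is.null(spec$bed)) {
    body_bottom <- spec$body_center[1] + spec$body_semiaxes[1]
    gap_rows <- floor(spec$bed$rows[1] * spec$shape[1]) -
      ceiling(body_bottom * spec$shape[1])
    if (gap_rows < 1)
      stop("bed must be separated from the body by >= 1 background row")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Thoracic phantom spec: %d slices of %d x %d\n",
              x$n_slices, x$shape[1], x$shape[2]))
  cat(sprintf("  %d lesion(s), noise sigma %.1f HU, seed %d\n",
              length(x$lesions), x$noise_sigma, x$seed))
  invisible(x)
}

# Pixel-center coordinate grids as fractions of the slice shape.
frac_grid <- function(shape) {
  list(r = (seq_len(shape[1]) - 0.5) / shape[1],
       c = (seq_len(shape[2]) - 0.5) / shape[2])
}

ellipse_mask <- function(shape, center, semiaxes) {
  g <- frac_grid(shape)
  u <- (g$r - center[1]) / semiaxes[1]
  v <- (g$c - center[2]) / semiaxes[2]
  outer(u^2, v^2, `+`) < 1
}

#' Generate a synthetic thoracic phantom
#'
#' Rasterizes a [phantom_spec] into a CT-like volume with analytic ground
#' truth. A voxel belongs to a structure when its center lies inside the
#' corresponding ellipse/sphere. The parenchyma ground truth is the lung
#' interiors minus all lesion voxels; the generated volume and masks are
#' deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec].
#' @return A `labeled_volume`: list with `volume` ([ct_volume]),
#'   `gt_parenchyma` and `gt_lesions` (logical arrays), and `spec`.
#' @examples
#' lv <- generate_phantom(phantom_spec(n_slices = 2, shape = c(64, 64),
#'                                     noise_sigma = 0))
#' sum(lv$gt_parenchyma)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  shape <- spec$shape
  ns <- spec$n_slices
  ti <- spec$tissue_intensities
  vol <- array(ti[["air"]], c(shape, ns))
  gt_lung <- array(FALSE, c(shape, ns))
  gt_les <- array(FALSE, c(shape, ns))

  body <- ellipse_mask(shape, spec$body_center, spec$body_semiaxes)
  # mild apex/base tapering of the lung cross-section
  u <- if (ns > 1) 2 * (seq_len(ns) - 1) / (ns - 1) - 1 else 0
  taper <- sqrt(1 - spec$lung_taper * u^2)

  for (s in seq_len(ns)) {
    sl <- matrix(ti[["air"]], shape[1], shape[2])
    sl[body] <- ti[["body"]]
    lung_s <- matrix(FALSE, shape[1], shape[2])
    for (l in 1:nrow(spec$lung_centers)) {
      lm <- ellipse_mask(shape, spec$lung_centers[l, ],
                         spec$lung_semiaxes[l, ] * taper[s])
      lung_s <- lung_s | lm
    }
    sl[lung_s] <- ti[["parenchyma"]]
    gt_lung[, , s] <- lung_s
    vol[, , s] <- sl
  }

  if (!is.null(spec$bed)) {
    rows <- max(1, floor(spec$bed$rows[1] * shape[1])):
      min(shape[1], ceiling(spec$bed$rows[2] * shape[1]))
    cols <- max(1, floor(spec$bed$cols[1] * shape[2])):
      min(shape[2], ceiling(spec$bed$cols[2] * shape[2]))
    bed_slab <- vol[rows, cols, , drop = FALSE]
    bed_slab[bed_slab == ti[["air"]]] <- ti[["bed"]]
    vol[rows, cols, ] <- bed_slab
  }

  if (length(spec$lesions) > 0) {
    g <- frac_grid(shape)
    sfrac <- if (ns > 1) (seq_len(ns) - 0.5) / ns else 0.5
    for (les in spec$lesions) {
      ctr <- les$center
      rad <- les$radius
      inten <- if (!is.null(les$intensity)) les$intensity else ti[["lesion"]]
      # sphere in voxel units: radius given as fraction of rows
      dr2 <- ((g$r - ctr[1]) * shape[1])^2
      dc2 <- ((g$c - ctr[2]) * shape[2])^2
      ds2 <- ((sfrac - ctr[3]) * ns)^2
      rad_vox2 <- (rad * shape[1])^2
      for (s in seq_len(ns)) {
        rem <- rad_vox2 - ds2[s]
        if (rem <= 0) next
        lm <- outer(dr2, dc2, `+`) < rem
        if (!any(lm)) next
        sl <- vol[, , s]
        sl[lm] <- inten
        vol[, , s] <- sl
        gt_les[, , s] <- gt_les[, , s] | lm
      }
    }
  }

  gt_par <- gt_lung & !gt_les

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sigma),
                       dim(vol))
  }

  structure(list(volume = ct_volume(vol),
                 gt_parenchyma = gt_par,
                 gt_lesions = gt_les,
                 spec = spec),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  print(x$volume)
  cat(sprintf("  ground truth: %d parenchyma voxels, %d lesion voxels\n",
              sum(x$gt_parenchyma), sum(x$gt_lesions)))
  invisible(x)
}

#' Serialize / restore a phantom spec as YAML
#'
#' @param spec A [phantom_spec].
#' @param path YAML file path.
#' @return `read_phantom_spec()` returns a [phantom_spec];
#'   `write_phantom_spec()` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$lung_centers <- as.data.frame(x$lung_centers)
  x$lung_semiaxes <- as.data.frame(x$lung_semiaxes)
  x$tissue_intensities <- as.list(x$tissue_intensities)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(n_slices = x$n_slices, shape = unlist(x$shape),
               body_center = unlist(x$body_center),
               body_semiaxes = unlist(x$body_semiaxes),
               lung_centers = as.matrix(as.data.frame(x$lung_centers)),
               lung_semiaxes = as.matrix(as.data.frame(x$lung_semiaxes)),
               lung_taper = x$lung_taper,
               bed = x$bed,
               lesions = lapply(x$lesions, function(l)
                 list(center = unlist(l$center), radius = l$radius,
                      intensity = l$intensity)),
               tissue_intensities = unlist(x$tissue_intensities),
               noise_sigma = x$noise_sigma, seed = x$seed)
}
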