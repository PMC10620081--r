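#' @importFrom stats approx median sd setNames rnorm runif
#' @importFrom utils head tail write.csv read.csv
NULL

# Parcel codes used throughout: 0 = none, 1 = Ant, 2 = Mid, 3 = Post
PARCEL_LEVELS <- c(none = 0L, Ant = 1L, Mid = 2L, Post = 3L)

#' Construct a voxel phantom
#'
#' Low-level constructor for a labeled voxel volume with a tissue
#' conductivity table. Most users will call
#' [make_layered_sphere_phantom()] instead.
#'
#' @param labels integer 3D array of tissue ids; 0 marks non-conducting
#'   background.
#' @param spacing voxel edge length(s) in mm; scalar or length-3.
#' @param tissue_table data.frame with columns `id`, `name`, `sigma`
#'   (conductivity, S/m) covering every non-zero label.
#' @param origin world coordinate (mm) of the center of voxel `[1,1,1]`.
#'   Defaults to centering the grid on the world origin.
#' @param orientation optional 4D array `c(dim(labels), 3)` of per-voxel
#'   unit direction vectors.
#' @param geometry optional list describing analytic geometry (used by
#'   electrode placement on spherical phantoms).
#' @return An object of class `ti_phantom`: a list with fields `dim`,
#'   `spacing`, `origin`, `labels`, `tissue_table`, `orientation`,
#'   `parcels`, `centerline`, `target_label`, `geometry`.
#' @export
phantom <- function(labels, spacing, tissue_table, origin = NULL,
                    orientation = NULL, geometry = NULL) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  dm <- dim(labels)
  if (is.null(origin)) origin <- -(dm - 1) * spacing / 2
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  if (!all(ids %in% tissue_table$id))
    stop("every non-zero label must appear in tissue_table$id")
  if (any(tissue_table$sigma <= 0))
    stop("tissue conductivities must be > 0")
  structure(list(
    dim = dm, spacing = as.numeric(spacing), origin = as.numeric(origin),
    labels = labels, tissue_table = tissue_table,
    orientation = orientation, parcels = NULL,
    centerline = NULL, target_label = NULL, geometry = geometry
  ), class = "ti_phantom")
}

#' Default five-tissue conductivity table
#'
#' Scalp 0.4, compact skull 0.008, CSF 1.79, gray matter 0.28 and white
#' matter 0.13 S/m; values taken from the head-conductivity meta-analysis
#' literature and exposed as configuration defaults.
#'
#' @return data.frame with columns `id`, `name`, `sigma`.
#' @export
default_tissue_table <- function() {
  data.frame(
    id = 1:5,
    name = c("scalp", "skull", "csf", "gray", "white"),
    sigma = c(0.4, 0.008, 1.79, 0.28, 0.13),
    stringsAsFactors = FALSE
  )
}

# Per-axis world coordinates of voxel centers
axis_coords <- function(ph) {
  lapply(1:3, function(a) ph$origin[a] + (seq_len(ph$dim[a]) - 1) * ph$spacing[a])
}

# Full X/Y/Z coordinate arrays (mm), same dim as labels
coord_arrays <- function(ph) {
  ax <- axis_coords(ph)
  d <- ph$dim
  list(
    x = array(rep(ax[[1]], times = d[2] * d[3]), d),
    y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
    z = array(rep(ax[[3]], each = d[1] * d[2]), d)
  )
}

voxel_volume_mm3 <- function(ph) prod(ph$spacing)

#' Generate a layered spherical head phantom
#'
#' Builds concentric spherical shells (outermost first) on a regular voxel
#' grid, the synthetic stand-in for an anatomical head model. With five
#' radii the shells are labeled scalp, skull, CSF, gray and white matter
#' from the outside in; voxels outside the outermost radius are
#' non-conducting background.
#'
#' @param radii shell outer radii in mm, strictly decreasing.
#' @param conductivities per-shell conductivity in S/m, same length as
#'   `radii`. Defaults to the five-tissue table when 5 shells are asked for.
#' @param resolution voxel edge length in mm.
#' @param names optional tissue names, same length as `radii`.
#' @param margin_voxels background padding around the outer shell.
#' @return A [phantom()] with `geometry$type == "layered_sphere"`.
#' @examples
#' ph <- make_layered_sphere_phantom(radii = c(40, 36), conductivities = c(0.4, 0.3),
#'                                   resolution = 4)
#' table(ph$labels)
#' @export
make_layered_sphere_phantom <- function(radii,
                                        conductivities = NULL,
                                        resolution = 2,
                                        names = NULL,
                                        margin_voxels = 2L) {
  if (resolution <= 0) stop("resolution must be > 0")
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (is.null(conductivities)) {
    if (length(radii) == 5L) conductivities <- default_tissue_table()$sigma
    else stop("conductivities must be given unless 5 shells are requested")
  }
  if (length(conductivities) != length(radii))
    stop("radii and conductivities must have the same length")
  if (is.null(names)) {
    names <- if (length(radii) == 5L) default_tissue_table()$name
             else paste0("shell", seq_along(radii))
  }
  n_half <- ceiling(radii[1] / resolution) + margin_voxels
  n <- 2L * n_half  # even count, grid centered on the origin
  dm <- c(n, n, n)
  origin <- -(dm - 1) * resolution / 2
  ax <- origin[1] + (seq_len(n) - 1) * resolution
  x2 <- ax^2
  r2 <- outer(outer(x2, x2, `+`), x2, `+`)
  labels <- array(0L, dm)
  # label = count of shell radii enclosing the voxel (radii decreasing)
  for (j in seq_along(radii)) labels[r2 <= radii[j]^2] <- j
  tt <- data.frame(id = seq_along(radii), name = names,
                   sigma = conductivities, stringsAsFactors = FALSE)
  phantom(labels, resolution, tt,
          origin = origin,
          geometry = list(type = "layered_sphere", radii = radii,
                          center = c(0, 0, 0)))
}

# Resample a polyline (control points, n x 3 mm) to dense points at
# roughly `step` mm spacing; returns list(points, tangents, s = arc length)
resample_polyline <- function(points, step) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("centerline must contain at least one point")
  if (nrow(points) == 1L)
    return(list(points = points, tangents = matrix(c(0, 1, 0), 1), s = 0))
  seg <- sqrt(rowSums(diff(points)^2))
  s_ctrl <- c(0, cumsum(seg))
  L <- s_ctrl[length(s_ctrl)]
  s <- seq(0, L, length.out = max(2L, ceiling(L / step) + 1L))
  dense <- sapply(1:3, function(k) approx(s_ctrl, points[, k], xout = s)$y)
  tg <- apply(dense, 2, function(v) c(diff(v), NA))
  tg[nrow(tg), ] <- tg[nrow(tg) - 1L, ]
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = dense, tangents = tg, s = s)
}

# Index of nearest dense centerline point for each row of `xyz` (m x 3).
# Loops over the (few hundred) centerline points, vectorized over voxels.
nearest_centerline_index <- function(xyz, dense) {
  m <- nrow(xyz)
  best_d2 <- rep(Inf, m)
  best_i <- rep(1L, m)
  for (i in seq_len(nrow(dense))) {
    d2 <- (xyz[, 1] - dense[i, 1])^2 + (xyz[, 2] - dense[i, 2])^2 +
      (xyz[, 3] - dense[i, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  list(index = best_i, dist = sqrt(best_d2))
}

#' Embed a tubular deep target in a phantom
#'
#' Adds a tube of given radius around a (possibly curved) centerline as a
#' new tissue label, overwriting brain voxels (gray/white matter) only.
#' This is the synthetic stand-in for a deep structure such as the
#' hippocampus; by convention its long axis runs along +y and the +y end
#' is "anterior".
#'
#' @param ph a [phantom()].
#' @param centerline matrix of 3D control points (mm), ordered
#'   anterior-to-posterior or posterior-to-anterior.
#' @param radius tube radius in mm.
#' @param label integer id for the new tissue (default 100).
#' @param sigma target conductivity; defaults to gray matter's.
#' @param name tissue name.
#' @return The phantom with the target embedded and the resampled
#'   centerline stored for later parcellation and orientation fields.
#' @export
embed_target <- function(ph, centerline, radius, label = 100L,
                         sigma = NULL, name = "target") {
  stopifnot(inherits(ph, "ti_phantom"))
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L) stop("centerline needs at least 2 control points")
  if (radius <= 0) stop("radius must be > 0")
  brain_ids <- ph$tissue_table$id[ph$tissue_table$name %in% c("gray", "white")]
  if (length(brain_ids) == 0L)  # generic phantom: innermost shell is "brain"
    brain_ids <- max(ph$tissue_table$id)
  cl <- resample_polyline(centerline, min(ph$spacing) / 2)
  # the whole tube must stay inside brain tissue
  co <- coord_arrays(ph)
  lo <- apply(cl$points, 2, min) - radius - max(ph$spacing)
  hi <- apply(cl$points, 2, max) + radius + max(ph$spacing)
  box <- co$x >= lo[1] & co$x <= hi[1] & co$y >= lo[2] & co$y <= hi[2] &
    co$z >= lo[3] & co$z <= hi[3]
  idx <- which(box)
  xyz <- cbind(co$x[idx], co$y[idx], co$z[idx])
  nn <- nearest_centerline_index(xyz, cl$points)
  inside <- nn$dist <= radius
  # flat end caps: drop voxels whose nearest point is an endpoint and
  # whose axial offset overshoots the centerline (capsule -> cylinder)
  np <- nrow(cl$points)
  first <- inside & nn$index == 1L
  if (any(first)) {
    t0 <- (xyz[first, , drop = FALSE] -
             matrix(cl$points[1, ], sum(first), 3, byrow = TRUE)) %*% cl$tangents[1, ]
    inside[which(first)[t0 < 0]] <- FALSE
  }
  last <- inside & nn$index == np
  if (any(last)) {
    t1 <- (xyz[last, , drop = FALSE] -
             matrix(cl$points[np, ], sum(last), 3, byrow = TRUE)) %*% cl$tangents[np, ]
    inside[which(last)[t1 > 0]] <- FALSE
  }
  tube_idx <- idx[inside]
  if (any(!(ph$labels[tube_idx] %in% brain_ids)))
    stop("centerline tube exits the brain compartment")
  if (is.null(sigma)) {
    g <- ph$tissue_table$sigma[ph$tissue_table$name == "gray"]
    sigma <- if (length(g)) g[1] else ph$tissue_table$sigma[nrow(ph$tissue_table)]
  }
  ph$labels[tube_idx] <- as.integer(label)
  ph$tissue_table <- rbind(ph$tissue_table,
                           data.frame(id = as.integer(label), name = name,
                                      sigma = sigma, stringsAsFactors = FALSE))
  ph$centerline <- cl
  ph$target_label <- as.integer(label)
  ph
}

#' Split the target into anterior/middle/posterior thirds
#'
#' Assigns each target voxel to the Ant, Mid or Post parcel by arc-length
#' thirds along the centerline used to embed it, measured from the
#' anterior (+y) end.
#'
#' @param ph phantom with an embedded target.
#' @param label target label (defaults to the stored one).
#' @return The phantom with a `parcels` array (0 none, 1 Ant, 2 Mid, 3 Post).
#' @export
parcellate_target <- function(ph, label = ph$target_label) {
  stopifnot(inherits(ph, "ti_phantom"))
  if (is.null(label) || !any(ph$labels == label))
    stop("target label absent from phantom")
  if (is.null(ph$centerline))
    stop("phantom has no stored centerline; embed the target first")
  cl <- ph$centerline
  s <- cl$s
  # measure arc length from the anterior (+y) end
  n <- nrow(cl$points)
  if (cl$points[1, 2] < cl$points[n, 2]) s <- max(s) - s
  idx <- which(ph$labels == label)
  co <- coord_arrays(ph)
  xyz <- cbind(co$x[idx], co$y[idx], co$z[idx])
  nn <- nearest_centerline_index(xyz, cl$points)
  sv <- s[nn$index]
  L <- max(cl$s)
  pk <- ifelse(sv <= L / 3, PARCEL_LEVELS[["Ant"]],
               ifelse(sv <= 2 * L / 3, PARCEL_LEVELS[["Mid"]],
                      PARCEL_LEVELS[["Post"]]))
  parcels <- array(0L, ph$dim)
  parcels[idx] <- as.integer(pk)
  ph$parcels <- parcels
  ph
}

#' Attach a per-voxel orientation field
#'
#' Assigns a unit direction vector (the local principal structure
#' direction n, the synthetic stand-in for a DTI-derived principal axis)
#' to every conducting voxel.
#'
#' @param ph a phantom.
#' @param mode `"along_target_axis"` (tangent of the nearest centerline
#'   point, requires an embedded target), `"uniform"` (constant vector) or
#'   `"radial"` (away from the phantom center).
#' @param vector unit vector for `mode = "uniform"`.
#' @return The phantom with an `orientation` array of dim `c(dim, 3)`.
#' @export
make_orientation_field <- function(ph,
                                   mode = c("along_target_axis", "uniform", "radial"),
                                   vector = c(1, 0, 0)) {
  stopifnot(inherits(ph, "ti_phantom"))
  mode <- match.arg(mode)
  idx <- which(ph$labels > 0L)
  orient <- array(NA_real_, c(ph$dim, 3L))
  n <- length(idx)
  nvox <- prod(ph$dim)
  if (mode == "uniform") {
    v <- vector / sqrt(sum(vector^2))
    for (k in 1:3) orient[idx + (k - 1L) * nvox] <- v[k]
  } else if (mode == "radial") {
    co <- coord_arrays(ph)
    ctr <- if (!is.null(ph$geometry$center)) ph$geometry$center else c(0, 0, 0)
    vx <- co$x[idx] - ctr[1]; vy <- co$y[idx] - ctr[2]; vz <- co$z[idx] - ctr[3]
    nr <- sqrt(vx^2 + vy^2 + vz^2)
    deg <- nr < .Machine$double.eps
    vx[deg] <- 1; vy[deg] <- 0; vz[deg] <- 0; nr[deg] <- 1
    orient[idx] <- vx / nr
    orient[idx + nvox] <- vy / nr
    orient[idx + 2L * nvox] <- vz / nr
  } else {
    if (is.null(ph$centerline))
      stop("mode 'along_target_axis' requires an embedded target")
    co <- coord_arrays(ph)
    xyz <- cbind(co$x[idx], co$y[idx], co$z[idx])
    nn <- nearest_centerline_index(xyz, ph$centerline$points)
    tg <- ph$centerline$tangents[nn$index, , drop = FALSE]
    orient[idx] <- tg[, 1]
    orient[idx + nvox] <- tg[, 2]
    orient[idx + 2L * nvox] <- tg[, 3]
  }
  ph$orientation <- orient
  ph
}

#' @export
print.ti_phantom <- function(x, ...) {
  cat("ti_phantom:", paste(x$dim, collapse = " x "), "voxels @",
      paste(signif(x$spacing, 3), collapse = "/"), "mm\n")
  counts <- table(factor(x$labels[x$labels > 0L], levels = x$tissue_table$id))
  tt <- x$tissue_table
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-8s id=%-4d sigma=%.3g S/m  %d voxels\n",
                tt$name[i], tt$id[i], tt$sigma[i],
                as.integer(counts[as.character(tt$id[i])])))
  if (!is.null(x$parcels)) {
    pc <- table(factor(x$parcels[x$parcels > 0L], levels = 1:3))
    cat("  parcels Ant/Mid/Post:", paste(as.integer(pc), collapse = "/"), "\n")
  }
  if (!is.null(x$orientation)) cat("  orientation field: present\n")
  invisible(x)
}
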