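# TI exposure metrics: projected envelope-modulation and absolute
# amplitude maps, current-ratio steering, ROI summaries.

dot3 <- function(V, n) {
  if (is.null(dim(V))) V <- matrix(V, 1)
  if (is.null(dim(n))) n <- matrix(n, nrow(V), 3, byrow = TRUE)
  rowSums(V * n)
}

check_unit <- function(n, tol = 1e-6) {
  if (is.null(dim(n))) n <- matrix(n, 1)
  nrm <- sqrt(rowSums(n^2))
  if (any(abs(nrm - 1) > tol))
    stop("orientation vector(s) not unit norm")
  invisible(TRUE)
}

#' Projected TI envelope-modulation amplitude
#'
#' For two fields oscillating at nearby carrier frequencies, the
#' amplitude of the beat-frequency envelope modulation of their
#' superposition, projected along the local structure direction `n`:
#' `||(E1 + E2) . n| - |(E1 - E2) . n||`, which equals
#' `2 * min(|E1 . n|, |E2 . n|)`.
#'
#' @param E1,E2 3-vectors (or m x 3 matrices) of per-pair field
#'   amplitudes, V/m.
#' @param n unit direction vector(s).
#' @return envelope-modulation amplitude(s), V/m.
#' @examples
#' projected_envelope_amplitude(c(3, 0, 0), c(1, 0, 0), c(1, 0, 0))  # 2
#' @export
projected_envelope_amplitude <- function(E1, E2, n) {
  check_unit(n)
  p1 <- dot3(E1, n); p2 <- dot3(E2, n)
  abs(abs(p1 + p2) - abs(p1 - p2))
}

#' Projected absolute amplitude
#'
#' Peak of the summed two-frequency projected field over one beat cycle:
#' `|E1 . n| + |E2 . n|`.
#'
#' @inheritParams projected_envelope_amplitude
#' @return absolute amplitude(s), V/m.
#' @export
projected_absolute_amplitude <- function(E1, E2, n) {
  check_unit(n)
  abs(dot3(E1, n)) + abs(dot3(E2, n))
}

#' Per-voxel TI exposure maps
#'
#' Combines the two unit-current pair solutions, scaled by the applied
#' currents, into the envelope-modulation amplitude map (`eam`) and the
#' absolute-amplitude map (`eabs`), both projected on the phantom's
#' orientation field.
#'
#' @param sol1,sol2 pair solutions normalized to 1 mA
#'   (see [normalize_to_current()]).
#' @param I1,I2 applied currents per pair, mA.
#' @param ph phantom carrying the orientation field.
#' @return Object of class `ti_exposure`: `eam`, `eabs` (arrays, V/m; NA
#'   outside the oriented voxels), `currents_mA`, grid metadata.
#' @export
exposure_maps <- function(sol1, sol2, I1, I2, ph) {
  stopifnot(inherits(sol1, "ti_field"), inherits(sol2, "ti_field"))
  if (!identical(sol1$dim, sol2$dim) || !identical(ph$dim, sol1$dim))
    stop("solutions and phantom are on different grids")
  if (is.null(ph$orientation)) stop("phantom has no orientation field")
  if (I1 < 0 || I2 < 0) stop("currents must be >= 0")
  dm <- ph$dim
  nvox <- prod(dm)
  idx <- which(!is.na(ph$orientation[seq_len(nvox)]))
  nx <- ph$orientation[idx]; nyv <- ph$orientation[idx + nvox]
  nz <- ph$orientation[idx + 2L * nvox]
  p1 <- I1 * (sol1$E[idx] * nx + sol1$E[idx + nvox] * nyv +
                sol1$E[idx + 2L * nvox] * nz)
  p2 <- I2 * (sol2$E[idx] * nx + sol2$E[idx + nvox] * nyv +
                sol2$E[idx + 2L * nvox] * nz)
  eam <- array(NA_real_, dm); eabs <- array(NA_real_, dm)
  eam[idx] <- abs(abs(p1 + p2) - abs(p1 - p2))
  eabs[idx] <- abs(p1) + abs(p2)
  structure(list(eam = eam, eabs = eabs, currents_mA = c(I1, I2),
                 dim = dm, spacing = ph$spacing, origin = ph$origin),
            class = "ti_exposure")
}

#' Location of the envelope-modulation peak
#'
#' Voxel indices of the maximum of the `eam` map. Ties are broken
#' deterministically by the lowest linear voxel index.
#'
#' @param exp_map a [exposure_maps()] result.
#' @param mask optional logical array restricting the search (e.g. brain
#'   voxels only; by default all mapped voxels compete).
#' @return integer triple of voxel indices.
#' @export
eam_peak <- function(exp_map, mask = NULL) {
  v <- exp_map$eam
  if (!is.null(mask)) v[!mask] <- NA
  v[is.na(v)] <- -Inf
  arrayInd(which.max(v), exp_map$dim)[1, ]
}

#' ROI summary statistics of an exposure map
#'
#' @param map 3D array (e.g. `$eam` of an exposure).
#' @param roi_masks named list of logical arrays on the same grid.
#' @param normalization `"none"`, `"to_target_median"` (divide medians by
#'   the target ROI's median, which then reports exactly 1) or
#'   `"fraction_of_subregion_sum"` (each ROI's median divided by the sum
#'   of the listed ROIs' medians; fractions sum to 1).
#' @param target name of the target ROI for `"to_target_median"`.
#' @return data.frame with columns `roi`, `nvox`, `median`, `sd`,
#'   `normalized`.
#' @export
roi_summary <- function(map, roi_masks,
                        normalization = c("none", "to_target_median",
                                          "fraction_of_subregion_sum"),
                        target = names(roi_masks)[1]) {
  normalization <- match.arg(normalization)
  if (is.null(names(roi_masks)) || any(!nzchar(names(roi_masks))))
    stop("roi_masks must be a named list")
  stats_one <- function(m) {
    if (!any(m)) stop("empty ROI mask")
    v <- map[m]
    v <- v[!is.na(v)]
    if (!length(v)) stop("ROI contains no mapped voxels")
    c(n = sum(m), med = median(v), sd = sd(v))
  }
  st <- t(vapply(roi_masks, stats_one, c(n = 0, med = 0, sd = 0)))
  out <- data.frame(roi = names(roi_masks), nvox = as.integer(st[, "n"]),
                    median = st[, "med"], sd = st[, "sd"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$normalized <- switch(normalization,
    none = out$median,
    to_target_median = {
      tm <- out$median[out$roi == target]
      if (!length(tm)) stop("target ROI not found")
      out$median / tm
    },
    fraction_of_subregion_sum = out$median / sum(out$median)
  )
  out
}

#' Parcel masks of the embedded target
#'
#' @param ph a parcellated phantom (see [parcellate_target()]).
#' @return named list of logical arrays `Ant`, `Mid`, `Post`.
#' @export
target_parcel_masks <- function(ph) {
  if (is.null(ph$parcels)) stop("phantom has no parcels")
  list(Ant = ph$parcels == PARCEL_LEVELS[["Ant"]],
       Mid = ph$parcels == PARCEL_LEVELS[["Mid"]],
       Post = ph$parcels == PARCEL_LEVELS[["Post"]])
}

#' Superficial-cortex ROI under the stimulating electrodes
#'
#' Gray-matter voxels lying within an angular cap beneath each electrode
#' center, the stand-in for the cortex overlying the stimulation site.
#'
#' @param ph spherical phantom; `mt` placed montage.
#' @param cap_deg half-angle of each cap in degrees.
#' @return logical array (union over the four electrodes).
#' @export
superficial_cortex_roi <- function(ph, mt, cap_deg = 25) {
  gray_id <- ph$tissue_table$id[match("gray", ph$tissue_table$name)]
  if (is.na(gray_id)) stop("phantom has no gray-matter tissue")
  ctr <- ph$geometry$center
  co <- coord_arrays(ph)
  gidx <- which(ph$labels == gray_id)
  vx <- co$x[gidx] - ctr[1]; vy <- co$y[gidx] - ctr[2]; vz <- co$z[gidx] - ctr[3]
  nr <- sqrt(vx^2 + vy^2 + vz^2)
  keep <- rep(FALSE, length(gidx))
  cth <- cos(cap_deg * pi / 180)
  el <- mt$electrodes
  for (i in seq_len(nrow(el))) {
    e <- c(el$x[i], el$y[i], el$z[i]) - ctr
    e <- e / sqrt(sum(e^2))
    keep <- keep | ((vx * e[1] + vy * e[2] + vz * e[3]) / nr >= cth)
  }
  out <- array(FALSE, ph$dim)
  out[gidx[keep]] <- TRUE
  out
}

#' Current-ratio steering sweep
#'
#' Recomputes the exposure map for a list of current splits at fixed
#' total current and summarizes how the envelope-modulation amplitude
#' distributes over the target subregions; the stimulation locus shifts
#' toward the electrode pair carrying the smaller current.
#'
#' @param sol1,sol2 1 mA-normalized pair solutions.
#' @param ratios list of `c(I1, I2)` in mA (fixed `I1 + I2` recommended).
#' @param rois named list of target-subregion masks (e.g.
#'   [target_parcel_masks()]).
#' @param ph phantom with orientation field.
#' @param axis axis along the target (2 = y, the long-axis convention)
#'   used for the eam-weighted centroid.
#' @return data.frame: one row per ratio with `I1`, `I2`, one
#'   `frac_<roi>` column per ROI (fractions of the subregion median sum,
#'   summing to 1) and `centroid_mm`, the eam-weighted centroid of the
#'   target along `axis`.
#' @export
steering_sweep <- function(sol1, sol2, ratios, rois, ph, axis = 2L) {
  if (any(vapply(ratios, function(r) any(r < 0), TRUE)))
    stop("negative current in ratio list")
  co <- coord_arrays(ph)
  coord <- switch(axis, co$x, co$y, co$z)
  target_mask <- Reduce(`|`, rois)
  rows <- lapply(ratios, function(r) {
    ex <- exposure_maps(sol1, sol2, r[1], r[2], ph)
    rs <- roi_summary(ex$eam, rois, normalization = "fraction_of_subregion_sum")
    w <- ex$eam[target_mask]
    cen <- sum(coord[target_mask] * w) / sum(w)
    out <- data.frame(I1 = r[1], I2 = r[2], centroid_mm = cen)
    for (k in seq_along(rs$roi)) out[[paste0("frac_", rs$roi[k])]] <- rs$normalized[k]
    out
  })
  do.call(rbind, rows)
}

#' @export
print.ti_exposure <- function(x, ...) {
  cat(sprintf("ti_exposure: I = %s mA; eam max %.4g V/m, eabs max %.4g V/m\n",
              paste(x$currents_mA, collapse = "/"),
              max(x$eam, na.rm = TRUE), max(x$eabs, na.rm = TRUE)))
  invisible(x)
}
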