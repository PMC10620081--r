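#' Construct a two-pair stimulation montage
#'
#' @param electrodes data.frame with columns `label`, `x`, `y`, `z` (mm,
#'   electrode center on the scalp surface), `area_cm2`, and optionally
#'   `plane_z`, `side`, `arc_s_mm` (arc coordinate from the front of the
#'   placement plane).
#' @param pairs list of two length-2 character vectors,
#'   `(anode label, cathode label)` per pair.
#' @param currents_mA per-pair peak-to-baseline amplitudes `c(I1, I2)`.
#' @param freqs_khz per-pair carrier frequencies `c(f1, f2)` in kHz; must
#'   differ so a beat at `delta_f` exists.
#' @return Object of class `ti_montage`.
#' @export
montage <- function(electrodes, pairs, currents_mA = c(1, 1),
                    freqs_khz = c(2.005, 2.0)) {
  if (length(pairs) != 2L) stop("exactly 2 electrode pairs required")
  labs <- unlist(pairs)
  if (!all(labs %in% electrodes$label)) stop("pair labels missing from electrodes")
  if (any(currents_mA < 0)) stop("currents must be >= 0")
  if (length(freqs_khz) != 2L || freqs_khz[1] == freqs_khz[2])
    stop("the two carrier frequencies must differ")
  structure(list(
    electrodes = electrodes, pairs = pairs,
    currents_mA = as.numeric(currents_mA),
    freqs_khz = as.numeric(freqs_khz),
    delta_f_hz = (freqs_khz[1] - freqs_khz[2]) * 1000
  ), class = "ti_montage")
}

#' Hippocampal-targeting electrode placement rule
#'
#' Fractional-circumference offsets for the four electrodes: e1 and e3 sit
#' on the left hemisphere at the nasion plane, at 50% of the
#' half-circumference H minus/plus 2.5 cm (5 cm between centers); e2 and
#' e4 sit on the right hemisphere on a plane above the eyebrow, at
#' 0.2 H - 1 cm and 0.7 H + 1 cm. Pairs are (e1,e2) and (e3,e4).
#'
#' @param plane_z_left,plane_z_right heights (mm) of the two placement
#'   planes; `NULL` for the right plane places it at 35% of the outer
#'   radius above the nasion plane.
#' @param area_cm2 contact area per electrode (cm^2). 2.25 matches the
#'   1.5 cm x 1.5 cm experimental pads, 3.14 the circular simulated ones.
#' @return rule-spec list consumed by [place_electrode_pairs()].
#' @export
default_rule_spec <- function(plane_z_left = 0, plane_z_right = NULL,
                              area_cm2 = 2.25) {
  list(
    electrodes = list(
      list(label = "e1", side = "left",  plane_z = plane_z_left,  frac = 0.5, offset_cm = -2.5),
      list(label = "e3", side = "left",  plane_z = plane_z_left,  frac = 0.5, offset_cm = +2.5),
      list(label = "e2", side = "right", plane_z = plane_z_right, frac = 0.2, offset_cm = -1),
      list(label = "e4", side = "right", plane_z = plane_z_right, frac = 0.7, offset_cm = +1)
    ),
    pairs = list(c("e1", "e2"), c("e3", "e4")),
    area_cm2 = area_cm2
  )
}

#' Mirror-symmetric placement rule
#'
#' Places both electrodes of each plane symmetrically about the 50% arc
#' position, so the whole montage is mirror-symmetric about the coronal
#' (y = 0) plane of a centered spherical phantom. Used for steering
#' validation, where the 1:1 current ratio must put the envelope peak on
#' the symmetry plane.
#'
#' @param delta_left_cm,delta_right_cm half-separations (cm) along the
#'   left and right placement planes.
#' @inheritParams default_rule_spec
#' @return rule-spec list consumed by [place_electrode_pairs()].
#' @export
symmetric_rule_spec <- function(delta_left_cm = 2.5, delta_right_cm = 8,
                                plane_z_left = 0, plane_z_right = NULL,
                                area_cm2 = 2.25) {
  list(
    electrodes = list(
      list(label = "e1", side = "left",  plane_z = plane_z_left,  frac = 0.5, offset_cm = -delta_left_cm),
      list(label = "e3", side = "left",  plane_z = plane_z_left,  frac = 0.5, offset_cm = +delta_left_cm),
      list(label = "e2", side = "right", plane_z = plane_z_right, frac = 0.5, offset_cm = -delta_right_cm),
      list(label = "e4", side = "right", plane_z = plane_z_right, frac = 0.5, offset_cm = +delta_right_cm)
    ),
    pairs = list(c("e1", "e2"), c("e3", "e4")),
    area_cm2 = area_cm2
  )
}

#' Place electrode pairs on a spherical phantom
#'
#' Positions each electrode on the circle cut by its placement plane
#' through the analytic scalp surface, at an arc distance
#' `frac * H + offset` from the frontmost (+y) point of that circle,
#' where H is the half-circumference of the circle. Anterior is +y by
#' convention; "left" is x < 0.
#'
#' @param ph a spherical phantom from [make_layered_sphere_phantom()].
#' @param rule_spec from [default_rule_spec()] or [symmetric_rule_spec()].
#' @param currents_mA,freqs_khz passed to [montage()].
#' @return A [montage()] whose electrode centers lie exactly on the outer
#'   spherical surface.
#' @export
place_electrode_pairs <- function(ph, rule_spec = default_rule_spec(),
                                  currents_mA = c(1, 1),
                                  freqs_khz = c(2.005, 2.0)) {
  stopifnot(inherits(ph, "ti_phantom"))
  if (is.null(ph$geometry) || ph$geometry$type != "layered_sphere")
    stop("rule-based placement requires a spherical phantom with analytic geometry")
  R <- ph$geometry$radii[1]
  ctr <- ph$geometry$center
  rows <- lapply(rule_spec$electrodes, function(e) {
    z <- if (is.null(e$plane_z)) 0.35 * R else e$plane_z
    if (abs(z) >= R) stop("placement plane does not intersect the scalp")
    Rz <- sqrt(R^2 - z^2)
    H <- pi * Rz  # half circumference of the plane's circle, mm
    s <- e$frac * H + e$offset_cm * 10
    if (s < 0 || s > H)
      stop(sprintf("electrode %s: offset exceeds the half circumference", e$label))
    theta <- s / Rz  # angle from the front (+y) point
    sgn <- if (identical(e$side, "left")) -1 else 1
    data.frame(label = e$label,
               x = ctr[1] + sgn * Rz * sin(theta),
               y = ctr[2] + Rz * cos(theta),
               z = ctr[3] + z,
               area_cm2 = rule_spec$area_cm2,
               side = e$side, plane_z = z, arc_s_mm = s,
               stringsAsFactors = FALSE)
  })
  montage(do.call(rbind, rows), rule_spec$pairs, currents_mA, freqs_khz)
}

#' Arc distance between two electrode centers
#'
#' Within a shared placement plane this is the in-plane arc separation;
#' otherwise the great-circle distance on the outer sphere.
#'
#' @param mt a [montage()]; `ph` the phantom it was placed on.
#' @param a,b electrode labels.
#' @return distance in mm.
#' @export
electrode_arc_distance <- function(mt, a, b, ph = NULL) {
  el <- mt$electrodes
  ia <- match(a, el$label); ib <- match(b, el$label)
  if (is.na(ia) || is.na(ib)) stop("unknown electrode label")
  same_plane <- !is.null(el$plane_z) && el$plane_z[ia] == el$plane_z[ib] &&
    el$side[ia] == el$side[ib]
  if (same_plane) return(abs(el$arc_s_mm[ia] - el$arc_s_mm[ib]))
  if (is.null(ph) || is.null(ph$geometry))
    stop("great-circle distance needs the spherical phantom")
  R <- ph$geometry$radii[1]; ctr <- ph$geometry$center
  va <- c(el$x[ia], el$y[ia], el$z[ia]) - ctr
  vb <- c(el$x[ib], el$y[ib], el$z[ib]) - ctr
  ang <- acos(min(1, max(-1, sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)))))
  R * ang
}

#' Paint electrode contact patches into a phantom
#'
#' Marks scalp-surface voxels within each electrode's contact patch with
#' a dedicated label (1000 + electrode index) so the solver can apply
#' Dirichlet conditions there. The patch is the set of outer-surface
#' scalp voxels within the cap radius `sqrt(area / pi)` of the contact
#' center, mirroring a spherical-cap contact of the configured area.
#'
#' @param ph phantom; `mt` a placed [montage()].
#' @return The phantom with electrode labels added and an `electrodes`
#'   field mapping electrode label to tissue id.
#' @export
paint_electrodes <- function(ph, mt) {
  stopifnot(inherits(ph, "ti_phantom"), inherits(mt, "ti_montage"))
  lab <- ph$labels
  scalp_id <- ph$tissue_table$id[match("scalp", ph$tissue_table$name)]
  if (is.na(scalp_id)) scalp_id <- 1L
  # outer-surface scalp voxels: scalp with a 6-neighbor background voxel
  surf <- array(FALSE, ph$dim)
  bg <- lab == 0L
  d <- ph$dim
  pad_shift <- function(arr, ax, by) {
    out <- array(TRUE, d)  # out-of-domain counts as background
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- seq_len(n - by); idx_src[[ax]] <- seq_len(n - by) + by }
    else { idx_dst[[ax]] <- seq_len(n + by) - by; idx_src[[ax]] <- seq_len(n + by) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb_bg <- array(FALSE, d)
  for (ax in 1:3) for (by in c(-1L, 1L)) nb_bg <- nb_bg | pad_shift(bg, ax, by)
  surf <- (lab == scalp_id) & nb_bg
  co <- coord_arrays(ph)
  sidx <- which(surf)
  sx <- co$x[sidx]; sy <- co$y[sidx]; sz <- co$z[sidx]
  sigma_scalp <- ph$tissue_table$sigma[match(scalp_id, ph$tissue_table$id)]
  emap <- integer(0)
  el <- mt$electrodes
  for (i in seq_len(nrow(el))) {
    cap_r <- sqrt(el$area_cm2[i] * 100 / pi)  # mm
    d2 <- (sx - el$x[i])^2 + (sy - el$y[i])^2 + (sz - el$z[i])^2
    vox <- sidx[d2 <= cap_r^2]
    if (length(vox) == 0L)
      stop(sprintf("electrode %s patch is empty at this resolution", el$label[i]))
    id <- 1000L + i
    ph$labels[vox] <- id
    ph$tissue_table <- rbind(ph$tissue_table,
                             data.frame(id = id, name = el$label[i],
                                        sigma = sigma_scalp,
                                        stringsAsFactors = FALSE))
    emap[el$label[i]] <- id
  }
  ph$electrodes <- emap
  ph
}

#' Current density at an electrode contact
#'
#' @param current_mA peak-to-baseline current, mA.
#' @param contact_area_cm2 effective contact area, cm^2.
#' @return current density in mA/cm^2.
#' @examples
#' current_density(1, 3.14)   # ~0.318, circular 2 cm simulation contact
#' current_density(2, 2.25)   # ~0.889, 1.5 cm x 1.5 cm pads
#' @export
current_density <- function(current_mA, contact_area_cm2) {
  if (any(contact_area_cm2 <= 0)) stop("contact area must be > 0")
  current_mA / contact_area_cm2
}

#' @export
print.ti_montage <- function(x, ...) {
  cat("ti_montage: pairs",
      paste(vapply(x$pairs, paste, "", collapse = "-"), collapse = ", "),
      sprintf("| I = %s mA | f = %s kHz (delta f = %g Hz)\n",
              paste(x$currents_mA, collapse = "/"),
              paste(x$freqs_khz, collapse = "/"), x$delta_f_hz))
  print(x$electrodes[, c("label", "x", "y", "z", "area_cm2")], digits = 4)
  invisible(x)
}
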