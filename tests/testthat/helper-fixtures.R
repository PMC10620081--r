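# Shared fixtures and independent oracles for the test suite.

# Homogeneous cube with full opposite x-faces as electrode plates.
# side_mm total edge length; n voxels per edge.
make_cube_phantom <- function(n = 12, side_mm = 100, sigma = 0.3) {
  h <- side_mm / n
  lab <- array(1L, c(n, n, n))
  lab[1, , ] <- 2L
  lab[n, , ] <- 3L
  tt <- data.frame(id = 1:3, name = c("bulk", "anode", "cathode"),
                   sigma = sigma, stringsAsFactors = FALSE)
  phantom(lab, h, tt)
}

# Two equal-thickness conductivity layers along x between plate electrodes
make_two_layer_phantom <- function(n = 16, side_mm = 100,
                                   sigmas = c(0.3, 0.1)) {
  h <- side_mm / n
  lab <- array(0L, c(n, n, n))
  lab[1:(n / 2), , ] <- 1L
  lab[(n / 2 + 1):n, , ] <- 2L
  lab[1, , ] <- 3L
  lab[n, , ] <- 4L
  tt <- data.frame(id = 1:4, name = c("hi", "lo", "anode", "cathode"),
                   sigma = c(sigmas, sigmas[1], sigmas[2]),
                   stringsAsFactors = FALSE)
  phantom(lab, h, tt)
}

# Homogeneous sphere with small antipodal surface patch electrodes on +-x
make_antipodal_sphere <- function(radius = 40, resolution = 4, sigma = 0.3,
                                  patch_mm = 10) {
  ph <- make_layered_sphere_phantom(radius, sigma, resolution)
  co <- tistim:::coord_arrays(ph)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  surf <- ph$labels == 1L & r > radius - 1.5 * resolution
  d_an <- sqrt((co$x - radius)^2 + co$y^2 + co$z^2)
  d_ca <- sqrt((co$x + radius)^2 + co$y^2 + co$z^2)
  ph$labels[surf & d_an < patch_mm] <- 11L
  ph$labels[surf & d_ca < patch_mm] <- 12L
  ph$tissue_table <- rbind(ph$tissue_table,
                           data.frame(id = c(11L, 12L),
                                      name = c("anode", "cathode"),
                                      sigma = sigma))
  ph
}

# Lazily solved default-study fixture (phantom + both montages + 1 mA
# solutions), shared across test files.
sphere_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(rule = c("symmetric", "default"), resolution = 4) {
    rule <- match.arg(rule)
    key <- paste0(rule, "_", resolution)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- default_run_config(resolution = resolution)
    ph_key <- paste0("ph_", resolution)
    if (is.null(cache[[ph_key]]))
      cache[[ph_key]] <- build_config_phantom(cfg)
    ph <- cache[[ph_key]]
    rs <- if (rule == "symmetric") symmetric_rule_spec() else default_rule_spec()
    mt <- place_electrode_pairs(ph, rs)
    php <- paint_electrodes(ph, mt)
    tens <- build_conductivity_tensors(php)
    s1 <- normalize_to_current(
      solve_electrode_pair(php, tens, "e1", "e2"), 1, tens)
    s2 <- normalize_to_current(
      solve_electrode_pair(php, tens, "e3", "e4"), 1, tens)
    cache[[key]] <- list(ph = php, mt = mt, tens = tens, s1 = s1, s2 = s2)
    cache[[key]]
  }
})

# Time-domain oracle for the projected TI envelope-modulation amplitude:
# sample the summed projected two-tone signal densely over one beat
# period, trace its envelope through the local maxima of |s|, and return
# max - min of those peak values. Independent of the algebraic identity.
envelope_oracle_eam <- function(p1, p2, f1 = 2000, f2 = 2005) {
  beat <- 1 / abs(f1 - f2)
  fs <- 200 * max(f1, f2)
  t <- seq(0, beat, by = 1 / fs)
  s <- abs(p1 * sin(2 * pi * f1 * t) + p2 * sin(2 * pi * f2 * t))
  pk <- which(diff(sign(diff(s))) < 0) + 1L
  # parabolic refinement of each sampled peak value
  a <- s[pk - 1L]; b <- s[pk]; c <- s[pk + 1L]
  den <- 2 * b - a - c
  peaks <- ifelse(den > 0, b + (a - c)^2 / (8 * den), b)
  max(peaks) - min(peaks)
}

# Same oracle for the absolute amplitude: global peak over the beat
envelope_oracle_eabs <- function(p1, p2, f1 = 2000, f2 = 2005) {
  beat <- 1 / abs(f1 - f2)
  fs <- 200 * max(f1, f2)
  t <- seq(0, beat, by = 1 / fs)
  max(abs(p1 * sin(2 * pi * f1 * t) + p2 * sin(2 * pi * f2 * t)))
}

# 6-connectivity connected-component count for a voxel mask
n_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  dm <- dim(mask)
  pos <- arrayInd(idx, dm)
  id_of <- array(0L, dm)
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= dm[ax]
    nb_lin <- (nb[ok, 3] - 1L) * dm[1] * dm[2] + (nb[ok, 2] - 1L) * dm[1] + nb[ok, 1]
    has <- id_of[nb_lin] > 0L
    edges <- c(edges, rbind(id_of[idx[ok][has]], id_of[nb_lin[has]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::components(g)$no
}
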