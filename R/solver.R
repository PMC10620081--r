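# Electro-quasistatic conduction solver on the voxel grid.
#
# Discretization: trilinear (Q1) hexahedral elements with one constant
# conductivity tensor per voxel and 2x2x2 Gauss quadrature. On a regular
# grid this is a symmetric 27-point stencil; the stiffness matrix is SPD
# on the free nodes, so conjugate gradients apply. All lengths are
# converted to meters internally; potentials are V, fields V/m.

# Element node order: a = 1 + dx + 2*dy + 4*dz, (dx,dy,dz) in {0,1}^3
ELEM_OFFSETS <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

# 64 x 6 coefficient table: Ke[a,b] = sum_c M[(a,b), c] * S_c for tensor
# components c = xx, yy, zz, xy, xz, yz. Depends only on spacing (m).
element_coeff_table <- function(h_m) {
  gp <- (1 + c(-1, 1) / sqrt(3)) / 2      # unit-interval Gauss points
  G <- as.matrix(expand.grid(u = gp, v = gp, w = gp))
  vol <- prod(h_m)
  # gradients of the 8 shape functions at each of the 8 Gauss points
  grad <- array(0, c(8, 8, 3))  # [node, gp, comp]
  for (a in 1:8) {
    dxo <- ELEM_OFFSETS[a, 1]; dyo <- ELEM_OFFSETS[a, 2]; dzo <- ELEM_OFFSETS[a, 3]
    fx <- function(u) if (dxo == 1) u else 1 - u
    fy <- function(v) if (dyo == 1) v else 1 - v
    fz <- function(w) if (dzo == 1) w else 1 - w
    sx <- if (dxo == 1) 1 else -1
    sy <- if (dyo == 1) 1 else -1
    sz <- if (dzo == 1) 1 else -1
    grad[a, , 1] <- sx / h_m[1] * fy(G[, 2]) * fz(G[, 3])
    grad[a, , 2] <- fx(G[, 1]) * sy / h_m[2] * fz(G[, 3])
    grad[a, , 3] <- fx(G[, 1]) * fy(G[, 2]) * sz / h_m[3]
  }
  w <- vol / 8  # equal Gauss weights on the unit cube times volume
  M <- matrix(0, 64, 6)
  comp_pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (a in 1:8) for (b in 1:8) {
    row <- (a - 1) * 8 + b
    for (c in 1:6) {
      i <- comp_pairs[[c]][1]; j <- comp_pairs[[c]][2]
      v <- sum(grad[a, , i] * grad[b, , j]) * w
      if (i != j) v <- v + sum(grad[a, , j] * grad[b, , i]) * w
      M[row, c] <- v
    }
  }
  M
}

# Shift a logical array one voxel along `ax` in direction `by`;
# out-of-domain entries become `fill`.
shift_logical <- function(arr, ax, by, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d)
  n <- d[ax]
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) { idx_dst[[ax]] <- seq_len(n - 1); idx_src[[ax]] <- 2:n }
  else        { idx_dst[[ax]] <- 2:n;            idx_src[[ax]] <- seq_len(n - 1) }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Cells reachable from `seed` through `mask` by 6-connectivity
reachable_cells <- function(mask, seed) {
  reached <- seed & mask
  repeat {
    grow <- reached
    for (ax in 1:3) for (by in c(-1L, 1L))
      grow <- grow | shift_logical(reached, ax, by)
    grow <- grow & mask
    if (!any(grow & !reached)) return(reached)
    reached <- grow
  }
}

# Jacobi-preconditioned conjugate gradients
pcg_solve <- function(A, b, tol = 1e-8, max_iter = 20000L) {
  dg <- Matrix::diag(A)
  if (any(dg <= 0)) stop("singular system: non-positive diagonal entry")
  Minv <- 1 / dg
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, residual = 0, iterations = 0L))
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(list(x = x, residual = res, iterations = it))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("PCG did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Solve the conduction problem for one electrode pair
#'
#' Solves the discrete electro-quasistatic equation
#' `div(sigma grad phi) = 0` on the conducting voxels, with Dirichlet
#' values +V/2 on the anode patch and -V/2 on the cathode patch and
#' insulating (zero normal current) outer boundaries. The electric field
#' `E = -grad phi` is evaluated at voxel centers.
#'
#' @param ph phantom with painted electrode patches
#'   (see [paint_electrodes()]).
#' @param tens [build_conductivity_tensors()] output on the same grid.
#' @param anode_label,cathode_label tissue ids (or electrode names as in
#'   `ph$electrodes`) of the two contact patches.
#' @param applied_voltage total potential difference, V (default 1 V,
#'   normalized to a target current afterwards).
#' @param tolerance relative residual for the iterative solver.
#' @param max_iter iteration cap.
#' @param method `"pcg"` (Jacobi-preconditioned conjugate gradients) or
#'   `"direct"` (sparse Cholesky).
#' @return Object of class `ti_field`: `phi` (V, voxel centers), `E`
#'   (array `c(dim, 3)`, V/m), `residual`, `iterations`,
#'   `injected_current_mA` (NA until normalized or measured), plus grid
#'   metadata.
#' @export
solve_electrode_pair <- function(ph, tens, anode_label, cathode_label,
                                 applied_voltage = 1,
                                 tolerance = 1e-8, max_iter = 20000L,
                                 method = c("pcg", "direct")) {
  stopifnot(inherits(ph, "ti_phantom"), inherits(tens, "ti_tensors"))
  method <- match.arg(method)
  if (is.character(anode_label)) anode_label <- ph$electrodes[[anode_label]]
  if (is.character(cathode_label)) cathode_label <- ph$electrodes[[cathode_label]]
  dm <- ph$dim
  h_m <- ph$spacing / 1000
  an <- ph$labels == anode_label
  ca <- ph$labels == cathode_label
  if (!any(an) || !any(ca)) stop("electrode patch empty")
  if (any(an & ca)) stop("electrode patches overlap")
  conducting <- ph$labels > 0L
  dom <- reachable_cells(conducting, an)
  if (!any(dom & ca))
    stop("conducting domain disconnected between the electrodes")
  cells <- which(dom)
  ne <- length(cells)

  # node ids of the 8 corners of each conducting cell
  nd <- dm + 1L
  ci <- arrayInd(cells, dm)
  node_id <- function(i, j, k) (k - 1L) * nd[1] * nd[2] + (j - 1L) * nd[1] + i
  enodes <- matrix(0L, ne, 8)
  for (a in 1:8)
    enodes[, a] <- node_id(ci[, 1] + ELEM_OFFSETS[a, 1],
                           ci[, 2] + ELEM_OFFSETS[a, 2],
                           ci[, 3] + ELEM_OFFSETS[a, 3])

  active_nodes <- sort(unique(as.vector(enodes)))
  nn <- length(active_nodes)
  node_map <- integer(prod(nd))
  node_map[active_nodes] <- seq_len(nn)
  enodes_l <- matrix(node_map[enodes], ne, 8)

  # per-element stiffness values from the tensor components
  M <- element_coeff_table(h_m)
  nvox <- prod(dm)
  Svals <- matrix(0, ne, 6)
  for (c in 1:6) Svals[, c] <- tens$S[cells + (c - 1L) * nvox]
  Kv <- Svals %*% t(M)   # ne x 64, column (a-1)*8 + b

  ii <- integer(0); jj <- integer(0)
  ii <- rep(0L, 64L * ne); jj <- ii; xx <- numeric(64L * ne)
  for (a in 1:8) for (b in 1:8) {
    col <- (a - 1L) * 8L + b
    rng <- ((col - 1L) * ne + 1L):(col * ne)
    ii[rng] <- enodes_l[, a]
    jj[rng] <- enodes_l[, b]
    xx[rng] <- Kv[, col]
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  rm(ii, jj, xx, Kv)

  # Dirichlet nodes: the contact surface of each electrode patch — nodes
  # of electrode-cell faces that look into non-conducting space (the
  # outer surface where the physical contact sits)
  face_nodes <- list(`1-` = c(1, 3, 5, 7), `1+` = c(2, 4, 6, 8),
                     `2-` = c(1, 2, 5, 6), `2+` = c(3, 4, 7, 8),
                     `3-` = c(1, 2, 3, 4), `3+` = c(5, 6, 7, 8))
  dom_centroid <- colMeans(ci)
  contact_nodes <- function(emask) {
    # outward direction of the patch: from the conducting-domain centroid
    # toward the patch centroid (voxel coords scaled to physical)
    epos <- which(emask, arr.ind = TRUE)
    u <- (colMeans(epos) - dom_centroid) * ph$spacing
    u <- u / sqrt(sum(u^2))
    sel <- integer(0)
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      if (u[ax] * by <= 0.25) next  # keep only outward-aligned faces
      # electrode cells whose neighbor along (ax, by) is non-conducting
      open_face <- emask & !shift_logical(conducting, ax, by)
      if (!any(open_face)) next
      fc <- match(which(open_face), cells)
      fn <- face_nodes[[paste0(ax, ifelse(by > 0, "+", "-"))]]
      sel <- c(sel, as.vector(enodes_l[fc, fn]))
    }
    if (!length(sel))
      stop("electrode patch has no exterior-facing contact surface")
    unique(sel)
  }
  an_nodes <- contact_nodes(an)
  ca_nodes <- contact_nodes(ca)
  both <- intersect(an_nodes, ca_nodes)
  if (length(both)) stop("electrode patches touch: shared corner nodes")
  vmax <- applied_voltage / 2
  fixed <- c(an_nodes, ca_nodes)
  phi_fixed <- c(rep(vmax, length(an_nodes)), rep(-vmax, length(ca_nodes)))
  free <- setdiff(seq_len(nn), fixed)
  A <- K[free, free, drop = FALSE]
  b <- -as.numeric(K[free, fixed, drop = FALSE] %*% phi_fixed)

  if (method == "pcg") {
    sol <- pcg_solve(A, b, tol = tolerance, max_iter = max_iter)
  } else {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
    x <- as.numeric(Matrix::solve(ch, b))
    res <- sqrt(sum((b - as.numeric(A %*% x))^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
    sol <- list(x = x, residual = res, iterations = NA_integer_)
  }

  phi_nodes <- numeric(nn)
  phi_nodes[free] <- sol$x
  phi_nodes[fixed] <- phi_fixed

  # gather node potentials per element; cell phi and centered E
  P <- matrix(phi_nodes[enodes_l], ne, 8)
  Ex <- -rowMeans(P[, c(2, 4, 6, 8)] - P[, c(1, 3, 5, 7)]) / h_m[1]
  Ey <- -rowMeans(P[, c(3, 4, 7, 8)] - P[, c(1, 2, 5, 6)]) / h_m[2]
  Ez <- -rowMeans(P[, c(5, 6, 7, 8)] - P[, c(1, 2, 3, 4)]) / h_m[3]
  phi <- array(NA_real_, dm)
  phi[cells] <- rowMeans(P)
  E <- array(0, c(dm, 3L))
  E[cells] <- Ex
  E[cells + nvox] <- Ey
  E[cells + 2L * nvox] <- Ez

  structure(list(
    phi = phi, E = E, dim = dm, spacing = ph$spacing, origin = ph$origin,
    labels = ph$labels, anode_label = anode_label,
    cathode_label = cathode_label, applied_voltage = applied_voltage,
    injected_current_mA = NA_real_,
    residual = sol$residual, iterations = sol$iterations
  ), class = "ti_field")
}

#' Injected current through a surface enclosing one electrode
#'
#' Integrates the normal current density `j = sigma E` over the closed
#' surface of a voxel box surrounding the electrode patch (the patch's
#' bounding box grown by `margin` voxels). Faces adjacent to
#' non-conducting voxels carry no current (insulating boundary). Sign
#' convention: current flowing out of the anode is positive.
#'
#' @param sol a [solve_electrode_pair()] solution.
#' @param tens the conductivity tensors used for the solve.
#' @param electrode_label tissue id of the enclosed electrode (or `NULL`
#'   for the solution's anode).
#' @param margin box growth in voxels.
#' @return net current in mA.
#' @export
injected_current <- function(sol, tens, electrode_label = NULL, margin = 3L) {
  stopifnot(inherits(sol, "ti_field"), inherits(tens, "ti_tensors"))
  if (is.null(electrode_label)) electrode_label <- sol$anode_label
  dm <- sol$dim
  epos <- which(sol$labels == electrode_label, arr.ind = TRUE)
  if (nrow(epos) == 0L) stop("electrode label absent")
  lo <- pmax(apply(epos, 2, min) - margin, 1L)
  hi <- pmin(apply(epos, 2, max) + margin, dm)
  inB <- array(FALSE, dm)
  inB[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  other <- setdiff(c(sol$anode_label, sol$cathode_label), electrode_label)
  if (any(sol$labels[inB] %in% other))
    stop("integration surface encloses both electrodes; reduce margin")
  flux_box_mA(sol, tens, inB)
}

# Net outward current (mA) through the boundary of the voxel set `inB`
flux_box_mA <- function(sol, tens, inB) {
  dm <- sol$dim
  nvox <- prod(dm)
  h_m <- sol$spacing / 1000
  face_area <- c(h_m[2] * h_m[3], h_m[1] * h_m[3], h_m[1] * h_m[2])
  S <- tens$S
  Exv <- sol$E[seq_len(nvox)]
  Eyv <- sol$E[seq_len(nvox) + nvox]
  Ezv <- sol$E[seq_len(nvox) + 2L * nvox]
  jx <- array(S[seq_len(nvox)] * Exv + S[seq_len(nvox) + 3L * nvox] * Eyv +
                S[seq_len(nvox) + 4L * nvox] * Ezv, dm)
  jy <- array(S[seq_len(nvox) + 3L * nvox] * Exv + S[seq_len(nvox) + nvox] * Eyv +
                S[seq_len(nvox) + 5L * nvox] * Ezv, dm)
  jz <- array(S[seq_len(nvox) + 4L * nvox] * Exv + S[seq_len(nvox) + 5L * nvox] * Eyv +
                S[seq_len(nvox) + 2L * nvox] * Ezv, dm)
  jcomp <- list(jx, jy, jz)
  conducting <- array(sol$labels > 0L, dm)
  total <- 0
  for (ax in 1:3) {
    for (by in c(1L, -1L)) {
      # boundary faces: cell in the box, neighbor outside it but still
      # conducting (faces into background or past the grid are insulating)
      nb_in <- shift_logical(inB, ax, by)
      nb_cond <- shift_logical(conducting, ax, by)
      bnd <- inB & !nb_in & nb_cond
      if (!any(bnd)) next
      j_here <- jcomp[[ax]][bnd]
      j_nb <- shift_logical_num(jcomp[[ax]], ax, by)[bnd]
      total <- total + sum(0.5 * (j_here + j_nb)) * face_area[ax] * by
    }
  }
  total * 1000  # A -> mA
}

# numeric version of shift_logical with zero fill
shift_logical_num <- function(arr, ax, by) {
  d <- dim(arr)
  out <- array(0, d)
  n <- d[ax]
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) { idx_dst[[ax]] <- seq_len(n - 1); idx_src[[ax]] <- 2:n }
  else        { idx_dst[[ax]] <- 2:n;            idx_src[[ax]] <- seq_len(n - 1) }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Normalize a field solution to a target injected current
#'
#' Scales potential and field linearly so the injected current equals
#' `target_current_mA` (fields of the conduction problem are exactly
#' linear in the applied drive).
#'
#' @param sol a [solve_electrode_pair()] solution.
#' @param target_current_mA desired injected current, mA.
#' @param tens tensors used to measure the current (needed unless the
#'   solution already carries a measured current).
#' @return the rescaled `ti_field` with `injected_current_mA` set.
#' @export
normalize_to_current <- function(sol, target_current_mA, tens = NULL) {
  stopifnot(inherits(sol, "ti_field"))
  measured <- sol$measured_current_mA
  if (is.null(measured) || is.na(measured)) {
    if (is.null(tens)) stop("tensors required to measure the injected current")
    measured <- injected_current(sol, tens)
  }
  if (abs(measured) < .Machine$double.eps)
    stop("measured injected current is zero; cannot normalize")
  fac <- target_current_mA / measured
  sol$phi <- sol$phi * fac
  sol$E <- sol$E * fac
  sol$applied_voltage <- sol$applied_voltage * fac
  sol$measured_current_mA <- target_current_mA
  sol$injected_current_mA <- target_current_mA
  sol
}

#' @export
print.ti_field <- function(x, ...) {
  cat(sprintf("ti_field: %s grid, residual %.2e (%s iterations), I = %s mA\n",
              paste(x$dim, collapse = "x"), x$residual,
              ifelse(is.na(x$iterations), "direct", x$iterations),
              ifelse(is.na(x$injected_current_mA), "unnormalized",
                     format(x$injected_current_mA))))
  invisible(x)
}
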