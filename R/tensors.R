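# Tensor component order used throughout: xx, yy, zz, xy, xz, yz

#' Build per-voxel conductivity tensors
#'
#' Isotropic tissues get `sigma * I`. Tissues listed in `anisotropic`
#' (white matter by default) get the tensor
#' `sigma_trans * I + (sigma_long - sigma_trans) * n n^T`, whose principal
#' eigenvector is the local orientation `n` with eigenvalue `sigma_long`
#' and whose two transverse eigenvalues are `sigma_trans` — the standard
#' longitudinal/transverse decomposition used for DTI-derived
#' conductivity maps.
#'
#' @param ph a phantom; must carry an orientation field if any tissue is
#'   anisotropic.
#' @param sigma_long,sigma_trans longitudinal and transverse
#'   conductivities (S/m) for the anisotropic tissues. When both are
#'   `NULL` the whole map is isotropic.
#' @param anisotropic character vector of tissue names treated as
#'   anisotropic.
#' @return Object of class `ti_tensors`: list with `S`, an array of dim
#'   `c(dim, 6)` holding the symmetric tensor components
#'   (xx, yy, zz, xy, xz, yz) in S/m, zero at background voxels.
#' @export
build_conductivity_tensors <- function(ph, sigma_long = NULL,
                                       sigma_trans = NULL,
                                       anisotropic = "white") {
  stopifnot(inherits(ph, "ti_phantom"))
  dm <- ph$dim
  nvox <- prod(dm)
  S <- array(0, c(dm, 6L))
  sig <- ph$tissue_table$sigma[match(ph$labels, ph$tissue_table$id)]
  sig[is.na(sig)] <- 0
  S[seq_len(nvox)] <- sig                 # xx
  S[seq_len(nvox) + nvox] <- sig          # yy
  S[seq_len(nvox) + 2L * nvox] <- sig     # zz
  aniso_on <- !is.null(sigma_long) && !is.null(sigma_trans) &&
    sigma_long != sigma_trans
  if (aniso_on) {
    if (sigma_long <= 0 || sigma_trans <= 0)
      stop("sigma_long and sigma_trans must be > 0")
    ids <- ph$tissue_table$id[ph$tissue_table$name %in% anisotropic]
    idx <- which(ph$labels %in% ids)
    if (length(idx)) {
      if (is.null(ph$orientation))
        stop("anisotropic tissues present but no orientation field defined")
      nx <- ph$orientation[idx]
      ny <- ph$orientation[idx + nvox]
      nz <- ph$orientation[idx + 2L * nvox]
      if (anyNA(nx) || anyNA(ny) || anyNA(nz))
        stop("missing orientation vector at an anisotropic voxel")
      dlt <- sigma_long - sigma_trans
      S[idx]             <- sigma_trans + dlt * nx * nx
      S[idx + nvox]      <- sigma_trans + dlt * ny * ny
      S[idx + 2L * nvox] <- sigma_trans + dlt * nz * nz
      S[idx + 3L * nvox] <- dlt * nx * ny
      S[idx + 4L * nvox] <- dlt * nx * nz
      S[idx + 5L * nvox] <- dlt * ny * nz
    }
  }
  structure(list(S = S, dim = dm, spacing = ph$spacing), class = "ti_tensors")
}

#' Extract the 3x3 tensor at one voxel
#' @param tens a `ti_tensors`; `i,j,k` voxel indices.
#' @return symmetric 3x3 matrix (S/m).
#' @export
tensor_at <- function(tens, i, j, k) {
  v <- tens$S[i, j, k, ]
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}
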