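#' Image volumes
#'
#' A volume is a plain 3-D numeric array carrying a `"spacing"` attribute,
#' the physical voxel size in mm along each array dimension. Masks are 3-D
#' logical arrays on the same grid.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @return the array with class `image_volume` and a `spacing` attribute.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  attr(data, "spacing") <- as.numeric(spacing)
  class(data) <- c("image_volume", class(data))
  data
}

#' Voxel spacing of a volume or mask
#' @param x array with a `spacing` attribute.
#' @param default fallback when the attribute is absent.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_spacing <- function(x, default = c(1, 1, 1)) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) default else as.numeric(sp)
}

# Physical coordinates (mm) of voxel centres for the given array indices.
voxel_coords <- function(idx, dim, spacing) {
  arr <- arrayInd(idx, dim)
  sweep(arr - 1, 2, spacing, `*`)
}

#' Squared Euclidean distance map to a mask
#'
#' Distance (mm) from each voxel centre to the nearest `TRUE` voxel centre,
#' exact under anisotropic spacing.
#'
#' @param mask 3-D logical array.
#' @param spacing voxel spacing in mm.
#' @return numeric array of distances in mm.
#' @export
distance_to_mask <- function(mask, spacing = voxel_spacing(mask)) {
  stopifnot(length(dim(mask)) == 3)
  d2 <- edt_sq_cpp(as.logical(mask), dim(mask), as.numeric(spacing))
  array(sqrt(d2), dim(mask))
}

#' Trilinear resampling of a volume to a new voxel spacing
#'
#' @param vol 3-D numeric array with spacing attribute (or supply `spacing`).
#' @param new_spacing target spacing in mm.
#' @param spacing current spacing in mm.
#' @param method `"linear"` for images, `"nearest"` for masks/labels.
#' @return resampled array with updated spacing attribute.
#' @export
resample_volume <- function(vol, new_spacing, spacing = voxel_spacing(vol),
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  spacing <- as.numeric(spacing)
  new_spacing <- as.numeric(new_spacing)
  if (isTRUE(all.equal(spacing, new_spacing))) {
    attr(vol, "spacing") <- new_spacing
    return(vol)
  }
  d <- dim(vol)
  extent <- (d - 1) * spacing
  nd <- pmax(2L, as.integer(floor(extent / new_spacing + 1e-6)) + 1L)
  # target voxel centres in source voxel (0-based fractional) coordinates
  gx <- (seq_len(nd[1]) - 1) * new_spacing[1] / spacing[1]
  gy <- (seq_len(nd[2]) - 1) * new_spacing[2] / spacing[2]
  gz <- (seq_len(nd[3]) - 1) * new_spacing[3] / spacing[3]
  gx <- pmin(gx, d[1] - 1); gy <- pmin(gy, d[2] - 1); gz <- pmin(gz, d[3] - 1)
  v <- as.vector(vol)
  lin <- function(i, j, k) v[1L + i + d[1] * (j + d[2] * k)]
  if (method == "nearest") {
    ix <- round(gx); iy <- round(gy); iz <- round(gz)
    I <- rep(ix, times = nd[2] * nd[3])
    J <- rep(rep(iy, each = nd[1]), times = nd[3])
    K <- rep(iz, each = nd[1] * nd[2])
    out <- array(lin(I, J, K), nd)
  } else {
    x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
    fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
    x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
    z1 <- pmin(z0 + 1, d[3] - 1)
    rep3 <- function(a, b, c) list(
      rep(a, times = nd[2] * nd[3]),
      rep(rep(b, each = nd[1]), times = nd[3]),
      rep(c, each = nd[1] * nd[2]))
    g0 <- rep3(x0, y0, z0); g1 <- rep3(x1, y1, z1)
    f <- rep3(fx, fy, fz)
    out <- lin(g0[[1]], g0[[2]], g0[[3]]) * (1 - f[[1]]) * (1 - f[[2]]) * (1 - f[[3]]) +
      lin(g1[[1]], g0[[2]], g0[[3]]) * f[[1]] * (1 - f[[2]]) * (1 - f[[3]]) +
      lin(g0[[1]], g1[[2]], g0[[3]]) * (1 - f[[1]]) * f[[2]] * (1 - f[[3]]) +
      lin(g0[[1]], g0[[2]], g1[[3]]) * (1 - f[[1]]) * (1 - f[[2]]) * f[[3]] +
      lin(g1[[1]], g1[[2]], g0[[3]]) * f[[1]] * f[[2]] * (1 - f[[3]]) +
      lin(g1[[1]], g0[[2]], g1[[3]]) * f[[1]] * (1 - f[[2]]) * f[[3]] +
      lin(g0[[1]], g1[[2]], g1[[3]]) * (1 - f[[1]]) * f[[2]] * f[[3]] +
      lin(g1[[1]], g1[[2]], g1[[3]]) * f[[1]] * f[[2]] * f[[3]]
    out <- array(out, nd)
  }
  attr(out, "spacing") <- new_spacing
  out
}

#' Write a volume or mask to NIfTI
#' @param vol 3-D array with spacing attribute.
#' @param path output `.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path `.nii` / `.nii.gz` path.
#' @return 3-D array with spacing attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img)[1:3])
  image_volume(arr, RNifti::pixdim(img)[1:3])
}
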