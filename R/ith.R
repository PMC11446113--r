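#' Segment the intratumoral region into subregions (3-D SLIC)
#'
#' Simple linear iterative clustering restricted to the lesion mask: local
#' k-means on joint (standardized intensity, physical coordinate) space.
#' Cluster centres are initialised on a regular physical grid of pitch
#' `S = (V / n_segments)^(1/3)` inside the mask and iterated with search
#' windows of 2S. Segments smaller than `min_segment_voxels` are merged into
#' the adjacent segment with the closest mean intensity; unmergeable
#' remnants are dropped (label 0).
#'
#' @param volume 3-D numeric array.
#' @param itr_mask 3-D logical array (non-empty).
#' @param n_segments requested number of segments (default 100). If the
#'   mask has fewer voxels, the request is reduced with a warning.
#' @param compactness spatial weight (default 0.05): distance is
#'   `sqrt(d_intensity^2 + (compactness * d_space / S)^2)` with intensity
#'   standardized to zero mean / unit variance within the mask.
#' @param seed integer seed (centre top-up and tie behaviour).
#' @param max_iter SLIC iterations (default 10).
#' @param min_segment_voxels smallest retained segment (default 10).
#' @param spacing voxel spacing in mm.
#' @return integer label array (class `segment_map`), 0 outside the mask and
#'   for dropped remnants; attributes `n_requested`, `segment_sizes`.
#' @export
segment_subregions <- function(volume, itr_mask, n_segments = 100L,
                               compactness = 0.05, seed = 1L,
                               max_iter = 10L, min_segment_voxels = 10L,
                               spacing = voxel_spacing(volume)) {
  stopifnot(any(itr_mask), n_segments >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  d <- dim(volume)
  idx <- which(itr_mask)
  nvox <- length(idx)
  requested <- as.integer(n_segments)
  if (nvox < requested) {
    warning("ITR has ", nvox, " voxels; reducing segment request from ",
            requested, " to ", nvox)
    requested <- nvox
  }
  xyz <- voxel_coords(idx, d, spacing)
  val <- volume[idx]
  zval <- if (sd(val) > 0) (val - mean(val)) / sd(val) else rep(0, nvox)
  S <- (nvox * prod(spacing) / requested)^(1 / 3)

  # grid-initialised centres snapped to in-mask voxels
  rng <- apply(xyz, 2, range)
  grid <- expand.grid(seq(rng[1, 1] + S / 2, rng[2, 1], by = S),
                      seq(rng[1, 2] + S / 2, rng[2, 2], by = S),
                      seq(rng[1, 3] + S / 2, rng[2, 3], by = S))
  snap <- unique(vapply(seq_len(nrow(grid)), function(g) {
    which.min(colSums((t(xyz) - as.numeric(grid[g, ]))^2))
  }, 0L))
  if (length(snap) > requested) snap <- sample(snap, requested)
  if (length(snap) < requested)
    snap <- c(snap, sample(setdiff(seq_len(nvox), snap),
                           requested - length(snap)))
  cx <- xyz[snap, , drop = FALSE]
  ci <- zval[snap]
  k <- length(snap)
  w <- compactness / S

  lab <- integer(nvox)
  for (it in seq_len(max_iter)) {
    best <- rep(Inf, nvox)
    lab <- integer(nvox)
    for (j in seq_len(k)) {
      cand <- which(abs(xyz[, 1] - cx[j, 1]) < 2 * S &
                    abs(xyz[, 2] - cx[j, 2]) < 2 * S &
                    abs(xyz[, 3] - cx[j, 3]) < 2 * S)
      if (!length(cand)) next
      dsp2 <- (xyz[cand, 1] - cx[j, 1])^2 + (xyz[cand, 2] - cx[j, 2])^2 +
        (xyz[cand, 3] - cx[j, 3])^2
      dist <- (zval[cand] - ci[j])^2 + w^2 * dsp2
      upd <- dist < best[cand]
      best[cand[upd]] <- dist[upd]
      lab[cand[upd]] <- j
    }
    # orphans (outside every window): nearest centre spatially
    orph <- which(lab == 0L)
    for (o in orph)
      lab[o] <- which.min((cx[, 1] - xyz[o, 1])^2 + (cx[, 2] - xyz[o, 2])^2 +
                          (cx[, 3] - xyz[o, 3])^2)
    for (j in seq_len(k)) {
      mem <- lab == j
      if (any(mem)) {
        cx[j, ] <- colMeans(xyz[mem, , drop = FALSE])
        ci[j] <- mean(zval[mem])
      }
    }
  }

  labmap <- array(0L, d)
  labmap[idx] <- lab
  labmap <- merge_small_segments(labmap, val_map = volume,
                                 min_vox = min_segment_voxels)
  structure(labmap, class = "segment_map", spacing = spacing,
            n_requested = as.integer(n_segments),
            segment_sizes = table(labmap[labmap > 0]))
}

# Merge segments below min_vox into the 6-connected neighbour with the
# closest mean intensity; drop isolated remnants (label 0). Labels are
# re-numbered 1..K afterwards.
merge_small_segments <- function(labmap, val_map, min_vox) {
  d <- dim(labmap)
  repeat {
    sizes <- tabulate(labmap[labmap > 0])
    small <- which(sizes > 0 & sizes < min_vox)
    if (!length(small)) break
    target <- small[which.min(sizes[small])]
    vox <- which(labmap == target)
    nb_labels <- integer(0)
    arr <- arrayInd(vox, d)
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      sh <- arr
      sh[, axis] <- sh[, axis] + dir
      ok <- sh[, axis] >= 1 & sh[, axis] <= d[axis]
      nb <- labmap[sh[ok, , drop = FALSE]]
      nb_labels <- c(nb_labels, nb[nb > 0 & nb != target])
    }
    if (!length(nb_labels)) {
      labmap[vox] <- 0L
      next
    }
    cand <- unique(nb_labels)
    mt <- mean(val_map[vox])
    mdiff <- vapply(cand, function(l) abs(mean(val_map[labmap == l]) - mt), 0)
    labmap[vox] <- cand[which.min(mdiff)]
  }
  keep <- sort(unique(labmap[labmap > 0]))
  relab <- array(0L, d)
  relab[labmap > 0] <- match(labmap[labmap > 0], keep)
  attributes(relab) <- attributes(labmap)
  dim(relab) <- d
  relab
}

#' Select a Gaussian-mixture component count by BIC
#'
#' Fits one-dimensional Gaussian mixtures with k = 1..`k_max` components by
#' EM (5 random restarts, variance floor `1e-6 * var(values)`) and returns
#' the k minimising `BIC = -2 logL + (3k - 1) log(n)`; ties go to the
#' smaller k (parsimony). k is additionally capped at the number of
#' distinct values.
#'
#' @param values numeric vector (non-finite entries dropped; >= 2 required).
#' @param k_max maximum component count (default 5).
#' @param seed integer seed for the restarts.
#' @return integer in `1..k_max`.
#' @export
gmm_bic_select <- function(values, k_max = 5L, seed = 1L) {
  x <- sort(values[is.finite(values)])  # order-invariant by construction
  if (length(x) < 2) stop("need at least 2 finite values")
  # constant up to numerical fuzz: one population, no fitting
  if (diff(range(x)) <= 1e-9 * max(1, abs(mean(x)))) return(1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- length(x)
  kmax_eff <- min(k_max, length(unique(x)))
  floor_var <- 1e-6 * var(x)
  best_k <- 1L
  best_bic <- Inf
  for (k in seq_len(kmax_eff)) {
    ll <- gmm_em_loglik(x, k, restarts = 5L, floor_var = floor_var)
    bic <- -2 * ll + (3 * k - 1) * log(n)
    if (bic < best_bic - 1e-9) {
      best_bic <- bic
      best_k <- as.integer(k)
    }
  }
  best_k
}

# Best log-likelihood over random restarts of a 1-D k-component GMM EM.
# Initial means are drawn under the caller's RNG; the EM itself runs in
# compiled code.
gmm_em_loglik <- function(x, k, restarts = 5L, floor_var, tol = 1e-8,
                          max_iter = 200L) {
  if (k == 1) {
    v <- max(mean((x - mean(x))^2), floor_var)
    return(sum(dnorm(x, mean(x), sqrt(v), log = TRUE)))
  }
  ux <- unique(x)
  mu0 <- t(vapply(seq_len(restarts), function(r) sample(ux, k),
                  numeric(k)))
  gmm_best_loglik_cpp(x, mu0, floor_var, tol, max_iter)
}

#' Intratumoral ecological diversity vector
#'
#' For each of the 93 radiomic features: compute the feature on every
#' retained subregion of the lesion, then select the number of Gaussian
#' mixture components (1..5) across subregions by BIC. The resulting vector
#' of per-feature cluster counts quantifies how many distinct "habitats" the
#' tumor exhibits through the lens of each feature.
#'
#' @param volume 3-D numeric array.
#' @param segmap a [segment_subregions()] label map.
#' @param cfg a [disc_config()]; the bin reference (in-mask minimum) is
#'   computed per segment.
#' @param classes feature classes (default all six; 93 entries).
#' @param k_max maximum cluster count (default 5).
#' @param seed integer seed for the GMM restarts.
#' @param min_voxels segments below this are excluded from the GMM input.
#' @return named integer vector (class `diversity_vector`), one entry per
#'   feature, values in `1..k_max`; attribute `n_segments_used`.
#' @export
diversity_vector <- function(volume, segmap, cfg = disc_config(),
                             classes = c("firstorder", "glcm", "gldm",
                                         "glrlm", "glszm", "ngtdm"),
                             k_max = 5L, seed = 1L, min_voxels = 10) {
  fnames <- feature_names(classes)
  labs <- sort(unique(segmap[segmap > 0]))
  segfeats <- list()
  for (l in labs) {
    sf <- tryCatch(
      extract_features(volume, segmap == l, cfg, classes, min_voxels,
                       spacing = voxel_spacing(segmap)),
      renorad_feature_error = function(e) NULL)
    if (!is.null(sf)) segfeats[[length(segfeats) + 1]] <- sf
  }
  if (length(segfeats) < 2) {
    warning("fewer than 2 retained segments; degenerate diversity vector")
    return(structure(setNames(rep(1L, length(fnames)), fnames),
                     class = "diversity_vector", n_segments_used =
                       length(segfeats)))
  }
  M <- do.call(rbind, segfeats)
  out <- vapply(seq_along(fnames), function(j) {
    vals <- M[, fnames[j]]
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2 ||
        diff(range(vals)) <= 1e-9 * max(1, abs(mean(vals)))) return(1L)
    gmm_bic_select(vals, k_max, seed = seed + j)
  }, 0L)
  structure(setNames(out, fnames), class = "diversity_vector",
            n_segments_used = nrow(M))
}

#' Append diversity vectors to a feature table
#'
#' @param table feature table (data.frame with `case_id`).
#' @param divs list of [diversity_vector()]s in case order.
#' @return the table with `ITH__`-prefixed integer columns appended.
#' @export
bind_diversity <- function(table, divs) {
  D <- do.call(rbind, lapply(divs, as.integer))
  colnames(D) <- paste0("ITH__", names(divs[[1]]))
  cbind(table, as.data.frame(D))
}
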