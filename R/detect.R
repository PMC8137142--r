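#' Spot-detection parameters
#'
#' Settings for the LoG-style (difference-of-Gaussians) candidate
#' detector and the 3D Gaussian refinement fit.
#'
#' @param smoothing_sigma detection scale in um (roughly the lateral PSF
#'   sigma).
#' @param threshold_mode `"robust-zscore"` (default) thresholds the
#'   band-pass response at `median + threshold_value * MAD`; `"absolute"`
#'   uses `threshold_value` directly on the response.
#' @param threshold_value z-score (default 5) or absolute response level.
#' @param min_separation minimum distance between accepted spots (um).
#' @param fit_window voxels per axis of the fit neighbourhood (odd).
#' @param quality_min minimum fit quality (clamped R^2) to keep a spot.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma = 0.13,
                             threshold_mode = c("robust-zscore", "absolute"),
                             threshold_value = 5,
                             min_separation = 0.3,
                             fit_window = 7L,
                             quality_min = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (smoothing_sigma <= 0 || threshold_value <= 0 || min_separation <= 0)
    stop_mod("detection_params", "parameters", "must be positive")
  fit_window <- as.integer(fit_window)
  if (fit_window < 3L || fit_window %% 2L == 0L)
    stop_mod("detection_params", "fit_window", "must be odd and >= 3")
  if (quality_min < 0 || quality_min > 1)
    stop_mod("detection_params", "quality_min", "must lie in [0, 1]")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_separation = min_separation,
                 fit_window = fit_window,
                 quality_min = quality_min),
            class = "detection_params")
}

#' Detect diffraction-limited spots in a 3D stack
#'
#' Candidates are local maxima of a difference-of-Gaussians band-pass
#' response (sigma and 1.6 sigma), thresholded per
#' [detection_params()] and separated by at least `min_separation`.
#' Each candidate is refined by a least-squares 3D Gaussian fit
#' (background + amplitude + centre + per-axis sigma) inside
#' `fit_window`; fits below `quality_min` are dropped. The result is
#' sorted by descending fitted intensity.
#'
#' @param image single-channel 3D array, dim `(z, y, x)`, finite values.
#' @param voxel_size um triple `(z, y, x)`.
#' @param params a [detection_params()].
#' @return spot table: data.frame with columns `channel, cell_id, z_um,
#'   y_um, x_um, intensity, sigma_z_um, sigma_y_um, sigma_x_um, quality,
#'   compartment` (one row per spot; `channel`/`cell_id`/`compartment`
#'   start unassigned).
#' @examples
#' img <- array(10, c(12, 24, 24))
#' nrow(detect_spots(img, c(0.2, 0.1, 0.1)))  # blank image -> 0 spots
#' @export
detect_spots <- function(image, voxel_size, params = detection_params()) {
  if (!is.array(image) || length(dim(image)) != 3L)
    stop_mod("detect_spots", "image", "must be a 3D array (z, y, x)")
  if (any(!is.finite(image)))
    stop_mod("detect_spots", "image", "contains non-finite voxels")
  voxel_size <- check_axis_triple(voxel_size, "voxel_size", "detect_spots")
  if (any(voxel_size <= 0))
    stop_mod("detect_spots", "voxel_size", "must be > 0")
  empty <- empty_spot_table()
  if (diff(range(image)) == 0) return(empty)

  sig_vox <- pmax(params$smoothing_sigma / voxel_size, 0.5)
  resp <- gauss_filter3d(image, sig_vox) -
    gauss_filter3d(image, 1.6 * sig_vox)

  thr <- switch(params$threshold_mode,
    "robust-zscore" = {
      m <- median(resp); s <- mad(resp)
      if (s == 0) s <- sd(resp)
      m + params$threshold_value * s
    },
    "absolute" = params$threshold_value)

  half <- pmax(1L, as.integer(floor(params$min_separation / voxel_size)))
  mx <- max_filter3d(resp, half)
  cand <- which(resp >= mx & resp > thr & resp > 0)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(resp[cand], decreasing = TRUE)]
  idx <- arrayInd(cand, dim(resp)) - 1L          # 0-based (z, y, x)

  # greedy min-separation in physical units
  pos_um <- sweep(idx + 0.5, 2L, voxel_size, `*`)
  keep <- greedy_separate(pos_um, params$min_separation)
  idx <- idx[keep, , drop = FALSE]

  fits <- lapply(seq_len(nrow(idx)), function(k)
    fit_gaussian3d(image, idx[k, ], voxel_size, params))
  fits <- do.call(rbind, fits)
  fits <- fits[fits$quality >= params$quality_min & fits$intensity > 0, ,
               drop = FALSE]
  if (nrow(fits) == 0L) return(empty)
  fits <- fits[order(fits$intensity, decreasing = TRUE), , drop = FALSE]
  rownames(fits) <- NULL
  fits
}

empty_spot_table <- function() {
  data.frame(channel = character(0), cell_id = integer(0),
             z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
             intensity = numeric(0), sigma_z_um = numeric(0),
             sigma_y_um = numeric(0), sigma_x_um = numeric(0),
             quality = numeric(0), compartment = character(0),
             stringsAsFactors = FALSE)
}

# keep points (ordered by priority) whose pairwise distance >= min_sep
greedy_separate <- function(pos, min_sep) {
  n <- nrow(pos)
  keep <- logical(n)
  kept <- matrix(numeric(0), ncol = ncol(pos))
  for (i in seq_len(n)) {
    if (nrow(kept) == 0L ||
        min(sqrt(colSums((t(kept) - pos[i, ])^2))) >= min_sep) {
      keep[i] <- TRUE
      kept <- rbind(kept, pos[i, ])
    }
  }
  which(keep)
}

# separable Gaussian filter, replicate borders; sigma in voxels per axis
gauss_filter3d <- function(img, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    h <- max(1L, as.integer(ceiling(3.5 * s)))
    k <- exp(-((-h:h)^2) / (2 * s^2)); k <- k / sum(k)
    img <- filter_axis(img, k, ax)
  }
  img
}

# convolve along one axis of a 3D array with an odd kernel, replicate pad
filter_axis <- function(img, kernel, axis) {
  d <- dim(img)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(img, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], dm[2] * dm[3])
  h <- (length(kernel) - 1L) %/% 2L
  pad <- m[c(rep(1L, h), seq_len(dm[1]), rep(dm[1], h)), , drop = FALSE]
  f <- stats::filter(pad, kernel, sides = 2)
  out <- f[h + seq_len(dm[1]), , drop = FALSE]
  dim(out) <- dm
  aperm(out, order(perm))
}

# separable running-max over a box of half-widths `half` (voxels per axis)
max_filter3d <- function(img, half) {
  for (ax in 1:3) img <- runmax_axis(img, half[ax], ax)
  img
}

runmax_axis <- function(img, h, axis) {
  d <- dim(img)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(img, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], dm[2] * dm[3])
  res <- m
  n <- dm[1]
  for (o in seq_len(h)) {
    res <- pmax(res, m[pmin(seq_len(n) + o, n), , drop = FALSE],
                m[pmax(seq_len(n) - o, 1L), , drop = FALSE])
  }
  dim(res) <- dm
  aperm(res, order(perm))
}

# least-squares 3D Gaussian fit around a candidate voxel (0-based index)
fit_gaussian3d <- function(image, idx0, voxel_size, params) {
  d <- dim(image)
  hw <- (params$fit_window - 1L) %/% 2L
  lo <- pmax(idx0 - hw, 0L)
  hi <- pmin(idx0 + hw, d - 1L)
  win <- image[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L,
               drop = FALSE]
  gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
  grid <- expand.grid(z = gz, y = gy, x = gx)
  v <- as.vector(win)

  s0 <- unname(pmax(params$smoothing_sigma / voxel_size, 0.6))
  p0 <- c(b = min(v), A = max(v) - min(v),
          cz = unname(idx0[1]), cy = unname(idx0[2]), cx = unname(idx0[3]),
          sz = s0[1], sy = s0[2], sx = s0[3])
  model <- function(p) {
    p["b"] + p["A"] * exp(-0.5 * (((grid$z - p["cz"]) / p["sz"])^2 +
                                  ((grid$y - p["cy"]) / p["sy"])^2 +
                                  ((grid$x - p["cx"]) / p["sx"])^2))
  }
  obj <- function(p) sum((v - model(p))^2)
  fit <- nlminb(p0, obj,
                lower = c(-Inf, 0, lo[1] - 1, lo[2] - 1, lo[3] - 1,
                          0.2, 0.2, 0.2),
                upper = c(Inf, Inf, hi[1] + 1, hi[2] + 1, hi[3] + 1,
                          4 * s0[1] + 2, 4 * s0[2] + 2, 4 * s0[3] + 2))
  p <- fit$par
  tss <- sum((v - mean(v))^2)
  quality <- if (tss == 0) 0 else max(0, min(1, 1 - fit$objective / tss))
  data.frame(channel = NA_character_, cell_id = NA_integer_,
             z_um = unname((p["cz"] + 0.5) * voxel_size[1]),
             y_um = unname((p["cy"] + 0.5) * voxel_size[2]),
             x_um = unname((p["cx"] + 0.5) * voxel_size[3]),
             intensity = unname(p["A"]),
             sigma_z_um = unname(p["sz"]) * voxel_size[1],
             sigma_y_um = unname(p["sy"]) * voxel_size[2],
             sigma_x_um = unname(p["sx"]) * voxel_size[3],
             quality = quality, compartment = "unassigned",
             stringsAsFactors = FALSE, row.names = NULL)
}
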