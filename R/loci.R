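#' Segment the tagged-locus signal of one channel
#'
#' Thresholds the image (robust z-score over median/MAD, or absolute) and
#' keeps the brightest connected component — one tagged locus is expected
#' per nucleus, so when several blobs pass the threshold the one with the
#' largest integrated intensity wins. An empty mask is a valid outcome
#' (undetectable tag), not an error.
#'
#' @param image 2D matrix or 3D array of intensities.
#' @param params a [detection_params()]; only the threshold settings are
#'   used here.
#' @return logical mask of the same shape (possibly all-`FALSE`).
#' @export
segment_locus_signal <- function(image, params = detection_params()) {
  is3d <- length(dim(image)) == 3L
  if (!is3d && length(dim(image)) != 2L)
    stop_mod("segment_locus_signal", "image", "must be 2D or 3D")
  thr <- switch(params$threshold_mode,
    "robust-zscore" = {
      m <- median(image); s <- mad(image)
      if (s == 0) s <- sd(image)
      if (is.na(s) || s == 0) Inf else m + params$threshold_value * s
    },
    "absolute" = params$threshold_value)
  binary <- image > thr
  if (!any(binary)) return(array(FALSE, dim(image)))
  labels <- label_components(binary)
  sums <- vapply(seq_len(max(labels)), function(l)
    sum(image[labels == l]), numeric(1))
  labels == which.max(sums)
}

# connected-component labelling (orthogonal connectivity) for 2D/3D
# logical arrays; small images only, iterative BFS
label_components <- function(binary) {
  d <- dim(binary)
  if (length(d) == 2L) d <- c(d, 1L)
  arr <- array(binary, d)
  labels <- array(0L, d)
  current <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  todo <- which(arr)
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0L) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      ind <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        nb <- ind + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (arr[lin] && labels[lin] == 0L) {
          labels[lin] <- current
          queue <- c(queue, lin)
        }
      }
    }
  }
  array(labels, dim(binary))
}

#' Classify a tagged locus pair from its two signal masks
#'
#' Overlap is the intersection area over the smaller signal's area. The
#' label is `co-localized` (fully overlapping) when overlap >=
#' `full_threshold`, `not co-localized` when overlap is 0 (no shared
#' pixel), `adjacent` (partially overlapping) otherwise. The default
#' `full_threshold` of 0.9 treats visually complete overlap as full,
#' absorbing single-pixel rasterization effects. Classification is
#' symmetric in the two masks; the centroid distance is reported as
#' auxiliary output only.
#'
#' @param mask_a,mask_b logical masks in one coordinate frame; both must
#'   be non-empty (cells with an undetectable tag are excluded upstream,
#'   see [score_locus_cohort()]).
#' @param full_threshold overlap at or above which the pair counts as
#'   fully co-localized.
#' @param pixel_size_um pixel edge (um) for the centroid distance.
#' @param cell_id carried into the result.
#' @return object of class `locus_pair_call`: list with `cell_id`,
#'   `overlap`, `centroid_distance_um`, `label`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
#' classify_pair(m, m)$label
#' @export
classify_pair <- function(mask_a, mask_b, full_threshold = 0.9,
                          pixel_size_um = 0.1, cell_id = NA_integer_) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_mod("classify_pair", "masks", "must share one coordinate frame")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na == 0L && nb == 0L)
    stop_mod("classify_pair", "masks", "both masks are empty")
  if (na == 0L || nb == 0L)
    stop_mod("classify_pair", "masks",
             "one mask is empty; exclude cells with an undetectable tag upstream")
  inter <- sum(mask_a & mask_b)
  overlap <- inter / min(na, nb)
  label <- if (overlap >= full_threshold) "co-localized"
           else if (inter == 0L) "not co-localized"
           else "adjacent"
  centroid <- function(m) colMeans(which(m, arr.ind = TRUE))
  cdist <- sqrt(sum((centroid(mask_a) - centroid(mask_b))^2)) *
    pixel_size_um
  structure(list(cell_id = cell_id, overlap = overlap,
                 centroid_distance_um = cdist, label = label),
            class = "locus_pair_call")
}

#' Tabulate locus-pair calls into class percentages
#'
#' Percentages over scored cells (summing to 100 within rounding). When
#' replicate labels are supplied, per-replicate percentages are averaged
#' and the replicate-wise standard deviation is reported, mirroring a
#' "three biological replicas, avg. +/- std.dev." histogram.
#'
#' @param calls list of `locus_pair_call` objects, or a character vector
#'   of labels.
#' @param replicate optional replicate label per call.
#' @return data.frame with `label, percent, n` (and `sd_percent` when
#'   replicates are given), rows in the fixed class order.
#' @export
tabulate_calls <- function(calls, replicate = NULL) {
  lv <- c("co-localized", "adjacent", "not co-localized")
  labels <- if (is.character(calls)) calls
            else vapply(calls, function(cl) cl$label, character(1))
  if (length(labels) == 0L)
    stop_mod("tabulate_calls", "calls", "need at least one call")
  labels <- factor(labels, levels = lv)
  if (is.null(replicate)) {
    counts <- table(labels)
    return(data.frame(label = lv,
                      percent = as.numeric(100 * counts / sum(counts)),
                      n = as.integer(counts), stringsAsFactors = FALSE))
  }
  stopifnot(length(replicate) == length(labels))
  per_rep <- vapply(split(labels, replicate), function(l)
    as.numeric(100 * table(l) / length(l)), numeric(3))
  data.frame(label = lv,
             percent = rowMeans(per_rep),
             sd_percent = apply(per_rep, 1L, sd),
             n = as.integer(table(labels)), stringsAsFactors = FALSE)
}

#' Segment and classify a simulated locus cohort
#'
#' Runs [segment_locus_signal()] on both channels of every cell and
#' [classify_pair()] on the masks. Cells where either tag is
#' undetectable (empty segmentation) are excluded and their number is
#' reported.
#'
#' @param cohort result of [simulate_locus_cohort()], or a list of
#'   locus-pair objects with `image_a`/`image_b`.
#' @param params threshold settings for segmentation. The default
#'   absolute threshold of half the nominal disk intensity suits the
#'   simulator's zero-background images.
#' @param full_threshold passed to [classify_pair()].
#' @return list with `calls` (list of `locus_pair_call`), `table` (from
#'   [tabulate_calls()]), `n_excluded`.
#' @export
score_locus_cohort <- function(cohort,
                               params = detection_params(
                                 threshold_mode = "absolute",
                                 threshold_value = 50),
                               full_threshold = 0.9) {
  pairs <- cohort$pairs %||% cohort
  calls <- list()
  n_excluded <- 0L
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    ma <- segment_locus_signal(p$image_a, params)
    mb <- segment_locus_signal(p$image_b, params)
    if (!any(ma) || !any(mb)) { n_excluded <- n_excluded + 1L; next }
    calls[[length(calls) + 1L]] <-
      classify_pair(ma, mb, full_threshold,
                    pixel_size_um = p$pixel_size_um %||% 0.1,
                    cell_id = i)
  }
  if (length(calls) == 0L)
    stop_mod("score_locus_cohort", "calls", "no scorable cells")
  list(calls = calls, table = tabulate_calls(calls),
       n_excluded = n_excluded)
}
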