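#' Assign spots to cells by mask lookup
#'
#' Sets each spot's `cell_id` to the label of the cell mask containing
#' its voxel (physical position divided by voxel size, floored). Spots
#' outside every cell mask stay unassigned (`NA`) and are excluded from
#' per-cell statistics downstream. Cell masks must be disjoint; this is
#' checked via [validate_geometry()].
#'
#' @param spots a spot table (as from [detect_spots()]) with `z_um, y_um,
#'   x_um` columns.
#' @param geometry a `cell_geometry`.
#' @return the spot table with `cell_id` filled in.
#' @export
assign_spots_to_cells <- function(spots, geometry) {
  stopifnot(is.data.frame(spots), inherits(geometry, "cell_geometry"))
  validate_geometry(geometry)
  if (nrow(spots) == 0L) return(spots)
  vs <- geometry$voxel_size
  vox <- cbind(floor(spots$z_um / vs[1]),
               floor(spots$y_um / vs[2]),
               floor(spots$x_um / vs[3]))
  cell_id <- rep(NA_integer_, nrow(spots))
  for (region in geometry$regions) {
    loc <- sweep(vox, 2L, region$offset, `-`) + 1L   # 1-based local index
    d <- dim(region$cell)
    inside <- loc[, 1] >= 1 & loc[, 1] <= d[1] &
              loc[, 2] >= 1 & loc[, 2] <= d[2] &
              loc[, 3] >= 1 & loc[, 3] <= d[3]
    w <- which(inside)
    if (length(w) == 0L) next
    hit <- region$cell[cbind(loc[w, 1], loc[w, 2], loc[w, 3])]
    cell_id[w[hit]] <- region$cell_id
  }
  spots$cell_id <- cell_id
  spots
}

#' Classify spots as nuclear or cytoplasmic
#'
#' A spot is `nuclear` if its voxel lies in the nucleus mask of its cell
#' (boundary voxels, being part of the mask, count as nuclear) and
#' `cytoplasmic` otherwise. Requires `cell_id` to be assigned; spots with
#' `NA` cell stay `"unassigned"`.
#'
#' @param spots spot table with `cell_id` assigned.
#' @param geometry a `cell_geometry`; every referenced cell must carry a
#'   nucleus mask.
#' @return the spot table with `compartment` filled in.
#' @export
classify_compartment <- function(spots, geometry) {
  stopifnot(is.data.frame(spots), inherits(geometry, "cell_geometry"))
  if (nrow(spots) == 0L) return(spots)
  vs <- geometry$voxel_size
  regions <- setNames(geometry$regions,
                      vapply(geometry$regions, function(r)
                        as.character(r$cell_id), character(1)))
  comp <- spots$compartment %||% rep("unassigned", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    cid <- spots$cell_id[i]
    if (is.na(cid)) { comp[i] <- "unassigned"; next }
    region <- regions[[as.character(cid)]]
    if (is.null(region))
      stop_mod("classify_compartment", "cell_id",
               sprintf("spot %d references unknown cell %s", i, cid))
    if (is.null(region$nucleus))
      stop_mod("classify_compartment", "nucleus",
               sprintf("cell %s lacks a nucleus mask", cid))
    loc <- floor(c(spots$z_um[i], spots$y_um[i], spots$x_um[i]) / vs) -
      region$offset + 1L
    d <- dim(region$nucleus)
    inside <- all(loc >= 1) && all(loc <= d)
    comp[i] <- if (inside && region$nucleus[loc[1], loc[2], loc[3]])
      "nuclear" else "cytoplasmic"
  }
  spots$compartment <- comp
  spots
}
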