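#' Generate non-overlapping cell and nucleus masks
#'
#' Lays `n_cells` ellipsoidal cells out on a square grid with a fixed
#' margin, rasterizes each cell and its nucleus at `voxel_size`, and
#' returns one region per cell. Masks are stored per cell as logical
#' arrays over the cell's bounding box together with the box's offset in
#' the global voxel frame, which keeps memory linear in cell volume
#' rather than field volume.
#'
#' Coordinate conventions used package-wide: voxel indices are 0-based in
#' axis order `(z, y, x)`; the physical position of voxel `i` spans
#' `[i, i+1) * voxel_size` um with its centre at `(i + 0.5) * voxel_size`.
#'
#' @param config a [sim_config()].
#' @param margin_um gap between neighbouring cell bounding boxes (um).
#' @return An object of class `cell_geometry`: a list with `regions` (a
#'   list of `cell_region` objects with fields `cell_id`, `cell`,
#'   `nucleus`, `offset`, `voxel_size`, `center_um`), `field_dim` (global
#'   voxel dimensions, `(z, y, x)`), and `voxel_size`.
#' @examples
#' geom <- generate_cell_geometry(sim_config(n_cells = 2))
#' length(geom$regions)
#' @export
generate_cell_geometry <- function(config, margin_um = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  vs <- config$voxel_size
  r <- config$cell_radius
  rn <- config$nucleus_radius

  # per-cell bounding box in voxels
  box <- ceiling(2 * (r + margin_um / 2) / vs)
  if (any(box < 3))
    stop_mod("generate_cell_geometry", "cell_radius",
             sprintf("cell of semi-axes (%s) um cannot be rasterized at voxel (%s) um",
                     paste(r, collapse = ", "), paste(vs, collapse = ", ")))
  if (n == 0L)
    return(structure(list(regions = list(), field_dim = c(z = 0, y = 0, x = 0),
                          voxel_size = vs),
                     class = "cell_geometry"))

  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  field_dim <- c(z = box[["z"]],
                 y = box[["y"]] * nrow_grid,
                 x = box[["x"]] * ncol_grid)

  regions <- vector("list", n)
  for (k in seq_len(n)) {
    gy <- (k - 1L) %/% ncol_grid
    gx <- (k - 1L) %% ncol_grid
    offset <- c(z = 0, y = gy * box[["y"]], x = gx * box[["x"]])
    center_vox <- box / 2           # local, continuous voxel units
    center_um <- (offset + center_vox) * vs

    regions[[k]] <- rasterize_region(k, box, offset, center_vox, vs, r, rn)
  }
  structure(list(regions = regions, field_dim = field_dim, voxel_size = vs),
            class = "cell_geometry")
}

# rasterize one ellipsoidal cell + nucleus into its bounding box
rasterize_region <- function(cell_id, box, offset, center_vox, vs, r, rn) {
  # voxel-centre coordinates relative to the cell centre, in um
  zc <- ((seq_len(box[["z"]]) - 0.5) - center_vox[["z"]]) * vs[["z"]]
  yc <- ((seq_len(box[["y"]]) - 0.5) - center_vox[["y"]]) * vs[["y"]]
  xc <- ((seq_len(box[["x"]]) - 0.5) - center_vox[["x"]]) * vs[["x"]]
  qz <- (zc / r[["z"]])^2
  qy <- (yc / r[["y"]])^2
  qx <- (xc / r[["x"]])^2
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  cell <- q <= 1
  if (!any(cell))
    stop_mod("generate_cell_geometry", "cell_radius",
             "cell mask is empty at this voxel_size")
  qn <- outer(outer((zc / rn[["z"]])^2, (yc / rn[["y"]])^2, `+`),
              (xc / rn[["x"]])^2, `+`)
  nucleus <- qn <= 1
  if (!any(nucleus))
    stop_mod("generate_cell_geometry", "nucleus_radius",
             "nucleus mask is empty at this voxel_size")
  structure(list(cell_id = as.integer(cell_id),
                 cell = cell, nucleus = nucleus,
                 offset = offset, voxel_size = vs,
                 center_um = (offset + center_vox) * vs),
            class = "cell_region")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("cell_geometry:", length(x$regions), "cells, field",
      paste(x$field_dim, collapse = " x "), "voxels\n")
  invisible(x)
}

#' Validate that cell masks are pairwise disjoint
#'
#' @param geometry a `cell_geometry`.
#' @return `TRUE` invisibly; errors if any two cell masks share a voxel.
#' @export
validate_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  regs <- geometry$regions
  n <- length(regs)
  if (n < 2L) return(invisible(TRUE))
  lo <- t(vapply(regs, function(r) r$offset, numeric(3)))
  hi <- lo + t(vapply(regs, function(r) dim(r$cell), numeric(3)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    l <- pmax(lo[i, ], lo[j, ]); h <- pmin(hi[i, ], hi[j, ])
    if (any(h <= l)) next
    sub <- function(r) {
      a <- l - r$offset + 1L; b <- h - r$offset
      r$cell[a[1]:b[1], a[2]:b[2], a[3]:b[3], drop = FALSE]
    }
    if (any(sub(regs[[i]]) & sub(regs[[j]])))
      stop_mod("geometry", "cell masks",
               sprintf("cells %d and %d overlap", regs[[i]]$cell_id,
                       regs[[j]]$cell_id))
  }
  invisible(TRUE)
}

# physical volume of a mask in um^3
mask_volume_um3 <- function(mask, voxel_size) {
  sum(mask) * prod(voxel_size)
}
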