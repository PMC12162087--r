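# pRF-mapping aperture movies: translating bars, rotating wedges and
# expanding/contracting rings rasterized on an S x S visual-field grid.
#
# Masks are stored as a cells x timepoints 0/1 matrix together with the cell
# center coordinates, which is the layout the pRF forward model consumes
# (response(t) = mask(t) . gaussian).

new_aperture_movie <- function(masks, x, y, radius, kind, tr, grid_size) {
  cell <- (2 * radius / (grid_size - 1))^2
  structure(list(masks = masks, x = x, y = y, radius = radius, kind = kind,
                 tr = tr, grid_size = grid_size, cell_area = cell,
                 n_time = ncol(masks)),
            class = "aperture_movie")
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf("<aperture_movie> kind = %s, %d timepoints, radius %g deg, %dx%d raster\n",
              x$kind, x$n_time, x$radius, x$grid_size, x$grid_size))
  invisible(x)
}

#' Generate pRF-mapping aperture movies
#'
#' Binary visual-field masks per timepoint, clipped to the circular field of
#' the given radius:
#' * `bar`: a bar translating across the field in `n_steps` positions per
#'   sweep; one sweep per entry of `directions` (deg, direction of travel).
#'   The default bar width tiles the field exactly (`2 * radius / n_steps`).
#' * `wedge`: an angular sector rotating in `n_steps` positions, one
#'   counterclockwise and one clockwise revolution.
#' * `ring`: an annulus expanding and then contracting in `n_steps` radial
#'   positions.
#'
#' Each position is held for `round(step_s / tr)` timepoints.
#'
#' @param kind `"bar"`, `"wedge"` or `"ring"`.
#' @param radius Field radius in deg (default 12.2, the enlarged mapping
#'   aperture).
#' @param grid_size Raster size per side (>= 32).
#' @param n_steps Positions per sweep (>= 4).
#' @param tr Seconds per timepoint.
#' @param step_s Seconds each position is held (default 3 s: an 8-position
#'   sweep spans 24 s).
#' @param width Bar width (deg); ignored for other kinds.
#' @param directions Bar sweep directions in deg; default the 8 cardinal and
#'   oblique directions.
#' @param wedge_deg Angular width of the wedge sector.
#' @param ring_thickness Radial thickness of the ring.
#' @return An `aperture_movie`.
#' @export
gen_prf_apertures <- function(kind = c("bar", "wedge", "ring"), radius = 12.2,
                              grid_size = 101, n_steps = 8, tr = 1, step_s = 3,
                              width = 2 * radius / n_steps,
                              directions = seq(0, 315, by = 45),
                              wedge_deg = 45, ring_thickness = radius / 4) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("radius must be positive")
  if (grid_size < 32) stop("grid_size must be >= 32")
  if (n_steps < 4) stop("n_steps must be >= 4")
  gx <- seq(-radius, radius, length.out = grid_size)
  xy <- expand.grid(x = gx, y = gx)
  x <- xy$x; y <- xy$y
  infield <- x^2 + y^2 <= radius^2
  hold <- max(1L, as.integer(round(step_s / tr)))

  step_masks <- switch(kind,
    bar = {
      centers <- -radius + (seq_len(n_steps) - 0.5) * 2 * radius / n_steps
      out <- list()
      for (a in directions) {
        u <- x * cos(a * pi / 180) + y * sin(a * pi / 180)
        for (p in centers)
          out[[length(out) + 1]] <- infield & abs(u - p) <= width / 2 + 1e-9
      }
      out
    },
    wedge = {
      ang <- atan2(y, x) * 180 / pi
      centers <- (seq_len(n_steps) - 1) * 360 / n_steps
      sector <- function(ctr) {
        d <- abs(((ang - ctr + 180) %% 360) - 180)
        infield & d <= wedge_deg / 2 + 1e-9
      }
      c(lapply(centers, sector), lapply(rev(centers), sector))
    },
    ring = {
      r <- sqrt(x^2 + y^2)
      outer_r <- seq_len(n_steps) / n_steps * radius
      ann <- function(ro) infield & r <= ro & r > pmax(0, ro - ring_thickness) - 1e-12
      c(lapply(outer_r, ann), lapply(rev(outer_r), ann))
    })

  masks <- do.call(cbind, lapply(step_masks, function(m) {
    matrix(rep(as.numeric(m), hold), ncol = hold)
  }))
  new_aperture_movie(masks, x, y, radius, kind, tr, grid_size)
}

#' Concatenate aperture movies in time
#' @param ... `aperture_movie`s on identical rasters.
#' @return An `aperture_movie`.
#' @export
concat_apertures <- function(...) {
  aps <- list(...)
  a1 <- aps[[1]]
  for (a in aps[-1])
    if (a$grid_size != a1$grid_size || a$radius != a1$radius || a$tr != a1$tr)
      stop("aperture movies must share raster, radius and tr")
  new_aperture_movie(do.call(cbind, lapply(aps, `[[`, "masks")),
                     a1$x, a1$y, a1$radius,
                     paste(vapply(aps, `[[`, "", "kind"), collapse = "+"),
                     a1$tr, a1$grid_size)
}

#' Stimulated area per timepoint
#' @param apertures An `aperture_movie`.
#' @return Numeric vector of mask areas in deg^2.
#' @export
aperture_area <- function(apertures) {
  colSums(apertures$masks) * apertures$cell_area
}

#' Export an aperture movie as dense binary + JSON sidecar
#'
#' Writes `<prefix>.bin` (doubles, column order = timepoints) and
#' `<prefix>.json` describing grid size, radius and tr.
#'
#' @param apertures An `aperture_movie`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_apertures <- function(apertures, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.numeric(apertures$masks), con)
  close(con)
  write_sidecar(list(grid_size = apertures$grid_size, radius = apertures$radius,
                     tr = apertures$tr, n_time = apertures$n_time,
                     kind = apertures$kind),
                paste0(prefix, ".json"))
  invisible(prefix)
}
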