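# Synthetic cortical hemisphere: a flat vertex grid carrying ground-truth
# region labels and per-vertex tuning. Column index runs posterior->anterior,
# row index dorsal->ventral, so "anterior and/or inferior" means greater
# column and/or greater row.
#
# The default geometry places a V1-like control patch posteriorly, an
# hMT/MST-like region of 296 vertices, and a pFST-like crescent of 95
# vertices wrapped around its anterior/inferior flank — the vertex counts
# behind the example-hemisphere degrees of freedom (one-sample df 295/94,
# two-sample df 389).

#' Configuration for the synthetic hemisphere generator
#'
#' Per-region tuning means follow the study's qualitative ordering: the
#' hMT/MST-like region has the strongest 2D-motion gain, strong opponency
#' suppression, high myelination (short T1) and mid-sized pRFs; the pFST-like
#' region has the strongest coherent-3D gain, weak opponency, lower
#' myelination and very large pRFs; the V1-like control has small pRFs.
#' T1 means (background 1.331 s, hMT/MST 1.19 s, pFST 1.26 s) bracket R1
#' rates of 0.751 / 0.84 / 0.79 s^-1.
#'
#' @param grid Grid dimensions (rows, cols).
#' @param regions Named list (`V1like`, `hMTMST`, `pFST`) of
#'   `list(center = c(row, col), n = size)`.
#' @param means Named list of per-region tuning means; each entry is a vector
#'   with components `background`, `V1like`, `hMTMST`, `pFST`.
#' @param tuning_cv Coefficient of variation of the multiplicative vertex
#'   spread applied to gains, opponency and pRF size.
#' @param t1_sd Absolute SD (seconds) of vertex T1 spread.
#' @param smooth_ell Correlation length (vertices) of the spatial tuning
#'   fields; 0 gives iid spread.
#' @param ecc_range Per-region radius (deg) of the disk pRF centers are drawn
#'   from.
#' @param atlas_jitter Maximum |offset| (vertices) of the synthetic atlas
#'   labels relative to the true labels; 0 makes the atlas exact.
#' @return A config list for [make_hemisphere()].
#' @export
hemisphere_config <- function(
    grid = c(96, 96),
    regions = list(
      V1like = list(center = c(30, 14), n = 200),
      hMTMST = list(center = c(36, 58), n = 296),
      pFST   = list(center = c(46, 66), n = 95)),
    means = list(
      gain2d    = c(background = 0,     V1like = 1.2,  hMTMST = 2.0,  pFST = 0.8),
      gain3d    = c(background = 0,     V1like = 0.2,  hMTMST = 1.0,  pFST = 1.5),
      coh_sel   = c(background = 0,     V1like = 0.1,  hMTMST = 0.5,  pFST = 1.0),
      opponency = c(background = 0,     V1like = 0.05, hMTMST = 0.6,  pFST = 0.15),
      prf_gain  = c(background = 0,     V1like = 2.5,  hMTMST = 2.0,  pFST = 1.5),
      t1        = c(background = 1.331, V1like = 1.28, hMTMST = 1.19, pFST = 1.26),
      prf_sigma = c(background = 3,     V1like = 1,    hMTMST = 4,    pFST = 20)),
    tuning_cv = 0.15, t1_sd = 0.05, smooth_ell = 2,
    ecc_range = c(background = 8, V1like = 8, hMTMST = 8, pFST = 4),
    atlas_jitter = 2) {
  list(grid = grid, regions = regions, means = means, tuning_cv = tuning_cv,
       t1_sd = t1_sd, smooth_ell = smooth_ell, ecc_range = ecc_range,
       atlas_jitter = atlas_jitter)
}

region_names <- c("background", "V1like", "hMTMST", "pFST")

# n nearest free vertices to a center (Euclidean; ties by vertex index).
nearest_patch <- function(center, n, dims, taken) {
  rows <- rep(seq_len(dims[1]), times = dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  ord <- order(d2, seq_along(d2))
  ord <- ord[!taken[ord]]
  if (length(ord) < n) stop("region of size ", n, " does not fit on the grid")
  ord[seq_len(n)]
}

shift_mask <- function(mask, dr, dc) {
  dims <- dim(mask)
  out <- matrix(FALSE, dims[1], dims[2])
  r <- seq_len(dims[1]); c <- seq_len(dims[2])
  rs <- r + dr; cs <- c + dc
  ok_r <- rs >= 1 & rs <= dims[1]; ok_c <- cs >= 1 & cs <= dims[2]
  out[rs[ok_r], cs[ok_c]] <- mask[r[ok_r], c[ok_c]]
  out
}

dilate4 <- function(mask) {
  mask | shift_mask(mask, 1, 0) | shift_mask(mask, -1, 0) |
    shift_mask(mask, 0, 1) | shift_mask(mask, 0, -1)
}

erode4 <- function(mask) {
  mask & shift_mask(mask, 1, 0) & shift_mask(mask, -1, 0) &
    shift_mask(mask, 0, 1) & shift_mask(mask, 0, -1)
}

#' Generate a synthetic hemisphere
#'
#' Lays out the ground-truth regions, draws smoothly varying per-vertex
#' tuning (2D/3D gains, coherence selectivity, opponency index, pRF center
#' and size, T1), and builds a jittered "atlas" label set standing in for an
#' anatomical parcellation (true labels displaced by a seeded offset plus one
#' boundary dilation/erosion, emulating atlas-function misalignment).
#' Deterministic given `seed`.
#'
#' @param config From [hemisphere_config()].
#' @param seed Integer seed.
#' @return A `synthetic_hemisphere`: list with `shape`, `region` (factor
#'   vector in column-major vertex order), `region_matrix`, `tuning`
#'   (data.frame: row, col, region, gain2d, gain3d, coh_sel, opponency,
#'   prf_x0, prf_y0, prf_sigma, t1), `atlas` (factor vector), `config`,
#'   `seed`.
#' @export
make_hemisphere <- function(config = hemisphere_config(), seed = 1) {
  # tolerate JSON-round-tripped configs where named vectors return as lists
  config$grid <- unlist(config$grid)
  config$means <- lapply(config$means, unlist)
  config$ecc_range <- unlist(config$ecc_range)
  config$regions <- lapply(config$regions, function(r)
    list(center = unlist(r$center), n = unlist(r$n)))
  dims <- config$grid
  nv <- prod(dims)
  for (rn in names(config$regions)) {
    ctr <- config$regions[[rn]]$center
    if (ctr[1] < 1 || ctr[1] > dims[1] || ctr[2] < 1 || ctr[2] > dims[2])
      stop("region ", rn, " center lies outside the grid")
  }
  if (sum(vapply(config$regions, `[[`, 0, "n")) > nv)
    stop("regions exceed the grid")

  set.seed(derive_seed(seed, "hemisphere"))
  taken <- rep(FALSE, nv)
  region <- rep("background", nv)
  # hMT/MST first, then pFST (wraps around it), then the V1-like control
  for (rn in c("hMTMST", "pFST", "V1like")) {
    idx <- nearest_patch(config$regions[[rn]]$center, config$regions[[rn]]$n,
                         dims, taken)
    region[idx] <- rn
    taken[idx] <- TRUE
  }
  region <- factor(region, levels = region_names)
  rows <- rep(seq_len(dims[1]), times = dims[2])
  cols <- rep(seq_len(dims[2]), each = dims[1])

  # smooth multiplicative spread fields, one per tuning dimension
  fld <- function() as.vector(smooth_field(dims[1], dims[2], config$smooth_ell))
  m <- config$means
  per_region <- function(v) unname(v[as.character(region)])
  gain2d <- per_region(m$gain2d) * (1 + config$tuning_cv * fld())
  gain3d <- per_region(m$gain3d) * (1 + config$tuning_cv * fld())
  coh_sel <- clamp(per_region(m$coh_sel), 0, 1)
  opponency <- clamp(per_region(m$opponency) * (1 + config$tuning_cv * fld()), 0, 1)
  prf_sigma <- clamp(per_region(m$prf_sigma) * (1 + config$tuning_cv * fld()), 0.05, Inf)
  prf_gain <- per_region(m$prf_gain) * (1 + config$tuning_cv * fld())
  t1 <- per_region(m$t1) + config$t1_sd * fld()

  ecc_max <- unname(config$ecc_range[as.character(region)])
  u <- stats::runif(nv); th <- stats::runif(nv, 0, 2 * pi)
  r <- ecc_max * sqrt(u)
  prf_x0 <- r * cos(th); prf_y0 <- r * sin(th)

  # invariant checks on the configured ordering (the realized per-seed means
  # fluctuate around these; the configuration itself must respect them)
  if (!(m$gain2d["hMTMST"] > m$gain2d["pFST"])) stop("config violates gain2d ordering")
  if (!(m$gain3d["pFST"] >= m$gain3d["hMTMST"])) stop("config violates gain3d ordering")
  if (!(m$opponency["hMTMST"] > m$opponency["pFST"])) stop("config violates opponency ordering")
  if (!(m$t1["hMTMST"] < m$t1["pFST"] && m$t1["pFST"] < m$t1["background"]))
    stop("config violates T1 ordering")
  if (!(m$prf_sigma["pFST"] > m$prf_sigma["hMTMST"] &&
          m$prf_sigma["hMTMST"] > m$prf_sigma["V1like"]))
    stop("config violates pRF size ordering")
  ctr_of <- function(rn) c(mean(rows[region == rn]), mean(cols[region == rn]))
  ch <- ctr_of("hMTMST"); cf <- ctr_of("pFST")
  if (!(cf[2] > ch[2] || cf[1] > ch[1]))
    stop("pFST centroid is not anterior and/or inferior to hMT/MST")

  # jittered atlas: shift each region, then one random dilation or erosion
  atlas <- rep("background", nv)
  region_mat <- matrix(as.character(region), dims[1], dims[2])
  for (rn in c("hMTMST", "pFST", "V1like")) {
    mask <- region_mat == rn
    if (config$atlas_jitter > 0) {
      off <- sample(-config$atlas_jitter:config$atlas_jitter, 2, replace = TRUE)
      mask <- shift_mask(mask, off[1], off[2])
      mask <- if (stats::runif(1) < 0.5) dilate4(mask) else erode4(mask)
    }
    free <- atlas == "background"
    atlas[as.vector(mask) & free] <- rn
  }

  tuning <- data.frame(vertex = seq_len(nv), row = rows, col = cols,
                       region = as.character(region),
                       gain2d = gain2d, gain3d = gain3d, coh_sel = coh_sel,
                       opponency = opponency,
                       prf_x0 = prf_x0, prf_y0 = prf_y0, prf_sigma = prf_sigma,
                       prf_gain = prf_gain, t1 = t1)
  structure(list(shape = dims, region = region,
                 region_matrix = region_mat,
                 tuning = tuning,
                 atlas = factor(atlas, levels = region_names),
                 config = config, seed = seed),
            class = "synthetic_hemisphere")
}

#' @export
print.synthetic_hemisphere <- function(x, ...) {
  tab <- table(x$region)
  cat(sprintf("<synthetic_hemisphere> %dx%d grid; %s\n", x$shape[1], x$shape[2],
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Logical mask of a ground-truth (or atlas) region
#' @param hemi A `synthetic_hemisphere`.
#' @param region Region name.
#' @param atlas Use the jittered atlas labels instead of the truth.
#' @return Logical matrix in grid shape.
#' @export
region_mask <- function(hemi, region, atlas = FALSE) {
  lab <- if (atlas) hemi$atlas else hemi$region
  matrix(lab == region, hemi$shape[1], hemi$shape[2])
}

#' Write the hemisphere ground truth as CSV
#' @param hemi A `synthetic_hemisphere`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hemisphere_csv <- function(hemi, path) {
  d <- hemi$tuning
  d$atlas <- as.character(hemi$atlas)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
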