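# Independent oracles and shared fixtures.
#
# The oracles are written from first principles (hand formulas, brute-force
# enumeration) and never call the package code paths they check.

# --- t statistics from the textbook formulas -------------------------------

hand_one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  (mean(x) - mu) / (sd(x) / sqrt(n))
}

hand_pooled_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

hand_paired_t <- function(a, b) hand_one_sample_t(a - b)

# --- normal-equations least squares (GLM oracle) ---------------------------

normal_eq_betas <- function(X, y) solve(crossprod(X), crossprod(X, y))

# --- brute-force pRF grid search oracle ------------------------------------
# Scores every (x0, y0, sigma) candidate by direct forward simulation and
# squared correlation; first-encountered maximum in row-major (x0, y0, sigma)
# order.
brute_prf_grid <- function(y, apertures, xs, sigmas, kernel) {
  best <- NULL; best_r2 <- -Inf
  for (x0 in xs) for (y0 in xs) for (s in sigmas) {
    g <- exp(-((apertures$x - x0)^2 + (apertures$y - y0)^2) / (2 * s^2)) *
      apertures$cell_area / (2 * pi * s^2)
    neural <- as.numeric(crossprod(apertures$masks, g))
    pred <- fstloc::conv_ts(neural, kernel)
    if (sd(pred) < 1e-12) next
    r2 <- cor(pred, y)^2
    if (is.finite(r2) && r2 > best_r2 + 1e-12) {
      best_r2 <- r2
      best <- c(x0 = x0, y0 = y0, sigma = s)
    }
  }
  list(par = best, r2 = best_r2)
}

# --- shared fixtures (built once per session, cached) ----------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# reduced-resolution sweeping-bar protocol used by the pRF fitting and bias
# simulation tests (61-cell raster, 4 cardinal sweep directions, 96 TRs)
bar_ap <- function() fixture("bar_ap", function()
  gen_prf_apertures("bar", radius = 12.2, grid_size = 61, n_steps = 8,
                    tr = 1, step_s = 3, directions = c(0, 90, 180, 270)))

bar_grid <- function() fixture("bar_grid", function() prf_fit_grid(bar_ap()))

# combined bar + wedge + ring mapping protocol (the model-comparison setting)
map_ap <- function() fixture("map_ap", function() {
  concat_apertures(
    bar_ap(),
    gen_prf_apertures("wedge", 12.2, 61, 8, 1, 3),
    gen_prf_apertures("ring", 12.2, 61, 8, 1, 3))
})

map_grid <- function() fixture("map_grid", function() prf_fit_grid(map_ap()))

# simulate a mapping-run series for one vertex: peak-normalized prediction
# at amplitude `amp` plus iid noise
sim_map_series <- function(apertures, x0, y0, sigma, amp = 1, noise = 0,
                           seed = 1) {
  p <- predict_prf(apertures, x0, y0, sigma)
  pk <- max(abs(p))
  if (pk > 0) p <- p / pk
  if (noise > 0) {
    set.seed(seed)
    p <- amp * p + rnorm(length(p), sd = noise)
  } else p <- amp * p
  p
}
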