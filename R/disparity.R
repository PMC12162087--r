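# Changing-disparity stereomotion trajectories for the 3D-motion localizer.
#
# The 3D percept is carried purely by the temporal coherence of binocular
# disparity: a central disk and a surrounding annulus move in antiphase
# between the near and far sides of the volume (+/- 18 arcmin), reversing
# direction every second. The scrambled control permutes whole stereo frame
# pairs, preserving the set of disparities shown (the same static depth
# content) while abolishing coherent motion in depth.

#' Generate a center/surround disparity trajectory
#'
#' Coherent condition: the center-surface disparity follows a triangle wave of
#' amplitude `amp_arcmin` and period 2 s (constant-speed motion in depth with
#' a direction reversal every second), and the surround is its negation.
#' Scrambled condition: a seeded permutation of the coherent stereo frame
#' pairs, re-shuffled within each 1-s segment so that every relative-disparity
#' magnitude of the cycle still appears every second.
#'
#' @param condition `"coherent"` or `"scrambled"`.
#' @param frame_rate Frames per second.
#' @param duration Seconds; must be a multiple of the 2 s cycle.
#' @param seed Integer seed (used by the scrambled permutation).
#' @param amp_arcmin Disparity amplitude in arcmin.
#' @return A `disparity_trajectory`: list with `frame_rate`,
#'   `center_disparity`, `surround_disparity` (arcmin per frame), `condition`,
#'   and for the scrambled condition the permutation `order` applied.
#' @export
gen_disparity_trajectory <- function(condition = c("coherent", "scrambled"),
                                     frame_rate = 120, duration, seed = 1,
                                     amp_arcmin = 18) {
  condition <- match.arg(condition)
  cycle <- 2
  if (abs(duration / cycle - round(duration / cycle)) > 1e-9)
    stop("duration must be a multiple of the 2 s toward/away cycle")
  n <- round(duration * frame_rate)
  tt <- (seq_len(n) - 1) / frame_rate
  phase <- tt %% cycle
  center <- ifelse(phase < 1, amp_arcmin - 2 * amp_arcmin * phase,
                   -amp_arcmin + 2 * amp_arcmin * (phase - 1))
  ord <- seq_len(n)
  if (condition == "scrambled") {
    set.seed(derive_seed(seed, "scramble"))
    fps <- round(frame_rate)
    for (s in seq_len(n %/% fps)) {
      idx <- ((s - 1) * fps + 1):(s * fps)
      ord[idx] <- idx[sample.int(length(idx))]
    }
    center <- center[ord]
  }
  structure(list(frame_rate = frame_rate,
                 center_disparity = center,
                 surround_disparity = -center,
                 condition = condition,
                 order = ord),
            class = "disparity_trajectory")
}

#' @export
print.disparity_trajectory <- function(x, ...) {
  cat(sprintf("<disparity_trajectory> %s, %d frames @ %g Hz, |d| <= %.1f arcmin\n",
              x$condition, length(x$center_disparity), x$frame_rate,
              max(abs(x$center_disparity))))
  invisible(x)
}
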