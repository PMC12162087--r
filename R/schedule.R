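# Block schedules for the three localizer experiments.
#
# A schedule is an ordered set of non-overlapping condition blocks on a TR
# grid; it is the single description of a run consumed both by the stimulus
# generators (at display frame resolution) and by the BOLD simulator / GLM
# (at TR resolution, through per-TR condition labels).

new_block_schedule <- function(blocks, total_duration, tr) {
  structure(list(blocks = blocks, total_duration = total_duration, tr = tr),
            class = "block_schedule")
}

#' Validate a block schedule
#'
#' Checks the schedule invariants: blocks sorted by onset and non-overlapping,
#' onsets/durations integer multiples of the TR, and total duration at least
#' the end of the last block.
#'
#' @param x A `block_schedule`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_schedule <- function(x) {
  stopifnot(inherits(x, "block_schedule"))
  b <- x$blocks
  if (nrow(b) == 0) stop("schedule has no blocks")
  if (is.unsorted(b$onset, strictly = FALSE)) stop("blocks are not sorted by onset")
  ends <- b$onset + b$duration
  if (any(b$onset[-1] < ends[-nrow(b)] - 1e-9)) stop("blocks overlap")
  mult <- c(b$onset, b$duration) / x$tr
  if (any(abs(mult - round(mult)) > 1e-9)) stop("onsets/durations are not multiples of tr")
  if (x$total_duration < ends[nrow(b)] - 1e-9) stop("total_duration shorter than last block")
  invisible(x)
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> %d blocks, %.0f s total (tr = %g s)\n",
              nrow(x$blocks), x$total_duration, x$tr))
  cat(sprintf("  conditions: %s\n", paste(unique(x$blocks$condition), collapse = ", ")))
  invisible(x)
}

#' Stimulus duration of a schedule (excluding blank blocks)
#' @param schedule A `block_schedule`.
#' @return Seconds of non-blank stimulation.
#' @export
stimulus_duration <- function(schedule) {
  b <- schedule$blocks
  sum(b$duration[b$condition != "blank"])
}

#' Build the 2D-motion localizer schedule
#'
#' Alternating moving/static blocks over the four motion directions
#' (radial-in, radial-out, clockwise, counterclockwise), each direction
#' repeated `reps_per_direction` times, followed by a final blank block.
#' With the defaults (15 s blocks, 3 repetitions) the stimulus portion lasts
#' 6 minutes.
#'
#' @param block_s Block duration in seconds (> 0).
#' @param reps_per_direction Repetitions of each motion direction (>= 1).
#' @param tr Repetition time in seconds (blocks must be TR multiples).
#' @param blank_s Duration of the trailing blank block.
#' @return A `block_schedule` with labels `radial_in`, `radial_out`, `cw`,
#'   `ccw`, `static` and `blank`.
#' @export
build_2d_schedule <- function(block_s = 15, reps_per_direction = 3, tr = 1,
                              blank_s = 15) {
  if (block_s <= 0) stop("block_s must be positive")
  if (reps_per_direction < 1) stop("reps_per_direction must be >= 1")
  directions <- c("radial_in", "radial_out", "cw", "ccw")
  conds <- character(0)
  for (r in seq_len(reps_per_direction))
    for (d in directions) conds <- c(conds, d, "static")
  conds <- c(conds, "blank")
  durs <- c(rep(block_s, length(conds) - 1), blank_s)
  onsets <- cumsum(c(0, durs[-length(durs)]))
  sched <- new_block_schedule(
    data.frame(condition = conds, onset = onsets, duration = durs),
    total_duration = sum(durs), tr = tr)
  validate_schedule(sched)
  sched
}

#' Build the 3D-motion (stereomotion) localizer schedule
#'
#' Strict alternation of coherent-stereomotion and temporally scrambled
#' blocks (`reps` of each), followed by a trailing blank block. With the
#' defaults (10 s blocks, 15 repetitions) the stimulus portion lasts 5 min.
#'
#' @inheritParams build_2d_schedule
#' @param reps Repetitions of each condition (>= 1).
#' @return A `block_schedule` with labels `coherent`, `scrambled`, `blank`.
#' @export
build_3d_schedule <- function(block_s = 10, reps = 15, tr = 1, blank_s = 15) {
  if (block_s <= 0) stop("block_s must be positive")
  if (reps < 1) stop("reps must be >= 1")
  conds <- c(rep(c("coherent", "scrambled"), reps), "blank")
  durs <- c(rep(block_s, 2 * reps), blank_s)
  onsets <- cumsum(c(0, durs[-length(durs)]))
  sched <- new_block_schedule(
    data.frame(condition = conds, onset = onsets, duration = durs),
    total_duration = sum(durs), tr = tr)
  validate_schedule(sched)
  sched
}

#' Build the opponent-motion schedule
#'
#' Strict alternation of unpaired- and paired-dot blocks. The default
#' (15 s blocks, 21 blocks) gives the 5 m 15 s scan.
#'
#' @inheritParams build_2d_schedule
#' @param n_blocks Number of blocks (>= 2).
#' @param start First condition, `"unpaired"` (default) or `"paired"`.
#' @return A `block_schedule` with labels `unpaired` and `paired`.
#' @export
build_opponent_schedule <- function(block_s = 15, n_blocks = 21, tr = 1,
                                    start = c("unpaired", "paired")) {
  if (block_s <= 0) stop("block_s must be positive")
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  start <- match.arg(start)
  other <- setdiff(c("unpaired", "paired"), start)
  conds <- rep(c(start, other), length.out = n_blocks)
  onsets <- (seq_len(n_blocks) - 1) * block_s
  sched <- new_block_schedule(
    data.frame(condition = conds, onset = onsets, duration = rep(block_s, n_blocks)),
    total_duration = n_blocks * block_s, tr = tr)
  validate_schedule(sched)
  sched
}

#' Per-TR condition labels of a schedule
#'
#' @param schedule A `block_schedule`.
#' @param n_tr Number of TRs; defaults to `ceiling(total_duration / tr)`.
#' @return Character vector of length `n_tr`; gaps are labelled `"blank"`.
#' @export
schedule_labels <- function(schedule, n_tr = NULL) {
  tr <- schedule$tr
  if (is.null(n_tr)) n_tr <- ceiling(schedule$total_duration / tr)
  t0 <- (seq_len(n_tr) - 1) * tr
  lab <- rep("blank", n_tr)
  b <- schedule$blocks
  for (i in seq_len(nrow(b))) {
    sel <- t0 >= b$onset[i] - 1e-9 & t0 < b$onset[i] + b$duration[i] - 1e-9
    lab[sel] <- b$condition[i]
  }
  lab
}

#' Condition label at an arbitrary time
#' @param schedule A `block_schedule`.
#' @param t Time in seconds.
#' @return Character label (`"blank"` outside any block).
#' @export
label_at_time <- function(schedule, t) {
  b <- schedule$blocks
  i <- which(t >= b$onset - 1e-9 & t < b$onset + b$duration - 1e-9)
  if (length(i) == 0) "blank" else b$condition[i[1]]
}

#' Write a schedule as a BIDS-style events table
#'
#' Tab-separated file with columns `onset`, `duration`, `trial_type`.
#'
#' @param schedule A `block_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  d <- data.frame(onset = schedule$blocks$onset,
                  duration = schedule$blocks$duration,
                  trial_type = schedule$blocks$condition)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
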