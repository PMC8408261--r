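#' Temporal slot grid of a trial
#'
#' A trial is divided into `n_slots` contiguous slots of equal duration.
#' Slot `k` (1-based) spans `[(k-1) * slot_duration, k * slot_duration)`;
#' the item occupying slot `k` appears at the slot onset
#' `(k - 1) * slot_duration` and stays on screen for `stimulus_on` seconds.
#' The first and last slots hold the anchor items that delineate the trial,
#' so intermediate items can only occupy slots `2 .. n_slots - 1`.
#'
#' @param n_slots Integer number of slots (>= 3). Default 11.
#' @param slot_duration Slot length in seconds (> 0). Default 1.5.
#' @param stimulus_on Stimulus-on time within a slot, seconds
#'   (<= `slot_duration`). Default 1.0.
#'
#' @return An object of class `slot_grid`.
#' @examples
#' g <- slot_grid()
#' total_duration(g)      # 16.5 s
#' intermediate_slots(g)  # 2:10
#' @export
slot_grid <- function(n_slots = 11L, slot_duration = 1.5, stimulus_on = 1.0) {
  n_slots <- as.integer(n_slots)
  stopifnot(length(n_slots) == 1L, length(slot_duration) == 1L,
            length(stimulus_on) == 1L)
  if (is.na(n_slots) || n_slots < 3L)
    stop("`n_slots` must be an integer >= 3")
  if (!is.finite(slot_duration) || slot_duration <= 0)
    stop("`slot_duration` must be > 0")
  if (!is.finite(stimulus_on) || stimulus_on < 0 || stimulus_on > slot_duration)
    stop("`stimulus_on` must lie in [0, slot_duration]")
  structure(
    list(n_slots = n_slots, slot_duration = slot_duration,
         stimulus_on = stimulus_on),
    class = "slot_grid"
  )
}

#' @export
print.slot_grid <- function(x, ...) {
  cat(sprintf("<slot_grid> %d slots x %g s (total %g s), stimulus on %g s\n",
              x$n_slots, x$slot_duration, total_duration(x), x$stimulus_on))
  invisible(x)
}

#' Total trial duration in seconds
#' @param grid A [slot_grid()].
#' @return `n_slots * slot_duration`, seconds.
#' @export
total_duration <- function(grid) {
  stopifnot(inherits(grid, "slot_grid"))
  grid$n_slots * grid$slot_duration
}

#' Onset time of a slot
#'
#' Presentation time of the item in slot `k` is the slot onset,
#' `(k - 1) * slot_duration`.
#'
#' @param slot Slot index or vector of indices (1-based).
#' @param grid A [slot_grid()].
#' @return Onset times in seconds.
#' @export
slot_onset <- function(slot, grid) {
  stopifnot(inherits(grid, "slot_grid"))
  if (any(slot < 1 | slot > grid$n_slots))
    stop("slot index out of range")
  (slot - 1) * grid$slot_duration
}

#' Slots available to intermediate items
#' @param grid A [slot_grid()].
#' @return Integer vector `2:(n_slots - 1)`.
#' @export
intermediate_slots <- function(grid) {
  stopifnot(inherits(grid, "slot_grid"))
  seq.int(2L, grid$n_slots - 1L)
}

#' Bin a continuous report time onto the slot grid
#'
#' `floor(t / slot_duration) + 1`, clipped to `[1, n_slots]`. Binning a slot
#' onset returns that slot, so the operation is idempotent on onsets.
#'
#' @param t Time(s) in seconds.
#' @param grid A [slot_grid()].
#' @return Integer bin indices in `1:n_slots`.
#' @export
time_to_bin <- function(t, grid) {
  stopifnot(inherits(grid, "slot_grid"))
  b <- floor(t / grid$slot_duration) + 1
  as.integer(pmin(pmax(b, 1), grid$n_slots))
}
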