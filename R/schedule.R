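#' @rdname make_schedule
#' @export
experiment_ids <- function() c("exp1", "exp2", "exp3", "exp4_1", "exp4_2")

# number of intermediate items and post-presentation delay per experiment
experiment_spec <- function(experiment_id) {
  switch(experiment_id,
    exp1   = list(n_intermediate = 1L, post_delay = 0),
    exp2   = list(n_intermediate = 2L, post_delay = 0),
    exp3   = list(n_intermediate = 3L, post_delay = 0),
    exp4_1 = list(n_intermediate = 1L, post_delay = 16),
    exp4_2 = list(n_intermediate = 2L, post_delay = 16),
    stop("unknown experiment_id: ", experiment_id)
  )
}

#' Draw a trial schedule
#'
#' The first and last items are anchored to the first and last slots;
#' the experiment's intermediate items are placed in slots drawn uniformly
#' without replacement from the intermediate range `2:(n_slots - 1)`.
#' Item rank follows presentation time, so the returned slots are sorted:
#' rank-1 is the earliest intermediate item.
#'
#' @param experiment_id One of `experiment_ids()`; determines the number of
#'   intermediate items (1 for exp1/exp4_1, 2 for exp2/exp4_2, 3 for exp3)
#'   and the post-presentation delay (16 s for exp4).
#' @param grid A [slot_grid()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A `trial_schedule`: list with `experiment_id`, `n_intermediate`,
#'   `intermediate_slots` (sorted, distinct), `post_delay`.
#' @examples
#' make_schedule("exp2", seed = 1)
#' @export
make_schedule <- function(experiment_id, grid = slot_grid(), seed = NULL) {
  spec <- experiment_spec(match.arg(experiment_id, experiment_ids()))
  avail <- intermediate_slots(grid)
  if (spec$n_intermediate > length(avail))
    stop("not enough intermediate slots for ", spec$n_intermediate, " items")
  if (!is.null(seed)) set.seed(seed)
  slots <- sort(avail[sample.int(length(avail), spec$n_intermediate)])
  structure(
    list(experiment_id = experiment_id,
         n_intermediate = spec$n_intermediate,
         intermediate_slots = slots,
         post_delay = spec$post_delay),
    class = "trial_schedule"
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %s: intermediate slots [%s]%s\n",
              x$experiment_id, paste(x$intermediate_slots, collapse = ", "),
              if (x$post_delay > 0) sprintf(", %g s delay", x$post_delay) else ""))
  invisible(x)
}
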