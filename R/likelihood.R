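#' Estimate the single-item report likelihood
#'
#' Builds the empirical likelihood of an internal/reported time given the
#' true presented slot, from single-intermediate-item records. Two coupled
#' representations are kept: a row-stochastic matrix over
#' (presented slot x report bin), used by the Bayesian decoder's discrete
#' posterior, and the raw report samples per presented slot, used as a
#' bootstrap sampler of internal times.
#'
#' @param records Trial records (single intermediate item per trial), as
#'   from [simulate_session()] or [read_records()].
#' @param grid A [slot_grid()].
#' @param pseudocount Additive count per (slot, bin) cell before row
#'   normalization; guards against zero-likelihood bins annihilating the
#'   posterior. Default 0.5.
#' @return An object of class `report_likelihood`: list with `grid`,
#'   `matrix` (rows = presented slots `2:(n_slots-1)`, columns = report
#'   bins `1:n_slots`, each row summing to 1) and `samples_by_slot` (named
#'   list of raw reported times).
#' @examples
#' rec <- simulate_session("exp1", n_participants = 20, seed = 1)
#' lik <- estimate_likelihood(rec)
#' rowSums(lik$matrix)
#' @export
estimate_likelihood <- function(records, grid = slot_grid(),
                                pseudocount = 0.5) {
  stopifnot(inherits(grid, "slot_grid"))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` is empty")
  if (!is.finite(pseudocount) || pseudocount < 0)
    stop("`pseudocount` must be >= 0")
  slots <- intermediate_slots(grid)
  bad <- !(records$presented_slot %in% slots)
  if (any(bad))
    stop("records contain presented slots outside the intermediate range")

  bins <- time_to_bin(records$reported_time_s, grid)
  counts <- matrix(0, length(slots), grid$n_slots,
                   dimnames = list(slot = slots, bin = seq_len(grid$n_slots)))
  tab <- table(factor(records$presented_slot, levels = slots),
               factor(bins, levels = seq_len(grid$n_slots)))
  counts[] <- as.numeric(tab)
  if (pseudocount == 0 && any(rowSums(counts) == 0))
    stop("presented slot with zero records and pseudocount = 0; ",
         "supply data for every intermediate slot or a positive pseudocount")
  m <- counts + pseudocount
  m <- m / rowSums(m)

  samples <- lapply(slots, function(s)
    records$reported_time_s[records$presented_slot == s])
  names(samples) <- slots
  structure(
    list(grid = grid, matrix = m, samples_by_slot = samples),
    class = "report_likelihood"
  )
}

#' @export
print.report_likelihood <- function(x, ...) {
  ns <- vapply(x$samples_by_slot, length, integer(1))
  cat(sprintf(
    "<report_likelihood> %d presented slots x %d report bins; %d raw samples (%s per slot)\n",
    nrow(x$matrix), ncol(x$matrix), sum(ns),
    if (length(ns)) paste0(min(ns), "-", max(ns)) else "0"))
  invisible(x)
}

# shared validation
assert_likelihood <- function(likelihood) {
  if (!inherits(likelihood, "report_likelihood"))
    stop("`likelihood` must be a report_likelihood")
  invisible(likelihood)
}

slot_samples <- function(likelihood, slot) {
  s <- likelihood$samples_by_slot[[as.character(slot)]]
  if (is.null(s) || length(s) == 0L)
    stop("no stored report samples for presented slot ", slot)
  s
}

#' Sample internal times by bootstrap resampling
#'
#' Draws internal time representations for an item presented in
#' `true_slot` by uniform resampling of the raw stored reports for that
#' slot (an empirical bootstrap), not from the binned matrix.
#'
#' @param likelihood A [estimate_likelihood()] result.
#' @param true_slot Presented slot of the item.
#' @param n Number of draws. Default 1.
#' @return Numeric vector of `n` resampled report times (seconds).
#' @export
sample_internal_time <- function(likelihood, true_slot, n = 1L) {
  assert_likelihood(likelihood)
  s <- slot_samples(likelihood, true_slot)
  s[sample.int(length(s), n, replace = TRUE)]
}

#' Read / write a report likelihood
#'
#' Two CSV files: `<path>` holds the row-stochastic matrix (column `slot`
#' then one column per report bin), and `<samples_path>` the raw samples
#' (columns `presented_slot`, `reported_time_s`).
#'
#' @param likelihood A `report_likelihood`.
#' @param path Matrix CSV path.
#' @param samples_path Raw-samples CSV path; default `<path>` with a
#'   `_samples.csv` suffix.
#' @param grid Grid used when reading back.
#' @return `read_likelihood()` returns a `report_likelihood`;
#'   `write_likelihood()` returns `path` invisibly.
#' @export
write_likelihood <- function(likelihood, path,
                             samples_path = sub("\\.csv$", "_samples.csv", path)) {
  assert_likelihood(likelihood)
  m <- as.data.frame(likelihood$matrix)
  names(m) <- paste0("bin_", seq_len(ncol(m)))
  m <- cbind(slot = as.integer(rownames(likelihood$matrix)), m)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  sm <- data.frame(
    presented_slot = rep(as.integer(names(likelihood$samples_by_slot)),
                         vapply(likelihood$samples_by_slot, length, integer(1))),
    reported_time_s = sprintf("%.6f", unlist(likelihood$samples_by_slot,
                                             use.names = FALSE)))
  utils::write.csv(sm, samples_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_likelihood
#' @export
read_likelihood <- function(path,
                            samples_path = sub("\\.csv$", "_samples.csv", path),
                            grid = slot_grid()) {
  m <- utils::read.csv(path, check.names = FALSE)
  slots <- as.integer(m$slot)
  mat <- as.matrix(m[, grep("^bin_", names(m)), drop = FALSE])
  dimnames(mat) <- list(slot = slots, bin = seq_len(ncol(mat)))
  sm <- utils::read.csv(samples_path)
  samples <- lapply(slots, function(s)
    as.numeric(sm$reported_time_s[sm$presented_slot == s]))
  names(samples) <- slots
  structure(list(grid = grid, matrix = mat, samples_by_slot = samples),
            class = "report_likelihood")
}
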