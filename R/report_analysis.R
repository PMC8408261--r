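#' Rank-conditioned report summaries
#'
#' Mean reported time as a function of presented slot, separately per item
#' rank — the average-report curves whose separation by rank is the
#' signature of order information biasing absolute-time reports.
#'
#' @param records Trial records ([simulate_session()] schema).
#' @return A data.frame with one row per (item_rank, presented_slot):
#'   `n`, `mean_report`, `sd_report`, `se_report` (SE is `NA` for n < 2).
#' @export
summarize_reports <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(records)),
         sum = records$reported_time_s,
         sumsq = records$reported_time_s^2),
    by = list(item_rank = records$item_rank,
              presented_slot = records$presented_slot),
    FUN = sum)
  agg$mean_report <- agg$sum / agg$n
  v <- (agg$sumsq - agg$n * agg$mean_report^2) / (agg$n - 1)
  agg$sd_report <- ifelse(agg$n >= 2L, sqrt(pmax(v, 0)), NA_real_)
  agg$se_report <- agg$sd_report / sqrt(agg$n)
  out <- agg[order(agg$item_rank, agg$presented_slot),
             c("item_rank", "presented_slot", "n",
               "mean_report", "sd_report", "se_report")]
  rownames(out) <- NULL
  out
}

#' Per-slot rank-difference tests (Welch)
#'
#' For each presented slot, compares the reported times of the two given
#' item ranks presented (in different trials) at that same slot, using a
#' two-sample t-test with unequal variances. Slots where either rank has
#' fewer than two reports yield `NA` rows.
#'
#' @param records Trial records.
#' @param ranks Two item ranks to compare. Default `c(1, 2)`.
#' @return A data.frame with per-slot `n_a`, `n_b`, `statistic`, `df`,
#'   `p_value` (two-sided).
#' @export
rank_difference_tests <- function(records, ranks = c(1L, 2L)) {
  stopifnot(is.data.frame(records), length(ranks) == 2L)
  slots <- sort(unique(records$presented_slot))
  res <- lapply(slots, function(s) {
    xa <- records$reported_time_s[records$presented_slot == s &
                                    records$item_rank == ranks[1L]]
    xb <- records$reported_time_s[records$presented_slot == s &
                                    records$item_rank == ranks[2L]]
    row <- data.frame(presented_slot = s, n_a = length(xa), n_b = length(xb),
                      statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_)
    if (length(xa) >= 2L && length(xb) >= 2L &&
        (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      row$statistic <- unname(tt$statistic)
      row$df <- unname(tt$parameter)
      row$p_value <- tt$p.value
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Does the reported time depend on the presented slot?
#'
#' One-way fixed-effects F test of reported position (reported time in
#' slot units) on presented slot treated as a categorical factor, for one
#' item rank. The null hypothesis is that reports do not depend on the
#' presentation slot — true in the quantized (rank-only) limit.
#'
#' @param records Trial records.
#' @param item_rank Item rank to analyze.
#' @param grid A [slot_grid()] (for the slot-unit scaling).
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
slot_dependence_test <- function(records, item_rank, grid = slot_grid()) {
  stopifnot(is.data.frame(records), inherits(grid, "slot_grid"))
  d <- records[records$item_rank == item_rank, ]
  if (length(unique(d$presented_slot)) < 2L)
    stop("need data at >= 2 presented slots for rank ", item_rank)
  pos <- d$reported_time_s / grid$slot_duration
  fit <- stats::lm(pos ~ factor(d$presented_slot))
  a <- stats::anova(fit)
  list(statistic = a$`F value`[1L], df1 = a$Df[1L], df2 = a$Df[2L],
       p_value = a$`Pr(>F)`[1L])
}

#' Fitted slope of mean report versus presented time
#'
#' Least-squares slope of the rank-conditioned mean reported time against
#' the presented slot onset, a scalar summary of how strongly reports
#' track the presentation time (1 = perfect tracking, 0 = rank-only
#' reports).
#'
#' @param records Trial records.
#' @param item_rank Item rank.
#' @param grid A [slot_grid()].
#' @return Numeric slope (dimensionless, seconds per second).
#' @export
report_slope <- function(records, item_rank, grid = slot_grid()) {
  s <- summarize_reports(records)
  s <- s[s$item_rank == item_rank, ]
  if (nrow(s) < 2L) stop("need >= 2 slots for a slope")
  x <- slot_onset(s$presented_slot, grid)
  unname(stats::coef(stats::lm(s$mean_report ~ x))[2L])
}
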