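#' UCLA-20 reverse-scored item indices
#'
#' The nine items of the revised UCLA loneliness scale that are phrased
#' positively (e.g. "How often do you feel part of a group of friends?") and
#' therefore reverse scored before summation.
#'
#' @return integer vector of item indices (1-based)
#' @export
ucla_reverse_items <- function() c(1L, 5L, 6L, 9L, 10L, 15L, 16L, 19L, 20L)

#' Score a UCLA-20 loneliness response
#'
#' Each of the 20 items is rated 1 (never) to 4 (always). The nine reverse
#' items are scored as `5 - raw`; all scored items are summed, giving a total
#' in 20..80 with higher values indicating more loneliness.
#'
#' @param items integer vector of 20 raw responses in 1..4
#' @return integer total score
#' @export
score_ucla <- function(items) {
  if (length(items) != 20L) stop("UCLA response must have exactly 20 items")
  items <- as.numeric(items)
  if (anyNA(items) || any(items < 1 | items > 4) || any(items != round(items)))
    stop("UCLA items must be integers in 1..4")
  scored <- items
  rev <- ucla_reverse_items()
  scored[rev] <- 5 - items[rev]
  as.integer(sum(scored))
}

#' Categorize a UCLA total score into a loneliness level
#'
#' Totals of 40 and below (rarely/never experiencing loneliness) are low
#' loneliness ("LL"); totals above 40 are high loneliness ("HL").
#'
#' @param total integer total score(s) in 20..80
#' @return character vector of "LL"/"HL"
#' @export
categorize_level <- function(total) {
  total <- as.numeric(total)
  if (anyNA(total) || any(total < 20 | total > 80))
    stop("UCLA totals must lie in 20..80")
  ifelse(total > 40, "HL", "LL")
}

#' Change category between two loneliness levels
#'
#' "DL" (decreased loneliness) when the level drops from HL to LL, "IL"
#' (increased) for LL to HL, "UL" (unchanged) otherwise.
#'
#' @param pre_level,post_level character "LL"/"HL"
#' @return character vector of "DL"/"IL"/"UL"
#' @export
change_category <- function(pre_level, post_level) {
  ok <- c("LL", "HL")
  if (!all(pre_level %in% ok) || !all(post_level %in% ok))
    stop("levels must be 'LL' or 'HL'")
  out <- rep("UL", length(pre_level))
  out[pre_level == "HL" & post_level == "LL"] <- "DL"
  out[pre_level == "LL" & post_level == "HL"] <- "IL"
  out
}

#' Descriptive summary of pre/post loneliness scores in a cohort
#'
#' Reports per-wave mean/SD/quartiles, HL/LL counts, the count of scores more
#' than one SD above the wave mean, and the change-band partition used in the
#' study reporting: unchanged (delta = 0), minor increase (1..6), increase
#' above 6, minor decrease (1..7), decrease above 7 (delta = post - pre).
#'
#' @param pre_totals,post_totals paired integer score vectors
#' @return list with `pre`, `post` (each mean/sd/median/q1/q3/n_hl/n_ll/
#'   n_above_1sd) and `change` (band counts plus min/max delta)
#' @export
summarize_cohort <- function(pre_totals, post_totals) {
  if (length(pre_totals) == 0) stop("empty cohort")
  if (length(pre_totals) != length(post_totals))
    stop("pre/post score vectors must be paired")
  wave_summary <- function(x) {
    lv <- categorize_level(x)
    list(
      n = length(x), mean = mean(x), sd = sd(x), median = median(x),
      q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
      n_hl = sum(lv == "HL"), n_ll = sum(lv == "LL"),
      n_above_1sd = sum(x > mean(x) + sd(x))
    )
  }
  delta <- post_totals - pre_totals
  bands <- c(
    unchanged      = sum(delta == 0),
    increase_1_6   = sum(delta >= 1 & delta <= 6),
    increase_gt6   = sum(delta >= 7),
    decrease_1_7   = sum(delta <= -1 & delta >= -7),
    decrease_gt7   = sum(delta <= -8)
  )
  list(
    pre = wave_summary(pre_totals),
    post = wave_summary(post_totals),
    change = list(
      bands = bands,
      mean_delta = mean(delta),
      max_increase = max(delta),
      max_decrease = -min(delta)
    )
  )
}

#' Score a survey table into participant outcomes
#'
#' @param surveys data.frame with columns participant_id, wave ("pre"/"post")
#'   and q1..q20 raw responses
#' @return data.table with one row per participant: pre/post totals, levels,
#'   change category and score delta
#' @export
score_survey_table <- function(surveys) {
  dt <- data.table::as.data.table(surveys)
  qcols <- paste0("q", 1:20)
  stopifnot(all(qcols %in% names(dt)), all(c("participant_id", "wave") %in% names(dt)))
  dt[, total := apply(.SD, 1, score_ucla), .SDcols = qcols]
  wide <- data.table::dcast(dt, participant_id ~ wave, value.var = "total")
  stopifnot(all(c("pre", "post") %in% names(wide)))
  wide[, `:=`(
    pre_total = pre, post_total = post,
    pre_level = categorize_level(pre), post_level = categorize_level(post)
  )]
  wide[, change := change_category(pre_level, post_level)]
  wide[, score_delta := post_total - pre_total]
  wide[, c("pre", "post") := NULL]
  wide[]
}
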