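## Behavioral assay scoring. The worm is the experimental unit (per-worm
## score, then group statistics); the plate is the unit only for the
## aldicarb paralysis time course.

## Group mean +- SEM over per-unit scores.
group_summary <- function(values, genotype) {
  out <- do.call(rbind, lapply(split(values, genotype), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  out$genotype <- rownames(out)
  rownames(out) <- NULL
  out[, c("genotype", "n", "mean", "sem")]
}

#' Score nose-touch responses
#'
#' Per worm, the fraction of trials (nominally 10) answered with a
#' locomotor reversal; group mean and SEM over worms. Worms with zero
#' trials are excluded with a warning.
#'
#' @param table Data frame with columns `worm_id`, `genotype`, `response`
#'   (0/1 per trial).
#' @return A list with `per_worm` (worm_id, genotype, n_trials, fraction)
#'   and `by_group` (genotype, n, mean, sem).
#' @export
nose_touch_score <- function(table) {
  req <- c("worm_id", "genotype", "response")
  if (!all(req %in% names(table)))
    stopf("trial table needs columns %s", paste(req, collapse = ", "))
  if (!all(table$response %in% c(0, 1)))
    stopf("responses must be binary")
  per <- do.call(rbind, lapply(split(table, table$worm_id), function(d) {
    data.frame(worm_id = d$worm_id[1L], genotype = d$genotype[1L],
               n_trials = nrow(d), fraction = mean(d$response))
  }))
  rownames(per) <- NULL
  empty <- per$n_trials == 0
  if (any(empty)) {
    warning(sprintf("excluding %d worm(s) with zero trials", sum(empty)))
    per <- per[!empty, ]
  }
  list(per_worm = per,
       by_group = group_summary(per$fraction, per$genotype))
}

#' Score optogenetic ASH responses
#'
#' Fraction of light pulses answered with a locomotor reversal per worm;
#' identical scoring to [nose_touch_score()] over pulses instead of touch
#' trials.
#'
#' @param table Data frame with columns `worm_id`, `genotype`, `response`
#'   (0/1 per pulse).
#' @return As [nose_touch_score()].
#' @export
opto_response <- function(table) nose_touch_score(table)

#' Score count assays (thrashing, spontaneous reversals)
#'
#' Counts are reported per the stated assay window (30 s for thrashing,
#' 5 min for spontaneous reversals) with no re-scaling across assays; all
#' rows of one assay must share the same period.
#'
#' @param table Data frame with columns `worm_id`, `genotype`, `count`,
#'   `period`, `assay`.
#' @return A list with `per_worm` (the table, counts validated) and
#'   `by_group` (genotype, n, mean, sem), plus `period` and `assay`.
#' @export
rate_score <- function(table) {
  req <- c("worm_id", "genotype", "count", "period", "assay")
  if (!all(req %in% names(table)))
    stopf("count table needs columns %s", paste(req, collapse = ", "))
  if (any(table$count < 0)) stopf("counts must be >= 0")
  if (length(unique(table$assay)) != 1L)
    stopf("one assay per table")
  if (length(unique(table$period)) != 1L)
    stopf("period mismatch within assay '%s'", table$assay[1L])
  list(per_worm = table,
       by_group = group_summary(table$count, table$genotype),
       period = table$period[1L], assay = table$assay[1L])
}

#' Aldicarb paralysis time course
#'
#' Pooled fraction of paralyzed worms per genotype at each check time, with
#' binomial standard errors. Counts must be non-decreasing in time within
#' each plate; a decrease is a scoring error and is reported with the plate
#' name.
#'
#' @param table Data frame with columns `plate_id`, `genotype`, `time_min`,
#'   `n_paralyzed`, `n_total`.
#' @return Data frame per genotype and time: `time_min`, `n_paralyzed`,
#'   `n_total`, `fraction`, `se` (binomial).
#' @export
paralysis_curve <- function(table) {
  req <- c("plate_id", "genotype", "time_min", "n_paralyzed", "n_total")
  if (!all(req %in% names(table)))
    stopf("paralysis table needs columns %s", paste(req, collapse = ", "))
  if (any(table$n_paralyzed > table$n_total))
    stopf("n_paralyzed exceeds n_total")
  for (pl in unique(table$plate_id)) {
    d <- table[table$plate_id == pl, ]
    d <- d[order(d$time_min), ]
    if (any(diff(d$n_paralyzed) < 0))
      stopf("paralyzed count decreases over time on plate '%s'", pl)
  }
  out <- do.call(rbind, lapply(split(table, table$genotype), function(d) {
    do.call(rbind, lapply(split(d, d$time_min), function(dd) {
      np <- sum(dd$n_paralyzed); nt <- sum(dd$n_total)
      p <- np / nt
      data.frame(genotype = dd$genotype[1L], time_min = dd$time_min[1L],
                 n_paralyzed = np, n_total = nt, fraction = p,
                 se = sqrt(p * (1 - p) / nt))
    }))
  }))
  rownames(out) <- NULL
  out[order(out$genotype, out$time_min), ]
}
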