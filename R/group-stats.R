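#' Build the tidy group table of efficiency metrics
#'
#' One row per (subject, condition, band, threshold, metric): the long
#' format every group-level test consumes.
#'
#' @param reports list of `efficiency_report`s (any nesting is flattened).
#' @return Data frame with columns `subject_id`, `condition`, `band`,
#'   `threshold_T`, `metric`, `value`.
#' @export
group_table <- function(reports) {
  flat <- list()
  walk <- function(x) {
    if (inherits(x, "efficiency_report")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, walk)
    invisible(NULL)
  }
  walk(reports)
  do.call(rbind, lapply(flat, function(r)
    data.frame(subject_id = r$subject_id, condition = r$condition,
               band = r$band, threshold_T = r$threshold_T,
               metric = c("e_glob", "e_loc"),
               value = c(r$e_glob, r$e_loc),
               stringsAsFactors = FALSE)))
}

check_paired <- function(wide) {
  if (nrow(wide) < 3) stop("paired tests need at least 3 subjects")
  if (anyNA(wide$play) || anyNA(wide$rest))
    stop("paired structure broken: some subjects lack one condition")
}

#' Paired play-vs-rest tests at every threshold
#'
#' At each connection density `T`, a two-sided paired t-test on the
#' per-subject condition differences of one metric in one band, with 95%
#' confidence intervals of the difference and of each condition mean.
#'
#' @param table tidy table from [group_table()].
#' @param metric `"e_loc"` or `"e_glob"`.
#' @param band rhythm band name.
#' @return Data frame with one row per threshold: `threshold_T`,
#'   `statistic`, `df`, `p_value`, `ci_low`, `ci_high` (difference
#'   play - rest), plus per-condition means and CIs.
#' @export
paired_test_per_threshold <- function(table, metric, band) {
  sub <- table[table$metric == metric & table$band == band, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for metric ", metric, ", band ", band)
  out <- lapply(sort(unique(sub$threshold_T)), function(T) {
    st <- sub[sub$threshold_T == T, , drop = FALSE]
    wide <- stats::reshape(st[, c("subject_id", "condition", "value")],
                           idvar = "subject_id", timevar = "condition",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    check_paired(wide)
    d <- wide$play - wide$rest
    if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
      # zero-variance differences: t undefined; identical pairs are a null
      # result, a constant nonzero shift is maximal evidence
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0,
                 conf.int = c(mean(d), mean(d)))
    } else {
      tt <- stats::t.test(wide$play, wide$rest, paired = TRUE)
    }
    ci_of <- function(x) {
      se <- stats::sd(x) / sqrt(length(x))
      mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) * se
    }
    cp <- ci_of(wide$play); cr <- ci_of(wide$rest)
    data.frame(threshold_T = T, statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               mean_play = mean(wide$play), ci_play_low = cp[1],
               ci_play_high = cp[2], mean_rest = mean(wide$rest),
               ci_rest_low = cr[1], ci_rest_high = cr[2])
  })
  do.call(rbind, out)
}

#' Two-way condition x band ANOVA on an efficiency metric
#'
#' Standard two-way fixed-effects decomposition (`value ~ condition * band`)
#' on the per-subject metric values at one connection density, returning F
#' and p for the condition factor, the band factor and their interaction.
#'
#' @param table tidy table from [group_table()].
#' @param metric `"e_loc"` or `"e_glob"`.
#' @param threshold_T density at which the metric is analyzed (default
#'   0.35).
#' @return Data frame with rows `condition`, `band`, `condition:band`:
#'   columns `term`, `df`, `statistic` (F), `p_value`.
#' @export
two_way_anova <- function(table, metric, threshold_T = 0.35) {
  sub <- table[table$metric == metric &
                 abs(table$threshold_T - threshold_T) < 1e-9, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for metric ", metric, " at T = ",
                           threshold_T)
  sub$condition <- factor(sub$condition)
  sub$band <- factor(sub$band)
  cells <- table(sub$condition, sub$band)
  if (any(cells < 2)) stop("need at least 2 replicates per condition x ",
                           "band cell")
  if (length(unique(cells)) != 1)
    stop("condition x band layout must be balanced")
  wvar <- stats::aggregate(value ~ condition + band, sub, stats::var)
  if (all(wvar$value == 0))
    stop("zero within-cell variance: F statistics undefined")
  fit <- stats::aov(value ~ condition * band, data = sub)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms %in% c("condition", "band", "condition:band")
  data.frame(term = terms[keep], df = sm$Df[keep],
             statistic = sm$`F value`[keep], p_value = sm$`Pr(>F)`[keep],
             stringsAsFactors = FALSE)
}

#' Headline summary of condition contrasts per band
#'
#' For every metric and band at the illustration density, the play - rest
#' mean contrast and its paired p-value; the band with the largest absolute
#' contrast per metric is flagged, along with significance at `alpha`.
#'
#' @param table tidy table from [group_table()].
#' @param threshold_T density for the summary (default 0.35).
#' @param alpha significance level (default 0.05).
#' @return List with `contrasts` (data frame: metric, band, contrast,
#'   p_value, significant) and `max_contrast_band` (named character vector
#'   per metric).
#' @export
headline_report <- function(table, threshold_T = 0.35, alpha = 0.05) {
  sub <- table[abs(table$threshold_T - threshold_T) < 1e-9, , drop = FALSE]
  rows <- list()
  for (metric in sort(unique(sub$metric)))
    for (band in sort(unique(sub$band))) {
      pt <- paired_test_per_threshold(sub, metric, band)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, band = band,
        contrast = pt$mean_play - pt$mean_rest, p_value = pt$p_value,
        significant = pt$p_value < alpha, stringsAsFactors = FALSE)
    }
  contrasts <- do.call(rbind, rows)
  mx <- vapply(split(contrasts, contrasts$metric), function(d)
    d$band[which.max(abs(d$contrast))], character(1))
  list(contrasts = contrasts, max_contrast_band = mx,
       threshold_T = threshold_T, alpha = alpha)
}
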