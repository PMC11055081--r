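# Channel / region / all-channel sensitivity of the concordance analysis.

#' Sensitivity of a channel (percent)
#'
#' 100 x (episodes concordant on the channel) / (total episodes).
#'
#' @param labels An `episode_labels` data frame from [label_episodes()],
#'   or a count of concordant episodes when `total` is given.
#' @param total Total episode count (only with scalar `labels`).
#' @return Percent in \[0, 100\].
#' @export
channel_sensitivity <- function(labels, total = NULL) {
  if (!is.null(total)) {
    if (total <= 0) stop("total episode count must be positive")
    return(100 * as.numeric(labels) / total)
  }
  n <- nrow(labels)
  if (n == 0) stop("no episodes: sensitivity undefined")
  100 * sum(labels$correlated) / n
}

#' Cross-subject average sensitivity (percent)
#'
#' @param per_subject Non-empty numeric vector of per-subject percentages.
#' @return Arithmetic mean.
#' @export
average_sensitivity <- function(per_subject) {
  if (!length(per_subject)) stop("empty per-subject vector")
  mean(per_subject)
}

#' Combine sensitivity of a channel set (percent)
#'
#' 100 x (1 - uncorrelated-by-union / total): an episode counts as
#' concordant when at least one channel in the set makes it so. For a
#' single channel this equals [channel_sensitivity()]; enlarging the set
#' can only raise it.
#'
#' @param labels_by_channel Named list of `episode_labels` (one per
#'   channel, same episodes), or a single `episode_labels` already
#'   computed over the union (see [label_episodes()] with several
#'   channels).
#' @return Percent in \[0, 100\].
#' @export
combine_sensitivity <- function(labels_by_channel) {
  if (inherits(labels_by_channel, "episode_labels"))
    return(channel_sensitivity(labels_by_channel))
  if (!length(labels_by_channel)) stop("empty channel set")
  corr <- Reduce(`|`, lapply(labels_by_channel, function(l) l$correlated))
  total <- nrow(labels_by_channel[[1]])
  if (total == 0) stop("no episodes: sensitivity undefined")
  100 * (1 - sum(!corr) / total)
}

#' Matched-episode percentages from per-class counts
#'
#' Reproduces the report-stage arithmetic that converts matched/total
#' episode counts per class into the drowsiness, wakefulness and overall
#' match percentages (one decimal place).
#'
#' @param drowsy_matched,drowsy_total Drowsy-episode counts.
#' @param wake_matched,wake_total Wake-episode counts.
#' @return Named list with `drowsy_pct`, `wake_pct`, `overall_pct`
#'   (rounded to one decimal) and the raw `counts`.
#' @export
match_percentages <- function(drowsy_matched, drowsy_total,
                              wake_matched, wake_total) {
  if (drowsy_total <= 0 || wake_total <= 0) stop("totals must be positive")
  list(
    drowsy_pct = round(100 * drowsy_matched / drowsy_total, 1),
    wake_pct = round(100 * wake_matched / wake_total, 1),
    overall_pct = round(100 * (drowsy_matched + wake_matched) /
                          (drowsy_total + wake_total), 1),
    counts = c(drowsy_matched = drowsy_matched, drowsy_total = drowsy_total,
               wake_matched = wake_matched, wake_total = wake_total)
  )
}

#' Cohort sensitivity report
#'
#' For every feature: the six single-channel sensitivities, the three
#' paired-region combine sensitivities (frontal F3/F4, central C3/C4,
#' occipital O1/O2) and the all-channel combine sensitivity, each averaged
#' across subjects with the per-subject vectors retained. Also reports the
#' per-feature best channel and best region, and aggregate matched/total
#' counts by episode class under the all-channel union.
#'
#' @param cohort_features Named list (one element per subject) of feature
#'   matrices from [episode_features()].
#' @param channels Channel labels to use (default the six 10-20 channels).
#' @param features Feature names (default all ten).
#' @return A list of class `sensitivity_report`: `table` (data frame with
#'   `feature`, `scope`, `scope_members`, `mean_pct`, `per_subject`),
#'   `best` (per-feature best channel and region), `class_counts`
#'   (per-feature matched/total counts by episode class), `subjects`.
#' @export
build_report <- function(cohort_features,
                         channels = EXPECTED_CHANNELS,
                         features = feature_names()) {
  if (!length(cohort_features)) stop("empty cohort")
  subjects <- names(cohort_features) %||% as.character(seq_along(cohort_features))
  if (is.null(names(cohort_features))) names(cohort_features) <- subjects

  regions <- Filter(function(p) all(p %in% channels), REGION_PAIRS)
  rows <- list(); counts <- list()
  for (feat in features) {
    per_scope <- list()
    for (ch in channels)
      per_scope[[paste0("channel:", ch)]] <-
        vapply(cohort_features, function(fm)
          channel_sensitivity(label_episodes(fm, ch, feat)), 0)
    for (rn in names(regions))
      per_scope[[paste0("region:", rn)]] <-
        vapply(cohort_features, function(fm)
          channel_sensitivity(label_episodes(fm, regions[[rn]], feat)), 0)
    per_scope[["all:all"]] <-
      vapply(cohort_features, function(fm)
        channel_sensitivity(label_episodes(fm, channels, feat)), 0)

    for (nm in names(per_scope)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      members <- switch(parts[1],
                        channel = parts[2],
                        region = paste(regions[[parts[2]]], collapse = "/"),
                        all = paste(channels, collapse = "/"))
      rows[[length(rows) + 1]] <- data.frame(
        feature = feat, scope = parts[1], scope_members = members,
        mean_pct = average_sensitivity(per_scope[[nm]]),
        per_subject = paste(formatC(per_scope[[nm]], digits = 10, format = "g"),
                            collapse = ";"),
        stringsAsFactors = FALSE)
    }

    cls <- lapply(cohort_features, function(fm)
      correlation_counts(label_episodes(fm, channels, feat), by_class = TRUE))
    agg <- Reduce(function(a, b) {
      a$correlated <- a$correlated + b$correlated
      a$total <- a$total + b$total
      a
    }, cls)
    agg$feature <- feat
    counts[[feat]] <- agg
  }
  table <- do.call(rbind, rows)

  best <- do.call(rbind, lapply(features, function(feat) {
    tf <- table[table$feature == feat, ]
    ch <- tf[tf$scope == "channel", ]
    rg <- tf[tf$scope == "region", ]
    data.frame(
      feature = feat,
      best_channel = ch$scope_members[which.max(ch$mean_pct)],
      best_channel_pct = round(max(ch$mean_pct), 1),
      best_region = if (nrow(rg)) rg$scope_members[which.max(rg$mean_pct)] else NA,
      best_region_pct = if (nrow(rg)) round(max(rg$mean_pct), 1) else NA,
      all_channel_pct = round(tf$mean_pct[tf$scope == "all"], 1),
      stringsAsFactors = FALSE)
  }))

  structure(list(table = table, best = best,
                 class_counts = do.call(rbind, counts),
                 subjects = subjects),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> ", length(x$subjects), " subject(s)\n", sep = "")
  print(x$best, row.names = FALSE)
  invisible(x)
}
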