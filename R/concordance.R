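# Per-episode concordance between visual-based scoring and EEG features.
#
# Each of the ten features has a direction of change with drowsiness: the
# ratios, theta/delta powers and spectral spread increase; alpha power,
# entropy, centroid and rolloff decrease. A drowsy episode i is concordant
# ("correlated") on a channel when its feature value is on the drowsy side
# of BOTH neighbouring wakefulness episodes i-1 and i+1 (single-sided at
# session boundaries). A wakefulness episode is concordant when its value
# is on the wake side of every adjacent drowsy episode. Over a channel
# set, an episode is concordant if any channel makes it so.

#' The ten feature criteria and their drowsiness trends
#'
#' @return Data frame with columns `feature` and `direction`
#'   (`"increases"` or `"decreases"` with drowsiness).
#' @export
feature_criteria <- function() {
  data.frame(
    feature = feature_names(),
    direction = c("increases", "increases", "decreases",  # delta, theta power up; alpha down
                  "increases", "increases", "increases",  # the three ratios
                  "decreases", "increases", "decreases", "decreases"),
    stringsAsFactors = FALSE
  )
}

# direction lookup, with validation
.feature_direction <- function(feature) {
  fc <- feature_criteria()
  d <- fc$direction[fc$feature == feature]
  if (!length(d)) stop("unknown feature: ", feature)
  d
}

#' Evaluate the drowsy-episode criterion for one episode and channel
#'
#' For an "increases" feature the criterion is
#' `value(i) > value(i-1) && value(i) > value(i+1)`; mirrored with `<` for
#' "decreases" features. At a session boundary the single available
#' neighbour decides.
#'
#' @param features Feature matrix from [episode_features()].
#' @param drowsy_index Episode index `i` (must be a drowsy episode).
#' @param channel Channel label.
#' @param feature Feature name (see [feature_names()]).
#' @return Logical: does the criterion hold?
#' @export
evaluate_criterion <- function(features, drowsy_index, channel, feature) {
  direction <- .feature_direction(feature)
  f <- features[features$channel == channel, ]
  f <- f[order(f$episode), ]
  i <- match(drowsy_index, f$episode)
  if (is.na(i)) stop("episode ", drowsy_index, " not present for channel ", channel)
  if (f$label[i] != "drowsy")
    stop("episode ", drowsy_index, " is not a drowsy episode")
  v <- f[[feature]]
  nbr <- c(i - 1, i + 1)
  nbr <- nbr[nbr >= 1 & nbr <= nrow(f)]
  if (!length(nbr)) return(FALSE)
  cmp <- if (direction == "increases") v[i] > v[nbr] else v[i] < v[nbr]
  isTRUE(all(cmp))
}

# Per-episode concordance flags for one channel's ordered value vector.
.label_one_channel <- function(values, labels, direction) {
  n <- length(values)
  out <- logical(n)
  for (i in seq_len(n)) {
    nbr <- c(i - 1, i + 1)
    nbr <- nbr[nbr >= 1 & nbr <= n]
    if (labels[i] == "drowsy") {
      nbr <- nbr[labels[nbr] == "wake"]
      if (!length(nbr)) next
      cmp <- if (direction == "increases") values[i] > values[nbr]
             else values[i] < values[nbr]
    } else {
      nbr <- nbr[labels[nbr] == "drowsy"]
      if (!length(nbr)) next
      cmp <- if (direction == "increases") values[i] < values[nbr]
             else values[i] > values[nbr]
    }
    out[i] <- isTRUE(all(cmp))
  }
  out
}

#' Label episodes as concordant with an EEG feature
#'
#' An episode is concordant over a channel set iff the per-channel rule
#' holds on at least one channel in the set (union rule), so enlarging the
#' set never removes a concordant episode. Episodes with missing (`NA`)
#' feature values fail the rule on that channel.
#'
#' @param features Feature matrix from [episode_features()].
#' @param channels Character vector of channel labels (non-empty).
#' @param feature Feature name.
#' @return Data frame of class `episode_labels` with columns `episode`,
#'   `label`, `correlated`, plus attributes `feature` and `channels`.
#' @export
label_episodes <- function(features, channels, feature) {
  if (!length(channels)) stop("channel set must be non-empty")
  missing_ch <- setdiff(channels, unique(features$channel))
  if (length(missing_ch))
    stop("feature matrix lacks channel(s): ", paste(missing_ch, collapse = ", "))
  direction <- .feature_direction(feature)
  base <- features[features$channel == channels[1], c("episode", "label")]
  base <- base[order(base$episode), ]
  agg <- logical(nrow(base))
  for (ch in channels) {
    f <- features[features$channel == ch, ]
    f <- f[order(f$episode), ]
    if (!identical(f$episode, base$episode))
      stop("feature matrix is not complete for channel ", ch)
    agg <- agg | .label_one_channel(f[[feature]], f$label, direction)
  }
  out <- data.frame(episode = base$episode, label = base$label,
                    correlated = agg, stringsAsFactors = FALSE)
  attr(out, "feature") <- feature
  attr(out, "channels") <- channels
  class(out) <- c("episode_labels", "data.frame")
  out
}

#' Concordant/total episode counts
#'
#' @param labels An `episode_labels` data frame.
#' @param by_class Split counts by episode class (wake/drowsy)?
#' @return Named vector `c(correlated, total)`, or a data frame when
#'   `by_class = TRUE`.
#' @export
correlation_counts <- function(labels, by_class = FALSE) {
  if (!by_class)
    return(c(correlated = sum(labels$correlated), total = nrow(labels)))
  out <- do.call(rbind, lapply(c("drowsy", "wake"), function(cl) {
    l <- labels[labels$label == cl, ]
    data.frame(class = cl, correlated = sum(l$correlated), total = nrow(l),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Spearman association between episode totals and concordant counts
#'
#' Tie-corrected (average-rank) Spearman correlation across subjects
#' between the number of scored episodes and the number concordant with a
#' feature, with a two-sided p-value from the t approximation.
#'
#' @param totals Per-subject episode totals (length >= 3).
#' @param correlated Per-subject concordant counts (same length).
#' @return List with `rho` and `p`.
#' @export
spearman_association <- function(totals, correlated) {
  n <- length(totals)
  if (length(correlated) != n) stop("inputs must have equal length")
  if (n < 3) stop("need at least 3 subjects")
  if (var(totals) == 0 || var(correlated) == 0)
    stop("zero variance: Spearman correlation undefined")
  rho <- cor(rank(totals), rank(correlated))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
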