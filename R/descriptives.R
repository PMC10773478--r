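# Descriptive vignette analyses: reverse coding, per-group mean vignette
# ratings, severity ranks, rating range, and a-priori order violations.

#' Reverse-code the reverse-keyed items
#'
#' The EPDS keys three items (1, 2 and 4) in the opposite direction; their
#' ratings are flipped (`rating -> 3 - rating`) on both self-reports and
#' vignette ratings so that higher always means more distress. Guarded by
#' the dataset's orientation flag so the involution cannot be applied twice.
#'
#' @param data an unoriented [av_dataset()].
#' @param items integer vector of reverse-keyed items.
#' @return the oriented dataset.
#' @export
reverse_code <- function(data, items = c(1L, 2L, 4L)) {
  stopifnot(inherits(data, "av_dataset"))
  if (is_oriented(data))
    stop("dataset is already oriented; refusing to reverse-code twice")
  flip <- data$item %in% items
  data$rating[flip] <- 3L - data$rating[flip]
  attr(data, "oriented") <- TRUE
  data
}

resolve_group <- function(data, group) {
  if (identical(group, "ALL")) return(rep(TRUE, nrow(data)))
  if (group %in% COUNTRIES) return(data$country == group)
  if (group %in% COHORTS) return(data$cohort == group)
  stop("unknown group '", group, "' (use ALL, a country or a cohort)")
}

#' Mean vignette ratings for a group and item
#'
#' Arithmetic mean of the available ratings per vignette; vignettes with no
#' raters in the group are `NA` (flagged absent).
#'
#' @param data an oriented [av_dataset()].
#' @param group `"ALL"`, a country (`"IN"`, `"UK"`) or a cohort label. The
#'   cohort option exists because the study's UK vignette means come from the
#'   auxiliary calibration cohort alone.
#' @param item item number.
#' @param vignettes vignette labels to summarize.
#' @return named numeric vector of means with a `counts` attribute.
#' @export
vignette_means <- function(data, group = "ALL", item, vignettes = LETTERS[1:6]) {
  require_oriented(data)
  sel <- resolve_group(data, group) & data$source == "VIGNETTE" &
    data$item == item
  d <- data[sel, ]
  means <- setNames(rep(NA_real_, length(vignettes)), vignettes)
  counts <- setNames(integer(length(vignettes)), vignettes)
  if (nrow(d)) {
    agg_m <- tapply(d$rating, d$vignette, mean)
    agg_n <- tapply(d$rating, d$vignette, length)
    means[names(agg_m)] <- agg_m
    counts[names(agg_n)] <- agg_n
  }
  attr(means, "counts") <- counts
  means
}

#' Rank vignettes by mean severity (6 = most severe)
#'
#' The largest mean gets the top rank (equal to the number of vignettes with
#' data), the smallest rank 1. Ties are broken by the a-priori severity order
#' (A most severe ... F least), the a-priori more severe vignette taking the
#' higher rank; integer ranks are always returned.
#'
#' @param means named vector from [vignette_means()]; `NA` entries (absent
#'   vignettes) are dropped.
#' @return named integer ranks.
#' @export
rank_vignettes <- function(means) {
  means <- means[!is.na(means)]
  if (!length(means)) stop("no vignette has data")
  prio <- match(names(means), rev(LETTERS[1:6])) # F=1 ... A=6
  ord <- order(means, prio) # ascending mean, ties: less a-priori severe first
  ranks <- integer(length(means))
  ranks[ord] <- seq_along(means)
  setNames(ranks, names(means))
}

#' A-priori order violations among vignette means
#'
#' Scans all pairs (u, v) with u a-priori more severe than v and reports
#' those where the less severe vignette received the higher mean rating,
#' with the magnitude of the reversal.
#'
#' @param means named vector from [vignette_means()].
#' @param expected_order labels from most to least a-priori severe.
#' @return data frame with columns `more_severe`, `less_severe`, `magnitude`
#'   (`mean(less) - mean(more)`, positive); zero rows if the order holds.
#' @export
order_violations <- function(means, expected_order = LETTERS[1:6]) {
  expected_order <- intersect(expected_order, names(means)[!is.na(means)])
  out <- list()
  for (a in seq_along(expected_order)) {
    for (b in seq_along(expected_order)) {
      if (a >= b) next
      u <- expected_order[a]; v <- expected_order[b]
      if (means[[u]] < means[[v]])
        out[[length(out) + 1L]] <- data.frame(
          more_severe = u, less_severe = v,
          magnitude = means[[v]] - means[[u]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(more_severe = character(), less_severe = character(),
                      magnitude = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Range of vignette mean ratings
#'
#' `max - min` over vignettes with data.
#'
#' @param means named vector from [vignette_means()].
#' @return nonnegative scalar.
#' @export
rating_range <- function(means) {
  means <- means[!is.na(means)]
  if (!length(means)) return(NA_real_)
  max(means) - min(means)
}

#' Full descriptive summary of one item's vignettes
#'
#' @inheritParams vignette_means
#' @return a `vignette_summary` object: group, item, means, counts, ranks,
#'   range and order violations.
#' @export
vignette_summary <- function(data, group = "ALL", item) {
  means <- vignette_means(data, group, item)
  structure(list(group = group, item = item, means = means,
                 counts = attr(means, "counts"),
                 ranks = rank_vignettes(means),
                 range = rating_range(means),
                 violations = order_violations(means)),
            class = "vignette_summary")
}

#' @export
print.vignette_summary <- function(x, ...) {
  cat("Vignette summary - group", x$group, "item", x$item, "\n")
  tab <- rbind(mean = round(x$means, 3), n = x$counts,
               rank = x$ranks[names(x$means)])
  print(tab)
  cat("range:", format(x$range, digits = 3), "\n")
  if (nrow(x$violations)) {
    cat("order violations:\n"); print(x$violations)
  } else cat("no order violations\n")
  invisible(x)
}
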