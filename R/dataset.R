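# Long-format response data: one ordinal rating per person x item x source
# (x vignette). The long layout represents the design's structural
# missingness (vignette-only calibration cohort, random vignette subsets)
# without sentinel values.

DATASET_COLUMNS <- c("person_id", "country", "cohort", "item", "source",
                     "vignette", "rating")

#' Construct a validated response dataset
#'
#' @param records data frame with columns `person_id`, `country` (IN/UK),
#'   `cohort` (IN_MAIN/UK_SELF/UK_AV), `item` (integer 1-10), `source`
#'   (SELF/VIGNETTE), `vignette` (A-F, `NA` for self-reports) and `rating`
#'   (integer 0-3).
#' @param oriented logical: have ratings already been oriented so that higher
#'   means more distress (reverse-keyed items flipped)? Model fitting
#'   requires an oriented dataset; see [reverse_code()].
#' @return an object of class `av_dataset` (a data frame with an `oriented`
#'   attribute).
#' @export
av_dataset <- function(records, oriented = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  miss <- setdiff(DATASET_COLUMNS, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- records[DATASET_COLUMNS]
  records$person_id <- as.character(records$person_id)
  records$country <- as.character(records$country)
  records$cohort <- as.character(records$cohort)
  records$source <- as.character(records$source)
  records$vignette <- as.character(records$vignette)
  records$vignette[!is.na(records$vignette) & records$vignette == ""] <- NA
  rat <- suppressWarnings(as.numeric(records$rating))
  itm <- suppressWarnings(as.numeric(records$item))

  fail_row <- function(bad, msg) {
    if (any(bad)) stop(msg, " in row(s) ", paste(head(which(bad), 5L), collapse = ", "),
                       if (sum(bad) > 5L) " ..." else "", call. = FALSE)
  }
  fail_row(is.na(rat) | rat != round(rat) | rat < 0 | rat > 3,
           "malformed rating (must be an integer 0-3)")
  fail_row(is.na(itm) | itm != round(itm) | itm < 1 | itm > 10,
           "malformed item (must be an integer 1-10)")
  fail_row(!records$country %in% COUNTRIES, "unknown country code")
  fail_row(!records$cohort %in% COHORTS, "unknown cohort code")
  fail_row(!records$source %in% c("SELF", "VIGNETTE"), "unknown source code")
  fail_row(records$source == "SELF" & !is.na(records$vignette),
           "SELF record with a vignette label")
  fail_row(records$source == "VIGNETTE" & is.na(records$vignette),
           "VIGNETTE record without a vignette label")
  fail_row(!is.na(records$vignette) & !records$vignette %in% LETTERS[1:6],
           "unknown vignette label")
  records$rating <- as.integer(rat)
  records$item <- as.integer(itm)
  rownames(records) <- NULL
  structure(records, class = c("av_dataset", "data.frame"),
            oriented = isTRUE(oriented))
}

#' @export
print.av_dataset <- function(x, ...) {
  cat("av_dataset:", nrow(x), "records,",
      length(unique(x$person_id)), "persons;",
      "oriented =", isTRUE(attr(x, "oriented")), "\n")
  tab <- table(x$cohort, x$source)
  print(tab)
  invisible(x)
}

is_oriented <- function(data) isTRUE(attr(data, "oriented"))

require_oriented <- function(data) {
  if (!is_oriented(data))
    stop("dataset is not oriented (higher = distress); apply reverse_code() first",
         call. = FALSE)
  invisible(data)
}

#' Structural validation of a response dataset
#'
#' Checks the design invariants that go beyond per-row field validity:
#' duplicated self-reports or vignette ratings, persons appearing under more
#' than one country/cohort, country inconsistent with cohort, and the
#' structural missingness of the three-cohort design (the vignette-only
#' calibration cohort contributes no self-reports; the self-only cohort no
#' vignette ratings). Reports issues; never raises.
#'
#' @param data an [av_dataset()].
#' @return data frame with columns `person_id`, `type`, `detail`; zero rows
#'   when every invariant holds.
#' @export
validate_responses <- function(data) {
  stopifnot(inherits(data, "av_dataset"))
  issues <- list()
  add <- function(pid, type, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      person_id = pid, type = type, detail = detail, stringsAsFactors = FALSE)
  }
  self <- data[data$source == "SELF", ]
  key <- paste(self$person_id, self$item)
  for (k in unique(key[duplicated(key)]))
    add(sub(" .*", "", k), "duplicate_self",
        paste0("more than one self-report for (person, item) = (", k, ")"))
  vig <- data[data$source == "VIGNETTE", ]
  keyv <- paste(vig$person_id, vig$item, vig$vignette)
  for (k in unique(keyv[duplicated(keyv)]))
    add(sub(" .*", "", k), "duplicate_vignette",
        paste0("more than one rating for (person, item, vignette) = (", k, ")"))
  pi <- unique(data[c("person_id", "country", "cohort")])
  for (p in unique(pi$person_id[duplicated(pi$person_id)]))
    add(p, "inconsistent_person", "person appears with conflicting country/cohort")
  bad_cc <- pi$country != ifelse(pi$cohort == "IN_MAIN", "IN", "UK")
  for (p in pi$person_id[bad_cc])
    add(p, "country_cohort_mismatch", "country does not match cohort")
  for (p in unique(self$person_id[self$person_id %in%
                                  pi$person_id[pi$cohort == "UK_AV"]]))
    add(p, "structural_design",
        "UK_AV (vignette-only calibration cohort) person has a SELF record")
  for (p in unique(vig$person_id[vig$person_id %in%
                                 pi$person_id[pi$cohort == "UK_SELF"]]))
    add(p, "structural_design", "UK_SELF (self-only cohort) person has a VIGNETTE record")
  if (!length(issues))
    return(data.frame(person_id = character(), type = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Read a response table from delimited text
#'
#' Expects a UTF-8 comma-separated file with a header row and the columns of
#' [av_dataset()]; an empty string marks the absent vignette on self-report
#' rows. Row-level problems (rating outside 0-3, unknown codes, a SELF row
#' carrying a vignette label) are rejected with the offending row named.
#'
#' @param path file path.
#' @param oriented whether the file's ratings are already oriented
#'   (higher = distress). Files written by [write_responses()] from simulated
#'   data are; raw questionnaire exports keyed like the EPDS are not.
#' @return an [av_dataset()].
#' @export
read_responses <- function(path, oriented = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", na.strings = character())
  av_dataset(df, oriented = oriented)
}

#' Write a response table as delimited text
#'
#' Inverse of [read_responses()]: the written file re-reads to an equal
#' dataset (records compared after canonical ordering).
#'
#' @param data an [av_dataset()].
#' @param path destination path.
#' @export
write_responses <- function(data, path) {
  stopifnot(inherits(data, "av_dataset"))
  out <- as.data.frame(data)
  out$vignette[is.na(out$vignette)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Canonical record ordering, for equality comparisons.
sort_records <- function(data) {
  o <- order(data$person_id, data$item, data$source, data$vignette,
             method = "radix", na.last = TRUE)
  out <- as.data.frame(data)[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "oriented") <- NULL
  attr(out, "config_seed") <- NULL
  class(out) <- "data.frame"
  out
}
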