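# MFI-20 questionnaire scoring (five 4-item domains + total, 20..100) and
# task-behavior metrics (accuracy, reaction time).

MFI_DOMAINS <- c("general_fatigue", "physical_fatigue", "reduced_activity",
                 "reduced_motivation", "mental_fatigue")

#' Load an MFI-20 scoring key
#'
#' The key maps each of the 20 items to one of the five fatigue domains and
#' flags positively phrased items for reverse scoring (`r -> 6 - r`). The key
#' is configuration, not code: any YAML file with the same structure can be
#' supplied. The bundled default encodes the published MFI-20 key.
#'
#' @param path YAML key file; defaults to the key shipped with the package.
#' @return Data frame with columns `item`, `domain`, `reversed`.
#' @export
mfi_key <- function(path = system.file("extdata", "mfi20_key.yaml",
                                       package = "phasicfmri")) {
  raw <- yaml::read_yaml(path)$items
  key <- do.call(rbind, lapply(raw, function(r) {
    data.frame(item = as.integer(r$item), domain = r$domain,
               reversed = isTRUE(r$reversed))
  }))
  key <- key[order(key$item), , drop = FALSE]
  if (!identical(key$item, 1:20)) {
    stop_config("MFI key must cover items 1..20 exactly once")
  }
  tab <- table(key$domain)
  if (!setequal(names(tab), MFI_DOMAINS) || any(tab != 4L)) {
    stop_config("MFI key must assign exactly 4 items to each of the 5 domains")
  }
  rownames(key) <- NULL
  key
}

#' Score an MFI-20 response
#'
#' Reverse-scored items are mapped `r -> 6 - r`; each domain score is the sum
#' of its four scored items (range 4..20); the total is the sum of the five
#' domains (range 20..100, higher = more fatigue). Missing items are an
#' error, not imputed.
#'
#' @param items Integer vector of 20 raw responses, each in 1..5.
#' @param key Scoring key, see [mfi_key()].
#' @return Named list with the five domain scores and `mfi_total`.
#' @examples
#' score_mfi(rep(5, 20))$mfi_total  # maximum fatigue: 100
#' @export
score_mfi <- function(items, key = mfi_key()) {
  if (length(items) != 20L) {
    stop_config("expected 20 MFI items, got %d", length(items))
  }
  if (anyNA(items)) {
    stop_config("missing MFI item(s): %s",
                paste(which(is.na(items)), collapse = ", "))
  }
  items <- as.numeric(items)
  bad <- which(items < 1 | items > 5 | items != round(items))
  if (length(bad)) {
    stop_config("MFI item(s) out of range 1..5: item %s",
                paste(bad, collapse = ", "))
  }
  scored <- ifelse(key$reversed, 6 - items, items)
  domains <- vapply(MFI_DOMAINS, function(d) sum(scored[key$domain == d]),
                    numeric(1))
  c(as.list(domains), list(mfi_total = sum(domains)))
}

#' Decompose a target MFI-total into 20 item responses
#'
#' Inverse of [score_mfi()] in the total: draws scored item values in 1..5
#' summing exactly to `total` (base value 1 per item plus a seeded random
#' allocation of the remainder, at most +4 per item), then maps them back to
#' raw responses through the key's reverse-scoring flags. Used by the
#' synthetic-cohort generator so that scoring round-trips exactly.
#'
#' @param total Target MFI-total in 20..100.
#' @param key Scoring key.
#' @param seed Integer seed.
#' @return Integer vector of 20 raw item responses.
#' @export
decompose_mfi_total <- function(total, key = mfi_key(), seed = 1L) {
  total <- assert_count(total, "total", min = 20L)
  if (total > 100L) stop_config("MFI total must be <= 100 (got %d)", total)
  scored <- with_seed(seed, {
    s <- rep(1L, 20L)
    extra <- total - 20L
    while (extra > 0L) {
      open <- which(s < 5L)
      take <- if (length(open) == 1L) open else sample(open, 1L)
      bump <- min(5L - s[take], sample.int(extra, 1L))
      s[take] <- s[take] + bump
      extra <- extra - bump
    }
    s
  })
  as.integer(ifelse(key$reversed, 6L - scored, scored))
}

#' Task accuracy from a response log
#'
#' Accuracy is the percentage of correct responses over all recorded
#' responses to cue-plus-stimulus trials.
#'
#' @param log Response log data frame with a logical `correct` column (one
#'   row per CUE_STIM trial), as produced by [synthesize_behavior()].
#' @return Percentage in 0..100, or `NA` (with a warning) for an empty log.
#' @export
compute_accuracy <- function(log) {
  if (is.null(log) || nrow(log) == 0L) {
    warning("no responses recorded: accuracy undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(log$correct) / nrow(log)
}

#' Mean reaction time from a response log
#'
#' Reaction time is response time minus stimulus presentation time,
#' averaged over correct responses only.
#'
#' @param log Response log with columns `correct` and `rt_ms`.
#' @return Mean reaction time in milliseconds, or `NA` (with a warning) if
#'   there are no correct responses.
#' @export
compute_rt <- function(log) {
  if (is.null(log) || nrow(log) == 0L || !any(log$correct)) {
    warning("no correct responses: reaction time undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(log$rt_ms[log$correct])
}

#' Read MFI responses from CSV
#'
#' @param path CSV with columns `subject_id`, `item_01`..`item_20`.
#' @return Data frame.
#' @export
read_mfi_responses <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", sprintf("item_%02d", 1:20))
  if (!all(need %in% names(df))) {
    stop_config("MFI response file lacks columns: %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Score a table of MFI responses
#'
#' @param responses Data frame as read by [read_mfi_responses()].
#' @param key Scoring key.
#' @return Data frame with subject_id, the five domain scores and mfi_total.
#' @export
score_mfi_table <- function(responses, key = mfi_key()) {
  item_cols <- sprintf("item_%02d", 1:20)
  out <- lapply(seq_len(nrow(responses)), function(i) {
    s <- score_mfi(as.integer(responses[i, item_cols]), key)
    data.frame(subject_id = responses$subject_id[i], as.data.frame(s))
  })
  do.call(rbind, out)
}
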