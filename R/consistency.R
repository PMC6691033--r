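# Temporal consistency scoring in CIELuv and synesthete classification.
#
# For each item answered three times, d is the sum of the three pairwise
# Euclidean distances between the trial colors in CIELuv; a participant's
# consistency score c is the mean of d over items with three valid color
# responses. Low c means stable associations; participants with
# c < cutoff (default 135.3) are classified as synesthetes.

#' Default task item counts
#'
#' The vowel task has 16 items, the grapheme task 36 (letters A-Z and
#' digits 0-9).
#'
#' @param task `"vowel"` or `"grapheme"`.
#' @return Integer item count.
#' @export
task_n_items <- function(task = c("vowel", "grapheme")) {
  task <- match.arg(task)
  c(vowel = 16L, grapheme = 36L)[[task]]
}

#' Per-item consistency d
#'
#' Sum of the three pairwise Euclidean distances in CIELuv between the
#' repeated color choices for one item. Invariant under any permutation of
#' the three trials; zero exactly when all three choices are identical.
#'
#' @param c1,c2,c3 Luv coordinates of the three repetitions (length-3
#'   vectors). Alternatively pass a single 3 x 3 matrix as `c1` (one
#'   repetition per row).
#' @return Nonnegative `d`.
#' @export
item_consistency <- function(c1, c2, c3 = NULL) {
  if (is.null(c3) && is.matrix(c1) && nrow(c1) == 3L) {
    m <- c1
  } else {
    m <- rbind(c1, c2, c3)
  }
  if (nrow(m) != 3L) {
    stop("item consistency needs exactly three color responses",
         call. = FALSE)
  }
  if (anyNA(m)) stop("missing color in item_consistency()", call. = FALSE)
  luv_distance(m[1, ], m[2, ]) + luv_distance(m[2, ], m[3, ]) +
    luv_distance(m[1, ], m[3, ])
}

#' Classify a consistency score
#'
#' Strictly-below-cutoff classification: `c < cutoff` is a synesthete.
#' A score exactly at the cutoff is a nonsynesthete.
#'
#' @param c Consistency score(s), nonnegative.
#' @param cutoff Classification cutoff (default 135.3).
#' @return Character vector, `"synesthete"` or `"nonsynesthete"`.
#' @export
classify_synesthete <- function(c, cutoff = 135.3) {
  if (any(is.finite(c) & c < 0)) {
    stop("negative consistency score", call. = FALSE)
  }
  ifelse(c < cutoff, "synesthete", "nonsynesthete")
}

# d values for one participant's trials; returns named vector with NA for
# items lacking three color responses.
.item_d_values <- function(trials) {
  items <- unique(trials$item)
  d <- rep(NA_real_, length(items))
  names(d) <- as.character(items)
  for (k in seq_along(items)) {
    rows <- trials[trials$item == items[k], , drop = FALSE]
    if (nrow(rows) != 3L || any(rows$no_color)) next
    luv <- rgb_to_luv(as.matrix(rows[, c("r", "g", "b")]))
    d[k] <- item_consistency(luv)
  }
  d
}

#' Consistency result for one participant
#'
#' Computes per-item `d`, the mean score `c` over valid items, and the
#' classification. An item is valid only when all three repetitions carry a
#' color; any no-color trial invalidates the item. A participant whose
#' valid items number fewer than half the task's item count is excluded
#' (no-color for more than half the items), as is a participant with no
#' valid item at all.
#'
#' @param trials Trial data.frame for a single participant and task
#'   (columns `participant`, `task`, `item`, `repetition`, `r`, `g`, `b`,
#'   `no_color`).
#' @param cutoff Classification cutoff (default 135.3).
#' @param n_items Total items in the task; defaults from the task label.
#' @return A list of class `"consistency_result"`: `participant`,
#'   `per_item_d` (named, `NA` for invalid items), `c`, `n_valid_items`,
#'   `classification` (`"synesthete"`, `"nonsynesthete"` or `"excluded"`).
#' @export
participant_consistency <- function(trials, cutoff = 135.3,
                                    n_items = NULL) {
  stopifnot(length(unique(trials$participant)) == 1L)
  if (is.null(n_items)) n_items <- task_n_items(trials$task[1])
  d <- .item_d_values(trials)
  valid <- sum(!is.na(d))
  res <- list(participant = trials$participant[1],
              per_item_d = d,
              c = if (valid > 0) mean(d, na.rm = TRUE) else NA_real_,
              n_valid_items = valid,
              classification = NA_character_)
  # "more than half the items" no-color => excluded; exactly half retained
  if (valid == 0L || (n_items - valid) > n_items / 2) {
    res$classification <- "excluded"
  } else {
    res$classification <- classify_synesthete(res$c, cutoff)
  }
  class(res) <- "consistency_result"
  res
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("Consistency result for participant", x$participant, "\n")
  cat(sprintf("  c = %s over %d valid item(s); classification: %s\n",
              ifelse(is.na(x$c), "NA", formatC(x$c, digits = 4,
                                               format = "f")),
              x$n_valid_items, x$classification))
  invisible(x)
}

#' Score a whole cohort's consistency
#'
#' Runs [participant_consistency()] per participant and summarizes the
#' cohort: classified counts and group mean/sd of `c`.
#'
#' @param trials Trial data.frame for one task (possibly many
#'   participants).
#' @param task Task to score; trials of other tasks are dropped.
#' @param cutoff Classification cutoff (default 135.3).
#' @param n_items Total items in the task; defaults from `task`.
#' @return A list of class `"consistency_cohort"` with `results` (one row
#'   per participant: `participant`, `c`, `n_valid_items`,
#'   `classification`) and `summary` (counts and group statistics).
#' @export
cohort_consistency <- function(trials, task = c("vowel", "grapheme"),
                               cutoff = 135.3, n_items = NULL) {
  task <- match.arg(task)
  trials <- validate_trials(trials)
  trials <- trials[trials$task == task, , drop = FALSE]
  if (is.null(n_items)) n_items <- task_n_items(task)
  ids <- unique(trials$participant)
  rows <- lapply(ids, function(id) {
    r <- participant_consistency(
      trials[trials$participant == id, , drop = FALSE],
      cutoff = cutoff, n_items = n_items)
    data.frame(participant = id, c = r$c, n_valid_items = r$n_valid_items,
               classification = r$classification, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  if (is.null(results)) {
    results <- data.frame(participant = character(0), c = numeric(0),
                          n_valid_items = integer(0),
                          classification = character(0))
  }
  grp <- function(cls) {
    v <- results$c[results$classification == cls]
    list(n = length(v), mean_c = if (length(v)) mean(v) else NA_real_,
         sd_c = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  out <- list(results = results,
              summary = list(task = task, cutoff = cutoff,
                             n_participants = nrow(results),
                             n_excluded =
                               sum(results$classification == "excluded"),
                             synesthete = grp("synesthete"),
                             nonsynesthete = grp("nonsynesthete")))
  class(out) <- "consistency_cohort"
  out
}

#' @export
print.consistency_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Consistency cohort (%s task, cutoff %.1f): %d participants\n",
              s$task, s$cutoff, s$n_participants))
  cat(sprintf("  excluded: %d\n", s$n_excluded))
  cat(sprintf("  synesthetes:    n = %4d  mean c = %s (sd %s)\n",
              s$synesthete$n, .fmt(s$synesthete$mean_c),
              .fmt(s$synesthete$sd_c)))
  cat(sprintf("  nonsynesthetes: n = %4d  mean c = %s (sd %s)\n",
              s$nonsynesthete$n, .fmt(s$nonsynesthete$mean_c),
              .fmt(s$nonsynesthete$sd_c)))
  invisible(x)
}

.fmt <- function(x) {
  if (is.null(x) || is.na(x)) "NA" else formatC(x, digits = 2, format = "f")
}
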