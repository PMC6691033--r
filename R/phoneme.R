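# Nearest-phoneme categorization of vowel stimuli in F1-F2 formant space.
#
# A phoneme inventory is a table of canonical monophthong formant values;
# categorizing a stimulus by its nearest Euclidean neighbor in raw Hz is
# identical to locating it in the Voronoi tessellation seeded by the
# inventory. Ties (measure-zero for real formants) break deterministically
# to the earliest inventory row.

#' Read a phoneme inventory table
#'
#' Expects a delimited text file with header columns `phoneme`, `F1`, `F2`
#' and optionally `grapheme` (the orthographic category associated with the
#' phoneme). Errors report the offending line number.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `phoneme`, `F1`, `F2` and, when
#'   present, `grapheme`.
#' @export
read_phoneme_inventory <- function(path) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phoneme", "F1", "F2")
  miss <- setdiff(need, names(inv))
  if (length(miss)) {
    stop("inventory ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_inventory(inv, where = path)
  inv
}

#' Validate a phoneme inventory
#'
#' @param inv Inventory data.frame (`phoneme`, `F1`, `F2`\[, `grapheme`\]).
#' @param where Label used in error messages (e.g., a file path).
#' @return The inventory, invisibly, after checks.
#' @export
validate_inventory <- function(inv, where = "inventory") {
  if (nrow(inv) < 2L) {
    stop(where, ": at least 2 inventory entries are required for ",
         "categorization", call. = FALSE)
  }
  if (anyDuplicated(inv$phoneme)) {
    dup <- inv$phoneme[duplicated(inv$phoneme)][1]
    stop(where, ": duplicate phoneme label '", dup, "' (row ",
         which(inv$phoneme == dup)[2] + 1L, ")", call. = FALSE)
  }
  bad <- which(!is.finite(inv$F1) | !is.finite(inv$F2) |
               inv$F1 <= 0 | inv$F2 <= 0)
  if (length(bad)) {
    stop(where, ": non-positive or missing formant at line ", bad[1] + 1L,
         call. = FALSE)
  }
  invisible(inv)
}

#' Read a vowel-stimulus table
#'
#' Expects header columns `item`, `F1`, `F2`. `F2 <= F1` is physically
#' unusual for ordinary vowels and triggers a warning, not an error.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `item`, `F1`, `F2`.
#' @export
read_vowel_stimuli <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "F1", "F2")
  miss <- setdiff(need, names(st))
  if (length(miss)) {
    stop("stimuli ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(st$item)) {
    stop("stimuli ", path, ": duplicate item id '",
         st$item[duplicated(st$item)][1], "'", call. = FALSE)
  }
  bad <- which(!is.finite(st$F1) | !is.finite(st$F2) |
               st$F1 <= 0 | st$F2 <= 0)
  if (length(bad)) {
    stop("stimuli ", path, ": non-positive or missing formant at line ",
         bad[1] + 1L, call. = FALSE)
  }
  if (any(st$F2 <= st$F1)) {
    warning("stimuli ", path, ": F2 <= F1 for item(s) ",
            paste(st$item[st$F2 <= st$F1], collapse = ", "), call. = FALSE)
  }
  st
}

#' Path to a packaged example table
#'
#' The packaged stimulus and inventory tables are synthetic placeholders:
#' 16 stimulus points spread through a plausible acoustic vowel space and a
#' 12-monophthong inventory with typical adult Dutch-like formant values.
#' They exercise the machinery; they are not measured data.
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
crossmodal_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "crossmodal")))
  }
  path <- system.file("extdata", file, package = "crossmodal")
  if (path == "") stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Nearest canonical phoneme in F1-F2 space
#'
#' Returns, for each query point, the inventory phoneme minimizing
#' Euclidean distance in raw Hz (equivalently, the Voronoi cell the query
#' falls in). Ties break to the earliest inventory row.
#'
#' @param F1,F2 Numeric vectors of query formants (Hz), recycled to a
#'   common length.
#' @param inventory Inventory data.frame (`phoneme`, `F1`, `F2`).
#' @param standardize If `TRUE`, z-score each formant axis (using the
#'   inventory's mean/sd) before measuring distance. Off by default:
#'   categorization operates in raw Hz.
#' @return Character vector of phoneme labels.
#' @export
nearest_phoneme <- function(F1, F2, inventory, standardize = FALSE) {
  validate_inventory(inventory)
  n <- max(length(F1), length(F2))
  F1 <- rep_len(F1, n)
  F2 <- rep_len(F2, n)
  i1 <- inventory$F1
  i2 <- inventory$F2
  if (standardize) {
    m1 <- mean(i1); s1 <- stats::sd(i1)
    m2 <- mean(i2); s2 <- stats::sd(i2)
    F1 <- (F1 - m1) / s1; i1 <- (i1 - m1) / s1
    F2 <- (F2 - m2) / s2; i2 <- (i2 - m2) / s2
  }
  # which.min returns the first minimizer: the deterministic tie-break
  idx <- vapply(seq_len(n), function(k) {
    which.min((F1[k] - i1)^2 + (F2[k] - i2)^2)
  }, integer(1))
  inventory$phoneme[idx]
}

#' Categorize stimuli by nearest phoneme and attach graphemes
#'
#' @param stimuli Stimulus data.frame (`item`, `F1`, `F2`).
#' @param inventory Inventory data.frame (`phoneme`, `F1`, `F2`) with a
#'   `grapheme` column or a separate `orthography` mapping.
#' @param orthography Optional named character vector mapping phoneme label
#'   to grapheme label; defaults to the inventory's `grapheme` column.
#' @param standardize Passed to [nearest_phoneme()].
#' @return The stimulus table with `phoneme` and `grapheme` columns filled.
#' @export
assign_categories <- function(stimuli, inventory, orthography = NULL,
                              standardize = FALSE) {
  if (nrow(stimuli) == 0L) {
    stimuli$phoneme <- character(0)
    stimuli$grapheme <- character(0)
    return(stimuli)
  }
  stimuli$phoneme <- nearest_phoneme(stimuli$F1, stimuli$F2, inventory,
                                     standardize = standardize)
  if (is.null(orthography)) {
    if (is.null(inventory$grapheme)) {
      stop("no orthography: supply `orthography` or an inventory with a ",
           "`grapheme` column", call. = FALSE)
    }
    orthography <- stats::setNames(inventory$grapheme, inventory$phoneme)
  }
  missing_orth <- setdiff(unique(stimuli$phoneme), names(orthography))
  if (length(missing_orth)) {
    stop("orthography has no grapheme for phoneme(s): ",
         paste(missing_orth, collapse = ", "), call. = FALSE)
  }
  stimuli$grapheme <- unname(orthography[stimuli$phoneme])
  stimuli
}

#' Canonical coordinates of categorized stimuli
#'
#' Maps each item to the canonical F1-F2 coordinates of its assigned
#' phoneme (not the stimulus's own raw formants). Two stimuli falling in
#' the same Voronoi cell therefore collapse onto identical coordinates;
#' this categorical collapse is deliberate, and these are the coordinates
#' the structure score measures vowel distances on.
#'
#' @param stimuli A categorized stimulus table (must carry `phoneme`).
#' @param inventory Inventory data.frame.
#' @return A data.frame with columns `item`, `phoneme`, `F1`, `F2` where
#'   the formants are the inventory's canonical values.
#' @export
canonical_coordinates <- function(stimuli, inventory) {
  if (is.null(stimuli$phoneme) || anyNA(stimuli$phoneme)) {
    stop("stimuli are not categorized; run assign_categories() first",
         call. = FALSE)
  }
  validate_inventory(inventory)
  idx <- match(stimuli$phoneme, inventory$phoneme)
  if (anyNA(idx)) {
    stop("phoneme label(s) not in inventory: ",
         paste(unique(stimuli$phoneme[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(item = stimuli$item,
             phoneme = stimuli$phoneme,
             F1 = inventory$F1[idx],
             F2 = inventory$F2[idx],
             stringsAsFactors = FALSE)
}
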