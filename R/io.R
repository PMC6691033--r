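# Trial-table I/O, validation and the end-to-end pipeline.
#
# One canonical trial schema serves both real and synthetic data:
#   participant, task, item, repetition, r, g, b, no_color
# No-color responses are encoded explicitly (no_color = TRUE with empty
# RGB), never as (0,0,0). Files from other sources can be adapted by
# renaming columns before validation (see `col_map` in read_trials()).

.TRIAL_COLS <- c("participant", "task", "item", "repetition",
                 "r", "g", "b", "no_color")

#' Validate a trial table
#'
#' Checks schema, channel ranges, repetition values, the no-color encoding
#' and (participant, task, item, repetition) uniqueness. Errors name the
#' offending data row (row 1 = first data row; add 1 for the file line
#' when the table came from a headered CSV).
#'
#' @param trials A data.frame in the canonical trial schema.
#' @return The validated trials, with `repetition` coerced to integer and
#'   `no_color` to logical.
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(.TRIAL_COLS, names(trials))
  if (length(miss)) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) return(trials)
  if (is.character(trials$no_color)) {
    lowered <- tolower(trials$no_color)
    if (!all(lowered %in% c("true", "false"))) {
      bad <- which(!lowered %in% c("true", "false"))[1]
      stop("row ", bad, ": unknown no-color encoding '",
           trials$no_color[bad], "' (use TRUE/FALSE)", call. = FALSE)
    }
    trials$no_color <- lowered == "true"
  }
  if (!is.logical(trials$no_color)) {
    stop("no_color must be logical (TRUE/FALSE)", call. = FALSE)
  }
  trials$item <- as.character(trials$item)
  trials$repetition <- as.integer(trials$repetition)
  bad <- which(!trials$repetition %in% 1:3)
  if (length(bad)) {
    stop("row ", bad[1], ": repetition must be 1, 2 or 3", call. = FALSE)
  }
  bad <- which(!trials$task %in% c("vowel", "grapheme"))
  if (length(bad)) {
    stop("row ", bad[1], ": task must be 'vowel' or 'grapheme'",
         call. = FALSE)
  }
  colored <- !trials$no_color
  rgb <- as.matrix(trials[, c("r", "g", "b")])
  bad <- which(colored & (is.na(rgb[, 1]) | is.na(rgb[, 2]) |
                            is.na(rgb[, 3])))
  if (length(bad)) {
    stop("row ", bad[1], ": color trial with missing RGB", call. = FALSE)
  }
  bad <- which(!colored & !(is.na(rgb[, 1]) & is.na(rgb[, 2]) &
                              is.na(rgb[, 3])))
  if (length(bad)) {
    stop("row ", bad[1], ": no-color trial must have empty RGB ",
         "(never 0,0,0)", call. = FALSE)
  }
  vals <- rgb[colored, , drop = FALSE]
  if (length(vals) && (any(vals < 0 | vals > 255) ||
                       any(vals != round(vals)))) {
    off <- which(colored)[which(rowSums(vals < 0 | vals > 255 |
                                          vals != round(vals)) > 0)[1]]
    stop("row ", off, ": RGB channels must be integers in [0, 255]",
         call. = FALSE)
  }
  key <- paste(trials$participant, trials$task, trials$item,
               trials$repetition, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("row ", dup[1], ": duplicate (participant, task, item, ",
         "repetition) record", call. = FALSE)
  }
  trials
}

#' Read a trial table from delimited text
#'
#' @param path Path to a headered CSV in the canonical schema.
#' @param col_map Optional named character vector adapting foreign column
#'   names, e.g. `c(participant = "subject_id")` reads the file's
#'   `subject_id` column as `participant`.
#' @return A validated trial data.frame.
#' @export
read_trials <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(trials)) {
        stop(path, ": adapter column '", col_map[[canon]], "' not found",
             call. = FALSE)
      }
      names(trials)[names(trials) == col_map[[canon]]] <- canon
    }
  }
  out <- tryCatch(validate_trials(trials), error = function(e) {
    stop(path, ": ", conditionMessage(e), call. = FALSE)
  })
  out[, .TRIAL_COLS, drop = FALSE]
}

#' Write a trial table as delimited text
#'
#' @param trials A trial data.frame (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.csv(trials[, .TRIAL_COLS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults mirror the study conditions: cutoff 135.3, 10,000 permutations,
#' per-item triples as the permutation unit.
#'
#' @param task `"vowel"` or `"grapheme"`.
#' @param cutoff Consistency classification cutoff.
#' @param n_perm Permutations per participant for the structure score.
#' @param seed Integer seed governing the permutation streams.
#' @param stimuli_path,inventory_path Paths to the stimulus and inventory
#'   tables; default to the packaged synthetic placeholders.
#' @param permutation_unit `"triple"` or `"response"`.
#' @param alpha Significance level for structured-mapping flags.
#' @param out_dir Optional directory for result files.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(task = "vowel", cutoff = 135.3, n_perm = 10000,
                       seed = 1L,
                       stimuli_path =
                         crossmodal_example("vowel_stimuli_synthetic.csv"),
                       inventory_path =
                         crossmodal_example("phoneme_inventory_synthetic.csv"),
                       permutation_unit = c("triple", "response"),
                       alpha = 0.05, out_dir = NULL) {
  out <- list(task = match.arg(task, c("vowel", "grapheme")),
              cutoff = cutoff, n_perm = as.integer(n_perm),
              seed = as.integer(seed), stimuli_path = stimuli_path,
              inventory_path = inventory_path,
              permutation_unit = match.arg(permutation_unit),
              alpha = alpha, out_dir = out_dir)
  class(out) <- "run_config"
  out
}

#' Run the full analysis pipeline
#'
#' Validation, consistency scoring with exclusion, synesthete
#' classification, per-participant structure scores, and the group report,
#' with a manifest recording the seed and the participant counts at every
#' filter stage (the counts reconcile exactly: scored + excluded +
#' too-few-responses = total). If `out_dir` is set, writes
#' `consistency.csv`, `structure.csv` and `manifest.json` there.
#'
#' @param trials A trial data.frame or a path to a trial CSV.
#' @param config A [run_config()].
#' @return A list of class `"pipeline_result"`: `consistency`, `structure`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(trials, config = run_config()) {
  if (is.character(trials)) trials <- read_trials(trials)
  trials <- validate_trials(trials)
  trials <- trials[trials$task == config$task, , drop = FALSE]
  n_total <- length(unique(trials$participant))

  st <- read_vowel_stimuli(config$stimuli_path)
  inv <- read_phoneme_inventory(config$inventory_path)
  coords <- canonical_coordinates(assign_categories(st, inv), inv)

  cons <- cohort_consistency(trials, task = config$task,
                             cutoff = config$cutoff)
  retained <- cons$results$participant[
    cons$results$classification != "excluded"]
  struct <- cohort_structure(
    trials[trials$participant %in% retained, , drop = FALSE], coords,
    n_perm = config$n_perm, seed = config$seed,
    unit = config$permutation_unit, alpha = config$alpha)
  report <- compare_groups(struct, cons, alpha = config$alpha)

  manifest <- list(
    task = config$task, cutoff = config$cutoff, n_perm = config$n_perm,
    seed = config$seed, permutation_unit = config$permutation_unit,
    package_version = as.character(utils::packageVersion("crossmodal")),
    stages = list(
      input = list(n_in = n_total, n_out = n_total, rule = "validated"),
      consistency_exclusion = list(
        n_in = n_total, n_out = length(retained),
        rule = "no-color for more than half the items"),
      structure = list(
        n_in = length(retained),
        n_out = sum(!is.na(struct$z)),
        rule = "at least 3 colored responses")),
    counts = list(
      synesthete = sum(cons$results$classification == "synesthete"),
      nonsynesthete = sum(cons$results$classification == "nonsynesthete"),
      excluded = sum(cons$results$classification == "excluded"),
      degenerate_structure = sum(struct$degenerate)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cons$results,
                     file.path(config$out_dir, "consistency.csv"),
                     row.names = FALSE)
    utils::write.csv(struct, file.path(config$out_dir, "structure.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out <- list(consistency = cons, structure = struct, report = report,
              manifest = manifest)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run (", m$task, " task, seed ", m$seed, ")\n", sep = "")
  cat(sprintf("  participants: %d in, %d retained, %d structure-scored\n",
              m$stages$input$n_in, m$stages$consistency_exclusion$n_out,
              m$stages$structure$n_out))
  print(x$consistency)
  print(x$report)
  invisible(x)
}
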