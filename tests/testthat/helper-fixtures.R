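# Small in-code fixtures shared across test files.

# A random phoneme inventory with guaranteed-distinct points.
random_inventory <- function(n = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(phoneme = paste0("ph", seq_len(n)),
             F1 = runif(n, 250, 900),
             F2 = runif(n, 700, 2400),
             grapheme = paste0("g", seq_len(n)),
             stringsAsFactors = FALSE)
}

# A tiny canonical-coordinate table.
toy_coords <- function(n_items = 4) {
  data.frame(item = seq_len(n_items),
             F1 = seq(300, 800, length.out = n_items),
             F2 = seq(2200, 900, length.out = n_items))
}

# Build a trial table directly from an item -> rgb matrix spec.
make_trials <- function(rgb_by_item, participant = "p1", task = "vowel",
                        no_color = NULL) {
  rows <- list()
  for (it in names(rgb_by_item)) {
    m <- rgb_by_item[[it]]
    for (rep in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = participant, task = task, item = it,
        repetition = rep, r = m[rep, 1], g = m[rep, 2], b = m[rep, 3],
        no_color = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(no_color)) {
    for (k in no_color) {
      out$no_color[k] <- TRUE
      out$r[k] <- NA_integer_; out$g[k] <- NA_integer_
      out$b[k] <- NA_integer_
    }
  }
  out
}
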