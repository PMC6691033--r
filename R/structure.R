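# Mantel-permutation structure score.
#
# A participant's mapping is "structured" when pairs of items that are
# close in canonical F1-F2 space received colors that are close in CIELab
# (measured by CIEDE2000), and distant items received distant colors. The
# score correlates the two pairwise distance matrices (Mantel statistic),
# builds a permutation null by shuffling responses within each item and
# then reassigning responses across items, and reports where the veridical
# correlation sits in that null (z, one-sided p).

#' Pairwise vowel distances between responses
#'
#' Euclidean distances in F1-F2 space between the canonical coordinates of
#' each response's item. Same-item response pairs have distance zero by
#' construction.
#'
#' @param items Vector of item ids, one per response.
#' @param coords Canonical coordinate table (`item`, `F1`, `F2`), e.g. from
#'   [canonical_coordinates()].
#' @return A symmetric n x n matrix with zero diagonal.
#' @export
vowel_distances <- function(items, coords) {
  idx <- match(items, coords$item)
  if (anyNA(idx)) {
    stop("no canonical coordinates for item(s): ",
         paste(unique(items[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  xy <- cbind(coords$F1[idx], coords$F2[idx])
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- NULL
  D
}

#' Pairwise CIEDE2000 distances between response colors
#'
#' @param lab An n x 3 matrix of CIELab coordinates (no-color responses
#'   must have been removed upstream).
#' @return A symmetric n x n matrix with zero diagonal.
#' @export
color_distances <- function(lab) {
  lab <- .as_color_matrix(lab, "Lab")
  if (anyNA(lab)) {
    stop("color_distances() received missing colors; drop no-color ",
         "responses first", call. = FALSE)
  }
  n <- nrow(lab)
  D <- matrix(0, n, n)
  if (n > 1) {
    pr <- which(upper.tri(D), arr.ind = TRUE)
    d <- delta_e2000(lab[pr[, 1], , drop = FALSE],
                     lab[pr[, 2], , drop = FALSE])
    D[upper.tri(D)] <- d
    D <- D + t(D)
  }
  D
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation over the vectorized strict upper triangles. The two
#' matrices must index the same responses in the same order.
#'
#' @param A,B Symmetric n x n distance matrices (n >= 3).
#' @return Correlation in \[-1, 1\], or `NA` when either triangle has zero
#'   variance (degenerate signal).
#' @export
mantel_r <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)))
  if (nrow(A) < 3L) stop("mantel_r() needs at least 3 responses",
                         call. = FALSE)
  x <- A[upper.tri(A)]
  y <- B[upper.tri(B)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' One permutation of the item-to-color mapping
#'
#' Implements the null-model shuffle: responses are first shuffled within
#' each item, then whole per-item response sets are reassigned across
#' items (a random bijection of item labels). Color values are untouched;
#' only which item they answer changes. With the `"response"` unit, item
#' labels are instead shuffled across individual responses, breaking up
#' the per-item sets.
#'
#' @param responses Data.frame with an `item` column; every other column is
#'   response payload (e.g., `r`, `g`, `b`).
#' @param unit `"triple"` (per-item response sets move as a unit; default)
#'   or `"response"`.
#' @return The data.frame with the same multiset of payload rows, items
#'   permuted.
#' @export
permute_mapping <- function(responses, unit = c("triple", "response")) {
  unit <- match.arg(unit)
  if (is.null(responses$item)) stop("responses need an `item` column",
                                    call. = FALSE)
  payload <- setdiff(names(responses), "item")
  out <- responses
  if (unit == "response") {
    out$item <- responses$item[sample(nrow(responses))]
    return(out)
  }
  items <- unique(responses$item)
  # step 1: shuffle payload within each item
  for (it in items) {
    rows <- which(responses$item == it)
    out[rows, payload] <- responses[sample(rows), payload, drop = FALSE]
  }
  # step 2: reassign item labels across items
  relab <- stats::setNames(sample(items), items)
  out$item <- unname(relab[as.character(responses$item)])
  out
}

# Fast path shared by structure_score()/cohort_structure(): permuting whole
# per-item response sets across items changes the vowel-distance matrix only
# through the item relabeling (the within-item shuffle cannot change any
# distance because same-item vowel distances are all zero), so each
# permutation reduces to indexing a precomputed item-level distance matrix.
.structure_engine <- function(it, lab, Ditem, n_perm, unit) {
  n <- length(it)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ia <- pr[, 1]; ib <- pr[, 2]
  colorvec <- delta_e2000(lab[ia, , drop = FALSE], lab[ib, , drop = FALSE])
  vowelvec <- Ditem[cbind(it[ia], it[ib])]
  if (stats::sd(colorvec) == 0 || stats::sd(vowelvec) == 0) {
    return(list(r = NA_real_, perm = numeric(0), degenerate = TRUE))
  }
  r0 <- stats::cor(vowelvec, colorvec)
  m <- nrow(Ditem)
  perm <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    if (unit == "triple") {
      pi_k <- sample.int(m)
      pit <- pi_k[it]
    } else {
      pit <- it[sample.int(n)]
    }
    pv <- Ditem[cbind(pit[ia], pit[ib])]
    s <- stats::sd(pv)
    perm[k] <- if (s == 0) 0 else stats::cor(pv, colorvec)
  }
  list(r = r0, perm = perm, degenerate = FALSE)
}

#' Structure score for one participant
#'
#' Correlates the participant's vowel-distance matrix (canonical F1-F2)
#' with the CIEDE2000 color-distance matrix, then compares the veridical
#' correlation against `n_perm` random reassignments of responses to items.
#' Reports `z = (r - mean(perm)) / sd(perm)` and the one-sided
#' add-one-smoothed p-value `p = (1 + #\{r_perm >= r\}) / (1 + n_perm)`
#' (ties count against significance). A mapping is flagged significant
#' when fewer than `alpha` of the permuted mappings are at least as
#' structured as the real one.
#'
#' Degenerate inputs (a single color for every response, or responses to a
#' single item) have no structure signal: `degenerate = TRUE`, `z = 0`,
#' `p = 1`.
#'
#' @param trials Data.frame of one participant's responses with columns
#'   `item`, `r`, `g`, `b` and optionally `no_color` (no-color rows are
#'   dropped; at least 3 colored responses must remain).
#' @param coords Canonical coordinate table (`item`, `F1`, `F2`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for a reproducible permutation stream.
#' @param unit Permutation unit, see [permute_mapping()].
#' @param alpha Significance level for the `significant` flag.
#' @return A list of class `"structure_result"`: `r_veridical`, `n_perm`,
#'   `perm_mean`, `perm_sd`, `z`, `p`, `significant`, `degenerate`,
#'   `n_responses`, `seed`, `unit`.
#' @export
structure_score <- function(trials, coords, n_perm = 10000, seed = NULL,
                            unit = c("triple", "response"), alpha = 0.05) {
  unit <- match.arg(unit)
  if (!is.null(trials$no_color)) {
    trials <- trials[!trials$no_color, , drop = FALSE]
  }
  if (nrow(trials) < 3L) {
    stop("structure_score() needs at least 3 colored responses",
         call. = FALSE)
  }
  lab <- rgb_to_lab(as.matrix(trials[, c("r", "g", "b")]))
  items <- unique(trials$item)
  it <- match(trials$item, items)
  Ditem <- vowel_distances(items, coords)

  res <- .with_seed(seed, .structure_engine(it, lab, Ditem, n_perm, unit))

  out <- list(r_veridical = res$r, n_perm = n_perm,
              perm_mean = NA_real_, perm_sd = NA_real_,
              z = 0, p = 1, significant = FALSE,
              degenerate = TRUE, n_responses = nrow(trials),
              seed = seed, unit = unit)
  if (!res$degenerate) {
    pm <- mean(res$perm)
    ps <- stats::sd(res$perm)
    out$perm_mean <- pm
    out$perm_sd <- ps
    if (ps > 0) {
      out$degenerate <- FALSE
      out$z <- (res$r - pm) / ps
      out$p <- (1 + sum(res$perm >= res$r)) / (1 + n_perm)
      out$significant <- out$p <= alpha
    }
  }
  class(out) <- "structure_result"
  out
}

#' @export
print.structure_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Structure score: degenerate (no usable distance signal)\n")
  } else {
    cat(sprintf(
      "Structure score: r = %.4f, z = %.3f, p = %.4g (%d permutations)%s\n",
      x$r_veridical, x$z, x$p, x$n_perm,
      if (x$significant) "  [significant]" else ""))
  }
  invisible(x)
}

#' Structure scores for a cohort
#'
#' Runs [structure_score()] per participant with a deterministic per-
#' participant seed stream (`seed + participant index`), so cohort runs
#' reproduce exactly and could be parallelized without seed collisions.
#' Participants with fewer than 3 colored responses are skipped with
#' `NA` scores and `degenerate = TRUE`.
#'
#' @param trials Trial data.frame (many participants, canonical schema).
#' @param coords Canonical coordinate table (`item`, `F1`, `F2`).
#' @inheritParams structure_score
#' @return A data.frame: `participant`, `n_responses`, `r_veridical`, `z`,
#'   `p`, `significant`, `degenerate`.
#' @export
cohort_structure <- function(trials, coords, n_perm = 10000, seed = NULL,
                             unit = c("triple", "response"), alpha = 0.05) {
  unit <- match.arg(unit)
  ids <- unique(trials$participant)
  rows <- lapply(seq_along(ids), function(i) {
    tr <- trials[trials$participant == ids[i], , drop = FALSE]
    tr_col <- if (is.null(tr$no_color)) tr else tr[!tr$no_color, ,
                                                   drop = FALSE]
    si <- if (is.null(seed)) NULL else (seed + i) %% 2147483647L
    if (nrow(tr_col) < 3L) {
      return(data.frame(participant = ids[i], n_responses = nrow(tr_col),
                        r_veridical = NA_real_, z = NA_real_, p = NA_real_,
                        significant = FALSE, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    s <- structure_score(tr, coords, n_perm = n_perm, seed = si,
                         unit = unit, alpha = alpha)
    data.frame(participant = ids[i], n_responses = s$n_responses,
               r_veridical = s$r_veridical, z = s$z, p = s$p,
               significant = s$significant, degenerate = s$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare structure across consistency-defined groups
#'
#' Joins per-participant structure scores with consistency
#' classifications and reports (i) a two-sample t statistic on `z` between
#' nonsynesthetes and synesthetes, (ii) the Pearson correlation between
#' `z` and the consistency score `c`, and (iii) the proportion of
#' participants with significantly structured mappings.
#'
#' @param structure_df Output of [cohort_structure()].
#' @param consistency Output of [cohort_consistency()] (or its `results`
#'   data.frame).
#' @param alpha Significance level for the structured-mapping proportion.
#' @return A list of class `"cohort_report"`: `n`, `t` (statistic, df, p,
#'   group means; `NULL` when a group has fewer than 2 members),
#'   `cor_z_c` (estimate, t, p), `prop_structured`, `merged` (the joined
#'   per-participant table).
#' @export
compare_groups <- function(structure_df, consistency, alpha = 0.05) {
  cons <- if (inherits(consistency, "consistency_cohort")) {
    consistency$results
  } else {
    consistency
  }
  merged <- merge(structure_df, cons, by = "participant")
  scored <- merged[!is.na(merged$z) &
                     merged$classification %in%
                       c("synesthete", "nonsynesthete"), , drop = FALSE]
  grp <- factor(scored$classification,
                levels = c("nonsynesthete", "synesthete"))
  tt <- NULL
  if (all(table(grp) >= 2L)) {
    ht <- stats::t.test(z ~ grp, data = scored)
    tt <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value,
               mean_z = stats::setNames(unname(ht$estimate),
                                        levels(grp)))
  }
  ct <- NULL
  ok <- !is.na(scored$c)
  if (sum(ok) >= 3L && stats::sd(scored$z[ok]) > 0 &&
      stats::sd(scored$c[ok]) > 0) {
    hc <- stats::cor.test(scored$z[ok], scored$c[ok])
    ct <- list(estimate = unname(hc$estimate),
               statistic = unname(hc$statistic), p = hc$p.value)
  }
  out <- list(n = nrow(scored), t = tt, cor_z_c = ct,
              prop_structured = mean(scored$p <= alpha),
              alpha = alpha, merged = merged)
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort structure report (", x$n, " classified participants)\n",
      sep = "")
  if (!is.null(x$t)) {
    cat(sprintf(
      "  z by group (nonsyn - syn): t = %.2f, df = %.0f, p = %.3g\n",
      x$t$statistic, x$t$df, x$t$p))
    cat(sprintf("    mean z: nonsynesthete %.2f, synesthete %.2f\n",
                x$t$mean_z[["nonsynesthete"]], x$t$mean_z[["synesthete"]]))
  } else {
    cat("  group comparison suppressed (fewer than 2 per group)\n")
  }
  if (!is.null(x$cor_z_c)) {
    cat(sprintf("  cor(z, c): r = %.3f, t = %.2f, p = %.3g\n",
                x$cor_z_c$estimate, x$cor_z_c$statistic, x$cor_z_c$p))
  }
  cat(sprintf("  structured mappings (p <= %.2f): %.1f%%\n",
              x$alpha, 100 * x$prop_structured))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. NULL seed runs in the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
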