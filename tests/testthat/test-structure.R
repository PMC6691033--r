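test_that("vowel distances use canonical coordinates", {
  co <- data.frame(item = c("a", "b"), F1 = c(300, 600),
                   F2 = c(2000, 2000))
  D <- vowel_distances(c("a", "a", "b"), co)
  expect_equal(D[1, 2], 0)      # same item -> identical coordinates
  expect_equal(D[1, 3], 300)
  expect_equal(D, t(D))
  expect_error(vowel_distances(c("a", "zz"), co), "zz")

  set.seed(1)
  co2 <- toy_coords(6)
  items <- sample(co2$item, 10, replace = TRUE)
  D2 <- vowel_distances(items, co2)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D2[i, j],
                 sqrt(sum((unlist(co2[co2$item == items[i], c("F1", "F2")]) -
                           unlist(co2[co2$item == items[j],
                                      c("F1", "F2")]))^2)))
  }
})

test_that("color distances are pairwise CIEDE2000", {
  set.seed(2)
  lab <- cbind(runif(8, 10, 90), runif(8, -60, 60), runif(8, -60, 60))
  D <- color_distances(lab)
  expect_equal(diag(D), rep(0, 8))
  expect_equal(D, t(D))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D[i, j], delta_e2000(lab[i, ], lab[j, ]))
  }
  expect_equal(color_distances(lab[c(1, 1, 1), ]), matrix(0, 3, 3))
  expect_error(color_distances(rbind(lab, NA)), "no-color")
})

test_that("mantel_r is the Pearson correlation of the upper triangles", {
  set.seed(3)
  x <- matrix(runif(16), 4); A <- as.matrix(dist(x))
  expect_equal(mantel_r(A, A), 1)
  expect_true(is.na(mantel_r(A, matrix(1, 4, 4) - diag(4) * 0)))

  # 4-response toy case: direct Pearson on the 6 upper-triangle pairs
  B <- as.matrix(dist(matrix(runif(16), 4)))
  a <- A[upper.tri(A)]; b <- B[upper.tri(B)]
  n <- 6
  ref <- (sum(a * b) - n * mean(a) * mean(b)) /
    sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  expect_equal(mantel_r(A, B), ref)
  expect_error(mantel_r(A[1:2, 1:2], B[1:2, 1:2]), "at least 3")
})

test_that("mantel_r agrees with an independent Mantel implementation", {
  skip_if_not_installed("vegan")
  set.seed(4)
  A <- as.matrix(dist(matrix(runif(30), 10)))
  B <- as.matrix(dist(matrix(runif(30), 10)))
  ref <- suppressWarnings(
    vegan::mantel(A, B, permutations = 0)$statistic)
  expect_equal(mantel_r(A, B), unname(ref), tolerance = 1e-12)
})

test_that("r_veridical is invariant under common reordering of responses", {
  set.seed(5)
  co <- toy_coords(4)
  items <- rep(co$item, each = 3)
  lab <- cbind(runif(12, 20, 80), runif(12, -50, 50), runif(12, -50, 50))
  r0 <- mantel_r(vowel_distances(items, co), color_distances(lab))
  ord <- sample(12)
  r1 <- mantel_r(vowel_distances(items[ord], co),
                 color_distances(lab[ord, ]))
  expect_equal(r1, r0)
})

test_that("permute_mapping conserves colors and admits the identity", {
  set.seed(6)
  resp <- data.frame(item = rep(1:4, each = 3),
                     r = sample(0:255, 12), g = sample(0:255, 12),
                     b = sample(0:255, 12))
  perm <- permute_mapping(resp)
  # multiset of colors untouched; items still a bijection of the originals
  key <- function(d) sort(paste(d$r, d$g, d$b))
  expect_identical(key(perm), key(resp))
  expect_identical(sort(unique(perm$item)), sort(unique(resp$item)))
  expect_identical(as.vector(table(perm$item)), as.vector(table(resp$item)))

  # the identity relabeling reproduces r_veridical, and a within-item
  # shuffle alone cannot change the correlation
  co <- toy_coords(4)
  lab <- rgb_to_lab(as.matrix(resp[, c("r", "g", "b")]))
  r0 <- mantel_r(vowel_distances(resp$item, co), color_distances(lab))
  shuffled <- resp
  for (it in unique(resp$item)) {
    rows <- which(resp$item == it)
    shuffled[rows, c("r", "g", "b")] <-
      resp[sample(rows), c("r", "g", "b")]
  }
  lab_s <- rgb_to_lab(as.matrix(shuffled[, c("r", "g", "b")]))
  expect_equal(mantel_r(vowel_distances(shuffled$item, co),
                        color_distances(lab_s)), r0)
})

test_that("permutation distribution on 3 items matches exhaustive enumeration", {
  set.seed(7)
  # irregular coordinates so all 3! reassignments give distinct r values
  co <- data.frame(item = 1:3, F1 = c(310, 560, 840),
                   F2 = c(2150, 1310, 980))
  resp <- data.frame(item = rep(1:3, each = 3),
                     r = sample(0:255, 9), g = sample(0:255, 9),
                     b = sample(0:255, 9))
  lab <- rgb_to_lab(as.matrix(resp[, c("r", "g", "b")]))
  Dc <- color_distances(lab)

  # exhaustive: all 3! reassignments of items
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  enumerated <- vapply(perms, function(p) {
    mantel_r(vowel_distances(p[resp$item], co), Dc)
  }, numeric(1))

  # empirical: repeated draws of the shuffle must live on, and cover, the
  # enumerated support roughly uniformly
  draws <- vapply(1:600, function(k) {
    pm <- permute_mapping(resp)
    labp <- rgb_to_lab(as.matrix(pm[, c("r", "g", "b")]))
    mantel_r(vowel_distances(pm$item, co), color_distances(labp))
  }, numeric(1))
  expect_equal(length(unique(round(enumerated, 9))), 6)
  match_idx <- vapply(draws, function(d) {
    which.min(abs(enumerated - d))
  }, integer(1))
  expect_true(all(abs(draws - enumerated[match_idx]) < 1e-12))
  freq <- tabulate(match_idx, 6) / 600
  expect_true(all(freq > 1 / 6 - 0.12 & freq < 1 / 6 + 0.12))
})

test_that("structure_score is reproducible and honors its seed stream", {
  co <- default_coords()
  tr <- synth_participant(synesthete_profile(9), co)
  s1 <- structure_score(tr, co, n_perm = 99, seed = 123)
  s2 <- structure_score(tr, co, n_perm = 99, seed = 123)
  expect_identical(s1[c("r_veridical", "z", "p", "perm_mean", "perm_sd")],
                   s2[c("r_veridical", "z", "p", "perm_mean", "perm_sd")])
  s3 <- structure_score(tr, co, n_perm = 99, seed = 124)
  expect_false(identical(s1$p, s3$p) && identical(s1$z, s3$z))
})

test_that("a constant-color responder is degenerate", {
  co <- default_coords()
  tr <- synth_participant(degenerate_profile(5), co)
  s <- structure_score(tr, co, n_perm = 199, seed = 1)
  expect_true(s$degenerate)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  expect_false(s$significant)
})

test_that("no-color responses are dropped and minimums enforced", {
  co <- default_coords()
  tr <- synth_participant(participant_profile(0.8, 10, 5, 0.5, seed = 2),
                          co)
  s <- structure_score(tr, co, n_perm = 99, seed = 3)
  expect_equal(s$n_responses, sum(!tr$no_color))
  tr_all_nc <- tr
  tr_all_nc$no_color <- TRUE
  tr_all_nc[, c("r", "g", "b")] <- NA_integer_
  expect_error(structure_score(tr_all_nc, co, n_perm = 99),
               "at least 3")
})

test_that("compare_groups gives t = 0 for identical groups", {
  z <- c(0.5, 1.2, -0.3, 2.0)
  structure_df <- data.frame(
    participant = paste0("p", 1:8), n_responses = 48,
    r_veridical = 0.1, z = rep(z, 2), p = 0.2, significant = FALSE,
    degenerate = FALSE, stringsAsFactors = FALSE)
  cons <- data.frame(
    participant = paste0("p", 1:8),
    c = c(80, 90, 100, 110, 200, 210, 220, 230),
    n_valid_items = 16L,
    classification = rep(c("synesthete", "nonsynesthete"), each = 4),
    stringsAsFactors = FALSE)
  rep_out <- compare_groups(structure_df, cons)
  expect_equal(rep_out$t$statistic, 0, tolerance = 1e-12)
  expect_equal(rep_out$n, 8)
})
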