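test_that("label_windows keeps annotated centers and rejects non-A annotations", {
  seqs <- tibble::tibble(
    id = "s1",
    residues = "GGAGGAGGAGC"  # A at 3, 6, 9; C at 11
  )
  windows <- extract_windows(seqs, xi = 2)
  expect_equal(windows$center_pos, c(3L, 6L, 9L))

  ann <- tibble::tibble(seq_id = "s1", position = c(3L, 6L),
                        label = c("pos", "neg"))
  labeled <- label_windows(windows, ann, seqs)
  expect_equal(nrow(labeled), 2)
  expect_equal(labeled$label, c("pos", "neg"))

  empty <- label_windows(windows, ann[0, ], seqs)
  expect_equal(nrow(empty), 0)

  bad <- tibble::tibble(seq_id = "s1", position = 11L, label = "pos")
  expect_error(label_windows(windows, bad, seqs), "s1 position 11")

  # opt-in inference: unannotated centers become negatives
  inferred <- label_windows(windows, ann[1, ], seqs,
                            unannotated_negative = TRUE)
  expect_equal(sort(inferred$label), c("neg", "neg", "pos"))
})

test_that("redundancy reduction clusters within label groups at strict threshold", {
  w <- random_window(25)
  dup <- make_windows(c(w, w), label = c("pos", "pos"))
  expect_equal(nrow(reduce_redundancy(dup, 0.6)), 1)

  # identical strings in opposite groups are both retained
  cross <- make_windows(c(w, w), label = c("pos", "neg"))
  expect_equal(nrow(reduce_redundancy(cross, 0.6)), 2)

  expect_error(reduce_redundancy(dup, 0), "0, 1")
  expect_error(reduce_redundancy(dup, 1.2), "0, 1")
})

test_that("the 60% identity boundary is strict: 30/51 kept, 31/51 removed", {
  base <- strsplit(random_window(25), "")[[1]]
  flip <- function(chars, positions) {
    for (p in positions) {
      chars[p] <- setdiff(c("C", "G", "U"), chars[p])[1]
    }
    paste(chars, collapse = "")
  }
  non_center <- setdiff(1:51, 26)
  # flipping 21 non-center columns leaves exactly 30 matches
  pair30 <- flip(base, non_center[1:21])
  expect_equal(oracle_identity(paste(base, collapse = ""), pair30), 30 / 51)
  ds30 <- make_windows(c(paste(base, collapse = ""), pair30),
                       label = c("pos", "pos"))
  expect_equal(nrow(reduce_redundancy(ds30, 0.60)), 2)

  # flipping 20 leaves 31 matches -> identity 0.6078 > 0.60, second removed
  pair31 <- flip(base, non_center[1:20])
  expect_equal(oracle_identity(paste(base, collapse = ""), pair31), 31 / 51)
  ds31 <- make_windows(c(paste(base, collapse = ""), pair31),
                       label = c("pos", "pos"))
  kept <- reduce_redundancy(ds31, 0.60)
  expect_equal(kept$residues, paste(base, collapse = ""))
})

test_that("redundancy reduction is idempotent and leaves no close same-label pair", {
  set.seed(21)
  # small alphabet windows so collisions above threshold actually occur
  ds <- make_windows(
    replicate(40, {
      chars <- sample(c("G", "U"), 9, replace = TRUE)
      chars[5] <- "A"
      paste(chars, collapse = "")
    }),
    label = sample(c("pos", "neg"), 40, replace = TRUE)
  )
  once <- reduce_redundancy(ds, 0.6)
  twice <- reduce_redundancy(once, 0.6)
  expect_equal(once, twice)
  expect_lt(nrow(once), nrow(ds))

  # all-pairs oracle scan: no same-label pair above threshold survives
  for (grp in c("pos", "neg")) {
    res <- once$residues[once$label == grp]
    if (length(res) >= 2) {
      pairs <- utils::combn(res, 2)
      idents <- apply(pairs, 2, function(p) oracle_identity(p[1], p[2]))
      expect_true(all(idents <= 0.6))
    }
  }
})

test_that("balancing samples uniformly without replacement and is seed-reproducible", {
  set.seed(2)
  ds <- make_windows(replicate(10, random_window(5)),
                     label = rep(c("pos", "neg"), each = 5))
  out <- balance_dataset(ds, 3, seed = 99)
  expect_equal(table(out$balanced$label)[["pos"]], 3)
  expect_equal(table(out$balanced$label)[["neg"]], 3)
  expect_equal(nrow(out$leftover_pos), 2)
  expect_true(all(out$leftover_pos$label == "pos"))
  again <- balance_dataset(ds, 3, seed = 99)
  expect_identical(out, again)

  whole <- balance_dataset(ds, 5, seed = 1)
  expect_equal(nrow(whole$leftover_pos), 0)

  expect_error(balance_dataset(ds, 6, seed = 1), "at least 6")
})

test_that("balancing selects each sample with frequency about n/N", {
  set.seed(4)
  ds <- make_windows(replicate(10, random_window(3)),
                     label = rep(c("pos", "neg"), each = 5))
  hits <- setNames(numeric(5), ds$source_id[1:5])
  n_draws <- 400
  for (s in seq_len(n_draws)) {
    b <- balance_dataset(ds, 3, seed = s)$balanced
    picked <- b$source_id[b$label == "pos"]
    hits[picked] <- hits[picked] + 1
  }
  freq <- hits / n_draws
  # expected 3/5 = 0.6; binomial noise at n=400 is about 0.025 sd
  expect_true(all(abs(freq - 0.6) < 0.1))
})

test_that("disjointness check compares residue strings across sets", {
  set.seed(6)
  pool <- make_windows(replicate(20, random_window(10)),
                       label = rep(c("pos", "neg"), 10))
  split <- balance_dataset(pool, 4, seed = 3)
  expect_true(assert_disjoint(split$balanced[split$balanced$label == "pos", ],
                              split$leftover_pos))
  expect_false(assert_disjoint(pool, pool))

  a <- make_windows(random_window(3), label = "pos")
  b <- make_windows(random_window(4), label = "pos")
  expect_error(assert_disjoint(a, b), "different xi")

  # randomized splits of a synthetic pool are always string-disjoint
  for (s in 1:5) {
    sp <- balance_dataset(pool, 5, seed = s)
    pos_in <- sp$balanced[sp$balanced$label == "pos", ]
    expect_true(length(intersect(pos_in$residues,
                                 sp$leftover_pos$residues)) == 0)
  }
})

test_that("build_benchmark assembles balanced and independent sets with a manifest", {
  set.seed(31)
  # one long sequence with many A centers, annotated alternately
  res <- paste(replicate(80, {
    paste0(random_rna(4, c("C", "G", "U")), "A")
  }), collapse = "")
  seqs <- tibble::tibble(id = "chrS", residues = res)
  windows <- extract_windows(seqs, xi = 5)
  ann <- tibble::tibble(seq_id = "chrS",
                        position = windows$center_pos,
                        label = rep_len(c("pos", "neg"),
                                        length(windows$center_pos)))
  built <- build_benchmark(seqs, ann, xi = 5, threshold = 0.9,
                           n_per_class = 10, seed = 7)
  expect_equal(sum(built$benchmark$label == "pos"), 10)
  expect_equal(sum(built$benchmark$label == "neg"), 10)
  expect_true(assert_disjoint(built$benchmark, built$independent))
  expect_equal(built$manifest$stage[1], "windows")
  expect_equal(attr(built$manifest, "params")$seed, 7)
})
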