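test_that("vectorize produces floor(N/chunk) vectors with channel-block layout", {
  em <- tiny_em(2500)
  fp <- vectorize(em, chunk_size = 1000)
  expect_equal(nrow(fp), 2)
  expect_equal(length(fp_cols(fp)), 3000)
  # indexing oracle: chunk c, channel ch, event e lives at
  # V[(ch-1)*B + e] and equals events[(c-1)*B + e, ch]
  B <- 1000
  for (c_i in 1:2) {
    for (ch in 1:3) {
      for (e in c(1, 37, 1000)) {
        expect_equal(fp[[paste0("V", (ch - 1) * B + e)]][c_i],
                     unname(em$events[(c_i - 1) * B + e, ch]))
      }
    }
  }
})

test_that("vector counts follow floor(N/chunk) including edge cases", {
  expect_equal(nrow(vectorize(tiny_em(999), chunk_size = 1000)), 0)
  expect_equal(nrow(vectorize(tiny_em(1000), chunk_size = 1000)), 1)
  for (n in c(0, 7, 24, 25, 26, 99, 100)) {
    em <- if (n > 0) tiny_em(n) else
      event_matrix(matrix(numeric(0), 0, 3), analysis_channels())
    expect_equal(nrow(vectorize(em, chunk_size = 25)), n %/% 25)
  }
})

test_that("a fingerprint reshapes back to its chunk exactly (flatten inverse)", {
  em <- tiny_em(60)
  fp <- vectorize(em, chunk_size = 20)
  for (c_i in 1:3) {
    chunk <- matrix(as.numeric(fp[c_i, fp_cols(fp)]), ncol = 3)
    expect_equal(chunk, em$events[((c_i - 1) * 20 + 1):(c_i * 20), ],
                 ignore_attr = TRUE)
  }
  # trailing remainder is discarded: values beyond row 60 never appear
  em2 <- tiny_em(70)
  fp2 <- vectorize(em2, chunk_size = 20)
  expect_equal(nrow(fp2), 3)
  expect_false(any(em2$events[61:70, 1] %in% as.matrix(fp2[, fp_cols(fp2)])))
})

test_that("per-channel sorting makes fingerprints event-order invariant", {
  em <- tiny_em(50)
  perm <- rev(seq_len(50))
  em_rev <- event_matrix(em$events[perm, ], em$channel_names)
  f1 <- vectorize(em, chunk_size = 50, sort_within = "ascending")
  f2 <- vectorize(em_rev, chunk_size = 50, sort_within = "ascending")
  expect_equal(as.matrix(f1[, fp_cols(f1)]), as.matrix(f2[, fp_cols(f2)]))
  # unsorted fingerprints differ under permutation
  g1 <- vectorize(em, chunk_size = 50)
  g2 <- vectorize(em_rev, chunk_size = 50)
  expect_false(identical(as.matrix(g1[, fp_cols(g1)]),
                         as.matrix(g2[, fp_cols(g2)])))
})

test_that("random chunk assignment reshuffles but preserves the event multiset", {
  em <- tiny_em(40)
  f1 <- vectorize(em, chunk_size = 20, chunk_method = "random", seed = 7)
  f2 <- vectorize(em, chunk_size = 20, chunk_method = "random", seed = 7)
  expect_identical(f1, f2)
  vals <- sort(c(as.matrix(f1[, fp_cols(f1)])))
  expect_equal(vals, sort(c(em$events)))
})

test_that("vectorize demands the canonical three analysis channels", {
  em <- event_matrix(matrix(1:8, 4, 2), c("FSC-A", "SSC-A"))
  expect_error(vectorize(em, 2), class = "cytofp_config_error")
})

test_that("clubbing maps perturbation labels onto the four putative groups", {
  X <- matrix(runif(12 * 6), 12, 6)
  ds <- fp_tibble(X, label = rep(c("PROP", "BUTY", "ACET", "SLUD", "NONE",
                                   "CELL", "GLUC", "BLAN"), length.out = 12))
  clubbed <- club_labels(ds)
  expect_equal(unname(clubbed$label[ds$label %in% c("PROP", "BUTY")]),
               rep("ACETO", 4))
  expect_equal(unname(clubbed$label[ds$label %in% c("ACET", "SLUD", "NONE",
                                                    "BLAN")]),
               rep("METHA", 6))
  expect_equal(unique(clubbed$label[ds$label == "CELL"]), "HYDRO")
  expect_equal(unique(clubbed$label[ds$label == "GLUC"]), "ACIDO")
  # values and size untouched
  expect_equal(as.matrix(clubbed[, fp_cols(clubbed)]), X,
               ignore_attr = TRUE)
  expect_equal(nrow(clubbed), nrow(ds))
  # identity map leaves the dataset unchanged
  idmap <- setNames(unique(ds$label), unique(ds$label))
  expect_identical(club_labels(ds, idmap), ds)
  # unmapped labels are named in the error
  expect_error(club_labels(ds, c(PROP = "ACETO")), "BUTY",
               class = "cytofp_clubbing_error")
})

test_that("stratified split honours per-label counts, disjointness and union", {
  X <- matrix(runif(1500 * 4), 1500, 4)
  ds <- fp_tibble(X, label = "GLUC")
  ds$chunk_index <- seq_len(1500)
  sp <- split_train_test(ds, 0.75, seed = 1)
  expect_equal(nrow(sp$train), 1125)
  expect_equal(nrow(sp$test), 375)
  expect_equal(sort(c(sp$train$chunk_index, sp$test$chunk_index)),
               seq_len(1500))
  # n = 10 at 0.5 -> 5/5
  ds10 <- fp_tibble(matrix(runif(20), 10, 2), label = "A")
  sp10 <- split_train_test(ds10, 0.5, seed = 2)
  expect_equal(c(nrow(sp10$train), nrow(sp10$test)), c(5, 5))
  # two labels with n = 100 each -> 75 of each in training, any seed
  ds2 <- fp_tibble(matrix(runif(200 * 2), 200, 2),
                   label = rep(c("A", "B"), each = 100))
  for (seed in 1:5) {
    sp2 <- split_train_test(ds2, 0.75, seed = seed)
    expect_equal(as.integer(table(sp2$train$label)), c(75L, 75L))
    expect_equal(nrow(sp2$train) + nrow(sp2$test), 200)
  }
  expect_error(split_train_test(fp_tibble(matrix(1, 1, 2), "A"), 0.75, 1),
               class = "cytofp_split_error")
})

test_that("group-aware splitting keeps all vectors of a sample together", {
  X <- matrix(runif(40 * 2), 40, 2)
  ds <- fp_tibble(X, label = rep(c("A", "B"), each = 20))
  ds$sample_id <- rep(sprintf("s%d", 1:8), each = 5)
  sp <- split_train_test(ds, 0.75, seed = 3, group_by_replicate = TRUE)
  expect_length(intersect(unique(sp$train$sample_id),
                          unique(sp$test$sample_id)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), 40)
})

test_that("the split is reproducible for a fixed seed", {
  ds <- small_ds()
  a <- split_train_test(ds, 0.75, seed = 10)
  b <- split_train_test(ds, 0.75, seed = 10)
  expect_identical(a$train, b$train)
})

test_that("Wald sample size reproduces the classical worst-case formula", {
  # 3% margin at 95% confidence: 1.96^2 * 0.25 / 0.03^2 -> 1068
  expect_equal(wald_sample_size(0.03, 0.95), 1068)
  expect_equal(wald_sample_size(0.05, 0.95), 385)
})

test_that("fingerprint CSV round trip preserves the dataset", {
  ds <- head(small_ds(), 20)
  p <- withr::local_tempfile(fileext = ".csv")
  write_fingerprints(ds, p)
  ds2 <- read_fingerprints(p)
  expect_equal(as.data.frame(ds2), as.data.frame(ds), tolerance = 1e-12)
})

test_that("channel_stats summarises per-channel distributions", {
  em <- tiny_em(500)
  st <- channel_stats(em)
  expect_equal(st$FSCA_mean, mean(em$events[, 1]))
  expect_equal(st$AmCyanA_sd, sd(em$events[, 3]))
  expect_equal(st$SSCA_p50, unname(quantile(em$events[, 2], 0.5)))
})
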