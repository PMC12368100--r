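test_that("dataset split arithmetic, determinism and balancing weights", {
  ds <- make_training_dataset(stub_chunks(100, "p"), stub_chunks(100, "n"),
                              split = 0.8, seed = 3)
  expect_equal(sum(ds$train$labels == 1), 80)
  expect_equal(sum(ds$train$labels == 0), 80)
  expect_equal(sum(ds$test$labels == 1), 20)
  expect_equal(sum(ds$test$labels == 0), 20)
  ds2 <- make_training_dataset(stub_chunks(100, "p"), stub_chunks(100, "n"),
                               split = 0.8, seed = 3)
  expect_identical(vapply(ds$train$chunks, `[[`, "", "read_id"),
                   vapply(ds2$train$chunks, `[[`, "", "read_id"))

  dsi <- make_training_dataset(stub_chunks(1000, "p"), stub_chunks(100, "n"),
                               split = 0.8, seed = 1)
  w1 <- dsi$train$weights[dsi$train$labels == 1][1]
  w0 <- dsi$train$weights[dsi$train$labels == 0][1]
  expect_equal(w0 / w1, 10)
  expect_equal(mean(dsi$train$weights), 1)
  expect_error(make_training_dataset(stub_chunks(5), stub_chunks(100)),
               "at least 10")
})

test_that("score mapping and threshold semantics are exact", {
  chunks <- stub_chunks(1)
  expect_equal(score_reads(stub_model(1), chunks)$score, 255L)
  expect_equal(score_reads(stub_model(0), chunks)$score, 0L)
  expect_equal(score_reads(stub_model(0.78), chunks)$score, 199L)

  sc <- data.frame(read_id = c("a", "b", "c"), score = c(199L, 200L, 255L))
  calls <- classify_charging(sc)
  expect_equal(calls$charged, c(FALSE, TRUE, TRUE))
  expect_equal(nrow(classify_charging(sc[0, ])), 0)
  # monotone in probability
  probs <- seq(0, 1, by = 0.05)
  scores <- vapply(probs, function(p) score_reads(stub_model(p), chunks)$score, 0L)
  expect_true(all(diff(scores) >= 0))
  expect_true(all(scores >= 0 & scores <= 255))
})

test_that("evaluation matches the F1 formula and a brute-force oracle", {
  mk <- function(pred, obs) {
    ids <- sprintf("r%03d", seq_along(pred))
    list(calls = data.frame(read_id = ids, charged = pred),
         truth = data.frame(read_id = ids, charged = obs))
  }
  x <- mk(rep(c(TRUE, FALSE), c(100, 100)),
          rep(c(TRUE, FALSE, TRUE, FALSE), c(96, 4, 4, 96)))
  ev <- evaluate_classifier(x$calls, x$truth)
  expect_equal(c(ev$TP, ev$FP, ev$FN, ev$TN), c(96, 4, 4, 96))
  expect_equal(ev$F1, 0.96)

  perfect <- mk(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(evaluate_classifier(perfect$calls, perfect$truth)$F1, 1)
  zero <- mk(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(evaluate_classifier(zero$calls, zero$truth)$F1, 0)
  expect_equal(f1_score(96, 4, 4), 0.96)
  expect_true(is.na(f1_score(0, 0, 0)))

  bad <- mk(TRUE, TRUE)
  bad$truth$read_id <- "zzz"
  expect_error(evaluate_classifier(bad$calls, bad$truth), "same read ids")

  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    obs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    y <- mk(pred, obs)
    # shuffle call order to exercise the id join
    y$calls <- y$calls[sample(n), ]
    ev <- evaluate_classifier(y$calls, y$truth)
    TP <- sum(pred & obs); FP <- sum(pred & !obs); FN <- sum(!pred & obs)
    expect_equal(c(ev$TP, ev$FP, ev$FN, ev$TN),
                 c(TP, FP, FN, sum(!pred & !obs)))
    if (2 * TP + FP + FN > 0) expect_equal(ev$F1, 2 * TP / (2 * TP + FP + FN))
  }
})

test_that("training is deterministic and checkpoints round-trip", {
  ref <- tiny_ref()
  eff <- effect_profiles("bio-default", ref_length = nchar(ref$sequence))
  rc <- sim_reads(ref, 40, charged = TRUE, aa = "M", seed = 41, effects = eff)
  ru <- sim_reads(ref, 40, charged = FALSE, seed = 42, effects = eff)
  cc <- extract_chunks(rc, ref)
  cu <- extract_chunks(ru, ref)
  ds <- make_training_dataset(cc, cu, seed = 5)
  m1 <- train_charging_model(ds$train, seed = 7)
  m2 <- train_charging_model(ds$train, seed = 7)
  expect_identical(predict(m1, ds$test$chunks), predict(m2, ds$test$chunks))

  path <- withr::local_tempfile(fileext = ".json")
  save_model(m1, path)
  m3 <- load_model(path)
  expect_equal(predict(m3, ds$test$chunks), predict(m1, ds$test$chunks),
               tolerance = 1e-12)
  expect_error(load_model({
    p <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(a = 1), p)
    p
  }), "not a classifier")
})

test_that("pairwise training enumerates n(n-1) models symmetrically", {
  sets <- list(
    G = extract_library_chunks(panel_library("G", 40, seed = 51)),
    W = extract_library_chunks(panel_library("W", 40, seed = 52)),
    D = extract_library_chunks(panel_library("D", 40, seed = 53)))
  pw <- train_pairwise_models(sets, seed = 2)
  expect_equal(pw$n_models, 6)
  expect_equal(sum(!is.na(pw$unordered)) / 2, 3)
  expect_identical(pw$unordered, t(pw$unordered))
  expect_true(all(pw$unordered[upper.tri(pw$unordered)] >= 0 &
                  pw$unordered[upper.tri(pw$unordered)] <= 1))
})

test_that("indistinguishable classes yield chance-level pairwise F1", {
  # two independent panels of the same amino acid on the same body
  sets <- list(
    A1 = extract_library_chunks(panel_library("G", 150, seed = 61)),
    A2 = extract_library_chunks(panel_library("G", 150, seed = 62)))
  pw <- train_pairwise_models(sets, seed = 3)
  n_test <- 2 * 30
  expect_lt(abs(pw$unordered[1, 2] - 0.5), 1.96 * sqrt(0.25 / n_test) + 0.05)
})

test_that("alignment baseline calls by adapter edit distance with tie rule", {
  ad <- tiny_adapters()
  ref_c <- tiny_ref("charged")
  ref_u <- tiny_ref("uncharged")
  bc <- data.frame(
    read_id = c("c1", "u1", "tie"),
    basecall = c(ref_c$sequence, ref_u$sequence, "A"),
    stringsAsFactors = FALSE)
  out <- alignment_baseline(bc, ad)
  expect_equal(out$calls$call, c("charged", "uncharged", "unassigned"))

  truth <- data.frame(read_id = bc$read_id,
                      charged = c(TRUE, FALSE, TRUE))
  rep <- alignment_baseline(bc, ad, truth = truth)$report
  # the unassigned truly-charged read counts as a false negative
  expect_equal(rep$FN, 1)
  expect_equal(rep$TP, 1)
  expect_equal(rep$TN, 1)
})
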