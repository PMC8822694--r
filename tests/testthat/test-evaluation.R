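# Detection metrics, DTI metrics and the normalized Smith-Waterman audit.

make_preds <- function(...) {
  df <- data.frame(...)
  names(df) <- c("complex_id", "start", "end", "confidence")[seq_along(df)]
  df
}

test_that("AP is 1 for a perfect detector and 0 for a disjoint one", {
  truths <- data.frame(complex_id = c("a", "a", "b"),
                       start = c(10, 50, 0), end = c(20, 60, 9))
  perfect <- cbind(truths, confidence = 1)
  expect_equal(average_precision(perfect, truths), 1)
  off <- transform(perfect, start = start + 100, end = end + 100)
  expect_equal(average_precision(off, truths), 0)
  expect_equal(average_precision(perfect[0, ], truths), 0)
  expect_error(average_precision(perfect, truths[0, ]), "truth")
})

test_that("AP matches an independent PR-curve oracle on random instances", {
  set.seed(17)
  err <- 0
  for (i in 1:500) {
    n_cx <- sample(1:4, 1)
    truths <- do.call(rbind, lapply(seq_len(n_cx), function(cx) {
      n_t <- sample(1:4, 1)
      st <- sample(seq(0, 400, by = 30), n_t)
      data.frame(complex_id = paste0("c", cx), start = st,
                 end = st + sample(10:25, n_t, replace = TRUE))
    }))
    preds <- do.call(rbind, lapply(seq_len(n_cx), function(cx) {
      n_p <- sample(0:6, 1)
      if (n_p == 0) return(NULL)
      st <- runif(n_p, 0, 420)
      data.frame(complex_id = paste0("c", cx), start = st,
                 end = st + runif(n_p, 8, 30),
                 confidence = runif(n_p))
    }))
    if (is.null(preds) || nrow(preds) == 0) next
    err <- max(err, abs(average_precision(preds, truths) -
                          oracle_ap(preds, truths)))
  }
  expect_lt(err, 2e-3)
})

test_that("AP is monotone: demoting a true positive below a false positive never helps", {
  truths <- data.frame(complex_id = "a", start = 100, end = 120)
  good <- data.frame(complex_id = "a", start = c(100, 300),
                     end = c(120, 320), confidence = c(0.9, 0.5))
  bad <- transform(good, confidence = c(0.5, 0.9))
  expect_gt(average_precision(good, truths),
            average_precision(bad, truths))
})

test_that("interpolated precision is non-increasing in recall", {
  set.seed(23)
  truths <- data.frame(complex_id = "a", start = seq(0, 450, by = 50),
                       end = seq(0, 450, by = 50) + 20)
  st <- runif(30, 0, 470)
  preds <- data.frame(complex_id = "a", start = st, end = st + 20,
                      confidence = runif(30))
  cv <- average_precision(preds, truths, curve = TRUE)$curve
  expect_true(all(diff(cv$precision_interp) <= 1e-12))
})

test_that("AP is invariant to input order within confidence ties", {
  truths <- data.frame(complex_id = c("a", "b"), start = c(0, 0),
                       end = c(20, 20))
  preds <- data.frame(complex_id = c("a", "b"), start = c(0, 50),
                      end = c(20, 70), confidence = c(0.5, 0.5))
  expect_equal(average_precision(preds, truths),
               average_precision(preds[2:1, ], truths))
})

test_that("top-n success applies the half-coverage criterion", {
  truths <- data.frame(complex_id = "a", start = 100, end = 120)
  # covering exactly half of the truth is a hit
  hit <- make_preds("a", 100, 110, 0.9)
  expect_equal(topn_success(hit, truths), 1)
  # 9 of 20 positions is a miss
  miss <- make_preds("a", 100, 109, 0.9)
  expect_equal(topn_success(miss, truths), 0)
  # identical predictions give rate 1
  expect_equal(topn_success(cbind(truths, confidence = 1), truths), 1)
})

test_that("top-(n+2) never scores below top-n and matches the oracle", {
  set.seed(29)
  err <- 0; mono <- TRUE
  for (i in 1:500) {
    n_cx <- sample(1:3, 1)
    truths <- do.call(rbind, lapply(seq_len(n_cx), function(cx) {
      st <- sample(seq(0, 300, by = 40), sample(1:3, 1))
      data.frame(complex_id = paste0("c", cx), start = st, end = st + 20)
    }))
    st <- runif(12, 0, 300)
    preds <- data.frame(
      complex_id = sample(paste0("c", seq_len(n_cx)), 12, replace = TRUE),
      start = st, end = st + runif(12, 10, 30), confidence = runif(12))
    t0 <- topn_success(preds, truths, extra = 0)
    t2 <- topn_success(preds, truths, extra = 2)
    mono <- mono && t2 >= t0
    err <- max(err, abs(t0 - oracle_topn(preds, truths, 0)),
               abs(t2 - oracle_topn(preds, truths, 2)))
  }
  expect_true(mono)
  expect_lt(err, 1e-12)
})

test_that("the any-hit variant upper-bounds the per-truth fraction", {
  truths <- data.frame(complex_id = "a", start = c(0, 100), end = c(20, 120))
  preds <- make_preds("a", 0, 20, 0.9)
  expect_equal(topn_success(preds, truths), 0.5)
  expect_equal(topn_success(preds, truths, per_complex_any = TRUE), 1)
})

test_that("DTI metrics separate perfect, random and degenerate scorers", {
  labels <- rep(c(1, 0), each = 50)
  perfect <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  m <- dti_metrics(perfect, labels)
  expect_equal(m$auroc, 1)
  expect_equal(m$aupr, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  # scores independent of labels at large n
  set.seed(37)
  labels2 <- rbinom(2000, 1, 1 / 3)
  rand <- runif(2000)
  m2 <- dti_metrics(rand, labels2)
  expect_equal(m2$auroc, 0.5, tolerance = 0.05)
  # all-equal scores: accuracy equals the predicted-class fraction
  m3 <- dti_metrics(rep(0.7, 100), labels)
  expect_equal(m3$accuracy, mean(labels == 1))
  expect_error(dti_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("AUPR matches a rank-by-rank enumeration", {
  set.seed(41)
  labels <- rbinom(200, 1, 0.3)
  labels[1] <- 1; labels[2] <- 0
  scores <- runif(200)
  m <- dti_metrics(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  manual <- 0
  tp <- 0
  for (k in seq_along(y)) {
    if (y[k] == 1) { tp <- tp + 1; manual <- manual + tp / k }
  }
  expect_equal(m$aupr, manual / sum(y), tolerance = 1e-12)
})

test_that("normalized Smith-Waterman is 1 on identity and symmetric", {
  set.seed(43)
  a <- random_protein(60)
  b <- random_protein(60)
  expect_equal(sw_norm(a, a), 1, tolerance = 1e-12)
  expect_equal(sw_norm(a, b), sw_norm(b, a), tolerance = 1e-12)
  expect_lt(sw_norm(a, b), 0.5)
  expect_error(sw_norm("", a), "non-empty")
})

test_that("sw_norm agrees with an affine-gap dynamic-programming oracle", {
  set.seed(47)
  for (i in 1:40) {
    a <- random_protein(sample(30:60, 1))
    b <- random_protein(sample(30:60, 1))
    expect_equal(sw_norm(a, b), oracle_sw_norm(a, b), tolerance = 1e-9)
  }
  # related sequences: a mutated copy scores high but below 1
  a <- random_protein(80)
  ch <- strsplit(a, "")[[1]]
  ch[sample(80, 8)] <- sample(c("A", "G", "K"), 8, replace = TRUE)
  b <- paste(ch, collapse = "")
  v <- sw_norm(a, b)
  expect_equal(v, oracle_sw_norm(a, b), tolerance = 1e-9)
  expect_gt(v, 0.7)
  expect_lt(v, 1)
})

test_that("similarity report finds the best training match per test protein", {
  set.seed(53)
  train <- c(t1 = random_protein(60), t2 = random_protein(60))
  test <- c(q1 = train[["t1"]], q2 = random_protein(60))
  rep <- similarity_report(test, train)
  expect_equal(rep$best_train_id[rep$test_id == "q1"], "t1")
  expect_equal(rep$sw_norm[rep$test_id == "q1"], 1, tolerance = 1e-12)
  expect_true(all(rep$sw_norm > 0 & rep$sw_norm <= 1))
})
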