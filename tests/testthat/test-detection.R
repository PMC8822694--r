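spec25 <- grid_spec(300, 25)

test_that("target encoding assigns the documented grid, offsets and anchor", {
  # BR [100,120): centre 110, width 20 -> grid 4 (s_g = 100), c = 0.4,
  # best anchor 15 with w = log(20/15)
  tgt <- encode_targets(rbind(c(100, 120)), spec25, anchors = c(9, 15, 21))
  g <- 5; a <- 2   # 1-based row/col of grid 4, anchor 15
  expect_true(tgt$resp[g, a])
  expect_equal(sum(tgt$resp), 1)
  expect_equal(tgt$c[g, a], 0.4)
  expect_equal(tgt$w[g, a], log(20 / 15))
  expect_equal(tgt$p[g, a], 1)
  expect_equal(sum(tgt$p), 1)
})

test_that("a BR of anchor width starting at a grid start encodes to zeros", {
  tgt <- encode_targets(rbind(c(100 - 4.5, 100 + 4.5)), spec25,
                        anchors = c(9, 15, 21))
  expect_true(tgt$resp[5, 1])
  expect_equal(tgt$c[5, 1], 0)
  expect_equal(tgt$w[5, 1], 0)
})

test_that("empty truth yields an all-negative tensor", {
  tgt <- encode_targets(matrix(numeric(0), 0, 2), spec25, c(9, 15, 21))
  expect_equal(sum(tgt$p), 0)
  expect_false(any(tgt$resp))
})

test_that("same-grid collisions fall back to free anchors, then drop", {
  # three BRs with centres in grid 2; two anchors only
  brs <- rbind(c(51, 61), c(55, 70), c(60, 72))
  expect_warning(
    tgt <- encode_targets(brs, spec25, anchors = c(9, 15)),
    "dropped")
  expect_equal(sum(tgt$resp), 2)
  expect_equal(sum(tgt$resp[3, ]), 2)   # both anchors of grid 2 used
})

test_that("decoding applies the reconstruction formulas", {
  # centre = s_g + grid_size * c ; width = r_i * exp(w)
  A <- 3
  cm <- matrix(0.5, 12, A); wm <- matrix(0, 12, A)
  pm <- matrix(0, 12, A)
  cm[5, 2] <- 0.4; wm[5, 2] <- 0; pm[5, 2] <- 0.9
  out <- detection_tensor(cm, wm, pm)
  dec <- decode(out, spec25, anchors = c(9, 15, 21), conf_threshold = 0.5)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$center, 100 + 25 * 0.4)
  expect_equal(dec$width, 15)
  expect_equal(dec$start, 110 - 7.5)
  expect_equal(dec$grid, 4L)
  # w = 1 stretches the anchor by e
  wm[5, 2] <- 1
  dec <- decode(detection_tensor(cm, wm, pm), spec25, c(9, 15, 21), 0.5)
  expect_equal(dec$width, 15 * exp(1))
  dec9 <- decode(detection_tensor(cm, wm,
                                  `[<-`(pm, cbind(5, 1), 0.9)),
                 spec25, c(9, 15, 21), 0.5, nms = FALSE)
  expect_equal(sort(dec9$width), sort(c(9, 15 * exp(1))))
})

test_that("non-maximum suppression keeps the higher-confidence duplicate", {
  A <- 1
  cm <- matrix(0.5, 4, A); wm <- matrix(0.5, 4, A); pm <- matrix(0, 4, A)
  cm[2, 1] <- 0.9; pm[2, 1] <- 0.9
  # adjacent grid predicts almost the same interval with lower confidence
  cm[3, 1] <- 0.02; pm[3, 1] <- 0.6
  sp <- grid_spec(100, 25)
  no_nms <- decode(detection_tensor(cm, wm, pm), sp, 12, 0.5, nms = FALSE)
  expect_equal(nrow(no_nms), 2)
  with_nms <- decode(detection_tensor(cm, wm, pm), sp, 12, 0.5, nms = TRUE)
  expect_equal(nrow(with_nms), 1)
  expect_equal(with_nms$confidence, 0.9)
  expect_equal(no_nms$confidence, c(0.9, 0.6))  # sorted descending
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  expect_equal(focal_loss(p, y, gamma = 0),
               -(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-10)
  expect_equal(focal_loss(0.5, 1, gamma = 0), -log(0.5), tolerance = 1e-9)
  expect_equal(focal_loss(0.9, 1, gamma = 2), -(0.1)^2 * log(0.9),
               tolerance = 1e-9)
  expect_equal(focal_loss(0.9, 0, gamma = 2), -(0.9)^2 * log(0.1),
               tolerance = 1e-9)
  expect_error(focal_loss(0.5, 1, gamma = -1), "gamma")
  expect_error(focal_loss(0.5, 2), "binary")
})

test_that("focal loss is monotone in p_t and never above cross-entropy", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (g in c(0, 0.5, 1, 2, 5)) {
    fl <- focal_loss(p, 1, gamma = g)
    expect_true(all(diff(fl) < 0))           # decreasing in p for y = 1
    expect_true(all(fl <= focal_loss(p, 1, gamma = 0) + 1e-12))
  }
})

test_that("the detection loss decomposes into its weighted parts", {
  set.seed(2)
  sp <- grid_spec(100, 25)
  tgt <- encode_targets(rbind(c(10, 25), c(60, 70)), sp, c(9, 15, 21))
  A <- 3
  out <- detection_tensor(matrix(runif(12), 4, A), matrix(runif(12), 4, A),
                          matrix(runif(12), 4, A))
  l11 <- br_loss(tgt, out, lambda_reg = 1, lambda_conf = 1, gamma = 2)
  l10 <- br_loss(tgt, out, lambda_reg = 1, lambda_conf = 0, gamma = 2)
  l01 <- br_loss(tgt, out, lambda_reg = 0, lambda_conf = 1, gamma = 2)
  expect_equal(as.numeric(l11), as.numeric(l10) + as.numeric(l01),
               tolerance = 1e-12)
  expect_equal(as.numeric(l01),
               mean(focal_loss(out$p, tgt$resp * 1, 2)), tolerance = 1e-12)
  # a 2.5x weight scales the parts linearly
  l <- br_loss(tgt, out, lambda_reg = 2.5, lambda_conf = 0.5, gamma = 2)
  expect_equal(as.numeric(l), 2.5 * attr(l, "regression") +
                 0.5 * attr(l, "focal"), tolerance = 1e-12)
})

test_that("perfect outputs drive the loss to zero", {
  sp <- grid_spec(100, 25)
  tgt <- encode_targets(rbind(c(10, 25)), sp, c(9, 15, 21))
  eps <- 1e-7
  out <- detection_tensor(tgt$c, tgt$w,
                          ifelse(tgt$resp, 1 - eps, eps))
  expect_lt(as.numeric(br_loss(tgt, out)), 1e-5)
})

test_that("a single responsible cell with known errors gives the L1 sum", {
  sp <- grid_spec(50, 25)
  tgt <- encode_targets(rbind(c(10, 25)), sp, c(15))
  out <- detection_tensor(tgt$c + 0.1, tgt$w + 0.2,
                          matrix(0.5, 2, 1))
  l <- br_loss(tgt, out, lambda_reg = 1, lambda_conf = 0)
  expect_equal(as.numeric(l), 0.3, tolerance = 1e-9)
})

test_that("encode/decode round trip recovers centres and overlaps truth", {
  set.seed(31)
  anchors <- c(9, 15, 21)
  sp <- grid_spec(500, 25)
  n_dec <- integer(1000); c_err <- numeric(1000); min_iou <- numeric(1000)
  for (i in 1:1000) {
    w <- runif(1, 9, 21 * exp(1) - 1e-6)
    ctr <- runif(1, w / 2, 500 - w / 2)
    br <- c(ctr - w / 2, ctr + w / 2)
    tgt <- encode_targets(rbind(br), sp, anchors)
    out <- detection_tensor(tgt$c, tgt$w,
                            ifelse(tgt$resp, 1, 0))
    dec <- decode(out, sp, anchors, conf_threshold = 0.5, nms = FALSE)
    n_dec[i] <- nrow(dec)
    c_err[i] <- abs(dec$center[1] - ctr)
    min_iou[i] <- iou(c(dec$start[1], dec$end[1]), br)
  }
  expect_true(all(n_dec == 1))
  expect_lt(max(c_err), 1e-9)
  expect_gte(min(min_iou), 0.5)
})

test_that("regression gradients flow only to responsible cells", {
  set.seed(4)
  sp <- grid_spec(100, 25)
  tgt <- encode_targets(rbind(c(30, 45)), sp, c(9, 15, 21))
  out <- detection_tensor(matrix(runif(12, 0.2, 0.8), 4, 3),
                          matrix(runif(12, 0.2, 0.8), 4, 3),
                          matrix(runif(12, 0.2, 0.8), 4, 3))
  base <- as.numeric(br_loss(tgt, out, lambda_conf = 0))
  eps <- 1e-6
  for (g in 1:4) for (a in 1:3) {
    out2 <- out
    out2$c[g, a] <- out2$c[g, a] + eps
    d <- as.numeric(br_loss(tgt, out2, lambda_conf = 0)) - base
    if (tgt$resp[g, a]) expect_gt(abs(d), eps / 10)
    else expect_equal(d, 0)
  }
})
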