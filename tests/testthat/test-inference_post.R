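test_that("padding reaches the next multiple of 96 bottom/right only", {
  p <- pad_to_grid(matrix(1, 960, 672))
  expect_equal(dim(p$slice), c(960, 672))
  expect_equal(p$pad, c(0L, 0L))
  p2 <- pad_to_grid(matrix(1, 950, 670))
  expect_equal(dim(p2$slice), c(960, 672))
  expect_equal(p2$pad, c(10L, 2L))
  expect_equal(p2$slice[1:950, 1:670], matrix(1, 950, 670))
  expect_true(all(p2$slice[951:960, ] == 0))
})

test_that("iou is the standard half-open intersection over union", {
  a <- c(0, 0, 100, 100)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(200, 200, 10, 10)), 0)
  expect_equal(iou(a, c(50, 0, 100, 100)), 1 / 3)
})

test_that("breast filtering keeps boxes with at least half their area inside", {
  mask <- matrix(FALSE, 100, 100)
  mask[1:100, 1:50] <- TRUE
  masks <- list(mask)
  boxes <- data.frame(x = c(10, 60, 40, 200), y = c(10, 10, 10, 10),
                      width = c(20, 20, 20, 20),
                      height = c(20, 20, 20, 20),
                      z = 0L, score = 0.5)
  # fully inside; fully outside; exactly half (x 40..60, mask to 50); off-image
  got <- filter_outside_breast(boxes, masks)
  expect_equal(got$x, c(10, 40))
  expect_identical(filter_outside_breast(got, masks), got)
  expect_error(filter_outside_breast(data.frame(x = 1, y = 1, width = 2,
                                                height = 2, z = 5L,
                                                score = 1), masks),
               class = "dbt_validation_error")
})

test_that("merge NMS applies the ratio and IoU gates as stated", {
  b <- data.frame(x = c(0, 10), y = c(0, 0), width = c(100, 100),
                  height = c(100, 100), score = c(0.9, 0.8), z = c(1L, 2L))
  m <- merge_nms(b)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 0.9)
  expect_equal(m$x, 0)       # geometry of the higher-scoring box
  expect_equal(m$z, 1L)

  b2 <- b
  b2$score <- c(0.9, 0.05)   # ratio 18 >= 10: no merge
  expect_equal(nrow(merge_nms(b2)), 2)

  b3 <- data.frame(x = c(0, 90), y = 0, width = 50, height = 50,
                   score = c(0.5, 0.4), z = 0L)  # disjoint: no merge
  expect_equal(nrow(merge_nms(b3)), 2)
  expect_error(merge_nms(data.frame(x = 0, y = 0, width = 1, height = 1,
                                    score = 0, z = 0L)),
               class = "dbt_parameter_error")
})

test_that("merge NMS output never contains a qualifying pair and keeps max score", {
  set.seed(14)
  for (rep in 1:30) {
    b <- random_boxes(sample(2:12, 1), span = 150)
    m <- merge_nms(b)
    expect_lte(nrow(m), nrow(b))
    expect_equal(max(m$score), max(b$score))
    if (nrow(m) >= 2) {
      for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
        r <- max(m$score[i], m$score[j]) / min(m$score[i], m$score[j])
        ov <- iou(as.numeric(m[i, c("x", "y", "width", "height")]),
                  as.numeric(m[j, c("x", "y", "width", "height")]))
        expect_false(r < 10 && ov > 0.5)
      }
    }
  }
})

# hand-crafted detector that fires where the local brightness is high: all
# dense-block weights are zeroed so the stem's mean-brightness channel is
# passed through the pooling chain untouched, and the head turns it into a
# confidence logit
brightness_detector <- function() {
  det <- build_detector(detector_config(growth_rate = 2L,
                                        stem_channels = 2L, seed = 1))
  det$params$stem$W[] <- 0
  det$params$stem$W[5, 1] <- 1  # center tap of the 3x3 kernel, channel 1
  det$params$stem$b[] <- 0
  for (b in seq_along(det$params$blocks))
    for (j in seq_along(det$params$blocks[[b]])) {
      det$params$blocks[[b]][[j]]$W[] <- 0
      det$params$blocks[[b]][[j]]$b[] <- 0
    }
  det$params$head$W[] <- 0
  det$params$head$W[1, 1] <- 40
  # decode to 64 x 64 boxes so they survive the breast-coverage filter
  det$params$head$b <- c(-20, 0, 0, log(64 / 256), log(64 / 256))
  det
}

test_that("predict_volume averages halves, assigns mid-slice z, and filters", {
  det <- brightness_detector()
  # breast occupies the full frame; bright 96x96 patch only in slices 1-3
  px <- array(0.3, c(96, 192, 7))
  px[, , ] <- px + with_seed_local(5, array(runif(96 * 192 * 7, 0, 0.05),
                                            c(96, 192, 7)))
  px[1:96, 1:96, 1:3] <- 0.95  # the first grid cell, first half only
  vol <- new_volume(px, "LCC", "PX", "SX", window_center = 0.5,
                    window_width = 1)
  masks <- rep(list(matrix(TRUE, 96, 192)), 7)
  got <- predict_volume(det, vol, masks, threshold = 0.5)
  # halves are 1:3 and 4:7 (floor split); only the first half fires
  expect_true(all(got$Z == 1L))
  expect_gte(nrow(got), 1)
  cx <- got$X + got$Width / 2
  expect_true(all(cx >= 0 & cx < 96))

  # all-dim volume: no boxes above threshold
  dark <- new_volume(array(0.1, c(96, 96, 4)), "LCC",
                     window_center = 0.5, window_width = 1)
  dmask <- rep(list(matrix(TRUE, 96, 96)), 4)
  expect_equal(nrow(predict_volume(det, dark, dmask, threshold = 0.5)), 0)

  # identical slices: per-half averaging is the identity, so after NMS the
  # volume predictions equal single-slice decoding, z at a half midpoint
  same <- new_volume(array(px[, , 1], c(96, 192, 4)), "LCC",
                     window_center = 0.5, window_width = 1)
  smask <- rep(list(matrix(TRUE, 96, 192)), 4)
  two <- predict_volume(det, same, smask, threshold = 0.5)
  one_grid <- detector_forward(det, pad_to_grid(px[, , 1])$slice)
  one <- decode_predictions(one_grid, 0.5)
  expect_equal(nrow(two), nrow(one))
  expect_true(all(two$Z %in% c(0L, 2L)))
  expect_equal(sort(two$Score), sort(one$score), tolerance = 1e-12)
})

test_that("an untrained detector stays quiet on an all-zero volume", {
  det <- build_detector(detector_config(growth_rate = 3L,
                                        stem_channels = 4L, seed = 9))
  vol <- new_volume(array(0, c(96, 96, 4)), "LCC", window_center = 1,
                    window_width = 2)
  masks <- rep(list(matrix(TRUE, 96, 96)), 4)
  expect_equal(nrow(predict_volume(det, vol, masks, threshold = 0.5)), 0)
})
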