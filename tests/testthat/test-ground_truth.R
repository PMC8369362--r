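test_that("positive_slice_count follows the square-root rule with half-to-even rounding", {
  expect_equal(positive_slice_count(64, 64), 8L)
  expect_equal(positive_slice_count(1, 1), 1L)
  # sqrt(72) = 8.485... rounds to 8
  expect_equal(positive_slice_count(100, 44), 8L)
  expect_error(positive_slice_count(0, 10), class = "dbt_parameter_error")
  # nondecreasing in both dims
  ws <- seq(5, 300, by = 7)
  expect_true(all(diff(positive_slice_count(ws, 50)) >= 0))
  expect_true(all(diff(positive_slice_count(50, ws)) >= 0))
})

test_that("slice spans center on the lesion, tie-break below, clip to the volume", {
  expect_equal(training_slice_range(30, 5, 60), c(28L, 32L))
  expect_equal(training_slice_range(30, 4, 60), c(28L, 31L))
  expect_equal(training_slice_range(1, 9, 60), c(0L, 5L))
  expect_error(training_slice_range(60, 3, 60), class = "dbt_validation_error")

  expect_equal(validation_slice_range(30, 8, 60), training_slice_range(30, 4, 60))
  expect_equal(validation_slice_range(30, 1, 60), c(30L, 30L))
  # round(5/2) = round(2.5) half-to-even = 2
  expect_equal(diff(validation_slice_range(30, 5, 60)) + 1L, 2L)

  expect_equal(evaluation_slice_range(30, 60), c(15L, 45L))
  expect_equal(evaluation_slice_range(5, 60), c(0L, 20L))
  expect_equal(evaluation_slice_range(0, 1), c(0L, 0L))
})

test_that("all spans stay inside the volume and contain the center slice", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(1:80, 1)
    c0 <- sample(0:(n - 1), 1)
    cnt <- sample(1:15, 1)
    for (rng in list(training_slice_range(c0, cnt, n),
                     validation_slice_range(c0, cnt, n),
                     evaluation_slice_range(c0, n))) {
      expect_gte(rng[1], 0)
      expect_lte(rng[2], n - 1)
      expect_true(rng[1] <= c0 && c0 <= rng[2])
    }
  }
})

test_that("target grids have the published geometry and parameterization", {
  # the reference crop: 1056 x 672 px -> 7 rows x 11 cols of 96-px cells
  g <- encode_target_grid(data.frame(x = 500, y = 300, width = 50,
                                     height = 40), c(672, 1056))
  expect_equal(dim(g$objectness), c(7L, 11L))

  # box centered exactly on a cell center with anchor dims -> all-zero target
  g2 <- encode_target_grid(data.frame(x = 48 - 128, y = 48 - 128,
                                      width = 256, height = 256),
                           c(192, 192))
  expect_equal(g2$objectness[1, 1], 1)
  expect_equal(as.numeric(g2$regression[1, 1, ]), rep(0, 4))

  expect_error(encode_target_grid(data.frame(x = 1, y = 1, width = 2,
                                             height = 2), c(100, 96)),
               class = "dbt_shape_error")
})

test_that("cell collisions keep the larger box", {
  boxes <- data.frame(x = c(10, 20), y = c(10, 20),
                      width = c(30, 60), height = c(30, 60))
  g <- encode_target_grid(boxes, c(96, 96))
  expect_equal(sum(g$objectness), 1)
  expect_equal(exp(g$regression[1, 1, 3]) * 256, 60)
})

test_that("encode/decode round-trips 200 random boxes to 1e-6", {
  set.seed(9)
  for (i in 1:200) {
    w <- runif(1, 5, 150)
    h <- runif(1, 5, 150)
    cx <- runif(1, 1, 287)
    cy <- runif(1, 1, 383)
    b <- data.frame(x = cx - w / 2, y = cy - h / 2, width = w, height = h)
    back <- decode_target_grid(encode_target_grid(b, c(384, 288)))
    expect_equal(unlist(back), unlist(b), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("gt_box_3d combines coordinate mapping with phase-specific spans", {
  ann <- data.frame(PatientID = "P", StudyUID = "S", View = "LCC",
                    X = 100, Y = 200, Width = 64, Height = 64, Slice = 30,
                    Class = "cancer", LesionType = "mass")
  tr <- gt_box_3d(ann, 60, "train")
  expect_equal(unname(tr$box2d), c(50, 100, 32, 32))
  expect_equal(c(tr$slice_lo, tr$slice_hi), c(26L, 33L))  # count 8
  va <- gt_box_3d(ann, 60, "validation")
  expect_equal(c(va$slice_lo, va$slice_hi), c(28L, 31L))  # count 4
  ev <- gt_box_3d(ann, 60, "evaluation")
  expect_equal(c(ev$slice_lo, ev$slice_hi), c(15L, 45L))
})
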