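mk_case <- function(vol, x = 40, y = 60, w = 30, h = 24, slice = 4,
                    phase = "train") {
  ann <- data.frame(PatientID = vol$patient_id, StudyUID = vol$study_id,
                    View = vol$view, X = 2 * x, Y = 2 * y, Width = 2 * w,
                    Height = 2 * h, Slice = slice, Class = "cancer",
                    LesionType = "mass")
  list(gt = gt_box_3d(ann, n_slices(vol), phase), volume = vol, ann = ann)
}

test_that("sampled crops always contain the full ground-truth box", {
  vol <- tiny_test_volume(nr = 200, nc = 160, ns = 10)
  cs <- mk_case(vol)
  set.seed(10)
  for (i in 1:300) {
    ex <- sample_training_example(cs$gt, cs$volume, c(96L, 96L))
    expect_true(ex$box$x >= 0 && ex$box$y >= 0)
    expect_true(ex$box$x + ex$box$width <= 96)
    expect_true(ex$box$y + ex$box$height <= 96)
    expect_true(ex$z >= cs$gt$slice_lo && ex$z <= cs$gt$slice_hi)
    expect_equal(sum(ex$target$objectness), 1)
  }
})

test_that("an image exactly crop-sized leaves a single offset", {
  vol <- tiny_test_volume(nr = 96, nc = 96, ns = 6)
  cs <- mk_case(vol, x = 30, y = 30, w = 20, h = 20, slice = 3)
  set.seed(1)
  ex <- sample_training_example(cs$gt, cs$volume, c(96L, 96L))
  expect_equal(ex$image, vol$pixels[, , ex$z + 1])
})

test_that("sampling is deterministic under a fixed seed", {
  vol <- tiny_test_volume(nr = 200, nc = 160, ns = 10)
  cs <- mk_case(vol)
  draw <- function() {
    set.seed(33)
    lapply(1:5, function(i)
      sample_training_example(cs$gt, cs$volume, c(96L, 96L)))
  }
  expect_identical(draw(), draw())
})

test_that("fixed validation examples are bitwise stable and use the halved span", {
  vol <- tiny_test_volume(nr = 200, nc = 160, ns = 20)
  cs <- mk_case(vol, slice = 10, phase = "validation")
  e1 <- fixed_validation_example(cs$gt, cs$volume, c(96L, 96L))
  e2 <- fixed_validation_example(cs$gt, cs$volume, c(96L, 96L))
  expect_identical(e1, e2)
  # full-res box 60 x 48 -> count round(sqrt(54)) = 7 -> validation 4
  tr <- gt_box_3d(cs$ann, 20, "train")
  expect_equal(tr$slice_hi - tr$slice_lo + 1L, 7L)
  expect_equal(cs$gt$slice_hi - cs$gt$slice_lo + 1L, 4L)
  # a box at the image corner stays contained after clipping
  corner <- mk_case(vol, x = 0, y = 0, w = 20, h = 16, slice = 4,
                    phase = "validation")
  ec <- fixed_validation_example(corner$gt, corner$volume, c(96L, 96L))
  expect_true(ec$box$x >= 0 && ec$box$x + ec$box$width <= 96)
  expect_true(ec$box$y >= 0 && ec$box$y + ec$box$height <= 96)
})

test_that("training on one phantom lesion drives the loss down and keeps books", {
  vol <- with_seed_local(3, {
    px <- array(runif(192 * 96 * 8, 0, 0.3), c(192, 96, 8))
    px[76:100, 36:60, 3:5] <- px[76:100, 36:60, 3:5] + 0.6
    new_volume(px, "LCC", "P1", "S1", window_center = 0.5,
               window_width = 1)
  })
  cs <- mk_case(vol, x = 36, y = 76, w = 24, h = 24, slice = 4)
  csv <- mk_case(vol, x = 36, y = 76, w = 24, h = 24, slice = 4,
                 phase = "validation")
  det <- build_detector(detector_config(growth_rate = 4L,
                                        stem_channels = 6L, seed = 2))
  cfg <- train_config(batch_size = 2L, max_epochs = 50L, patience = 49L,
                      crop = c(96L, 96L), seed = 7,
                      loss = loss_config("focal"))
  res <- train(det, list(cs), list(csv), cfg)
  expect_lte(nrow(res$history), 50)
  expect_lt(min(res$history$loss), res$history$loss[1])
  expect_equal(res$best_metric, max(res$history$val_sensitivity))
  # early stopping bookkeeping: if stopped early, patience epochs passed
  if (nrow(res$history) < cfg$max_epochs)
    expect_equal(nrow(res$history), res$best_epoch + cfg$patience)
  expect_error(train(det, list(), list(csv), cfg),
               class = "dbt_config_error")
})

test_that("training is reproducible end to end at tiny scale", {
  vol <- tiny_test_volume(nr = 96, nc = 96, ns = 6)
  cs <- mk_case(vol, x = 30, y = 30, w = 20, h = 20, slice = 3)
  run <- function() {
    det <- build_detector(detector_config(growth_rate = 3L,
                                          stem_channels = 4L, seed = 4))
    cfg <- train_config(batch_size = 1L, max_epochs = 2L, patience = 1L,
                        crop = c(96L, 96L), seed = 13,
                        loss = loss_config("bce"))
    train(det, list(cs), list(), cfg)$history
  }
  expect_identical(run(), run())
})

test_that("select_model prefers the dominating candidate and breaks ties by order", {
  # two fake 'detectors' evaluated through real inference would need
  # training; instead exercise selection with a single candidate and the
  # tie rule on identical candidates
  vol <- tiny_test_volume(nr = 192, nc = 96, ns = 8)
  pp <- preprocess_volume(new_volume(vol$pixels * 400, vol$view,
                                     vol$patient_id, vol$study_id,
                                     window_center = 100,
                                     window_width = 200))
  det <- build_detector(detector_config(growth_rate = 3L,
                                        stem_channels = 4L, seed = 4))
  ann <- data.frame(PatientID = "PT", StudyUID = "ST", View = "LCC",
                    X = 40, Y = 60, Width = 30, Height = 24, Slice = 4,
                    Class = "cancer", LesionType = "mass")
  idx <- data.frame(PatientID = "PT", StudyUID = "ST", View = "LCC",
                    Path = "", NumSlices = 8L, Group = "cancer")
  cands <- list(list(loss_kind = "bce", detector = det),
                list(loss_kind = "focal", detector = det))
  got <- select_model(cands, list(list(volume = pp$volume,
                                       masks = pp$masks)), ann, idx)
  expect_equal(got$loss_kind, "bce")  # tie -> first listed
  expect_error(select_model(list(), list(), ann, idx),
               class = "dbt_config_error")
})
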