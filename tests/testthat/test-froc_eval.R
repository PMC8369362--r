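test_that("the TP criterion combines the distance floor, half-diagonal rule, and z window", {
  crit <- match_criteria()
  gt100 <- list(x = 150, y = 150, width = 100, height = 100,
                center_slice = 30)  # center (200,200), half-diag 70.7
  mk <- function(cx, cy, z) list(x = cx - 10, y = cy - 10, width = 20,
                                 height = 20, z = z)
  # 90 px away: inside the 100-px floor
  expect_true(is_true_positive(mk(290, 200, 30), gt100, 60, crit))
  # 110 px away: beyond both the floor and the half diagonal
  expect_false(is_true_positive(mk(310, 200, 30), gt100, 60, crit))
  # large box: half diagonal 250 dominates the floor
  gt_big <- list(x = 0, y = 0, width = 300, height = 400,
                 center_slice = 30)
  expect_true(is_true_positive(mk(150 + 240, 200, 30), gt_big, 60, crit))
  expect_false(is_true_positive(mk(150 + 260, 200, 30), gt_big, 60, crit))
  # z window: center 30, n=60 -> [15, 45] inclusive
  expect_true(is_true_positive(mk(200, 200, 15), gt100, 60, crit))
  expect_true(is_true_positive(mk(200, 200, 45), gt100, 60, crit))
  expect_false(is_true_positive(mk(200, 200, 14), gt100, 60, crit))
  expect_false(is_true_positive(mk(200, 200, 46), gt100, 60, crit))
  # optional stricter containment rule
  strict <- match_criteria(require_center_in_gt = TRUE)
  expect_false(is_true_positive(mk(290, 200, 30), gt100, 60, strict))
  expect_true(is_true_positive(mk(240, 200, 30), gt100, 60, strict))
})

simple_scene <- function() {
  vols <- data.frame(PatientID = c("P1", "P1", "P2"), StudyUID = "S",
                     View = c("LCC", "LMLO", "RCC"), Path = "",
                     NumSlices = 40L,
                     Group = c("cancer", "cancer", "normal"))
  gts <- data.frame(PatientID = "P1", StudyUID = "S",
                    View = c("LCC", "LMLO"), X = c(100, 120),
                    Y = c(100, 130), Width = 40, Height = 40,
                    Slice = 20L, Class = "cancer", LesionType = "mass")
  list(vols = vols, gts = gts)
}

test_that("perfect predictions reach sensitivity 1 at 0 FP; none give 0", {
  sc <- simple_scene()
  perfect <- data.frame(PatientID = "P1", StudyUID = "S",
                        View = c("LCC", "LMLO"), X = c(100, 120),
                        Y = c(100, 130), Width = 40, Height = 40,
                        Z = 20L, Score = c(0.9, 0.8))
  cv <- froc_volume(perfect, sc$gts, sc$vols)
  expect_equal(sensitivity_at(cv, 0), 1)
  none <- perfect[0, ]
  cv0 <- froc_volume(none, sc$gts, sc$vols)
  expect_true(all(cv0$points$sensitivity == 0))
  expect_error(froc_volume(perfect, sc$gts, rbind(sc$vols, sc$vols[1, ])),
               class = "dbt_validation_error")
})

test_that("breast-based evaluation credits any lesion on any view", {
  sc <- simple_scene()
  # hit on CC only; MLO lesion missed; one far-off false positive
  preds <- data.frame(PatientID = c("P1", "P2"), StudyUID = "S",
                      View = c("LCC", "RCC"), X = c(102, 300),
                      Y = c(99, 300), Width = 40, Height = 40,
                      Z = c(20L, 5L), Score = c(0.9, 0.6))
  cb <- froc_breast(preds, sc$gts, sc$vols)
  expect_equal(sensitivity_at(cb, 2), 1)  # the one breast is detected
  cv <- froc_volume(preds, sc$gts, sc$vols)
  expect_equal(sensitivity_at(cv, 2), 0.5)  # one of two lesions
})

test_that("sensitivity_at reads the curve as a step function", {
  curve <- structure(list(points = data.frame(
    threshold = c(0.9, 0.5, 0.2),
    fp_per_unit = c(0, 1, 3), sensitivity = c(0.3, 0.5, 0.8)),
    unit = "volume", n_gt = 10, n_units = 5), class = "dbt_froc")
  expect_equal(sensitivity_at(curve, 2), 0.5)
  expect_equal(sensitivity_at(curve, 100), 0.8)
  expect_equal(sensitivity_at(curve, 0), 0.3)
  empty <- structure(list(points = data.frame()), class = "dbt_froc")
  expect_error(sensitivity_at(empty, 2), class = "dbt_validation_error")
})

test_that("curves are monotone and extra predictions move them the right way", {
  set.seed(15)
  for (rep in 1:20) {
    sc <- random_froc_scenario()
    cv <- froc_volume(sc$preds, sc$gts, sc$vols)
    expect_true(all(diff(cv$points$fp_per_unit) >= 0))
    expect_true(all(diff(cv$points$sensitivity) >= -1e-12))
  }
  sc <- simple_scene()
  base <- data.frame(PatientID = "P1", StudyUID = "S", View = "LCC",
                     X = 100, Y = 100, Width = 40, Height = 40, Z = 20L,
                     Score = 0.9)
  cv1 <- froc_volume(base, sc$gts, sc$vols)
  # an added false positive never raises sensitivity at any rate
  fp <- rbind(base, data.frame(PatientID = "P2", StudyUID = "S",
                               View = "RCC", X = 300, Y = 300, Width = 40,
                               Height = 40, Z = 5L, Score = 0.95))
  cv2 <- froc_volume(fp, sc$gts, sc$vols)
  for (r in c(0, 0.5, 1, 2, 5))
    expect_lte(sensitivity_at(cv2, r), sensitivity_at(cv1, r) + 1e-12)
  # an added correct prediction never lowers it
  tp <- rbind(base, data.frame(PatientID = "P1", StudyUID = "S",
                               View = "LMLO", X = 120, Y = 130, Width = 40,
                               Height = 40, Z = 20L, Score = 0.85))
  cv3 <- froc_volume(tp, sc$gts, sc$vols)
  for (r in c(0, 0.5, 1, 2, 5))
    expect_gte(sensitivity_at(cv3, r), sensitivity_at(cv1, r) - 1e-12)
})

test_that("bootstrap CIs are deterministic and collapse on degenerate data", {
  sc <- simple_scene()
  perfect <- data.frame(PatientID = "P1", StudyUID = "S",
                        View = c("LCC", "LMLO"), X = c(100, 120),
                        Y = c(100, 130), Width = 40, Height = 40,
                        Z = 20L, Score = c(0.9, 0.8))
  metric <- function(p, g, v) sensitivity_at(froc_volume(p, g, v), 2)
  ci <- bootstrap_ci(perfect, sc$gts, sc$vols, metric, n_boot = 50,
                     seed = 3)
  expect_equal(as.numeric(ci), c(1, 1))
  ci2 <- bootstrap_ci(perfect, sc$gts, sc$vols, metric, n_boot = 50,
                      seed = 3)
  expect_identical(as.numeric(ci), as.numeric(ci2))
})
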