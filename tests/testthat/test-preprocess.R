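test_that("window_level maps the window linearly onto [0,1] and clips", {
  expect_equal(window_level(matrix(50), 50, 100)[1], 0.5)
  expect_equal(window_level(matrix(75), 50, 100)[1], 0.75)
  expect_equal(window_level(matrix(-10), 50, 100)[1], 0)
  expect_equal(window_level(matrix(1e6), 50, 100)[1], 1)
  expect_error(window_level(matrix(1), 50, 0), class = "dbt_parameter_error")
  # monotone nondecreasing in pixel value
  x <- sort(runif(200, -100, 200))
  y <- window_level(matrix(x), 50, 100)
  expect_true(all(diff(as.vector(y)) >= 0))
})

test_that("downscale_2x is a 2x2 local mean with trailing odd lines dropped", {
  expect_equal(downscale_2x(matrix(c(10, 30, 20, 40), 2, 2)),
               matrix(25, 1, 1))
  expect_equal(downscale_2x(matrix(7, 6, 8)), matrix(7, 3, 4))
  expect_equal(dim(downscale_2x(matrix(runif(25), 5, 5))), c(2L, 2L))
  # commutes with transposition
  set.seed(5)
  m <- matrix(runif(48 * 36), 48, 36)
  expect_equal(downscale_2x(t(m)), t(downscale_2x(m)))
})

test_that("breast_mask matches a brute-force erosion + component oracle", {
  expect_false(any(breast_mask(matrix(0, 30, 30))))

  # two separated blobs: only the eroded large one survives
  sl <- matrix(0, 60, 60)
  sl[10:35, 10:35] <- 1   # ~676 px
  sl[50:54, 50:53] <- 1   # 20 px
  m <- breast_mask(sl, radius = 5)
  oracle <- oracle_largest_component(oracle_erode(sl > 0, 5))
  expect_equal(m, oracle)
  expect_false(any(m[45:60, 45:60]))

  # solid square: eroded area equals the brute-force erosion's area
  sq <- matrix(0, 120, 120)
  sq[11:110, 11:110] <- 1
  m2 <- breast_mask(sq, radius = 5)
  expect_equal(sum(m2), sum(oracle_erode(sq > 0, 5)))

  # random speckle images against the oracle
  set.seed(77)
  for (rep in 1:5) {
    img <- matrix(runif(40 * 40) > 0.35, 40, 40)
    got <- breast_mask(matrix(as.numeric(img), 40, 40), radius = 2)
    want <- oracle_largest_component(oracle_erode(img, 2))
    expect_equal(got, want)
  }
})

test_that("mask area never grows when the erosion radius grows", {
  # subset-ness can break when a tie between components flips under
  # stronger erosion, but the retained area is rigorously nonincreasing
  set.seed(8)
  for (rep in 1:3) {
    sl <- matrix(as.numeric(runif(50 * 50) > 0.2), 50, 50)
    areas <- vapply(c(1, 2, 3, 5),
                    function(r) sum(breast_mask(sl, radius = r)), 0)
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("preprocess_volume halves dims, bounds intensities, tolerates zeros", {
  vol <- tiny_test_volume(nr = 50, nc = 41, ns = 3)
  pp <- preprocess_volume(vol)
  expect_equal(dim(pp$volume$pixels), c(25, 20, 3))
  expect_true(all(pp$volume$pixels >= 0 & pp$volume$pixels <= 1))
  expect_length(pp$masks, 3)

  zvol <- new_volume(array(0, c(20, 20, 2)), "LCC", window_center = 1,
                     window_width = 2)
  ppz <- preprocess_volume(zvol)
  expect_false(any(vapply(ppz$masks, any, TRUE)))
})

test_that("phantom lesion centers land inside the breast mask", {
  p <- phantom_preset("tiny")
  hits <- 0L
  total <- 0L
  for (s in 1:15) {
    plan <- plan_dataset(0, 0, 1, 0, seed = 1000 + s, preset = "tiny")
    i <- which(vapply(seq_len(nrow(plan$volumes)), function(k)
      length(plan$lesions[[with(plan$volumes[k, ],
                                dbtdet:::vkey(PatientID, StudyUID,
                                              View))]]) > 0, TRUE))[1]
    g <- generate_plan_volume(plan, i)
    pp <- preprocess_volume(g$volume)
    ann <- annotations_to_preprocessed(g$annotations)
    for (a in seq_len(nrow(ann))) {
      cx <- ann$X[a] + ann$Width[a] / 2
      cy <- ann$Y[a] + ann$Height[a] / 2
      msk <- pp$masks[[ann$Slice[a] + 1]]
      total <- total + 1L
      if (msk[round(cy) + 1, round(cx) + 1]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
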