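# Independent brute-force oracles used to cross-check the package's
# optimized implementations, plus small random-input generators. These are
# deliberately naive re-implementations from the operation definitions.

# erosion: a pixel survives iff every offset of the disk lands on TRUE
oracle_erode <- function(m, radius) {
  nr <- nrow(m)
  nc <- ncol(m)
  r <- floor(radius)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!m[i, j]) next
      ok <- TRUE
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$di[k]
        jj <- j + offs$dj[k]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !m[ii, jj]) {
          ok <- FALSE
          break
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

# largest 8-connected component by repeated flood fill; scan order is
# column-major so that equal-area ties resolve to the same component as
# the implementation's documented lowest-label rule
oracle_largest_component <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (sj in seq_len(nc)) {
    for (si in seq_len(nr)) {
      if (!m[si, sj] || lab[si, sj] > 0) next
      cur <- cur + 1L
      stack <- list(c(si, sj))
      lab[si, sj] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di
          jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              m[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  if (cur == 0L) return(matrix(FALSE, nr, nc))
  areas <- tabulate(lab[lab > 0], cur)
  lab == which.max(areas)
}

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# fixed-point merge NMS applied naively from the rule statement
oracle_merge_nms <- function(boxes, ratio_max = 10, iou_min = 0.5) {
  repeat {
    n <- nrow(boxes)
    if (n < 2) break
    cand <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- max(boxes$score[i], boxes$score[j]) /
        min(boxes$score[i], boxes$score[j])
      ov <- oracle_iou(as.numeric(boxes[i, c("x", "y", "width", "height")]),
                       as.numeric(boxes[j, c("x", "y", "width", "height")]))
      if (r < ratio_max && ov > iou_min) {
        entry <- c(ov, max(boxes$score[i], boxes$score[j]), i, j)
        if (is.null(cand) || entry[1] > cand[1] ||
            (entry[1] == cand[1] && entry[2] > cand[2])) cand <- entry
      }
    }
    if (is.null(cand)) break
    i <- cand[3]
    j <- cand[4]
    win <- if (boxes$score[i] >= boxes$score[j]) i else j
    keep <- boxes[win, , drop = FALSE]
    keep$score <- max(boxes$score[i], boxes$score[j])
    boxes <- rbind(keep, boxes[-c(i, j), , drop = FALSE])
  }
  rownames(boxes) <- NULL
  boxes
}

# exhaustive threshold-by-threshold FROC oracle: at every threshold redo
# greedy matching from scratch on the surviving predictions. Works on
# plain vectors (data.frame ops in the hot loop are too slow for 1000
# scenarios); the matching rule itself goes through is_true_positive().
oracle_froc_points <- function(preds, gts, vols, criteria, breast = FALSE) {
  thr <- sort(unique(preds$Score), decreasing = TRUE)
  if (length(thr) == 0) thr <- 1
  keys <- paste(vols$PatientID, vols$StudyUID, vols$View, sep = "|")
  pkey <- paste(preds$PatientID, preds$StudyUID, preds$View, sep = "|")
  gkey <- paste(gts$PatientID, gts$StudyUID, gts$View, sep = "|")
  gbreast <- paste(gts$PatientID, gts$StudyUID, substr(gts$View, 1, 1),
                   sep = "|")
  all_breasts <- unique(gbreast)
  fp_per_unit <- numeric(length(thr))
  sens <- numeric(length(thr))
  for (ti in seq_along(thr)) {
    t <- thr[ti]
    n_tp <- 0
    n_fp <- 0
    det_breast <- character(0)
    for (k in seq_along(keys)) {
      pi <- which(pkey == keys[k] & preds$Score >= t)
      gi <- which(gkey == keys[k])
      used <- rep(FALSE, length(gi))
      for (i in pi[order(-preds$Score[pi])]) {
        hit <- NA
        hd <- Inf
        for (jj in seq_along(gi)) {
          if (used[jj]) next
          j <- gi[jj]
          ok <- is_true_positive(
            list(x = preds$X[i], y = preds$Y[i], width = preds$Width[i],
                 height = preds$Height[i], z = preds$Z[i]),
            list(x = gts$X[j], y = gts$Y[j], width = gts$Width[j],
                 height = gts$Height[j], center_slice = gts$Slice[j]),
            vols$NumSlices[k], criteria)
          if (!ok) next
          d <- sqrt((preds$X[i] + preds$Width[i] / 2 - gts$X[j] -
                       gts$Width[j] / 2)^2 +
                      (preds$Y[i] + preds$Height[i] / 2 - gts$Y[j] -
                         gts$Height[j] / 2)^2)
          if (d < hd) {
            hd <- d
            hit <- jj
          }
        }
        if (!is.na(hit)) {
          used[hit] <- TRUE
          n_tp <- n_tp + 1
          det_breast <- c(det_breast, gbreast[gi[hit]])
        } else {
          n_fp <- n_fp + 1
        }
      }
    }
    fp_per_unit[ti] <- n_fp / nrow(vols)
    sens[ti] <- if (breast) {
      if (length(all_breasts) == 0) 0
      else length(intersect(unique(det_breast), all_breasts)) /
        length(all_breasts)
    } else {
      if (nrow(gts) == 0) 0 else n_tp / nrow(gts)
    }
  }
  data.frame(threshold = thr, fp_per_unit = fp_per_unit,
             sensitivity = sens)
}

# random FROC scenario: a handful of volumes with 0-2 lesions and 0-5
# scored predictions each
random_froc_scenario <- function() {
  n_pat <- sample(2:3, 1)
  vols <- NULL
  gts <- NULL
  preds <- NULL
  for (p in seq_len(n_pat)) {
    pid <- sprintf("P%02d", p)
    sid <- sprintf("S%02d", p)
    for (view in sample(c("LCC", "RCC", "LMLO", "RMLO"),
                        sample(2:4, 1))) {
      ns <- sample(c(10L, 20L, 40L), 1)
      vols <- rbind(vols, data.frame(
        PatientID = pid, StudyUID = sid, View = view, Path = "",
        NumSlices = ns, Group = "normal", stringsAsFactors = FALSE))
      for (g in seq_len(sample(0:2, 1))) {
        gts <- rbind(gts, data.frame(
          PatientID = pid, StudyUID = sid, View = view,
          X = runif(1, 0, 300), Y = runif(1, 0, 300),
          Width = runif(1, 20, 120), Height = runif(1, 20, 120),
          Slice = sample.int(ns, 1) - 1L, Class = "cancer",
          LesionType = "mass", stringsAsFactors = FALSE))
      }
      for (q in seq_len(sample(0:5, 1))) {
        preds <- rbind(preds, data.frame(
          PatientID = pid, StudyUID = sid, View = view,
          X = runif(1, 0, 350), Y = runif(1, 0, 350),
          Width = runif(1, 20, 120), Height = runif(1, 20, 120),
          Z = sample.int(ns, 1) - 1L, Score = runif(1, 0.01, 1),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(gts))
    gts <- data.frame(PatientID = character(0), StudyUID = character(0),
                      View = character(0), X = numeric(0), Y = numeric(0),
                      Width = numeric(0), Height = numeric(0),
                      Slice = integer(0), Class = character(0),
                      LesionType = character(0))
  if (is.null(preds))
    preds <- data.frame(PatientID = character(0), StudyUID = character(0),
                        View = character(0), X = numeric(0), Y = numeric(0),
                        Width = numeric(0), Height = numeric(0),
                        Z = integer(0), Score = numeric(0))
  list(vols = vols, gts = gts, preds = preds)
}

random_boxes <- function(n, span = 300) {
  data.frame(x = runif(n, 0, span), y = runif(n, 0, span),
             width = runif(n, 10, 150), height = runif(n, 10, 150),
             score = runif(n, 0.01, 1),
             z = sample.int(10, n, replace = TRUE) - 1L)
}

tiny_test_volume <- function(nr = 128, nc = 96, ns = 10, seed = 4) {
  with_seed_local(seed, {
    px <- array(runif(nr * nc * ns, 0, 0.5), dim = c(nr, nc, ns))
    new_volume(px, view = "LCC", patient_id = "PT", study_id = "ST",
               window_center = 0.25, window_width = 0.5)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
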