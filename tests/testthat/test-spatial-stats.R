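emptyQC <- function(activeIds = integer(), unstableIds = integer()) {
  ids <- 1:64
  status <- ifelse(ids %in% unstableIds, "active_unstable",
                   ifelse(ids %in% activeIds, "active_stable", "inactive"))
  cs <- data.frame(channel_id = ids, status = status,
                   baseline_median_amp_uV = 0, baseline_mean_slope = 0,
                   baseline_cv = 0, reason = "")
  new("QCReport", sliceId = "s", channelStatus = cs,
      nActive = sum(status != "inactive"),
      nUnstable = sum(status == "active_unstable"),
      unstableFraction = 0, sliceExcluded = FALSE, exclusionReason = "")
}

mkCalls <- function(ids, label) {
  data.frame(slice_id = "s", channel_id = ids, layer = "deep",
             last_window_mean_pct = 150, label = label)
}

mkRecruit <- function(recruited = integer(), silenced = integer()) {
  ids <- c(recruited, silenced)
  data.frame(slice_id = "s", channel_id = ids, layer = "deep",
             baseline_amp_uV = 0, post_window_amp_uV = 20,
             recruited = ids %in% recruited, silenced = ids %in% silenced)
}

test_that("an all-inactive slice maps to 63 inactive cells plus stimulation", {
  m <- buildSpatialMap(emptyQC(), layout = gridLayout())
  expect_identical(sum(m$category == "inactive"), 63L)
  expect_identical(sum(m$category == "stimulation"), 1L)
})

test_that("categories are exclusive and conflicts are rejected", {
  qc <- emptyQC(activeIds = c(10:12, 20))
  m <- buildSpatialMap(qc, mkCalls(10:11, "potentiated"),
                       mkRecruit(recruited = 40), gridLayout())
  expect_identical(sum(table(m$category)), 64L)   # a single category per cell
  expect_identical(sort(m$channel_id[m$category == "plasticity"]), 10:11)
  expect_identical(m$category[m$channel_id == 40], factor("recruited",
                   levels = levels(m$category)))
  # a recruited channel that was baseline-active is inconsistent
  expect_error(buildSpatialMap(qc, NULL, mkRecruit(recruited = 10),
                               gridLayout()), "channel 10")
  expect_error(buildSpatialMap(qc, NULL, mkRecruit(silenced = 40),
                               gridLayout()), "channel 40")
})

test_that("layer counts add up and conserve the grid", {
  # superficial (cols 1-3): 10, 11, 12, 18, 19; deep: 22, 38
  qc <- emptyQC(activeIds = c(10:12, 18:19, 22, 38))
  calls <- mkCalls(c(10, 11, 18, 22), "potentiated")
  m <- buildSpatialMap(qc, calls, NULL, gridLayout())
  lc <- countByLayer(m)
  sup <- lc[lc$layer == "superficial", ]
  # hand count: 3 superficial channels with LTP, 2 without
  expect_identical(sup$n_with_plasticity, 3L)
  expect_identical(sup$n_without_plasticity, 2L)
  expect_identical(sup$n_active, 5L)
  expect_identical(lc$n_with_plasticity[lc$layer == "deep"], 1L)
  expect_true(all(lc$n_with_plasticity + lc$n_without_plasticity ==
                    lc$n_active))
  # all layers plus outside cover the 63 non-stimulation cells
  expect_identical(sum(table(m$layer[m$category != "stimulation"])), 63L)
})

test_that("edge flags match an exhaustive neighbour enumeration", {
  # oracle: direct enumeration over all 8 neighbours with the border
  # counting as outside
  edgeOracle <- function(m) {
    activeSet <- m$channel_id[m$category %in%
      c("activated_only", "plasticity", "silenced", "stimulation")]
    sapply(which(m$category == "recruited"), function(i) {
      r <- m$row[i]; cc <- m$col[i]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; c2 <- cc + dc
        if (rr < 0 || rr > 7 || c2 < 0 || c2 > 7) return(TRUE)
        if (!((rr * 8 + c2 + 1) %in% activeSet)) return(TRUE)
      }
      FALSE
    })
  }
  set.seed(99)
  for (rep in 1:200) {
    cat200 <- sample(c("inactive", "activated_only", "recruited"), 64,
                     replace = TRUE, prob = c(0.3, 0.55, 0.15))
    m <- data.frame(channel_id = 1:64, row = rep(0:7, each = 8),
                    col = rep(0:7, 8), layer = "deep",
                    category = factor(cat200,
                      levels = medplast:::SPATIAL_CATEGORIES))
    class(m) <- c("SpatialMap", "data.frame")
    attr(m, "nRows") <- 8L; attr(m, "nCols") <- 8L
    fl <- flagEdgeChannels(m)
    expect_identical(unname(fl$edge[m$category == "recruited"]),
                     unname(edgeOracle(m)))
  }
  # a recruited cell fully surrounded by activated cells is interior
  cat2 <- rep("activated_only", 64)
  cat2[3 * 8 + 4] <- "recruited"                      # (3,3), all nb active
  m2 <- data.frame(channel_id = 1:64, row = rep(0:7, each = 8),
                   col = rep(0:7, 8), layer = "deep",
                   category = factor(cat2,
                     levels = medplast:::SPATIAL_CATEGORIES))
  class(m2) <- c("SpatialMap", "data.frame")
  fl2 <- flagEdgeChannels(m2)
  expect_false(fl2$edge[fl2$category == "recruited"])
  # a recruited cell on the grid border is always edge
  cat2[3 * 8 + 4] <- "activated_only"; cat2[1] <- "recruited"
  m3 <- m2; m3$category <- factor(cat2, levels = levels(m2$category))
  fl3 <- flagEdgeChannels(m3)
  expect_true(fl3$edge[fl3$category == "recruited"])
})

test_that("synthetic recruited channels all lie on the activated edge", {
  b <- simulateSlice(conditionPreset("observer"), smallProtocol(),
                     seed = 61, params = smallParams(noiseSdUv = 0))
  f <- extractFeatures(b)
  qc <- sliceQC(f)
  rec <- detectRecruited(f, qc)
  m <- flagEdgeChannels(buildSpatialMap(qc, NULL, rec, layout2d(b)))
  expect_equal(attr(m, "edge_fraction"), 1.0)
})

test_that("Welch's t matches explicit formula evaluation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welchT(a, b)
  # brute-force Welch formula
  se2 <- var(a) / 3 + var(b) / 5
  tRef <- (mean(a) - mean(b)) / sqrt(se2)
  dfRef <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  pRef <- 2 * pt(-abs(tRef), dfRef)
  expect_equal(w$value, tRef, tolerance = 1e-10)
  expect_equal(w$df, dfRef, tolerance = 1e-10)
  expect_equal(w$p_value, pRef, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  w0 <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$value, 0); expect_equal(w0$p_value, 1)
  # scaling both samples leaves t unchanged
  wk <- welchT(5 * a, 5 * b)
  expect_equal(wk$value, w$value, tolerance = 1e-10)
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("two-way ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(7)
  d <- expand.grid(g = c("a", "b"), iv = c("x", "y"),
                   rep = 1:6, KEEP.OUT.ATTRS = FALSE)
  mu <- c(a.x = 10, b.x = 12, a.y = 11, b.y = 16)
  d$y <- mu[paste(d$g, d$iv, sep = ".")] + rnorm(nrow(d))
  res <- twoWayAnovaPosthoc(d, "y", "g", "iv", method = "sidak")

  # explicit balanced-design SS decomposition
  N <- nrow(d); gm <- mean(d$y)
  mA <- tapply(d$y, d$g, mean); mB <- tapply(d$y, d$iv, mean)
  mAB <- tapply(d$y, paste(d$g, d$iv), mean)
  nA <- N / 2; nB <- N / 2; nAB <- N / 4
  ssA <- nA * sum((mA - gm)^2)
  ssB <- nB * sum((mB - gm)^2)
  cellDev <- mAB - mA[substr(names(mAB), 1, 1)] -
    mB[substr(names(mAB), 3, 3)] + gm
  ssAB <- nAB * sum(cellDev^2)
  ssE <- sum((d$y - mAB[paste(d$g, d$iv)])^2)
  om <- res$omnibus
  expect_equal(om$sum_sq[om$term == "A"], ssA, tolerance = 1e-10)
  expect_equal(om$sum_sq[om$term == "B"], ssB, tolerance = 1e-10)
  expect_equal(om$sum_sq[om$term == "A:B"], ssAB, tolerance = 1e-10)
  expect_equal(om$sum_sq[om$term == "Residuals"], ssE, tolerance = 1e-10)
  fA <- (ssA / 1) / (ssE / (N - 4))
  expect_equal(om$F[om$term == "A"], fA, tolerance = 1e-10)

  # adjusted p never below raw p
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-12))
  # Sidak adjustment formula on the raw p (one comparison per B level)
  expect_equal(res$pairwise$p_adjusted, res$pairwise$p_raw,
               tolerance = 1e-10)

  # degenerate: zero variance -> flagged, not fitted
  d0 <- d; d0$y <- 5
  expect_identical(twoWayAnovaPosthoc(d0, "y", "g", "iv")$flag,
                   "no variance")
  # empty cell -> invalid design
  dEmpty <- d[!(d$g == "a" & d$iv == "x"), ]
  expect_error(twoWayAnovaPosthoc(dEmpty, "y", "g", "iv"), "empty")
})

test_that("Tukey post-hoc handles three groups with adjustment", {
  set.seed(8)
  d <- expand.grid(g = c("a", "b", "c"), iv = c("x", "y"), rep = 1:5,
                   KEEP.OUT.ATTRS = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$g == "b", 2, 0)
  res <- twoWayAnovaPosthoc(d, "y", "g", "iv", method = "tukey")
  expect_identical(nrow(res$pairwise), 6L)   # 3 pairs x 2 intervals
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-12))
  expect_true(all(res$pairwise$p_adjusted >= 0 &
                    res$pairwise$p_adjusted <= 1))
})
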