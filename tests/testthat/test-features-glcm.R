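test_that("a single horizontal pair gives the two symmetric cells", {
  q <- make_slice(matrix(c(1L, 2L), nrow = 1))
  g <- compute_glcm(q, "0")
  expect_equal(g$p[1, 2], 0.5)
  expect_equal(g$p[2, 1], 0.5)
  expect_equal(sum(g$p), 1)
  expect_equal(g$pair_count, 1)
  expect_error(compute_glcm(q, "90"), "90")
})

test_that("a constant slice concentrates all mass in one diagonal cell", {
  q <- make_slice(matrix(5L, 4, 4))
  for (o in c("0", "45", "90", "135")) {
    g <- compute_glcm(q, o)
    expect_equal(g$p[5, 5], 1)
    expect_equal(sum(g$p), 1)
  }
})

test_that("co-occurrence matrices equal brute-force pair enumeration", {
  dirs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  for (s in 1:100) {
    q <- random_masked_slice(s)
    for (o in names(dirs)) {
      ref <- tryCatch(
        brute_glcm(q$levels, q$mask, dirs[[o]][1], dirs[[o]][2]),
        error = function(e) NULL
      )
      if (is.null(ref)) {
        expect_error(compute_glcm(q, o))
      } else {
        g <- compute_glcm(q, o)
        expect_equal(g$p, ref, tolerance = 1e-12)
        expect_equal(g$p, t(g$p))  # symmetry
      }
    }
  }
})

test_that("matrices agree with scikit-image on unmasked rectangular images", {
  set.seed(5)
  lev <- matrix(sample(1:8, 48, replace = TRUE), 6, 8)
  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  write.table(lev, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.feature import graycomatrix\n",
    "img = np.loadtxt('%s', delimiter=',').astype(np.uint8) - 1\n",
    "g = graycomatrix(img, [1], [0, np.pi/4, np.pi/2, 3*np.pi/4],\n",
    "                 levels=8, symmetric=True, normed=True)\n",
    "np.savetxt('%s', g[:, :, 0, :].reshape(8, -1), delimiter=',')\n"), csv, out)
  status <- suppressWarnings(system2("python", "-", input = script,
                                     stdout = FALSE, stderr = FALSE))
  # scikit-image serves as an external oracle where available
  expect_equal(status, 0)
  ref <- as.matrix(read.csv(out, header = FALSE))
  q <- make_slice(lev)
  # scikit-image measures angles with image rows increasing downward, so its
  # pi/4 is our 135 degrees (and vice versa); symmetric matrices make the
  # sign of the displacement irrelevant.
  for (k in 1:4) {
    o <- c("0", "135", "90", "45")[k]
    ours <- compute_glcm(q, o)$p
    theirs <- matrix(ref[, seq(k, 32, by = 4)], 8, 8)
    expect_equal(ours, unname(theirs), tolerance = 1e-10)
  }
})

test_that("closed-form feature values hold on canonical matrices", {
  # single-cell matrix (constant slice)
  f1 <- haralick_features(compute_glcm(make_slice(matrix(5L, 3, 3)), "0"))
  expect_equal(unname(f1["energy"]), 1)
  expect_equal(unname(f1["entropy"]), 0)
  expect_equal(unname(f1["contrast"]), 0)
  expect_equal(unname(f1["dissimilarity"]), 0)
  expect_equal(unname(f1["maximum_probability"]), 1)

  # two-level checkerboard at 0 degrees: P(1,2) = P(2,1) = 0.5
  p2 <- matrix(0, 8, 8); p2[1, 2] <- 0.5; p2[2, 1] <- 0.5
  f2 <- haralick_features(p2)
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["dissimilarity"]), 1)

  # uniform matrix over all 64 cells
  f3 <- haralick_features(matrix(1 / 64, 8, 8))
  expect_equal(unname(f3["entropy"]), 6)
  expect_equal(unname(f3["energy"]), 1 / 64)
  expect_equal(unname(f3["maximum_probability"]), 1 / 64)
})

test_that("energy and entropy match direct summation on random matrices", {
  set.seed(3)
  for (i in 1:20) {
    raw <- matrix(rexp(64), 8, 8)
    p <- (raw + t(raw)); p <- p / sum(p)
    f <- haralick_features(p)
    expect_equal(unname(f["energy"]), sum(p^2))
    expect_equal(unname(f["entropy"]), -sum(p[p > 0] * log2(p[p > 0])))
    expect_equal(unname(f["contrast"]),
                 sum(outer(1:8, 1:8, function(i, j) (i - j)^2) * p))
    expect_true(f["energy"] > 0 && f["energy"] <= 1)
    expect_true(f["entropy"] >= 0)
  }
})

test_that("orientation pooling is the arithmetic feature mean", {
  q <- random_masked_slice(1, 12, 12)
  blocks <- lapply(c("0", "45", "90", "135"),
                   function(o) haralick_features(compute_glcm(q, o)))
  pooled <- pool_orientations(blocks)
  ref <- colMeans(do.call(rbind, blocks))
  expect_equal(pooled, ref)
  expect_equal(pool_orientations(rep(blocks[1], 4)), blocks[[1]])
  expect_error(pool_orientations(blocks[1:3]), "exactly 4")

  b <- blocks[[1]]
  made <- lapply(1:4, function(k) { b["contrast"] <- k; b })
  expect_equal(unname(pool_orientations(made)["contrast"]), 2.5)
})

test_that("rotating the slice by 90 degrees permutes orientations and fixes the pooled block", {
  q <- random_masked_slice(17, 9, 9)
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])  # 90-degree rotation
  qr <- make_slice(rot(q$levels), rot(q$mask))
  feats <- function(qq) lapply(c("0", "45", "90", "135"),
                               function(o) haralick_features(compute_glcm(qq, o)))
  a <- feats(q); b <- feats(qr)
  # 0 <-> 90 and 45 <-> 135 swap under rotation
  expect_equal(a[[1]], b[[3]], tolerance = 1e-12)
  expect_equal(a[[3]], b[[1]], tolerance = 1e-12)
  expect_equal(a[[2]], b[[4]], tolerance = 1e-12)
  expect_equal(a[[4]], b[[2]], tolerance = 1e-12)
  expect_equal(pool_orientations(a), pool_orientations(b), tolerance = 1e-12)
})
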