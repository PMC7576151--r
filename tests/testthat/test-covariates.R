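test_that("euclidean distance matches grid geometry and brute force", {
  m <- matrix(0, 7, 7); m[4, 4] <- 1
  d <- euclidean_distance(grid_raster(m, 120))$values
  expect_equal(d[4, 4], 0)
  expect_equal(d[4, 5], 120)              # rook neighbor
  expect_equal(d[3, 3], 120 * sqrt(2))    # diagonal neighbor
  # random 20x20 vs O(n^2) oracle
  set.seed(8)
  mm <- matrix(rbinom(400, 1, 0.08), 20, 20)
  if (!any(mm == 1)) mm[11, 3] <- 1
  dd <- euclidean_distance(grid_raster(mm, 120))$values
  tr <- which(mm == 1, arr.ind = TRUE)
  oracle <- matrix(NA_real_, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- 120 * min(sqrt((tr[, 1] - i)^2 + (tr[, 2] - j)^2))
  expect_lt(max(abs(dd - oracle)), 1e-9)
  expect_error(euclidean_distance(grid_raster(matrix(0, 3, 3), 120)),
               "no true cells")
})

test_that("focal density is a proportion with exact neighborhood counts", {
  ones <- grid_raster(matrix(1, 12, 12), 120)
  expect_true(all(focal_density(ones, 300)$values == 1))
  zeros <- grid_raster(matrix(0, 12, 12), 120)
  expect_true(all(focal_density(zeros, 300)$values == 0))
  # random 15x15, radius 2.5 cells, against a direct per-cell count
  set.seed(9)
  m <- matrix(rbinom(225, 1, 0.4), 15, 15)
  r <- grid_raster(m, 100)
  fd <- focal_density(r, 250)$values
  oracle <- matrix(NA_real_, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    acc <- 0L; cnt <- 0L
    for (di in -2:2) for (dj in -2:2) {
      if (di^2 + dj^2 > 2.5^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 15 || jj < 1 || jj > 15) next
      cnt <- cnt + 1L; acc <- acc + m[ii, jj]
    }
    oracle[i, j] <- acc / cnt
  }
  expect_lt(max(abs(fd - oracle)), 1e-12)
  expect_error(focal_density(r, 50), "radius")
})

test_that("TRI obeys its defining formula", {
  flat <- grid_raster(matrix(5, 8, 8), 120)
  expect_true(all(tri(flat)$values == 0))
  z <- matrix(0, 5, 5); z[3, 3] <- 1
  expect_equal(tri(grid_raster(z, 120))$values[3, 3], 1)
  set.seed(10)
  zr <- matrix(rnorm(100), 10, 10)
  got <- tri(grid_raster(zr, 120))$values
  oracle <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    sq <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 10 && jj >= 1 && jj <= 10)
        sq <- c(sq, (zr[ii, jj] - zr[i, j])^2)
    }
    oracle[i, j] <- sqrt(mean(sq))
  }
  expect_lt(max(abs(got - oracle)), 1e-12)
})

test_that("shape index is 1 for squares, hand-counted for rectangles", {
  sq <- matrix(0, 9, 9); sq[3:6, 3:6] <- 1
  expect_equal(shape_index(grid_raster(sq, 120))$per_patch$shape, 1)
  rect <- matrix(0, 6, 8); rect[3, 2:5] <- 1   # 1x4: P = 10, A = 4
  expect_equal(shape_index(grid_raster(rect, 120))$per_patch$shape, 1.25)
  # every random patch is at least 1 (grid isoperimetric bound)
  set.seed(11)
  m <- matrix(rbinom(300, 1, 0.35), 15, 20)
  if (!any(m == 1)) m[5, 5] <- 1
  si <- shape_index(grid_raster(m, 120))
  expect_true(all(si$per_patch$shape >= 1))
  # area-weighted mean uses areas as weights
  w <- with(si$per_patch, sum(shape * area_cells) / sum(area_cells))
  expect_equal(si$area_weighted_mean, w)
})

test_that("patch labeling is 4-connected", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1   # diagonal only
  lab <- label_patches(grid_raster(m, 120))$values
  expect_equal(length(unique(lab[lab > 0])), 2)
})

test_that("contiguity is 1 in filled windows, 0 for isolated cells", {
  full <- grid_raster(matrix(1, 12, 12), 120)
  cg <- contiguity(full)$values
  expect_equal(cg[6, 6], 1)
  lone <- matrix(0, 11, 11); lone[6, 6] <- 1
  cl <- contiguity(grid_raster(lone, 120))$values
  expect_equal(cl[6, 6], 0)
  expect_true(all(cl >= 0 & cl <= 1))
})

test_that("contiguity window average matches a direct template oracle", {
  set.seed(12)
  m <- matrix(rbinom(144, 1, 0.5), 12, 12)
  r <- grid_raster(m, 120)
  got <- contiguity(r, window_area_km2 = 0.5)$values
  lab <- label_patches(r)$values
  radius <- sqrt(0.5e6 / pi) / 120
  score <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    if (lab[i, j] == 0) next
    s <- 1
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 12 || jj < 1 || jj > 12) next
      if (lab[ii, jj] == lab[i, j])
        s <- s + ifelse(di == 0 || dj == 0, 2, 1)
    }
    score[i, j] <- (s - 1) / 12
  }
  oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    acc <- c()
    for (di in -12:12) for (dj in -12:12) {
      if (di^2 + dj^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 12 || jj < 1 || jj > 12) next
      if (lab[ii, jj] > 0) acc <- c(acc, score[ii, jj])
    }
    oracle[i, j] <- if (length(acc)) mean(acc) else 0
  }
  expect_lt(max(abs(got - oracle)), 1e-12)
})

test_that("correlation screen flags exact and strong correlations", {
  set.seed(13)
  base <- gen_gaussian_field(40, 40, 5, seed = 14)
  neg <- map_values(base, function(v) -v)
  noise1 <- gen_gaussian_field(40, 40, 0, seed = 15)
  noise2 <- gen_gaussian_field(40, 40, 0, seed = 16)
  flat <- map_values(base, function(v) v * 0 + 3)
  st <- covariate_stack(list(a = base, b = neg, n1 = noise1, n2 = noise2,
                             flat = flat))
  st <- correlation_screen(st)
  expect_equal(st$correlation["a", "a"], 1)
  expect_equal(st$correlation["a", "b"], -1)
  expect_true(any(st$flagged_pairs$var1 == "a" & st$flagged_pairs$var2 == "b"))
  # two independent white-noise fields are not flagged
  expect_lt(abs(st$correlation["n1", "n2"]), 0.05)
  expect_false(any(st$flagged_pairs$var1 == "n1" & st$flagged_pairs$var2 == "n2"))
  # zero-variance variable reported degenerate, excluded from pairs
  expect_equal(st$degenerate, "flat")
})

test_that("derived covariates inherit the grid and stay in range", {
  st <- tiny_stack()
  ref <- st$rasters[[1]]
  for (nm in names(st$rasters)) expect_true(same_grid(ref, st$rasters[[nm]]))
  expect_true(all(st$rasters$agric_density$values >= 0 &
                    st$rasters$agric_density$values <= 1))
  expect_true(all(st$rasters$natural_contig$values >= 0 &
                    st$rasters$natural_contig$values <= 1))
  expect_true(all(st$rasters$dist_natural$values >= 0))
  expect_true(all(st$rasters$tri$values >= 0))
})
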