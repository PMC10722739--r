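grid_of <- function(m, cell_area = 1) suitability_grid(m, cell_area)

test_that("normalization sums valid cells to 1 and is scale invariant", {
  g <- grid_of(matrix(c(1, 1, 1, 1), 2))
  expect_equal(normalize_grid(g)$values, matrix(0.25, 2, 2))
  g2 <- grid_of(matrix(c(2, 2, 2, 2), 2))
  expect_equal(normalize_grid(g2)$values, normalize_grid(g)$values)
  gm <- grid_of(matrix(c(1, NA, 1, 2), 2))
  n <- normalize_grid(gm)
  expect_equal(sum(n$values[n$mask]), 1)
  expect_true(is.na(n$values[2, 1]))
  expect_error(normalize_grid(grid_of(matrix(0, 2, 2))), "all-zero")
})

test_that("Schoener's D and Warren's I hit their closed-form values", {
  gx <- grid_of(matrix(c(1, 0), 1)); gy <- grid_of(matrix(c(0.5, 0.5), 1))
  expect_equal(schoener_d(gx, gy), 0.5)
  expect_equal(warren_i(gx, gy), 1 - 0.5 * ((1 - sqrt(0.5))^2 + 0.5))
  expect_equal(schoener_d(gx, gx), 1)
  expect_equal(warren_i(gy, gy), 1)
  dis1 <- grid_of(matrix(c(1, 1, 0, 0), 1))
  dis2 <- grid_of(matrix(c(0, 0, 1, 1), 1))
  expect_equal(schoener_d(dis1, dis2), 0)
  expect_equal(warren_i(dis1, dis2), 0)
  expect_error(schoener_d(gx, dis1), "shape")
})

test_that("overlap metrics are symmetric, bounded, rescale-invariant, and I >= D", {
  set.seed(51)
  for (r in 1:30) {
    a <- matrix(runif(24), 4); b <- matrix(runif(24), 4)
    ga <- grid_of(a); gb <- grid_of(b)
    D <- schoener_d(ga, gb); I <- warren_i(ga, gb)
    expect_equal(D, schoener_d(gb, ga))
    expect_equal(I, warren_i(gb, ga))
    expect_gte(D, 0); expect_lte(D, 1); expect_gte(I, 0); expect_lte(I, 1 + 1e-12)
    expect_gte(I, D - 1e-12)
    expect_equal(schoener_d(grid_of(3.7 * a), gb), D)
  }
})

test_that("grids round-trip through the ASCII format with NODATA", {
  m <- matrix(runif(20), 4, 5); m[2, 3] <- NA
  g <- grid_of(m, cell_area = 25)
  f <- tempfile(fileext = ".asc")
  write_grid(g, f)
  back <- read_grid(f, cell_area = 25)
  expect_equal(back$values, g$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$mask, g$mask, ignore_attr = TRUE)
})

test_that("the presence-percentile threshold follows the nearest-rank rule", {
  expect_equal(tpl_threshold(rep(0.4, 7), 10), 0.4)
  expect_equal(tpl_threshold(seq(0.05, 0.5, by = 0.05), 10), 0.05)
  expect_equal(tpl_threshold(seq(0.05, 0.5, by = 0.05), 15), 0.1)
  expect_equal(tpl_threshold(c(0.9, 0.2, 0.5), 0), 0.2)
  expect_error(tpl_threshold(numeric(0)), "no presence")
  expect_error(tpl_threshold(c(0.5, 1.2)), "0,1")
})

test_that("binary range area follows the threshold and cell area", {
  m <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1), 3)
  g <- grid_of(m, cell_area = 25)
  expect_equal(binary_range(g, 0)$area_km2, 9 * 25)
  expect_equal(binary_range(g, 0.95)$area_km2, 0)
  expect_equal(binary_range(g, 0.25)$area_km2, 7 * 25)
  # monotone non-increasing in threshold
  areas <- sapply(seq(0, 1, by = 0.1), function(t) binary_range(g, t)$area_km2)
  expect_true(all(diff(areas) <= 0))
})

test_that("range change reports gain/loss/stable and percent change", {
  g1 <- grid_of(matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2), cell_area = 10)
  m1 <- binary_range(g1, 0.5)
  expect_equal(range_change(m1, m1), list(gain_km2 = 0, loss_km2 = 0,
                                          stable_km2 = 50, pct_change = 0))
  empty <- binary_range(g1, 1)  # threshold above every suitability except 1s
  g0 <- grid_of(matrix(0, 2, 5), cell_area = 10)
  none <- binary_range(g0, 0.5)
  rc <- range_change(m1, none)
  expect_equal(rc$loss_km2, 50)
  expect_equal(rc$pct_change, -100)
  # planted 20% loss: 10 suitable cells -> 8
  a <- matrix(0, 2, 10); a[, 1:5] <- 1
  b <- a; b[, 5] <- 0
  rc2 <- range_change(binary_range(grid_of(a), 0.5), binary_range(grid_of(b), 0.5))
  expect_equal(rc2$pct_change, -20)
  expect_warning(range_change(none, none), "baseline")
})

test_that("predictor pruning keeps the higher-contribution member of hot pairs", {
  cm <- diag(2); cm[1, 2] <- cm[2, 1] <- 0.9
  dimnames(cm) <- list(c("bio1", "bio2"), c("bio1", "bio2"))
  expect_equal(prune_predictors(cm, c(bio1 = 30, bio2 = 10)), "bio1")
  cm[1, 2] <- cm[2, 1] <- 0.5
  expect_setequal(prune_predictors(cm, c(bio1 = 30, bio2 = 10)),
                  c("bio1", "bio2"))
  # chain A-B (0.95), B-C (0.85), contributions 5, 20, 10:
  # AB drops A (5 < 20), then BC drops C (10 < 20) -> keep B
  cm3 <- diag(3); dimnames(cm3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  cm3["A", "B"] <- cm3["B", "A"] <- 0.95
  cm3["B", "C"] <- cm3["C", "B"] <- 0.85
  expect_equal(prune_predictors(cm3, c(A = 5, B = 20, C = 10)), "B")
  # tie keeps the alphabetically first, with a warning
  cm2 <- diag(2); cm2[1, 2] <- cm2[2, 1] <- 0.9
  dimnames(cm2) <- list(c("x", "y"), c("x", "y"))
  expect_warning(keep <- prune_predictors(cm2, c(x = 10, y = 10)), "tie")
  expect_equal(keep, "x")
})

test_that("simulated grid pairs reproduce their generation-time oracle", {
  for (sd in 1:5) {
    gp <- simulate_grid_pair(seed = sd, noise_sd = 0.2)
    expect_equal(schoener_d(gp$gx, gp$gy), gp$D, tolerance = 1e-12)
    expect_equal(warren_i(gp$gx, gp$gy), gp$I, tolerance = 1e-12)
  }
  same <- simulate_grid_pair(centers = list(c(10, 10), c(10, 10)),
                             widths = c(4, 4), seed = 1)
  expect_equal(same$D, 1); expect_equal(same$I, 1)
  far <- simulate_grid_pair(shape = c(60, 200),
                            centers = list(c(30, 20), c(30, 180)),
                            widths = c(3, 3), seed = 1)
  expect_lt(far$D, 1e-6)
})
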