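test_that("lead-field assembly has the documented shape and row order", {
  mh <- mini_leadfield()
  lf <- mh$lf
  n <- sum(mh$grid$brain_mask)
  expect_identical(dim(lf$A), c(3L * n, 3L))
  expect_identical(lf$electrode_ids, c("A", "B", "C"))
  expect_identical(nrow(lf$voxel_index), n)
  # single-column pattern reproduces the stored unit solve bit for bit
  f <- total_field(lf, current_pattern(c(1, -1, 0), I_max = 2))
  direct <- lf$A %*% c(1, -1, 0)
  expect_identical(as.numeric(t(unclass(f))), as.numeric(direct))
})

test_that("total field is an explicit linear combination of columns", {
  mh <- mini_leadfield()
  lf <- mh$lf
  s <- c(0.5, -0.25, -0.25)
  f <- total_field(lf, s)
  manual <- 0.5 * lf$A[, 1] - 0.25 * lf$A[, 2] - 0.25 * lf$A[, 3]
  expect_equal(as.numeric(t(unclass(f))), as.numeric(manual), tolerance = 1e-15)
  # zero pattern, exact linearity
  expect_true(all(unclass(total_field(lf, c(0, 0, 0))) == 0))
  f2 <- total_field(lf, 2 * s, I_max = 2)
  expect_equal(as.numeric(unclass(f2)), as.numeric(2 * unclass(f)),
               tolerance = 1e-15)
})

test_that("superposition matches a direct bipolar solve", {
  mh <- mini_leadfield(ids = c("A", "B"),
                       dirs = rbind(c(0, 0, 1), c(1, 0, 0)))
  lf <- mh$lf; g <- mh$grid; montage <- mh$montage
  patches <- attr(montage, "patches")
  # direct solve: +1 mA at A, -1 mA at B, no reference involvement
  voxels <- c(patches[["A"]], patches[["B"]])
  currents <- c(rep(1 / length(patches[["A"]]), length(patches[["A"]])),
                rep(-1 / length(patches[["B"]]), length(patches[["B"]])))
  direct <- solve_current_sources(g, voxels, currents,
                                  sigma = interfield:::montage_sigma(g, montage),
                                  config = solver_config(tol = 1e-11))
  direct_brain <- interfield:::extract_brain_field(direct$E, g)
  super <- matrix(as.numeric(lf$A %*% c(1, -1)), ncol = 3, byrow = TRUE)
  scale <- max(abs(direct_brain))
  expect_lt(max(abs(super - direct_brain)) / scale, 2e-8 * 2)
})

test_that("random zero-sum patterns superpose against multipolar solves", {
  mh <- mini_leadfield()
  lf <- mh$lf; g <- mh$grid; montage <- mh$montage
  patches <- attr(montage, "patches")
  set.seed(401)
  for (rep in 1:3) {
    s <- rnorm(3); s <- s - mean(s); s <- s / sum(abs(s))
    voxels <- integer(0); currents <- numeric(0)
    for (j in 1:3) {
      p <- patches[[j]]
      voxels <- c(voxels, p)
      currents <- c(currents, rep(s[j] / length(p), length(p)))
    }
    direct <- solve_current_sources(g, voxels, currents,
                                    config = solver_config(tol = 1e-11))
    direct_brain <- interfield:::extract_brain_field(direct$E, g)
    super <- matrix(as.numeric(lf$A %*% s), ncol = 3, byrow = TRUE)
    expect_lt(max(abs(super - direct_brain)) / max(abs(direct_brain)), 4e-8)
  }
})

test_that("current patterns enforce conservation and the L1 budget exactly", {
  expect_error(current_pattern(c(0.5, -0.4)), "sum to zero")
  expect_error(current_pattern(c(0.6, -0.6), I_max = 1), "budget")
  # the boundary is admissible
  s <- current_pattern(c(0.5, -0.5), I_max = 1)
  expect_s3_class(s, "current_pattern")
  expect_error(current_pattern(c(0.5 + 1e-6, -0.5 - 1e-6), I_max = 1)," budget|exceeds")
  mh <- mini_leadfield()
  expect_error(total_field(mh$lf, c(0.9, -0.9, 0)), "budget|exceeds")
  expect_error(total_field(mh$lf, c(0.3, -0.3)), "does not match")
})

test_that("magnitude map is a rotation-invariant Euclidean norm", {
  expect_equal(magnitude_map(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude_map(matrix(0, 4, 3)), rep(0, 4))
  set.seed(7)
  f <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(magnitude_map(f %*% t(Rz)), magnitude_map(f), tolerance = 1e-12)
})

test_that("lead-field containers round-trip losslessly and reject corruption", {
  mh <- mini_leadfield()
  lf <- mh$lf
  dir <- tempfile("lf_")
  write_leadfield(lf, dir)
  back <- read_leadfield(dir)
  expect_identical(back$A, lf$A)  # bitwise
  expect_identical(back$electrode_ids, lf$electrode_ids)
  expect_identical(back$voxel_index, lf$voxel_index)
  expect_identical(back$n, lf$n)
  # corrupted shape metadata is rejected
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta$n <- meta$n + 1L
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(read_leadfield(dir), "shape")
  unlink(file.path(dir, "meta.json"))
  expect_error(read_leadfield(dir), "missing")
})

test_that("externally written minimal CSV containers load", {
  dir <- tempfile("ext_")
  dir.create(dir)
  A <- matrix(seq(0.1, 1.2, by = 0.1), 6, 2)  # N = 6 rows, m = 2
  df <- as.data.frame(A); names(df) <- c("E1", "E2")
  utils::write.csv(df, file.path(dir, "A.csv"), row.names = FALSE, quote = FALSE)
  vi <- data.frame(i = 1:2, j = 1L, k = 1L)
  utils::write.csv(vi, file.path(dir, "voxel_index.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(n = 2, m = 2, voxel_size = 4,
                            voxel_volume_mm3 = 64),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  lf <- read_leadfield(dir)
  expect_equal(lf$A, A, ignore_attr = TRUE)
  expect_identical(lf$m, 2L)
})
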