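test_that("shell specifications are validated", {
  expect_error(shell_spec("skin", -1, 0.465), "positive")
  expect_error(shell_spec("skin", 92, 0), "> 0 S/m")
  bad <- dplyr::bind_rows(shell_spec("skin", 80, 0.465),
                          shell_spec("skull", 85, 0.01))
  expect_error(build_shell_phantom(bad, 4), "decreasing")
})

test_that("phantom conductivities take exactly the five tissue values", {
  g <- suppressWarnings(build_shell_phantom(voxel_size = 4))
  vals <- sort(unique(as.numeric(g$sigma[g$sigma > 0])))
  expect_equal(vals, sort(c(0.465, 0.01, 1.65, 0.27, 0.126)))
  # every labeled voxel carries its shell's conductivity
  for (k in seq_len(nrow(g$shells))) {
    expect_true(all(g$sigma[g$label == k] == g$shells$conductivity[k]))
  }
})

test_that("labeled volume approximates the sphere volume", {
  R <- 50; h <- 2.5  # h = R/20
  g <- build_shell_phantom(shell_spec("s", R, 1), voxel_size = h)
  vol_vox <- sum(g$label > 0L) * h^3
  expect_lt(abs(vol_vox / (4 / 3 * pi * R^3) - 1), 0.05)
})

test_that("brain mask matches an independent per-voxel distance check", {
  g <- suppressWarnings(build_shell_phantom(voxel_size = 4))
  idx <- which(array(TRUE, g$dim), arr.ind = TRUE)
  r <- sqrt(rowSums(((idx - matrix(g$center, nrow(idx), 3, byrow = TRUE)) * 4)^2))
  # GM union WM: inside the GM outer radius
  expect_identical(as.vector(g$brain_mask), r <= 76)
})

test_that("a shell that captures no voxels is rejected", {
  # the 0.01 mm film band (30.005, 30.015] contains no voxel-center
  # distance of the 4 mm grid (4*sqrt(56) = 29.93, 4*sqrt(57) = 30.20)
  shells <- dplyr::bind_rows(shell_spec("skin", 40, 0.465),
                             shell_spec("film", 30.015, 1.65),
                             shell_spec("wm", 30.005, 0.126))
  expect_error(suppressWarnings(build_shell_phantom(shells, 4)),
               "unresolvable")
  expect_warning(try(build_shell_phantom(shells, 4), silent = TRUE),
                 "thinner")
})

test_that("10-20 montage places 19 electrodes on the requested surface", {
  g <- suppressWarnings(build_shell_phantom(voxel_size = 4))
  for (layer in c("scalp", "skull")) {
    m <- place_1020_montage(g, layer)
    expect_s3_class(m, "montage")
    expect_identical(nrow(m), 19L)
    expect_true(all(m$n_voxels > 0))
    tissue <- if (layer == "scalp") "skin" else "skull"
    surf <- which(surface_mask(g, tissue))
    patches <- attr(m, "patches")
    expect_true(all(unlist(patches) %in% surf))
    # no two electrodes share a voxel, reference disjoint
    expect_identical(anyDuplicated(unlist(patches)), 0L)
    expect_length(intersect(attr(m, "reference"), unlist(patches)), 0)
  }
})

test_that("epicranial electrodes carry an insulating back, scalp ones do not", {
  g <- suppressWarnings(build_shell_phantom(voxel_size = 4))
  m_tes <- place_1020_montage(g, "scalp")
  m_ecs <- place_1020_montage(g, "skull")
  expect_length(attr(m_tes, "insulation"), 0)
  ins <- attr(m_ecs, "insulation")
  expect_gt(length(ins), 0)
  # insulated voxels are all skin voxels
  skin_k <- match("skin", g$shells$name)
  expect_true(all(g$label[ins] == skin_k))
})

test_that("Cz maps to the vertex and overlapping montages are rejected", {
  g <- suppressWarnings(build_shell_phantom(voxel_size = 4))
  m <- place_1020_montage(g, "scalp")
  cz <- attr(m, "patches")[["Cz"]]
  mask <- array(FALSE, g$dim)
  mask[cz] <- TRUE
  idx <- which_idx(mask)
  zmax_surface <- max(which_idx(surface_mask(g, "skin"))[, 3])
  expect_identical(max(idx[, 3]), zmax_surface)
  expect_error(place_1020_montage(g, "scalp", diameter = 80), "overlap")
})

test_that("montage on a missing surface errors", {
  g <- small_homog_grid()  # single shell named "skin": no skull surface
  expect_error(place_1020_montage(g, "skull"), "lacks")
})

test_that("montage serializes to JSON", {
  g <- suppressWarnings(build_shell_phantom(voxel_size = 4))
  m <- place_1020_montage(g, "scalp")
  path <- tempfile(fileext = ".json")
  write_montage_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(back), 19L)
  expect_setequal(back$id, m$id)
  expect_equal(back$diameter_mm, rep(15, 19))
})

test_that("analytic radial profile evaluates the closed form", {
  sh <- shell_spec("s", 50, 1)
  # 1 mA through 1 S/m at 10 mm: 1e-3 / (4 pi 1e-4) V/m
  expect_equal(analytic_radial_profile(sh, 1, 10), 1e-3 / (4 * pi * 1e-4),
               tolerance = 1e-12)
  # doubling the conductivity halves the field
  sh2 <- shell_spec("s", 50, 2)
  expect_equal(analytic_radial_profile(sh2, 1, 10),
               analytic_radial_profile(sh, 1, 10) / 2)
  expect_error(analytic_radial_profile(sh, 1, 60), "outside")
  expect_error(analytic_radial_profile(sh, 1, 50), "interface")
})
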