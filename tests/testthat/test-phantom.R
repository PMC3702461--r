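test_that("label rasterisation matches geometry", {
  # zero regions -> all air
  sc0 <- phantom_scene(shape = c(8, 8, 4), regions = list(), supersampling = 1L,
                       bias_amplitude = 0, mr_sigma = 0, ct_sigma = 0)
  lab0 <- build_labels(sc0)
  air_idx <- match("air", tissue_table()$name)
  expect_true(all(lab0$values == air_idx))

  # one centred muscle ellipsoid: inside muscle, outside air, and the voxel
  # count matches the analytic ellipsoid volume
  semi <- c(12, 10, 8)
  sc <- phantom_scene(shape = c(32, 32, 16), spacing = c(1, 1, 1),
                      regions = list(region_ellipsoid("muscle", c(16, 16, 8),
                                                      semi)),
                      supersampling = 4L, bias_amplitude = 0, mr_sigma = 0,
                      ct_sigma = 0)
  lab <- build_labels(sc)
  mus_idx <- match("muscle", tissue_table()$name)
  vox_vol <- prod(lab$spacing)
  v_count <- sum(lab$values == mus_idx) * vox_vol
  v_true <- 4 / 3 * pi * prod(semi)
  expect_lt(abs(v_count - v_true) / v_true, 0.02)
  expect_true(all(lab$values %in% c(air_idx, mus_idx)))

  # unknown tissue is a configuration error
  expect_error(phantom_scene(shape = c(4, 4, 4),
                             regions = list(region_ellipsoid("kryptonite",
                                                             c(2, 2, 2),
                                                             c(1, 1, 1)))),
               "unknown tissue")
})

test_that("MR signal closed forms behave physically", {
  tt <- tissue_table()
  bone <- tt[tt$name == "bone", ]
  fat <- tt[tt$name == "fat", ]
  air <- tt[tt$name == "air", ]
  muscle <- tt[tt$name == "muscle", ]

  # air gives zero under any sequence
  for (sq in default_protocol()) expect_identical(mr_signal(air, sq), 0)

  # spin echo at TE -> 0, TR -> Inf approaches proton density
  se_lim <- sequence_params("spin_echo", te = 1e-9, tr = 1e9)
  expect_equal(mr_signal(muscle, se_lim), muscle$proton_density,
               tolerance = 1e-6)

  # fat saturation nulls fat-like tissues only
  tse2 <- default_protocol()$TSE2
  expect_identical(mr_signal(fat, tse2), 0)
  expect_gt(mr_signal(muscle, tse2), 0)

  # cortical bone (T2* = 0.45 ms): echo ratio between TE 0.05 and 4.91 ms
  # equals exp((4.91 - 0.05) / 0.45) ~ e^10.8 -- bone is visible only at
  # ultrashort TE
  ute_a <- default_protocol()$UTE2e1
  ute_b <- default_protocol()$UTE2e2
  r <- mr_signal(bone, ute_a) / mr_signal(bone, ute_b)
  expect_equal(r, exp((4.91 - 0.05) / 0.45), tolerance = 1e-9)

  # at spin-echo TE (8.3 ms) bone signal is indistinguishable from air
  expect_lt(mr_signal(bone, default_protocol()$TSE1),
            0.01 * bone$proton_density)
  # fully relaxed ultrashort-echo readout retains most of the bone signal
  ute_rel <- sequence_params("ute_gre", te = 0.05, tr = 1e6, flip_angle = 90)
  expect_gt(mr_signal(bone, ute_rel), 0.5 * bone$proton_density)
})

test_that("TE monotonicity: longer echo time strictly reduces signal", {
  tt <- tissue_table()
  for (nm in c("fat", "muscle", "cartilage", "bone")) {
    ti <- tt[tt$name == nm, ]
    s <- vapply(c(0.05, 1, 5, 20),
                function(te) mr_signal(ti, sequence_params("spin_echo",
                                                           te = te, tr = 5000)),
                0.0)
    expect_true(all(diff(s) < 0))
  }
})

test_that("rendering: identity configuration reproduces nominal HU", {
  sc <- phantom_scene(shape = c(12, 12, 6), spacing = c(2, 2, 2),
                      regions = list(region_ellipsoid("muscle", c(12, 12, 6),
                                                      c(8, 8, 4))),
                      supersampling = 1L, bias_amplitude = 0, mr_sigma = 0,
                      ct_sigma = 0)
  r <- render_volumes(sc)
  tt <- tissue_table()
  hu_map <- tt$nominal_hu[r$labels$values]
  expect_equal(r$ct$values, array(hu_map, dim = dim(r$ct$values)))
})

test_that("partial volume: block averaging preserves the fine mean and mixes boundaries", {
  sc <- phantom_scene(shape = c(16, 16, 8), spacing = c(2, 2, 2),
                      regions = list(region_ellipsoid("muscle", c(16, 16, 8),
                                                      c(10, 10, 5))),
                      supersampling = 2L, bias_amplitude = 0, mr_sigma = 0,
                      ct_sigma = 0)
  r <- render_volumes(sc)
  lab_fine <- build_labels(sc)
  fine_hu <- tissue_table()$nominal_hu[lab_fine$values]
  expect_equal(mean(r$ct$values), mean(fine_hu), tolerance = 1e-12)
  # boundary voxels take intermediate values: a half-air half-muscle block
  # averages the two nominal HU
  mix <- r$ct$values[r$ct$values > -1000 & r$ct$values < 40]
  expect_gt(length(mix), 0)
  expect_true(all(mix %in% (seq_len(7) / 8 * (40 - (-1000)) - 1000)))
})

test_that("rendering is deterministic and noise streams are seeded", {
  sc <- default_scene(seed = 7, shape = c(12, 12, 6))
  r1 <- render_volumes(sc)
  r2 <- render_volumes(sc)
  expect_identical(r1$ct$values, r2$ct$values)
  for (nm in names(r1$mr))
    expect_identical(r1$mr[[nm]]$values, r2$mr[[nm]]$values)
  # a different seed changes the noise
  r3 <- render_volumes(default_scene(seed = 8, shape = c(12, 12, 6)))
  expect_false(identical(r1$ct$values, r3$ct$values))
})

test_that("Rician noise at zero signal has mean sigma * sqrt(pi/2)", {
  sigma <- 0.7
  n <- 40000
  sc <- phantom_scene(shape = c(40, 40, 25), regions = list(),
                      supersampling = 1L, bias_amplitude = 0,
                      mr_sigma = sigma, ct_sigma = 0, seed = 11)
  r <- render_volumes(sc, sequences = default_protocol()["TSE1"])
  v <- as.numeric(r$mr$TSE1$values)
  mu_true <- sigma * sqrt(pi / 2)
  sd_true <- sigma * sqrt((4 - pi) / 2)
  se <- sd_true / sqrt(length(v))
  expect_lt(abs(mean(v) - mu_true), 3 * se)
})

test_that("bias field is strictly positive and bounded by its amplitude", {
  for (amp in c(0, 0.05, 0.3, 0.9)) {
    b <- pction:::bias_field(c(9, 8, 7), amp, seed = 5)
    expect_true(all(b > 0))
    expect_true(all(b >= 1 - amp - 1e-12 & b <= 1 + amp + 1e-12))
  }
  expect_error(phantom_scene(shape = c(4, 4, 4), bias_amplitude = 1),
               "bias_amplitude")
})

test_that("scene round-trips through a YAML config", {
  sc <- phantom_scene(shape = c(10, 10, 5), spacing = c(2, 2, 2),
                      regions = list(
                        region_ellipsoid("muscle", c(10, 10, 5), c(6, 6, 3)),
                        region_cylinder("bone", c(10, 10, 5), radius = 3,
                                        half_length = 4)),
                      supersampling = 2L, bias_amplitude = 0.1,
                      mr_sigma = 0.05, ct_sigma = 5, seed = 42)
  cfg <- list(shape = sc$shape, spacing = sc$spacing,
              supersampling = sc$supersampling,
              bias_amplitude = sc$bias_amplitude, mr_sigma = sc$mr_sigma,
              ct_sigma = sc$ct_sigma, seed = sc$seed,
              regions = list(
                list(type = "ellipsoid", tissue = "muscle",
                     center = c(10, 10, 5), semiaxes = c(6, 6, 3)),
                list(type = "cylinder", tissue = "bone",
                     center = c(10, 10, 5), radius = 3, half_length = 4)))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  sc2 <- read_scene(f)
  r1 <- render_volumes(sc, default_protocol()["UTE2e1"])
  r2 <- render_volumes(sc2, default_protocol()["UTE2e1"])
  expect_identical(r1$ct$values, r2$ct$values)
  expect_identical(r1$mr$UTE2e1$values, r2$mr$UTE2e1$values)
})
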