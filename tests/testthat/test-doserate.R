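test_that("particle histories follow the strength-to-activity conversion", {
  # 37.95 mGy m2/h -> 37950 cGy cm2/h -> /4.037 = 9401 mCi -> 9.401 Ci
  expect_equal(particle_histories(37.95, 1), 37950 / 4.037 / 1000 * 3.7e10)
  expect_equal(particle_histories(37.95, 1), 3.478e11, tolerance = 1e-3)
  expect_equal(particle_histories(37.95, 0), 0)
  # linear in dwell time and in source strength
  expect_equal(particle_histories(37.95, 2), 2 * particle_histories(37.95, 1))
  expect_equal(particle_histories(2 * 18.97, 5),
               2 * particle_histories(18.97, 5))
  expect_error(particle_histories(37.95, -1), ">= 0")
})

test_that("dwell and average dose rates are plain ratios", {
  expect_equal(dwell_dose_rate(2, 109.09), 0.018334, tolerance = 1e-4)
  expect_equal(dwell_dose_rate(0, 50), 0)
  expect_equal(dwell_dose_rate(2, 218.18), dwell_dose_rate(2, 109.09) / 2)
  expect_error(dwell_dose_rate(2, 0), "positive")

  expect_equal(average_dose_rate(2, 109.09), 1.1, tolerance = 1e-3)
  expect_equal(average_dose_rate(2, 218.18), 0.55, tolerance = 1e-3)
  expect_equal(average_dose_rate(0, 60), 0)
  expect_error(average_dose_rate(2, 0), "positive")
})

test_that("linac pulse dose and instantaneous rate", {
  p <- pulse_spec(calibration = 200 / 220, mu_per_pulse = 0.08)
  expect_equal(dose_per_pulse(p), 200 / 220 * 0.08)
  expect_equal(dose_per_pulse(p), 0.0727, tolerance = 1e-3)
  expect_equal(dose_per_pulse(pulse_spec(calibration = 1,
                                         mu_per_pulse = 0.03)), 0.03)
  expect_equal(dose_per_pulse(pulse_spec(calibration = 1,
                                         mu_per_pulse = 0.16)),
               2 * dose_per_pulse(pulse_spec(calibration = 1,
                                             mu_per_pulse = 0.08)))
  expect_error(dose_per_pulse(pulse_spec()), "calibration")

  expect_equal(pulse_instantaneous_dose_rate(0.072, 4e-6), 180)
  expect_equal(pulse_instantaneous_dose_rate(0.036, 4e-6), 90)
  expect_equal(pulse_instantaneous_dose_rate(0.072, 8e-6), 90)
  expect_error(pulse_instantaneous_dose_rate(0.072, 0), "positive")
})

test_that("inverse-square distance matching", {
  expect_equal(distance_for_dose_rate_factor(91, 0.5), 91 / sqrt(0.5))
  expect_equal(round(distance_for_dose_rate_factor(91, 0.5)), 129)
  expect_equal(distance_for_dose_rate_factor(123.4, 1), 123.4)
  expect_equal(distance_for_dose_rate_factor(91, 0.25), 182)
  expect_error(distance_for_dose_rate_factor(-1, 0.5), "positive")
  expect_error(distance_for_dose_rate_factor(91, 0), "positive")
})

test_that("point-source rate: worked value, inverse square, linearity", {
  expect_equal(point_source_rate(37.95, 1), 37950 * 1.109 / 100 / 60)
  expect_equal(point_source_rate(37.95, 1), 7.01, tolerance = 1e-3)
  expect_equal(point_source_rate(37.95, 2), point_source_rate(37.95, 1) / 4)
  r <- seq(0.5, 5, 0.25)
  expect_equal(point_source_rate(18.97, r) * r^2,
               rep(point_source_rate(18.97, 1), length(r)))
  expect_equal(point_source_rate(18.97, r),
               point_source_rate(37.94, r) / 2)
  expect_error(point_source_rate(37.95, 0), "singularity")
})

test_that("dwell plans: construction, round trip, validation", {
  p1 <- generate_dwell_plan(1)
  expect_equal(nrow(p1), 1)
  p5 <- generate_dwell_plan(5, step_cm = 0.5, time_per_dwell_s = 10)
  expect_equal(max(p5$x_cm) - min(p5$x_cm), 2)
  expect_equal(p5$x_cm, -rev(p5$x_cm))  # symmetric about origin
  expect_equal(sum(p5$time_s), 50)
  expect_equal(unique(p5$z_cm), 1.5)
  expect_error(generate_dwell_plan(3, step_cm = 0), "positive")

  f <- tempfile(fileext = ".csv")
  write.csv(p5, f, row.names = FALSE)
  expect_equal(read_dwell_plan(f)$x_cm, p5$x_cm)
  expect_error(read_dwell_plan({
    f2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(x_cm = 1), f2); f2
  }), "missing column")
})

test_that("dose-rate maps: geometry, additivity, source-strength scaling", {
  plan <- generate_dwell_plan(1, channel_height_cm = 1.5)
  m <- dwell_dose_rate_map(plan, 37.95, grid_bins = 21)
  centre <- c(11, 11)  # odd bins put a voxel centre at the origin
  expect_equal(max(m$max_rate), m$max_rate[centre[1], centre[2]])
  # rates decay monotonically moving away from the centre along a row
  row <- m$max_rate[centre[1], centre[2]:21]
  expect_true(all(diff(row) < 0))
  expect_true(all(m$max_rate >= m$avg_rate))

  # two dwells of t at one position == one dwell of 2t
  p2 <- plan[c(1, 1), ]
  p2$dwell_index <- 1:2
  pl <- plan; pl$time_s <- 2 * plan$time_s
  m2 <- dwell_dose_rate_map(p2, 37.95, grid_bins = 21)
  ml <- dwell_dose_rate_map(pl, 37.95, grid_bins = 21)
  expect_equal(m2$total_dose, ml$total_dose)
  expect_equal(m2$max_rate, ml$max_rate)

  # hot vs cold source: per-voxel ratio equals the strength ratio everywhere
  mc <- dwell_dose_rate_map(plan, 18.97, grid_bins = 21)
  expect_equal(m$max_rate / mc$max_rate,
               matrix(37.95 / 18.97, 21, 21))
  expect_output(print(m), "Maximum dose rates")
})

test_that("total dose equals the time-integral of the point timeline", {
  plan <- generate_dwell_plan(5, step_cm = 0.5, time_per_dwell_s = 12)
  m <- dwell_dose_rate_map(plan, 37.95, grid_bins = 21)
  # voxel centre coordinates of the map's central voxel (odd bins -> origin)
  i <- 11
  expect_equal(m$x[i], 0)
  tl <- dose_rate_timeline(plan, 37.95, point = c(0, 0, 0))
  expect_equal(sum(tl$dose_gy), m$total_dose[i, i])
  expect_equal(sum(tl$rate_gy_min * plan$time_s) / sum(plan$time_s),
               m$avg_rate[i, i])
  expect_equal(max(tl$rate_gy_min), m$max_rate[i, i])
  # timeline covers the full delivery without gaps
  expect_equal(tl$t_start[-1], tl$t_end[-nrow(tl)])
  expect_equal(max(tl$t_end), sum(plan$time_s))
})

test_that("singular geometries are rejected", {
  plan <- generate_dwell_plan(1, channel_height_cm = 0)
  expect_error(dose_rate_timeline(plan, 37.95, point = c(plan$x_cm, 0, 0)),
               "coincides")
})

test_that("map serialization writes matrices and a summary", {
  plan <- generate_dwell_plan(2, step_cm = 1)
  m <- dwell_dose_rate_map(plan, 18.97, grid_bins = 10)
  pre <- tempfile()
  write_dose_rate_map(m, pre)
  mat <- as.matrix(read.csv(paste0(pre, "_max_rate.csv"), header = FALSE))
  expect_equal(dim(mat), c(10, 10))
  expect_equal(unname(mat[1, 1]), m$max_rate[1, 1], tolerance = 1e-6)
  expect_true(any(grepl("n_dwells: 2", readLines(paste0(pre, "_summary.txt")))))
})
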