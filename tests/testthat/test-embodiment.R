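dp <- decoder_params(gain = 1)

test_that("wheel speeds follow the 40 ms bin rule", {
  spikes <- data.frame(t_ms = c(10, 20, 50), unit = c(3, 200, 17))
  sp <- decode_wheel_speeds(spikes, dp, horizon = 80)
  expect_equal(sp$t_ms, c(0, 40))
  expect_equal(sp$v_left, c(2, 1))
  expect_equal(sp$v_right, c(0, 0))
  # a spike exactly on a boundary joins the later bin
  sp2 <- decode_wheel_speeds(data.frame(t_ms = 40, unit = 1), dp,
                             horizon = 80)
  expect_equal(sp2$v_left, c(0, 1))
  # no spikes: all-zero speeds
  sp0 <- decode_wheel_speeds(data.frame(t_ms = numeric(0),
                                        unit = integer(0)), dp,
                             horizon = 120)
  expect_true(all(sp0$v_left == 0) && all(sp0$v_right == 0))
})

test_that("binning neither loses nor double-counts spikes", {
  withr::with_seed(31, {
    spikes <- data.frame(t_ms = runif(2000, 0, 1999.9),
                         unit = sample(500, 2000, replace = TRUE))
    spikes <- spikes[order(spikes$t_ms), ]
    sp <- decode_wheel_speeds(spikes, dp, horizon = 2000)
    expect_equal(sum(sp$v_left), sum(spikes$unit %in% 1:250))
    expect_equal(sum(sp$v_right), sum(spikes$unit %in% 251:500))
  })
})

test_that("differential-drive kinematics: straight, spin, and arc", {
  mk <- function(vl, vr, n = 25) data.frame(t_ms = (0:(n - 1)) * 40,
                                            v_left = vl, v_right = vr)
  # equal speeds: straight line of length v * T
  tr <- integrate_pose(mk(10, 10), dp)
  expect_equal(tr$x[25], 10 * 1, tolerance = 1e-9)   # 25 bins = 1 s
  expect_equal(tr$y[25], 0, tolerance = 1e-12)
  expect_equal(tr$heading[25], 0)
  # opposite speeds: rotation in place
  tr2 <- integrate_pose(mk(5, -5), dp)
  expect_equal(tr2$x[25], 0, tolerance = 1e-9)
  expect_equal(tr2$y[25], 0, tolerance = 1e-9)
  expect_false(tr2$heading[25] == 0)
  # v_l = 20, v_r = 10, wheelbase 48: clockwise circle of radius 72 mm
  tr3 <- integrate_pose(mk(20, 10, n = 2000), dp)
  expect_lt(tr3$heading[2000], 0)                    # clockwise
  r_signed <- (dp$wheelbase / 2) * (20 + 10) / (10 - 20)  # -72: clockwise
  expect_equal(abs(r_signed), 72)
  centre <- c(tr3$x[1], tr3$y[1]) -
    r_signed * c(sin(tr3$heading[1]), -cos(tr3$heading[1]))
  d <- sqrt((tr3$x - centre[1])^2 + (tr3$y - centre[2])^2)
  expect_true(all(abs(d - 72) < 1e-6))
})

test_that("pose integration is reversible", {
  withr::with_seed(7, {
    n <- 60
    sp <- data.frame(t_ms = (0:(n - 1)) * 40,
                     v_left = runif(n, -20, 20),
                     v_right = runif(n, -20, 20))
    fwd <- integrate_pose(sp, dp)
    back <- data.frame(t_ms = sp$t_ms,
                       v_left = rev(-sp$v_left),
                       v_right = rev(-sp$v_right))
    ret <- integrate_pose(back, dp,
                          x0 = fwd$x[n], y0 = fwd$y[n],
                          heading0 = fwd$heading[n])
    expect_equal(ret$x[n], 0, tolerance = 1e-6)
    expect_equal(ret$y[n], 0, tolerance = 1e-6)
    expect_equal(ret$heading[n], 0, tolerance = 1e-9)
  })
})

test_that("left-subpopulation dominance yields net clockwise rotation", {
  # a bump near unit 125 makes the left wheel faster
  withr::with_seed(12, {
    spikes <- data.frame(t_ms = sort(runif(600, 0, 999)),
                         unit = sample(100:150, 600, replace = TRUE))
  })
  sp <- decode_wheel_speeds(spikes, dp, horizon = 1000)
  tr <- integrate_pose(sp, dp)
  expect_lt(tr$heading[nrow(tr)], 0)
})

test_that("dominance readout applies the tie margin", {
  spikes <- data.frame(t_ms = seq(1, 999, length.out = 200),
                       unit = rep(c(10, 300), each = 100))
  expect_identical(dominance(spikes, c(0, 1000), dp), "NONE")
  only_left <- data.frame(t_ms = 1:50, unit = rep(10, 50))
  expect_identical(dominance(only_left, c(0, 1000), dp), "LEFT_SUBPOP")
  # 52 vs 48 is inside the default 5% band; 60 vs 40 is outside
  near <- data.frame(t_ms = 1:100, unit = c(rep(10, 52), rep(300, 48)))
  expect_identical(dominance(near, c(0, 1000), dp), "NONE")
  clear <- data.frame(t_ms = 1:100, unit = c(rep(10, 60), rep(300, 40)))
  expect_identical(dominance(clear, c(0, 1000), dp), "LEFT_SUBPOP")
  expect_identical(dominance(near[0, ], c(0, 1000), dp), "NONE")
  expect_error(dominance(near, c(5, 5), dp), "window")
})

test_that("bump centre is the circular mean of spiking indices", {
  at <- function(units) data.frame(t_ms = seq_along(units), unit = units)
  expect_equal(bump_center(at(rep(125, 30)), c(0, 100)), 125)
  expect_equal(bump_center(at(rep(c(120, 130), 15)), c(0, 100)), 125)
  # wrap-around: units 499 and 3 average to ring position 1
  expect_equal(bump_center(at(rep(c(499, 3), 10)), c(0, 100)), 1,
               tolerance = 1e-9)
  expect_error(bump_center(at(125)[0, ], c(0, 100)), "no spikes")
})
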