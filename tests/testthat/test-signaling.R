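p <- default_params("small")
sg <- p$signaling

test_that("ROS field: baseline fixed point, uniform-emission steady state,
           and monotone decay of a point source with distance", {
  g <- build_lattice(c(5, 1, 1), c(5, 1, 1))
  ros <- rep(sg$ros_base, 5)
  em_base <- rep(sg$k_scav * sg$ros_base, 5)
  # baseline emission keeps the field at baseline
  r1 <- ros_field_step(g, ros, em_base, sg, dt = 1)
  expect_equal(r1, ros)
  # uniform elevated emission settles at emission / scavenging
  em <- rep(4 * sg$k_scav * sg$ros_base, 5)
  r <- ros
  for (i in 1:200000) r <- ros_field_step(g, r, em, sg, dt = 5)
  expect_equal(r, rep(4 * sg$ros_base, 5), tolerance = 1e-6)
  # single emitting site: profile decreases with distance from the source
  em2 <- c(10 * sg$k_scav, rep(0, 4))
  r <- rep(0, 5)
  for (i in 1:200000) r <- ros_field_step(g, r, em2, sg, dt = 5)
  expect_true(all(diff(r) < 0))
})

test_that("CaMKII activation decays to its floor without drive and rises
           monotonically after a ROS step", {
  a <- sg$camkii_rest
  for (i in 1:5000) a <- a + 1000 * camkii_derivative(sg, a, 0, 0)
  expect_lt(a, sg$camkii_rest / 10)
  # step increase in ROS: activation increases monotonically (tracked over
  # the growth phase, before logistic saturation flattens the curve)
  a <- sg$camkii_rest; as <- a
  for (i in 1:200) {
    a <- a + 100 * camkii_derivative(sg, a, 0.3, 2)
    as <- c(as, a)
  }
  expect_true(all(diff(as) > 0))
})

test_that("clamped inputs drive CaMKII to the fixed point of its update law", {
  # long integration approaches the root of da/dt = 0 computed independently
  ca <- 0.3; ros <- 2
  a <- sg$camkii_rest
  for (i in 1:60000) {
    a <- a + 5000 * camkii_derivative(sg, a, ca, ros)
    a <- min(max(a, 0), sg$camkii_amax)
  }
  fp <- uniroot(function(x) camkii_derivative(sg, x, ca, ros),
                c(1e-6, sg$camkii_amax - 1e-9), tol = 1e-12)$root
  expect_equal(a, fp, tolerance = 1e-3)
})

test_that("ATP pool: fixed point at full production, monotone decay at zero
           production, increasing quasi-steady level in producing fraction", {
  expect_equal(atp_derivative(sg, sg$atp_max, 1), 0)
  atp <- sg$atp_rest
  vals <- atp
  for (i in 1:100) {
    atp <- atp + 1000 * atp_derivative(sg, atp, 0)
    vals <- c(vals, atp)
  }
  expect_true(all(diff(vals) < 0))
  targets <- vapply(seq(0, 1, 0.1), function(f) {
    a <- 5
    for (i in 1:5000) a <- a + 5000 * atp_derivative(sg, a, f)
    a
  }, 1)
  expect_true(all(diff(targets) >= -1e-9))
  expect_error(atp_derivative(sg, 5, 1.2), "\\[0,1\\]")
})

test_that("fast-forward slow integration reproduces closed-form exponential
           ATP relaxation", {
  drives <- list(ca_cyt = 0.25, ros_cyt = sg$ros_base, fraction_producing = 0.7)
  ff <- fast_forward_slow(p, drives, duration_s = 100, dt_s = 0.01)
  target <- max(sg$atp_min, sg$atp_max - sg$atp_drop * 0.3^sg$atp_pow)
  tau_s <- sg$tau_atp / 1000
  expect_equal(ff$atp[nrow(ff)],
               target + (sg$atp_rest - target) * exp(-100 / tau_s),
               tolerance = 1e-3)
  expect_equal(ff$adp, sg$atp_pool - ff$atp)
})

test_that("clamp validation: unknown targets, out-of-range values and
           conflicting clamps are rejected; idempotent application", {
  expect_error(validate_clamps(list(list(target = "bogus", value = 1))),
               "unknown clamp target")
  expect_error(validate_clamps(list(list(target = "camkii_act", value = 2))),
               "outside physical range")
  expect_error(validate_clamps(list(list(target = "ros_cyt", value = 0.1),
                                    list(target = "ros_cyt", value = 0.2))),
               "conflicting")
  st <- list(ros = c(0.5, 0.7), camkii_act = 0.1, atp = 5,
             ca_m = c(0.3, 0.4), ca_i = c(0.2, 0.2), mptp_state = c(2L, 1L))
  cl <- list(list(target = "ros_cyt", value = 0.1),
             list(target = "mptp_closed"))
  st1 <- apply_clamps(st, cl, t = 10)
  st2 <- apply_clamps(st1, cl, t = 10)
  expect_identical(st1, st2)
  expect_equal(st1$ros, c(0.1, 0.1))
  expect_equal(st1$mptp_state, c(0L, 0L))
  # before start_time the clamp is inert
  cl2 <- list(list(target = "atp_cyt", value = 2, start_time = 100))
  expect_equal(apply_clamps(st, cl2, t = 50)$atp, 5)
  expect_equal(apply_clamps(st, cl2, t = 150)$atp, 2)
})

test_that("an empty clamp list reproduces the unclamped trajectory bit for
           bit at equal seed", {
  prm <- small_params()
  pr1 <- protocol_spec(pcl = 400, duration = 1500)
  pr2 <- protocol_spec(pcl = 400, duration = 1500, clamps = list())
  r1 <- run_simulation(prm, pr1, seed = 11)
  r2 <- run_simulation(prm, pr2, seed = 11)
  expect_identical(r1$trace, r2$trace)
})

test_that("a ROS clamp pins measured ROS exactly from its start time on", {
  prm <- small_params()
  pr <- protocol_spec(pcl = 400, duration = 2000, alpha_mptp = 60,
                      clamps = list(list(target = "ros_cyt", value = 0.1,
                                         start_time = 500)))
  r <- run_simulation(prm, pr, seed = 5)
  after <- r$trace$ros[r$trace$t > 500.5]
  expect_true(all(after == 0.1))
})
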