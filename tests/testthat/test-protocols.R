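test_that("alternans amplitude on synthetic traces follows its definition", {
  pcl <- 500
  tt <- seq(0, 5 * pcl - 1)
  # constant peaks: amplitude 0
  ca <- 0.1 + 0.9 * exp(-((tt %% pcl) - 50)^2 / 200)
  a <- alternans_amplitude(data.frame(t = tt, ca_i = ca), pcl)
  expect_equal(a$amplitude, 0, tolerance = 1e-9)
  expect_false(a$alternating)
  expect_length(a$peaks, 5)
  # alternating 1.0 / 0.6 peaks: amplitude 0.4
  amp_beat <- ifelse((tt %/% pcl) %% 2 == 0, 0.9, 0.5)
  ca2 <- 0.1 + amp_beat * exp(-((tt %% pcl) - 50)^2 / 200)
  a2 <- alternans_amplitude(data.frame(t = tt, ca_i = ca2), pcl)
  expect_equal(a2$amplitude, 0.4, tolerance = 1e-9)
  expect_true(a2$alternating)
  expect_error(alternans_amplitude(data.frame(t = 1:600, ca_i = rnorm(600)),
                                   500), "3 beats")
})

test_that("amplitude estimator is invariant to time rescaling and baseline
           shifts below peak height", {
  pcl <- 400
  tt <- seq(0, 4 * pcl - 1)
  amp_beat <- ifelse((tt %/% pcl) %% 2 == 0, 1.0, 0.7)
  ca <- 0.1 + amp_beat * exp(-((tt %% pcl) - 40)^2 / 150)
  a0 <- alternans_amplitude(data.frame(t = tt, ca_i = ca), pcl)$amplitude
  # uniform time rescaling (halved sampling interval, doubled PCL axis)
  a1 <- alternans_amplitude(data.frame(t = 2 * tt, ca_i = ca), 2 * pcl)$amplitude
  expect_equal(a1, a0)
  # additive baseline shift
  a2 <- alternans_amplitude(data.frame(t = tt, ca_i = ca + 0.05), pcl)$amplitude
  expect_equal(a2, a0, tolerance = 1e-12)
})

test_that("missed beats are excluded with a warning", {
  pcl <- 500
  tt <- seq(0, 4 * pcl - 1)
  ca <- 0.1 + 0.9 * exp(-((tt %% pcl) - 50)^2 / 200)
  ca[tt >= pcl & tt < 2 * pcl] <- 0.1   # flat beat
  expect_warning(a <- alternans_amplitude(data.frame(t = tt, ca_i = ca), pcl),
                 "excluded")
  expect_equal(a$missed_beats, 1L)
  expect_length(a$peaks, 3)
})

test_that("onset PCL picks the longest alternating PCL and handles the
           no-alternans case", {
  curve <- data.frame(pcl = c(600, 550, 500), amplitude = c(0, 0.15, 0.2))
  expect_equal(onset_pcl(curve, 0.01), 550)
  none <- data.frame(pcl = c(600, 550, 500), amplitude = c(0, 0, 0))
  expect_true(is.na(onset_pcl(none, 0.01)))
  holey <- data.frame(pcl = c(600, 550, 500, 450),
                      amplitude = c(0, 0.2, 0.001, 0.3))
  expect_warning(o <- onset_pcl(holey, 0.01), "non-monotone")
  expect_equal(o, 550)
})

test_that("terminal mPTP open fraction averages the end window and is zero
           for closed-commanded runs", {
  tr <- data.frame(t = 0:5000, p_mptp = c(rep(0.1, 3001), rep(0.4, 2000)))
  expect_equal(measure_mptp_open_fraction(tr, window = 2000), 0.4)
  prm <- small_params()
  pr <- protocol_spec(pcl = 500, duration = 3000, alpha_mptp = 80,
                      clamps = list(list(target = "mptp_closed")))
  r <- run_simulation(prm, pr, seed = 1)
  expect_equal(measure_mptp_open_fraction(r$trace, 1000), 0)
})

test_that("a 1x1 scan row equals a direct run plus the alternans estimator", {
  prm <- small_params()
  pr <- protocol_spec(pcl = 400, duration = 2000)
  sc <- run_scan(prm, axes = list(alpha_mptp = 60), protocol = pr, seed = 2)
  expect_equal(nrow(sc), 1)
  pr60 <- protocol_spec(pcl = 400, duration = 2000, alpha_mptp = 60)
  direct <- run_simulation(prm, pr60, seed = sc$seed[1])
  alt <- suppressWarnings(alternans_amplitude(direct$trace, 400,
                                              prm$analysis$alternans_threshold))
  expect_equal(sc$amplitude[1], alt$amplitude)
  expect_equal(sc$p_mptp[1], measure_mptp_open_fraction(direct$trace, 2000))
  expect_false(sc$failed[1])
})

test_that("scan results are invariant to axis iteration order", {
  prm <- small_params()
  pr <- protocol_spec(pcl = 400, duration = 1700)
  s1 <- run_scan(prm, axes = list(alpha_mptp = c(1, 60)), protocol = pr, seed = 3)
  s2 <- run_scan(prm, axes = list(alpha_mptp = c(60, 1)), protocol = pr, seed = 3)
  s2s <- s2[order(s2$alpha_mptp), ]
  s1s <- s1[order(s1$alpha_mptp), ]
  rownames(s1s) <- rownames(s2s) <- NULL
  expect_equal(s1s, s2s)
})

test_that("write_outputs produces a CSV with a unit-bearing header, echoes
           the configuration, and an empty table gives a header-only file", {
  prm <- small_params()
  tmp <- tempfile(fileext = ".csv")
  tr <- data.frame(t = c(0, 1), ca_i = c(0.1, 0.2))
  write_outputs(tr, tmp, params = prm)
  lines <- readLines(tmp)
  expect_equal(lines[1], "t[ms],ca_i[uM]")
  expect_equal(length(lines), 3)
  expect_true(file.exists(paste0(tmp, ".config.yaml")))
  cfg <- read_config(paste0(tmp, ".config.yaml"))
  expect_equal(cfg$mptp$alpha0, prm$mptp$alpha0)
  tmp2 <- tempfile(fileext = ".csv")
  write_outputs(tr[0, ], tmp2)
  expect_equal(length(readLines(tmp2)), 1)
})

test_that("configuration round-trips through YAML and overrides merge
           recursively", {
  prm <- default_params("reduced")
  tmp <- tempfile(fileext = ".yaml")
  write_config(prm, tmp)
  back <- read_config(tmp)
  expect_equal(back$serca, prm$serca)
  expect_equal(back$geometry$cru_dims, prm$geometry$cru_dims)
  p2 <- modify_params(prm, list(mptp = list(alpha_mptp = 60)))
  expect_equal(p2$mptp$alpha_mptp, 60)
  expect_equal(p2$mptp$alpha0, prm$mptp$alpha0)
  expect_equal(p2$serca, prm$serca)
})
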