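make_trace <- function(time = 0:1000,
                       o2 = 180 - 0.01 * (0:1000),
                       events = data.frame(time_s = c(300, 600, 900),
                                           label = c("PM", "D", "G")),
                       amount = 4, group = "benign") {
  RespirometryTrace("s1", group, 1, time = time, o2 = o2, events = events,
                    chamberVolumeMl = 2, amount = amount)
}

test_that("trace validation rejects malformed objects", {
  expect_error(make_trace(time = c(0, 1, 1, 2), o2 = rep(180, 4)),
               "strictly increasing")
  expect_error(make_trace(o2 = c(rep(180, 1000), Inf)), "finite")
  expect_error(make_trace(events = data.frame(time_s = 10, label = "XYZ")),
               "unknown event label")
  expect_error(RespirometryTrace("s1", "elsewhere", 1, time = 0:9,
                                 o2 = rep(180, 10),
                                 events = data.frame(time_s = numeric(),
                                                     label = character()),
                                 amount = 4),
               "group")
})

test_that("trace CSV round-trips through write/parse", {
  tr <- simulateRespirometry(fast_config(), "CI_CII", seed = 2)[[1]]
  tf <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".json")
  writeTrace(tr, tf, ef, mf)
  back <- parseTrace(tf, ef, mf)
  expect_equal(back@time, tr@time)
  expect_equal(back@o2, tr@o2, tolerance = 1e-9)
  expect_equal(back@events, tr@events)
  expect_equal(back@amount, tr@amount)
  expect_equal(sampleId(back), sampleId(tr))
  # offending rows are named
  bad <- data.frame(time_s = c(1, 2), label = c("PM", "XYZ"))
  write.csv(bad, ef, row.names = FALSE)
  expect_error(parseTrace(tf, ef, mf), "XYZ.*row 2")
  # duplicate time stamps rejected
  write.csv(tr@events, ef, row.names = FALSE)
  write.csv(data.frame(time_s = c(0, 1, 1), o2_uM = c(180, 179, 178)),
            tf, row.names = FALSE)
  expect_error(parseTrace(tf, ef, mf), "duplicate")
})

test_that("segmentation windows follow discard/window arithmetic", {
  seg <- segmentStates(make_trace(), discard_s = 30, window_s = 60)
  expect_equal(seg$state, c("E", "PM", "PMD", "PMDG"))
  expect_equal(seg$t_start, c(30, 330, 630, 930))
  expect_equal(seg$t_end, c(90, 390, 690, 990))
  expect_false(any(seg$missing))
  # no events: single endogenous segment
  seg0 <- segmentStates(make_trace(events = data.frame(time_s = numeric(),
                                                       label = character())))
  expect_equal(seg0$state, "E")
  # events closer together than the discard: flagged missing, not dropped
  segm <- segmentStates(make_trace(
    events = data.frame(time_s = c(300, 310), label = c("PM", "D"))),
    discard_s = 30, window_s = 60)
  expect_true(segm$missing[segm$state == "PM"])
  expect_equal(nrow(segm), 3)
})

test_that("composite labels accumulate substrates and restart at inhibitors", {
  ev <- data.frame(time_s = seq(300, 2100, by = 300),
                   label = c("PM", "D", "G", "S", "CC", "OMY", "AMA"))
  tr <- make_trace(time = 0:2400, o2 = 180 - 0.01 * (0:2400), events = ev)
  seg <- segmentStates(tr)
  expect_equal(seg$state,
               c("E", "PM", "PMD", "PMDG", "PMDGS", "PMDGSC", "OMY", "AMA"))
  ev2 <- data.frame(time_s = c(300, 600, 900),
                    label = c("OMY", "AMA", "ROT"))
  seg2 <- segmentStates(make_trace(events = ev2))
  expect_equal(seg2$state, c("E", "OMY", "AMA", "AMA_ROT"))
})

test_that("JO2 estimation matches the closed form and the OLS oracle", {
  # slope -0.01 uM/s, 2 ml, 4 mg -> 5 pmol/s/mg
  tr <- make_trace()
  expect_equal(estimateJO2(tr, c(1, 101)), 5, tolerance = 1e-12)
  # constant O2: zero flux
  flat <- make_trace(o2 = rep(150, 1001))
  expect_equal(estimateJO2(flat, c(1, 101)), 0)
  # noisy window equals an independently coded regression oracle
  set.seed(3)
  noisy <- make_trace(o2 = 180 - 0.01 * (0:1000) + rnorm(1001, 0, 0.3))
  idx <- 101:200
  expected <- -ols_slope_oracle(noisy@time[idx], noisy@o2[idx]) * 2 * 1000 / 4
  expect_equal(estimateJO2(noisy, c(101, 200)), expected, tolerance = 1e-9)
  expect_error(estimateJO2(tr, c(1, 2)), "3 points")
})

test_that("JO2 is invariant to the sampling interval for noiseless traces", {
  for (dt in c(1, 2, 5)) {
    tt <- seq(0, 1000, by = dt)
    tr <- make_trace(time = tt, o2 = 180 - 0.02 * tt,
                     events = data.frame(time_s = numeric(),
                                         label = character()))
    seg <- segmentStates(tr)
    expect_equal(estimateJO2(tr, c(seg$i_start, seg$i_end)), 10,
                 tolerance = 1e-9)
  }
})

test_that("state tables pool technical replicates by arithmetic mean", {
  mk <- function(slope, rep_id) {
    tr <- make_trace(o2 = 180 - slope * (0:1000))
    tr@replicateId <- rep_id
    tr
  }
  # slopes chosen so replicate JO2 are 90 and 110 -> biological 100
  tab <- buildStateTable(list(mk(90 * 4 / 2000, 1L), mk(110 * 4 / 2000, 2L)))
  expect_equal(tab$jo2[tab$state == "E"], 100, tolerance = 1e-9)
  expect_true(all(tab$n_replicates == 2))
  # a single replicate passes through with a warning
  expect_warning(single <- buildStateTable(list(mk(0.2, 1L))),
                 "single technical replicate")
  expect_true(all(single$n_replicates == 1))
  # mixed protocols are rejected
  other <- make_trace(events = data.frame(time_s = 300, label = "PC"))
  expect_error(buildStateTable(list(mk(0.2, 1L), other)), "mix protocols")
})

test_that("ladder is monotone under the default generator and drops after OMY", {
  tab <- buildStateTable(
    simulateRespirometry(generatorConfig(), "CI_CII_coupling", seed = 21))
  ladder <- c("E", "PM", "PMD", "PMDG", "PMDGS")
  for (sid in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == sid, ]
    j <- sub$jo2[match(ladder, sub$state)]
    expect_true(all(diff(j) > -0.5))  # non-decreasing up to trace noise
    jomy <- sub$jo2[sub$state == "OMY"]
    expect_lt(jomy, j[5])
  }
})

test_that("coupling metrics recover the generator's coupling fractions", {
  # exact arithmetic on a hand-built table
  st <- data.frame(sample_id = "s", group = "tumor",
                   state = c("PMDGS", "OMY", "AMA_ROT"),
                   jo2 = c(100, 20, 2))
  cm <- couplingMetrics(st)
  expect_equal(cm$omy_inhibition_pct, 80)
  expect_equal(cm$residual_pct, 2)
  # cytochrome c with no response: 0%
  st2 <- rbind(st, data.frame(sample_id = "s", group = "tumor",
                              state = "PMDGSC", jo2 = 100))
  st2$jo2[st2$state == "PMDGS"] <- 100
  expect_equal(couplingMetrics(st2)$cc_response_pct, 0)
  expect_error(couplingMetrics(st[st$state != "OMY", ]), "PMDGS and OMY")
  expect_error(couplingMetrics(transform(st, jo2 = c(-1, 2, 3))), "positive")
  # parameter recovery on simulated cohorts
  cfg <- generatorConfig(
    benign = groupConfig(n_samples = 20, coupling_fraction = 0.55),
    tumor = groupConfig(n_samples = 20, coupling_fraction = 0.80,
                        true_jo2 = c(E = 7, PM = 10.5, PMD = 21, PMDG = 28,
                                     PMDGS = 35, M = 8.4, MPC = 14,
                                     MPCD = 21),
                        amount = 3.5))
  cm2 <- couplingMetrics(buildStateTable(
    simulateRespirometry(cfg, "CI_CII_coupling", seed = 13)))
  med <- tapply(cm2$omy_inhibition_pct, cm2$group, median)
  expect_lt(abs(med[["benign"]] - 55), 3)
  expect_lt(abs(med[["tumor"]] - 80), 3)
})
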