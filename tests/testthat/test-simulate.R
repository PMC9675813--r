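test_that("step classification covers the four cases and aborts on subset violation", {
  expect_identical(classify_step(c(1, 1, 0), c(1, 1, 0)), "A")
  expect_identical(classify_step(c(1, 1, 0), c(1, 0, 0)), "B")
  expect_identical(classify_step(c(1, 0, 0), c(0, 0, 0)), "C")
  expect_identical(classify_step(c(0, 0, 0), c(0, 0, 0)), "D")
  expect_error(classify_step(c(1, 0), c(1, 0, 0)), "length")
  expect_error(classify_step(c(0, 1, 0), c(0, 1, 1)), "subset")
  # total and exclusive over all healthy/defect output pairs of width 3
  for (h in 0:7) {
    for (f in 0:7) {
      hb <- as.integer(intToBits(h)[1:3]); fb <- as.integer(intToBits(f)[1:3])
      if (any(fb > hb)) next
      expect_true(classify_step(hb, fb) %in% c("A", "B", "C", "D"))
    }
  }
})

test_that("time series without defects only show cases A and D with equal strengths", {
  net <- build_lattice(10, 8, a = 0.5, b = 0.5, seed = 1)
  env <- init_inputs(10, 0.5, seed = 2)
  ts <- run_timeseries(net, NULL, env, 300)
  expect_identical(nrow(ts$records), 300L)
  expect_true(all(ts$records$case %in% c("A", "D")))
  expect_identical(ts$records$healthy_strength, ts$records$defect_strength)
})

test_that("time series are deterministic and respect the strength ordering", {
  net <- build_lattice(12, 12, a = 0.45, b = 0.6, seed = 3)
  ds <- place_defects(net, 5, 0.8, seed = 4)
  env <- init_inputs(12, 0.6, seed = 5)
  ts1 <- run_timeseries(net, ds, env, 400)
  ts2 <- run_timeseries(net, ds, env, 400)
  expect_identical(ts1$records, ts2$records)
  expect_true(all(ts1$records$defect_strength <= ts1$records$healthy_strength))
  # case is consistent with the recorded strengths
  r <- ts1$records
  expect_true(all((r$case == "D") == (r$healthy_strength == 0)))
  expect_true(all(r$defect_strength[r$case == "C"] == 0))
  expect_true(all(r$defect_strength[r$case == "B"] >= 1))
})

test_that("run categories follow the case-set taxonomy and are order-invariant", {
  expect_identical(classify_run(c("A", "A", "A")), "A")
  expect_identical(classify_run(c("A", "B", "A")), "B")
  expect_identical(classify_run(c("C", "C")), "C")
  expect_identical(classify_run(c("A", "B", "C")), "Cx")
  expect_identical(classify_run(c("D", "C", "B", "A")), "Dx")
  expect_identical(classify_run(c("D", "A", "B")), "D") # no C: not Dx
  expect_identical(classify_run(c("A", "C")), "C")      # no B: not Cx
  expect_error(classify_run(character(0)), "empty")
  set.seed(1)
  for (r in 1:50) {
    cases <- sample(c("A", "B", "C", "D"), sample(1:12, 1), replace = TRUE)
    expect_identical(classify_run(cases), classify_run(sample(cases)))
  }
})

test_that("episode extraction run-length encodes B and A stretches", {
  ep <- episode_distributions(c("A", "A", "B", "B", "B", "A"))
  expect_identical(sort(ep$symptomatic_lengths), 3L)
  expect_identical(sort(ep$asymptomatic_lengths), c(1L, 2L))
  ep2 <- episode_distributions(c("A", "A", "A", "A"))
  expect_length(ep2$symptomatic_lengths, 0)
  expect_identical(ep2$asymptomatic_lengths, 4L)
  # bookkeeping invariant on random sequences: episodes + lethal steps = length
  set.seed(2)
  for (r in 1:50) {
    cases <- sample(c("A", "B", "C", "D"), sample(1:200, 1), replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    ep <- episode_distributions(cases)
    expect_identical(
      sum(ep$symptomatic_lengths) + sum(ep$asymptomatic_lengths) +
        ep$n_lethal_disease + ep$n_lethal_environment,
      length(cases))
  }
})

test_that("episode lengths of an i.i.d. case process are geometric", {
  p <- 0.6 # P(B); episodes of B then have mean length 1/(1-p)
  set.seed(3)
  cases <- ifelse(runif(40000) < p, "B", "A")
  ep <- episode_distributions(cases)
  lens <- ep$symptomatic_lengths
  expected_mean <- 1 / (1 - p)
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected_mean), 4 * se)
})

test_that("chronicity metrics separate the chronic and acute signatures", {
  chronic <- chronicity_metrics(rep("B", 50))
  expect_equal(chronic$b_fraction, 1.0)
  expect_equal(chronic$ab_switch_rate, 0.0)
  acute <- chronicity_metrics(rep(c("A", "B"), 25))
  expect_equal(acute$b_fraction, 0.5)
  expect_equal(acute$ab_switch_rate, 1.0)
  expect_equal(chronicity_metrics("B")$ab_switch_rate, 0)
  # direct counting oracle on random sequences
  set.seed(4)
  for (r in 1:30) {
    cases <- sample(c("A", "B", "C", "D"), sample(2:100, 1), replace = TRUE)
    m <- chronicity_metrics(cases)
    nb <- 0L; nsw <- 0L
    for (i in seq_along(cases)) {
      if (cases[i] == "B") nb <- nb + 1L
      if (i > 1 && ((cases[i - 1] == "A" && cases[i] == "B") ||
                    (cases[i - 1] == "B" && cases[i] == "A"))) nsw <- nsw + 1L
    }
    expect_equal(m$b_fraction, nb / length(cases))
    expect_equal(m$ab_switch_rate, nsw / (length(cases) - 1))
  }
})

test_that("sweeps report category fractions that partition the replicates", {
  cfg <- default_config(H = 8, L = 8, b = 0.5, D = 3, d = 1, steps = 60,
                        replicates = 8, seed = 11)
  sw <- sweep_input_activity(cfg, c(0.3, 0.6, 0.9))
  expect_identical(nrow(sw), 3L)
  fr <- as.matrix(sw[, c("A", "B", "C", "Cx", "D", "Dx")])
  expect_equal(unname(rowSums(fr)), rep(1, 3))
  # one replicate: a single category carries fraction 1
  sw1 <- sweep_input_activity(cfg, 0.5, replicates = 1)
  expect_identical(nrow(sw1), 1L)
  expect_equal(sum(sw1[, c("A", "B", "C", "Cx", "D", "Dx")] == 1), 1)

  swa <- sweep_gate_ratio(cfg, c(0.2, 0.8), replicates = 6)
  expect_equal(unname(rowSums(as.matrix(swa[, c("A", "B", "C", "Cx", "D", "Dx")]))),
               rep(1, 2))
  expect_true(all(swa$dominant %in% c("A", "B", "C", "Cx", "D", "Dx")))
})

test_that("location sweep bins lambda per replicate and flags empty bins", {
  cfg <- default_config(H = 8, L = 10, b = 0.5, D = 1, d = 1, steps = 40,
                        replicates = 20, seed = 12)
  sw <- sweep_location(cfg, replicates = 20, a_grid = 0.3, b_grid = 0.5,
                       lambda_bins = 5)
  expect_identical(nrow(sw), 5L)
  expect_identical(sum(sw$n), 20L)
  populated <- sw$n > 0
  fr <- as.matrix(sw[, c("A", "B", "C", "Cx", "D", "Dx")])
  expect_equal(unname(rowSums(fr[populated, , drop = FALSE])),
               rep(1, sum(populated)))
  expect_true(all(is.na(fr[!populated, ])))
})

test_that("transition estimation returns the bracketing midpoint or errors", {
  tab <- data.frame(a = seq(0, 1, 0.1),
                    dominant = c(rep("A", 5), rep("D", 6)))
  expect_equal(estimate_transition(tab), 0.45)
  tab2 <- data.frame(a = seq(0, 1, 0.1),
                     dominant = c(rep("A", 4), "B", "Cx", rep("Dx", 5)))
  expect_equal(estimate_transition(tab2), 0.55)
  # dominant A up to 0.4 and D from 0.6 on a 0.1-step grid brackets 0.5
  tab3 <- data.frame(a = seq(0, 1, 0.1),
                     dominant = c(rep("A", 5), "C", rep("D", 5)))
  expect_equal(estimate_transition(tab3), 0.5)
  expect_error(estimate_transition(data.frame(a = seq(0, 1, 0.1),
                                              dominant = rep("A", 11))),
               "no transition")
  expect_error(estimate_transition(data.frame(a = c(0.2, 0.8),
                                              dominant = c("D", "A"))),
               "no transition")
})
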