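test_that("network sampling is deterministic, typed, and subcritical", {
  net <- sample_network(12, seed = 7)
  net2 <- sample_network(12, seed = 7)
  expect_identical(net$cell_type, net2$cell_type)
  expect_identical(net$w, net2$w)
  expect_true(all(net$cell_type %in% names(type_proportions_default())))
  expect_equal(unname(diag(net$w)), rep(0, 12))
  rho <- max(Mod(eigen(net$w, only.values = TRUE)$values))
  expect_lte(rho, 0.6 + 1e-9)
  # the raw preset exceeds the cap at this size, so rescaling must engage
  raw <- sample_network(12, seed = 7, max_spectral_radius = Inf)
  rho_raw <- max(Mod(eigen(raw$w, only.values = TRUE)$values))
  expect_gt(rho_raw, 0.6)
  expect_equal(net$w, raw$w * (0.6 / rho_raw))
  expect_error(sample_network(5, type_proportions = c(DGC = 0.5, CA1 = 0.4)),
               "sum to 1")
})

test_that("the weight preset elevates the native hippocampal axis", {
  rules <- hippocampal_weight_rules()
  pick <- function(s, t) rules$weight[rules$source_type == s &
                                      rules$target_type == t]
  expect_equal(pick("DGC", "CA3"), 0.25)
  expect_equal(pick("CA3", "CA1"), 0.25)
  expect_equal(pick("CA1", "CA1"), 0.25)
  expect_equal(pick("CA3", "DGC"), 0.08)
  expect_equal(pick("inhibitory", "DGC"), 0.08)
  expect_equal(nrow(rules), 16)
})

test_that("simulated trains respect epochs, refractory period and seeds", {
  net <- sample_network(8, seed = 3)
  cfg <- sim_config()
  sim <- simulate_spike_trains(net, cfg, seed = 11)
  expect_length(sim$trains, 8)
  for (tr in sim$trains) {
    for (e in seq_along(tr$times)) {
      t <- tr$times[[e]]
      expect_true(all(t >= 0 & t < 10000))
      if (length(t) > 1) expect_true(all(diff(t) >= 6))
    }
  }
  sim2 <- simulate_spike_trains(net, cfg, seed = 11)
  expect_identical(sim$ground_truth, sim2$ground_truth)
  sim3 <- simulate_spike_trains(net, cfg, seed = 12)
  expect_false(identical(sim$ground_truth$time_ms, sim3$ground_truth$time_ms))
  # triggered spikes carry their parent and a lag inside the support
  gt <- sim$ground_truth
  trig <- gt[!is.na(gt$parent_neuron), ]
  expect_gt(nrow(trig), 0)
  expect_true(all(trig$lag_ms >= 8 & trig$lag_ms <= 14))
  expect_equal(trig$time_ms, trig$parent_time_ms + trig$lag_ms)
})

test_that("a supercritical weight matrix is refused", {
  net <- list(cell_type = c("CA3", "CA3"),
              w = matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(simulate_spike_trains(net, sim_config()),
               "unstable weight matrix")
})

test_that("isolated neurons fire at their disinhibited Poisson rate", {
  # single CA3 neuron, no interneuron: rate 1.1 * 2.5 Hz
  net <- list(cell_type = "CA3", w = matrix(0, 1, 1))
  counts <- vapply(1:100, function(i) {
    n_spikes(simulate_spike_trains(net, sim_config(), seed = i)$trains[[1]])
  }, 1L)
  lambda <- 1.1 * 2.5 * 60                 # spikes per 6 x 10 s recording
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # with an interneuron present the excitatory rate is not boosted
  net2 <- list(cell_type = c("CA3", "inhibitory"), w = matrix(0, 2, 2))
  c2 <- vapply(1:100, function(i) {
    n_spikes(simulate_spike_trains(net2, sim_config(), seed = 200 + i)$trains[[1]])
  }, 1L)
  lambda2 <- 1.1 * 60
  expect_lt(abs(mean(c2) - lambda2), 3 * sqrt(lambda2 / 100))
})

test_that("observed rates follow the branching-process law (I - w')^-1 l", {
  # 3 neurons in a chain with known weights; expected rates solve the
  # first-moment equation of the subcritical branching process
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.5; w[2, 3] <- 0.4; w[3, 1] <- 0.2
  net <- list(cell_type = c("CA3", "CA1", "DGC"), w = w)
  cfg <- sim_config(refractory_ms = 0)     # the law ignores the refractory
  lam <- cfg$base_rates_hz[net$cell_type] * cfg$disinhibition_factor
  expected <- solve(diag(3) - t(w), as.numeric(lam))
  nrep <- 60
  obs <- matrix(0, nrep, 3)
  for (i in seq_len(nrep)) {
    sim <- simulate_spike_trains(net, cfg, seed = 5000 + i)
    obs[i, ] <- vapply(sim$trains, average_frequency, 1)
  }
  for (j in 1:3) {
    se <- sd(obs[, j]) / sqrt(nrep)
    expect_lt(abs(mean(obs[, j]) - expected[j]), 3 * se)
  }
})

test_that("rendered traces peak at the amplitude on the spike frame", {
  tr <- spike_train("a", c(100, 500), 1000)
  y <- render_traces(list(tr), amplitude = 0.1, tau_ms = 4, sigma = 0,
                     frame_period_ms = 2)[[1]][[1]]
  expect_length(y, 500)
  expect_equal(y[51], 0.1)                  # frame round(100/2) = 50, 0-based
  expect_equal(y[52], 0.1 * exp(-2 / 4))
  expect_equal(y[50], 0)
  expect_equal(max(y), 0.1)
  expect_error(render_traces(list(tr), amplitude = 0), "> 0")
  # noise is seeded
  a <- render_traces(list(tr), sigma = 0.01, seed = 4)
  b <- render_traces(list(tr), sigma = 0.01, seed = 4)
  expect_identical(a, b)
})

test_that("the rendered movie closes the loop through the pipeline", {
  net <- list(cell_type = c("CA3", "DGC"), w = matrix(0, 2, 2))
  sim <- simulate_spike_trains(net, sim_config(n_epochs = 1,
                                               epoch_duration_ms = 2000),
                               seed = 21)
  dff <- render_traces(sim, sigma = 0, seed = 1)
  out <- render_movie(dff, dim_hw = c(60, 200), seed = 2)
  expect_s3_class(out$movie, "movie_stack")
  expect_length(out$rois$neurons, 2)
  tr <- extract_traces(out$movie, out$rois)
  d <- compute_dff(tr[, 1])
  # extraction + dF/F recovers the rendered trace up to numeric noise
  expect_equal(as.numeric(d), dff[[1]][[1]], tolerance = 1e-8)
  # too many somata for the frame: placement must fail loudly
  expect_error(render_movie(rep(dff, 3), dim_hw = c(40, 60)),
               "non-overlapping")
})

test_that("ground truth round-trips to JSON", {
  net <- sample_network(4, seed = 2)
  sim <- simulate_spike_trains(net, sim_config(n_epochs = 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$cell_type, net$cell_type)
  expect_equal(back$w, net$w, tolerance = 1e-12)
  expect_equal(nrow(back$spikes), nrow(sim$ground_truth))
  expect_equal(back$spikes$time_ms, sim$ground_truth$time_ms,
               tolerance = 1e-9)
})
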