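test_that("XCI worked examples: inclusive window, single credit, asymmetry", {
  # 3 source spikes; two are answered within 8-14 ms, one is not
  a <- spike_train("a", c(100, 500, 900), 1000)
  b <- spike_train("b", c(110, 513, 950), 1000)
  expect_equal(xci(a, b), 2 / 3)
  # bounds are inclusive at both ends
  edges <- spike_train("b2", c(108, 514), 1000)
  expect_equal(xci(spike_train("a2", c(100, 500), 1000), edges), 1)
  just_out <- spike_train("b3", c(107.999, 514.001), 1000)
  expect_equal(xci(spike_train("a3", c(100, 500), 1000), just_out), 0)
  # several target spikes in one window still credit the source spike once
  burst <- spike_train("b4", c(109, 110, 112), 1000)
  expect_equal(xci(spike_train("a4", 100, 1000), burst), 1)
  # direction matters: B's spikes are never followed by A's within the window
  expect_equal(xci(spike_train("a5", 100, 1000),
                   spike_train("b5", 110, 1000)), 1)
  expect_equal(xci(spike_train("b5", 110, 1000),
                   spike_train("a5", 100, 1000)), 0)
})

test_that("XCI agrees exactly with the double-loop oracle", {
  set.seed(51)
  for (i in 1:20) {
    a <- poisson_train(runif(1, 0.5, 5), n_epochs = 3, roi_id = "a")
    b <- poisson_train(runif(1, 0.5, 5), n_epochs = 3, roi_id = "b")
    if (n_spikes(a) == 0) next
    w <- lag_window(8, 14)
    expect_identical(as.numeric(xci(a, b, w)),
                     xci_loop_oracle(a, b, 8, 14))
    w2 <- lag_window(2, 30)
    expect_identical(as.numeric(xci(a, b, w2)),
                     xci_loop_oracle(a, b, 2, 30))
  }
})

test_that("XCI is bounded, monotone in the window, and epoch-local", {
  set.seed(52)
  for (i in 1:10) {
    a <- poisson_train(3, n_epochs = 2, roi_id = "a")
    b <- poisson_train(3, n_epochs = 2, roi_id = "b")
    if (n_spikes(a) == 0) next
    v1 <- xci(a, b, lag_window(8, 14))
    v2 <- xci(a, b, lag_window(8, 30))   # widened window can only gain hits
    v3 <- xci(a, b, lag_window(1, 50))
    expect_gte(v1, 0); expect_lte(v1, 1)
    expect_lte(v1, v2)
    expect_lte(v2, v3)
  }
  # a target spike early in the next epoch never answers a late source spike
  a <- spike_train("a", list(9995, numeric(0)), c(10000, 10000))
  b <- spike_train("b", list(numeric(0), 5), c(10000, 10000))
  expect_equal(xci(a, b), 0)
})

test_that("an empty source train gives an undefined XCI, never zero", {
  a <- spike_train("a", numeric(0), 10000)
  b <- spike_train("b", c(100, 200), 10000)
  v <- xci(a, b)
  expect_true(is.na(v))
  expect_match(attr(v, "reason"), "empty source")
  expect_error(xci(spike_train("a", 1, 5000), b), "epoch structure")
})

test_that("the XCI matrix is directed with an uncomputed diagonal", {
  set.seed(53)
  trains <- list(
    spike_train("src", c(100, 300, 500), 1000, cell_type = "DGC"),
    spike_train("tgt", c(110, 310, 510), 1000, cell_type = "CA3"),
    spike_train("quiet", numeric(0), 1000, cell_type = "CA1"))
  out <- xci_matrix(trains, island_id = "i1")
  M <- out$matrix
  expect_true(all(is.na(diag(M))))
  expect_equal(M["src", "tgt"], 1)
  expect_equal(M["tgt", "src"], 0)
  expect_true(all(is.na(M["quiet", c("src", "tgt")])))
  expect_equal(M["src", "quiet"], 0)        # defined: source has spikes
  tab <- out$table
  expect_equal(nrow(tab), 6)
  r <- tab[tab$source_roi == "src" & tab$target_roi == "tgt", ]
  expect_equal(r$xci, 1)
  expect_equal(r$source_type, "DGC")
  expect_equal(r$target_type, "CA3")
  expect_false(tab$defined[tab$source_roi == "quiet"][1])
})

test_that("the type-resolved summary pools pairs and keeps empty cells NA", {
  trains <- list(
    spike_train("d1", c(100, 300), 1000, cell_type = "DGC"),
    spike_train("d2", c(105, 700), 1000, cell_type = "DGC"),
    spike_train("c3", c(110, 310), 1000, cell_type = "CA3"),
    spike_train("inh", c(50, 450), 1000, cell_type = "inhibitory"))
  tab <- xci_matrix(trains)$table
  s <- celltype_xci_summary(tab)
  expect_equal(nrow(s), 9)                   # 3 x 3 excitatory grid
  dg_ca3 <- s[s$source_type == "DGC" & s$target_type == "CA3", ]
  expect_equal(dg_ca3$n_pairs, 2)
  # d1 -> c3: both spikes answered at +10 ms; d2 -> c3: neither (lag 5 ms)
  expect_equal(dg_ca3$mean_xci, mean(c(1, 0)))
  ca1 <- s[s$source_type == "CA1" | s$target_type == "CA1", ]
  expect_true(all(ca1$n_pairs == 0))
  expect_true(all(is.na(ca1$mean_xci)))      # absent pairs are NA, not 0
  full <- celltype_xci_summary(tab, excitatory_only = FALSE)
  expect_equal(nrow(full), length(cell_types())^2)
  expect_gt(sum(full$n_pairs), sum(s$n_pairs))
})

test_that("lag histograms count signed lags in 2 ms bins, pooled and folded", {
  a <- spike_train("a", c(100, 300), 1000)
  b <- spike_train("b", c(111, 309), 1000)
  h <- lag_histogram(list(a, b), max_lag_ms = 50, bin_width_ms = 2)
  expect_equal(h$breaks, seq(-50, 50, by = 2))
  # lags A->B: +11, +9 (and the 200-ms cross terms are outside +-50)
  centers <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  expect_equal(sum(h$pooled), 4)             # both directions pooled
  expect_equal(h$pooled[centers == 11], 1)   # +11 and +9 land in [10,12),[8,10)
  expect_equal(h$pooled[centers == 9], 1)
  expect_equal(h$pooled[centers == -11], 1)  # mirrored by the reverse pair
  expect_equal(h$pooled[centers == -9], 1)
  # pooled signed histogram is symmetric by construction
  expect_equal(h$pooled, rev(h$pooled))
  fc <- (h$folded$breaks[-1] + h$folded$breaks[-length(h$folded$breaks)]) / 2
  expect_equal(sum(h$folded$counts), 4)
  expect_equal(h$folded$counts[fc == 11], 2)
  expect_equal(h$folded$counts[fc == 9], 2)
  # per-pair table reproduces the pooled counts
  expect_equal(sum(h$pairs$count), sum(h$pooled))
})

test_that("coincident firing produces a folded mode at zero lag", {
  set.seed(54)
  base <- seq(100, 9900, length.out = 60)
  trains <- lapply(1:3, function(i) {
    spike_train(paste0("n", i), base + runif(60, 0, 0.9), 10000)
  })
  h <- lag_histogram(trains)
  fc <- (h$folded$breaks[-1] + h$folded$breaks[-length(h$folded$breaks)]) / 2
  expect_equal(fc[which.max(h$folded$counts)], 1)   # [0, 2) bin
})
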