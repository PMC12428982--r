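# small three-well replica for fast bootstrap re-estimation
small_windows <- function(seed, n = 400) {
  plan <- reference_plan()
  sample_windows(paper_surface(), plan$center, plan$force_constant, n,
                 temperature = 300, seed = seed)
}

test_that("zero-variance windows give zero half-widths", {
  plan <- reference_plan()
  ws <- lapply(seq_len(nrow(plan)), function(i)
    umbrella_window(plan$center[i], plan$force_constant[i],
                    rep(plan$center[i], 50)))
  out <- bootstrap_uncertainty(ws, estimator = "wham", n_boot = 20,
                               block_len = 5, seed = 1)
  expect_equal(unname(out$half_widths), c(0, 0))
})

test_that("block_len = 1 matches a hand-rolled naive bootstrap on i.i.d. data", {
  hw_fun <- numeric(10); hw_naive <- numeric(10)
  for (s in 1:10) {
    ws <- small_windows(seed = s)
    out <- bootstrap_uncertainty(ws, estimator = "ui", n_boot = 80,
                                 block_len = 1, seed = 100 + s)
    hw_fun[s] <- out$half_widths[["barrier"]]
    # independent oracle: plain with-replacement resampling + re-estimation
    set.seed(200 + s)
    reps <- replicate(80, {
      wb <- lapply(ws, function(w)
        umbrella_window(w$center, w$force_constant,
                        sample(w$samples, replace = TRUE), w$temperature))
      stationary_points(umbrella_integration(wb))$barrier
    })
    q <- quantile(reps, c(0.15865, 0.84135), names = FALSE)
    hw_naive[s] <- 0.5 * (q[2] - q[1])
  }
  expect_lt(abs(mean(hw_fun) - mean(hw_naive)) / mean(hw_naive), 0.2)
})

test_that("replica-scale barrier half-width is the expected order", {
  # correlated (Langevin) chains at protocol scale: the block bootstrap must
  # report a barrier uncertainty of the same order as the quoted +/- 0.8
  plan <- reference_plan()
  ws <- sample_windows(paper_surface(), plan$center, plan$force_constant,
                       5000, temperature = 300, seed = 77,
                       sampler = "overdamped_langevin")
  out <- bootstrap_uncertainty(ws, estimator = "wham", n_boot = 30, seed = 3)
  expect_true(all(out$block_len > 1))   # autocorrelation detected
  expect_gt(out$half_widths[["barrier"]], 0.1)
  expect_lt(out$half_widths[["barrier"]], 2.0)
})

test_that("bootstrap argument validation", {
  ws <- small_windows(seed = 1, n = 50)
  expect_error(bootstrap_uncertainty(ws, n_boot = 5), ">= 10")
  expect_error(bootstrap_uncertainty(ws, n_boot = 20, block_len = 500),
               "exceeds")
})
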