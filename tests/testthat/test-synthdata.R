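test_that("zero mutation rate gives identical sequences; seeds reproduce", {
  s <- simulate_serial_coalescent(n = 10, Ne = 500, mu = 0, L = 80, seed = 5)
  expect_equal(segregating_sites(s$aln), 0L)
  expect_equal(length(unique(alignment_strings(s$aln))), 1L)

  a <- simulate_serial_coalescent(n = 8, Ne = 300, mu = 1e-5, L = 200, seed = 9)
  b <- simulate_serial_coalescent(n = 8, Ne = 300, mu = 1e-5, L = 200, seed = 9)
  expect_identical(alignment_strings(a$aln), alignment_strings(b$aln))
  expect_identical(a$truth, b$truth)
  c <- simulate_serial_coalescent(n = 8, Ne = 300, mu = 1e-5, L = 200, seed = 10)
  expect_false(identical(alignment_strings(a$aln), alignment_strings(c$aln)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); x1 <- runif(1)
  set.seed(123)
  invisible(simulate_serial_coalescent(n = 5, Ne = 100, mu = 1e-5, L = 50,
                                       seed = 77))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("homochronous simulations are unbiased for theta via both estimators", {
  theta <- 5; n <- 20; L <- 600; Ne <- 500
  mu <- theta / (4 * Ne * L)
  reps <- 200
  K <- numeric(reps); thetaW <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- simulate_serial_coalescent(n = n, Ne = Ne, mu = mu, L = L,
                                    seed = 1000 + i)
    K[i] <- pairwise_K(s$aln)
    thetaW[i] <- watterson_theta(segregating_sites(s$aln), n)
  }
  # mean within Monte-Carlo error (4 standard errors) of the truth
  expect_lt(abs(mean(K) - theta), 4 * stats::sd(K) / sqrt(reps))
  expect_lt(abs(mean(thetaW) - theta), 4 * stats::sd(thetaW) / sqrt(reps))
})

test_that("heterochronous sampling inflates pi by rate x age gap; correction removes it", {
  theta <- 5; n <- 20; L <- 600; Ne <- 500; gen <- 5
  mu <- theta / (4 * Ne * L)            # per site per generation
  ages <- seq(0, 12000, length.out = n) # years BP
  dt <- mean(dist(matrix(ages, ncol = 1), method = "manhattan"))
  rate_per_year <- mu / gen
  expected_inflation_K <- rate_per_year * dt * L
  reps <- 200
  K <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- simulate_serial_coalescent(n = n, ages = ages, Ne = Ne, mu = mu,
                                    L = L, generation_length = gen,
                                    seed = 5000 + i)
    K[i] <- pairwise_K(s$aln)
  }
  se <- stats::sd(K) / sqrt(reps)
  # raw K inflated by about the predicted amount
  expect_lt(abs(mean(K) - (theta + expected_inflation_K)), 4 * se)
  expect_gt(mean(K) - theta, 4 * se)    # inflation clearly detected
  # the correction returns the estimate to theta
  hc <- heterochrony_correction(mean(K) / L, ages,
                                rate_pct_per_myr = rate_per_year * 1e6 * 100,
                                generation_length = gen)
  expect_lt(abs(hc$pi_hmu * L - theta), 4 * se)
})

test_that("panel generator respects plans and validates frequencies", {
  plan <- list(cohort_sizes = c(Prehistoric = 5, Medieval = 14,
                                "Post-Medieval" = 26),
               haplogroup_freqs = c(T3 = 0.6, T3b = 0.4),
               private_rate = 0,
               y1_freq = list(Prehistoric = 0, Medieval = 0,
                              "Post-Medieval" = 1))
  p <- simulate_panel(plan, seed = 3)
  expect_equal(as.integer(table(p$samples$period)[c("Prehistoric", "Medieval",
                                                    "Post-Medieval")]),
               c(5L, 14L, 26L))
  expect_equal(nrow(p$aln$matrix), 45L)
  # private rate 0: classifier recovers labels with zero error
  cls <- batch_classify(p$aln, load_ruleset())
  expect_identical(cls$label, p$truth$haplogroup)
  # y1_freq extremes are honored
  ym <- p$truth[!is.na(p$truth$y_label), ]
  expect_true(all(ym$y_label[ym$period != "Post-Medieval"] == "Y2"))
  expect_true(all(ym$y_label[ym$period == "Post-Medieval"] == "Y1"))

  bad <- plan; bad$haplogroup_freqs <- c(T3 = 0.6, T3b = 0.5)
  expect_error(simulate_panel(bad, seed = 3))
})

test_that("cohort count simulator draws valid reproducible multinomials", {
  tabs <- simulate_cohort_counts(list(c(0.2, 0.8), c(0.5, 0.5)),
                                 sizes = c(30, 50), replicates = 5, seed = 8)
  expect_length(tabs, 5)
  for (m in tabs) {
    expect_equal(unname(rowSums(m)), c(30L, 50L))
    expect_true(all(m >= 0))
  }
  again <- simulate_cohort_counts(list(c(0.2, 0.8), c(0.5, 0.5)),
                                  sizes = c(30, 50), replicates = 5, seed = 8)
  expect_identical(tabs, again)
  # p = 0 category never appears
  z <- simulate_cohort_counts(c(0, 1), sizes = 40, replicates = 3, seed = 2)
  expect_true(all(vapply(z, function(m) m[1, 1] == 0L, TRUE)))
  expect_error(simulate_cohort_counts(c(0.5, 0.4), 10, 1, seed = 1), "sum to 1")
})
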