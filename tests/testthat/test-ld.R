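test_that("pairwise r2 reproduces hand-computed correlations", {
  x <- c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L)
  p <- make_panel(cbind(x, x), pos = c(100L, 200L))
  expect_equal(pairwise_r2(p)$r2, 1)
  y <- c(0L, 0L, 2L, 2L, 0L, 0L, 2L, 2L)
  expect_equal(pairwise_r2(make_panel(cbind(x, y), pos = c(100L, 200L)))$r2, 0)
  z <- c(0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L)
  expect_equal(pairwise_r2(make_panel(cbind(x, z), pos = c(100L, 200L)))$r2,
               0.6, tolerance = 1e-12)
})

test_that("pairwise r2 equals the per-pair correlation oracle", {
  set.seed(23)
  for (rep in 1:3) {
    p <- random_panel(20, 30)
    got <- pairwise_r2(p, max_dist_bp = 1e6)
    want <- r2_oracle(p, max_dist_bp = 1e6)
    got <- got[order(got$dist, got$r2), ]
    want <- want[order(want$dist, want$r2), ]
    expect_equal(got$dist, want$dist)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
  }
})

test_that("r2 is invariant to ref/alt recoding and respects max_dist", {
  set.seed(31)
  p <- random_panel(15, 20)
  q <- p
  q$geno[, 5] <- ifelse(p$geno[, 5] == 0L, 2L,
                        ifelse(p$geno[, 5] == 2L, 0L, p$geno[, 5]))
  a <- pairwise_r2(p); b <- pairwise_r2(q)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  narrow <- pairwise_r2(p, max_dist_bp = 5000)
  expect_true(all(narrow$dist <= 5000))
  # monomorphic sites yield no pair and are tallied
  mono <- make_panel(cbind(c(0L, 0L, 0L), c(0L, 2L, 0L)), pos = c(1e3L, 2e3L))
  out <- pairwise_r2(mono)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("Hill-Weir expectation matches its closed form and monotonicity", {
  expect_equal(hill_weir_r2(0, 10), (10 / 22) * (1 + 36 / 220),
               tolerance = 1e-12)
  # large-C limit is the 1/n sampling floor, and vanishes only as n grows
  expect_equal(hill_weir_r2(1e9, 50), 1 / 50, tolerance = 1e-3)
  expect_lt(hill_weir_r2(1e9, 1e6), 1e-4)
  C <- c(0.1, 1, 10, 100)
  expect_true(all(diff(hill_weir_r2(C, 25)) < 0))    # decreasing in C
  expect_true(all(hill_weir_r2(C, 10) > hill_weir_r2(C, 1000)))  # and in n
  expect_equal(hill_weir_r2(C, 1e6), (10 + C) / ((2 + C) * (11 + C)),
               tolerance = 1e-4)
  expect_error(hill_weir_r2(-1, 10), ">= 0")
})

test_that("noise-free Hill-Weir curves regenerate rho almost exactly", {
  rho <- 1e-5; n <- 50
  d <- round(exp(seq(log(100), log(1e6), length.out = 400)))
  pairs <- data.frame(chrom = "c", dist = d, r2 = hill_weir_r2(rho * d, n))
  fit <- fit_ld_decay(pairs, n = n, use_bins = FALSE)
  expect_equal(fit$rho_per_bp, rho, tolerance = 1e-4)
  expect_true(fit$reached)
  # the fitted curve crosses the baseline where the generating curve does
  expect_equal(hill_weir_r2(rho * fit$decay_distance, n), 0.2,
               tolerance = 1e-3)
})

test_that("noisy curves recover rho within 10% across seeds", {
  rho <- 1e-5; n <- 50
  for (seed in 1:3) {
    set.seed(seed)
    d <- round(runif(5000, 100, 1e6))
    r2 <- pmin(1, pmax(0, hill_weir_r2(rho * d, n) + rnorm(5000, 0, 0.05)))
    fit <- fit_ld_decay(data.frame(chrom = "c", dist = d, r2 = r2), n = n)
    expect_lt(abs(fit$rho_per_bp - rho) / rho, 0.10)
  }
})

test_that("a flat high-LD curve is flagged as not reaching the baseline", {
  d <- round(exp(seq(log(100), log(1e6), length.out = 100)))
  pairs <- data.frame(chrom = "c", dist = d, r2 = rep(0.9, 100))
  fit <- suppressWarnings(fit_ld_decay(pairs, n = 50))
  expect_false(fit$reached)
  expect_true(is.na(fit$decay_distance))
})

test_that("ld_fit behaves like a model object", {
  rho <- 2e-5; n <- 40
  d <- round(exp(seq(log(100), log(1e6), length.out = 300)))
  fit <- fit_ld_decay(data.frame(dist = d, r2 = hill_weir_r2(rho * d, n)),
                      n = n)
  expect_named(coef(fit), "rho_per_bp")
  expect_equal(predict(fit, 1000), hill_weir_r2(fit$rho_per_bp * 1000, n))
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_output(print(fit), "rho")
  expect_output(print(summary(fit)), "decay")
})

test_that("chromosomes simulated with equal rho decay alike; degenerate inputs", {
  cfg <- sim_config(seed = 17, n_pops = 1, n_per_pop = 25, n_chrom = 2,
                    rho_per_bp = 1e-5, n_mislabels = 0, n_duplicates = 0)
  sim <- simulate_panel(cfg)
  tab <- ld_chromosome_summary(sim$panel)
  expect_equal(nrow(tab), 2)
  d <- tab$decay_distance_mb
  expect_true(all(!is.na(d)))
  expect_lt(max(d) / min(d), 3)  # same rho, stochastic fits agree in scale
  # single chromosome: correlation undefined
  one <- subset_sites(sim$panel, which(sim$panel$sites$chrom == "chr01"))
  t1 <- ld_chromosome_summary(one)
  expect_true(is.na(attr(t1, "size_decay_r2")))
  expect_equal(attr(t1, "mean_decay_mb"), t1$decay_distance_mb[1])
})

test_that("size-decay correlation is near zero when rho ignores size", {
  set.seed(29)
  sizes <- seq(2e5, 1e6, length.out = 20)
  decay <- numeric(20)
  for (i in seq_along(sizes)) {
    cfg <- sim_config(seed = 1000 + i, n_pops = 1, n_per_pop = 20,
                      n_chrom = 1, chrom_len_bp = sizes[i],
                      n_sites_per_chrom = 250, rho_per_bp = 1e-5,
                      n_mislabels = 0, n_duplicates = 0)
    sim <- simulate_panel(cfg)
    pr <- pairwise_r2(sim$panel, chrom = "chr01")
    fit <- suppressWarnings(fit_ld_decay(pr, n = 20))
    decay[i] <- fit$decay_distance
  }
  expect_lt(cor(sizes, decay)^2, 0.15)
})
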