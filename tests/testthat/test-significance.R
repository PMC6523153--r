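test_that("window assignment uses half-open megabase intervals", {
  expect_equal(assign_window(2, 162150000), "2_162")
  expect_equal(assign_window(1, 0), "1_0")
  expect_equal(assign_window(1, 1e6), "1_1")         # boundary goes right
  expect_equal(assign_window(1, 1e6 - 1), "1_0")
  expect_error(assign_window(1, -5), "negative")
})

test_that("Bayes factors follow the posterior-to-prior odds ratio", {
  for (pi in c(0.5, 0.9, 0.99, 0.999))
    expect_equal(bayes_factor(1 - pi, pi), 1)        # posterior = prior odds
  expect_equal(bayes_factor(0.5, 0.99), 99)
  expect_equal(bayes_factor(0, 0.99), 0)
  expect_identical(bayes_factor(1, 0.99), Inf)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(bayes_factor(p, 0.99)) > 0))  # strictly increasing
  expect_error(bayes_factor(0.5, 1), "pi")
  expect_error(bayes_factor(1.2, 0.99), "model_freq")
})

test_that("evidence classes use strict thresholds at 3.2 / 20 / 100", {
  bf <- c(0, 3.2, 3.21, 20, 20.5, 100, 101, Inf, 50)
  expect_equal(as.character(classify_evidence(bf)),
               c("none", "none", "suggestive", "suggestive", "strong",
                 "strong", "decisive", "decisive", "strong"))
  expect_error(classify_evidence(-1), "negative")
})

test_that("window variance shares behave on constructed architectures", {
  # all signal in one window -> that window carries 100%
  set.seed(21)
  n <- 200
  G <- matrix(rbinom(n * 20, 2, 0.4), n, 20,
              dimnames = list(NULL, sprintf("S%02d", 1:20)))
  map <- data.frame(marker_id = colnames(G), chrom = 1,
                    pos_bp = c(seq(0, 9) * 1e4, 5e6 + seq(0, 9) * 1e4))
  beta <- c(rnorm(10), rep(0, 10))
  y <- drop(scale(G, scale = FALSE) %*% beta) + rnorm(n, sd = 0.3)
  fit <- run_chain(G, y, cfg = chain_config(pi = 0.5, n_iter = 800,
                                            burn_in = 200, seed = 3))
  wt <- window_variance_table(fit, G, map)
  expect_equal(sort(wt$window_id), c("1_0", "1_5"))
  expect_gt(wt$gv_pct[wt$window_id == "1_0"], 95)

  # two exactly orthogonal windows with equal variance -> 50/50
  set.seed(22)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 10), n, 10))))[, -1] * sqrt(n)
  colnames(X) <- sprintf("S%02d", 1:10)
  map2 <- data.frame(marker_id = colnames(X), chrom = 1,
                     pos_bp = c(seq(0, 4) * 1e4, 5e6 + seq(0, 4) * 1e4))
  beta2 <- rep(0.5, 10)
  y2 <- drop(X %*% beta2) + rnorm(n, sd = 0.5)
  fit2 <- run_chain(X, y2, cfg = chain_config(pi = 0, n_iter = 2000,
                                              burn_in = 500, seed = 4))
  wt2 <- window_variance_table(fit2, X, map2)
  expect_equal(wt2$gv_pct, c(50, 50), tolerance = 0.1)
  # per-sample shares sum to exactly 100% under orthogonality
  shares <- attr(wt2, "share_samples")
  expect_equal(colSums(shares), rep(1, ncol(shares)), tolerance = 1e-9)
})

test_that("informative regions combine the two thresholds with OR", {
  windows <- data.frame(window_id = c("1_0", "1_1", "1_2"),
                        chrom = "1", mb = 0:2,
                        gv_pct = c(1.88, 0.2, 0.4), n_markers = c(2, 1, 1))
  snps <- data.frame(marker_id = c("a", "b", "c", "d"),
                     chrom = 1, pos_bp = c(1e5, 9e5, 1.2e6, 2.3e6),
                     window_id = c("1_0", "1_0", "1_1", "1_2"),
                     effect = c(0.09, 0.01, 0.02, 0.03),
                     model_freq = c(0.75, 0.1, 0.2, 0.4),
                     bf = c(298.75, 11, 2, 66),
                     evidence = classify_evidence(c(298.75, 11, 2, 66)))
  rep1 <- informative_regions(windows, snps, trait = "ADG")
  # 1_0 via gv% AND BF; 1_2 via BF only; 1_1 neither
  expect_setequal(rep1$window_id, c("1_0", "1_2"))
  expect_equal(rep1$marker_id[rep1$window_id == "1_0"], "a")  # top BF member
  expect_equal(rep1$pos_mb[rep1$window_id == "1_0"], 0.1)
  # nothing passes -> empty report with stable columns
  rep0 <- informative_regions(windows, snps, gv_threshold = 10,
                              bf_threshold = 1e4)
  expect_equal(nrow(rep0), 0)
  expect_true(all(c("trait", "window_id", "gv_pct", "bf") %in% names(rep0)))
})

test_that("a planted QTL window is recovered as informative", {
  set.seed(23)
  n <- 300
  G <- matrix(rbinom(n * 30, 2, 0.4), n, 30,
              dimnames = list(NULL, sprintf("S%02d", 1:30)))
  map <- data.frame(marker_id = colnames(G), chrom = 1,
                    pos_bp = seq(0, 29) * 2e5)   # 6 windows of 5 markers
  beta <- rep(0, 30); beta[12] <- 1              # QTL in window 1_2
  y <- drop(scale(G, scale = FALSE) %*% beta) + rnorm(n, sd = 0.8)
  fit <- run_chain(G, y, cfg = chain_config(pi = 0.9, n_iter = 1500,
                                            burn_in = 500, seed = 5))
  snps <- snp_significance(fit, map)
  wt <- window_variance_table(fit, G, map)
  rep <- informative_regions(wt, snps)
  expect_equal(rep$window_id, "1_2")
})
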