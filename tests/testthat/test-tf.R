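toy_pwm <- function(consensus) {
  bases <- c("A", "C", "G", "T")
  M <- matrix(0.05, 4, nchar(consensus), dimnames = list(bases, NULL))
  idx <- match(strsplit(consensus, "")[[1]], bases)
  M[cbind(idx, seq_along(idx))] <- 0.85
  M
}

test_that("TF matching is case-insensitive and deduplicated", {
  nodes <- c("Arid3b", "GCM1", "gli2", "FABP4", "GCM1")
  tfs <- c("ARID3B", "GCM1", "GLI2", "NFYC", "gcm1")
  expect_setequal(match_tfs(nodes, tfs), c("Arid3b", "GCM1", "gli2"))
  expect_length(match_tfs(c("AATF", "PLAT"), tfs), 0)
  expect_error(match_tfs(nodes, character()), "empty")
})

test_that("log-odds scoring applies the pseudocount and monotonicity", {
  # PWM equal to background scores 0 everywhere (pseudocount cancels)
  flat <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(log_odds(flat), matrix(0, 4, 3,
               dimnames = list(c("A", "C", "G", "T"), NULL)), tolerance = 1e-12)
  # single-position point mass: log2((1.01/1.04)/0.25)
  pm <- matrix(c(1, 0, 0, 0), 4, 1)
  S <- log_odds(pm, pseudocount = 0.01)
  expect_equal(unname(S["A", 1]), log2((1.01 / 1.04) / 0.25),
               tolerance = 1e-12)
  expect_lt(S["A", 1], 2)
  expect_gt(S["A", 1], 1.9)
  # monotone in the probability
  probs <- seq(0.1, 0.9, by = 0.2)
  sc <- vapply(probs, function(p) {
    log_odds(matrix(c(p, (1 - p) / 3, (1 - p) / 3, (1 - p) / 3), 4, 1))[1, 1]
  }, numeric(1))
  expect_true(all(diff(sc) > 0))
  expect_error(log_odds(pm, background = c(0.5, 0.5, 0, 0)), "positive")
})

test_that("DP p-values equal exhaustive enumeration for short motifs", {
  set.seed(41)
  for (k in 1:8) {
    L <- sample(2:5, 1)
    M <- matrix(rgamma(4 * L, 1), 4, L)
    M <- sweep(M, 2, colSums(M), "/")
    rownames(M) <- c("A", "C", "G", "T")
    bg <- c(0.3, 0.2, 0.2, 0.3)
    S <- log_odds(M, bg)
    for (thr in quantile(S, c(0.1, 0.5, 0.9)) * L) {
      expect_equal(pwm_pvalue(S, thr, bg), pwm_pvalue_enum(S, thr, bg),
                   tolerance = 1e-12,
                   label = sprintf("L=%d thr=%.3f", L, thr))
    }
  }
  # extremes
  S <- log_odds(toy_pwm("ACGT"))
  expect_equal(pwm_pvalue(S, -100), 1)
  expect_equal(pwm_pvalue(S, 100), 0)
})

test_that("promoter scanning finds planted sites and honours N and p_max", {
  S <- log_odds(toy_pwm("ACGTAC"))
  set.seed(42)
  seq_bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  planted <- paste0(substr(seq_bg, 1, 120), "ACGTAC", substr(seq_bg, 127, 300))
  hits <- scan_promoter(S, planted)
  expect_true(121 %in% hits$start)
  expect_true(all(hits$p <= 0.001))
  expect_equal(nrow(scan_promoter(S, strrep("N", 50))), 0)
  expect_equal(nrow(scan_promoter(S, planted, p_max = 0)), 0)
  expect_equal(nrow(scan_promoter(S, "ACG")), 0)     # shorter than motif
  expect_error(scan_promoter(S, "ACGTXZ"), "outside")
})

test_that("target assignment warns on gaps and is monotone in p_max", {
  pwms <- list(TF1 = toy_pwm("ACGTACGT"), TF2 = toy_pwm("GGGTTTAA"))
  set.seed(43)
  mk_prom <- function(insert = NULL) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    if (!is.null(insert)) substr(s, 200, 199 + nchar(insert)) <- insert
    s
  }
  promoters <- c(g1 = mk_prom("ACGTACGT"), g2 = mk_prom("GGGTTTAA"),
                 g3 = mk_prom())
  mods <- assign_targets(c("TF1", "TF2"), pwms, promoters)
  expect_true("g1" %in% mods$TF1$gene)
  expect_true("g2" %in% mods$TF2$gene)
  expect_warning(assign_targets(c("TF1", "TF3"), pwms, promoters), "TF3")
  expect_warning(assign_targets("TF1", pwms, promoters,
                                genes = c("g1", "gX")), "gX")
  loose <- assign_targets("TF1", pwms, promoters, p_max = 0.05)
  strict <- assign_targets("TF1", pwms, promoters, p_max = 1e-4)
  expect_true(all(strict$TF1$gene %in% loose$TF1$gene))
  none <- assign_targets("TF1", pwms, promoters, p_max = 0)
  expect_equal(nrow(none$TF1), 0)
})

test_that("trio selection is exhaustive-optimal and deterministic on ties", {
  mods <- list(A = c("1", "2", "3"), B = c("3", "4"), C = c("5"), D = c("1"))
  trio <- select_top_trio(mods)
  expect_setequal(trio$tfs, c("A", "B", "C"))
  expect_equal(trio$coverage, 5)
  expect_setequal(trio$targets, as.character(1:5))
  same <- list(Z = c("a", "b"), Y = c("a", "b"), X = c("a", "b"),
               W = c("a", "b"))
  t2 <- select_top_trio(same)
  expect_equal(t2$tfs, c("W", "X", "Y"))       # lexicographic tie-break
  expect_equal(t2$coverage, 2)
  expect_error(select_top_trio(mods[1:2]), "at least 3")
  set.seed(44)
  for (k in 1:20) {
    nt <- sample(4:8, 1)
    sets <- setNames(lapply(seq_len(nt), function(i)
      sample(letters, sample(0:8, 1))), paste0("tf", seq_len(nt)))
    expect_equal(select_top_trio(sets)$coverage, trio_coverage_oracle(sets))
  }
})
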