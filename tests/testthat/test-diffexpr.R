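# em with two 4-replicate groups on separate arrays; group means given in
# log2 units per probe
two_group_em <- function(mu_a, mu_b, noise = 0.25, seed = 1) {
  set.seed(seed)
  n <- length(mu_a)
  a <- matrix(2^(mu_a + stats::rnorm(n * 4, 0, noise)), n, 4)
  b <- matrix(2^(mu_b + stats::rnorm(n * 4, 0, noise)), n, 4)
  v <- cbind(a, b)
  dimnames(v) <- list(sprintf("P%04d", seq_len(n)),
                      sprintf("c%d.%s", 1:8, rep(c("Cy5", "Cy3"), 4)))
  make_em(v, stage = rep(c("A", "B"), each = 4))
}

test_that("identical groups are not significant and ratios are zero", {
  v <- matrix(rep(c(4, 16, 64), 8), 3, 8, byrow = FALSE,
              dimnames = list(c("P1", "P2", "P3"),
                              sprintf("c%d.%s", 1:8, rep(c("Cy5", "Cy3"), 4))))
  em <- make_em(v, stage = rep(c("A", "B"), each = 4))
  de <- de_test(em, sample_ids(em, stage = "A"), sample_ids(em, stage = "B"))
  expect_equal(de$log2_ratio, rep(0, 3))
  expect_equal(de$call, rep("NS", 3))
  expect_error(de_test(em, sample_ids(em, stage = "A")[1],
                       sample_ids(em, stage = "B")), "A")
})

test_that("the 1.5-fold threshold is carried at full precision, shown as 0.58", {
  em <- two_group_em(rep(8, 10), rep(8, 10))
  de <- de_test(em, sample_ids(em, stage = "A"), sample_ids(em, stage = "B"))
  expect_equal(round(attr(de, "log2_fold"), 2), 0.58)
  expect_false(attr(de, "log2_fold") == 0.58)
  expect_equal(attr(de, "log2_fold"), log2(1.5))
})

test_that("swapping groups negates ratios and swaps UP/DOWN", {
  set.seed(9)
  mu <- stats::rnorm(200, 9, 1.5)
  em <- two_group_em(mu, mu + sample(c(-2, 0, 2), 200, TRUE))
  a <- sample_ids(em, stage = "A")
  b <- sample_ids(em, stage = "B")
  d1 <- de_test(em, a, b)
  d2 <- de_test(em, b, a)
  expect_equal(d2$log2_ratio, -d1$log2_ratio)
  expect_equal(d2$p_value, d1$p_value)
  expect_equal(d2$call == "UP", d1$call == "DOWN")
  # raising the fold cutoff never grows the UP or DOWN sets
  d_strict <- de_test(em, a, b, fold = 3)
  expect_true(all(d_strict$probe_id[d_strict$call == "UP"] %in%
                    d1$probe_id[d1$call == "UP"]))
  expect_true(all(d_strict$probe_id[d_strict$call == "DOWN"] %in%
                    d1$probe_id[d1$call == "DOWN"]))
})

test_that("planted four-fold changes are detected with high power", {
  em <- two_group_em(rep(10, 300), rep(8, 300), noise = 0.25, seed = 4)
  de <- de_test(em, sample_ids(em, stage = "A"), sample_ids(em, stage = "B"))
  expect_gte(mean(de$call == "UP" & de$p_value < 0.01), 0.95)
})

test_that("type-I error of the test matches alpha on null data", {
  em <- two_group_em(rep(8, 10000), rep(8, 10000), noise = 0.25, seed = 8)
  de <- de_test(em, sample_ids(em, stage = "A"), sample_ids(em, stage = "B"))
  rej <- mean(de$p_value <= 0.05)
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("paired design uses per-array ratios", {
  set.seed(13)
  n <- 100
  arr_eff <- stats::rnorm(4, 0, 2)  # strong array effects cancel in pairs
  v <- matrix(NA_real_, n, 8)
  for (a in 1:4) {
    v[, 2 * a - 1] <- 2^(10 + arr_eff[a] + stats::rnorm(n, 0, 0.1))
    v[, 2 * a] <- 2^(9 + arr_eff[a] + stats::rnorm(n, 0, 0.1))
  }
  dimnames(v) <- list(sprintf("P%04d", 1:n),
                      sprintf("c%d.%s", 1:8, rep(c("Cy5", "Cy3"), 4)))
  em <- make_em(v, stage = rep(c("A", "B"), 4))
  de <- de_test(em, sample_ids(em, stage = "A"), sample_ids(em, stage = "B"))
  expect_equal(attr(de, "method"), "paired")
  expect_gte(mean(de$call == "UP"), 0.99)
})

test_that("constitutive series flags only planted between-stage steps", {
  cfg <- quick_config(noise_sd = 0, dye_bias_amplitude = 0, negctrl_sd = 0,
                      stage_effect_sd = 0,
                      pattern_fractions = c(constitutive_on = 1))
  g <- generate_experiment(cfg)
  pats <- classify_patterns(suppressWarnings(call_detection(g$matrix)),
                            cfg$stages)
  flat <- constitutive_de_series(g$matrix, pats, cfg$stages)
  for (tr in flat) {
    expect_length(tr$up, 0)
    expect_length(tr$down, 0)
  }
  # plant a 4-fold step between stages 3 and 4 on one probe
  em <- g$matrix
  ids <- unlist(lapply(c("0.7", "1.0"), function(s) sample_ids(em, stage = s)))
  em$values["P00001", ids] <- em$values["P00001", ids] * 4
  ser <- constitutive_de_series(em, pats, cfg$stages)
  expect_equal(ser[["0.4->0.7"]]$up, "P00001")
  for (nm in setdiff(names(ser), "0.4->0.7"))
    expect_length(ser[[nm]]$up, 0)
  # UP and DOWN are disjoint everywhere on noisy data
  fx <- staged_fixture()
  ser2 <- constitutive_de_series(fx$norm, fx$patterns, fx$cfg$stages)
  for (tr in ser2) expect_length(intersect(tr$up, tr$down), 0)
})

test_that("pathway flagging applies the any-member and fraction rules", {
  sets <- list(empty_hit = c("g1", "g2", "g3"),
               half = sprintf("h%d", 1:10))
  flags_any <- pathway_flags(c("h1", "h2", "h3", "h4", "h5"), sets, "any")
  expect_equal(flags_any$flagged, c(FALSE, TRUE))
  flags_frac <- pathway_flags(sprintf("h%d", 1:5), sets, "fraction",
                              fraction = 0.45)
  expect_equal(flags_frac$fraction[2], 0.5)
  expect_true(flags_frac$flagged[2])
  expect_false(flags_frac$flagged[1])
  # boundary: exactly 45% is not flagged (rule is strictly greater)
  sets45 <- list(s = sprintf("x%d", 1:20))
  f45 <- pathway_flags(sprintf("x%d", 1:9), sets45, "fraction", 0.45)
  expect_false(f45$flagged)
  # random assignment equals brute-force recomputation
  set.seed(23)
  genes <- sprintf("g%03d", 1:200)
  smap <- lapply(1:15, function(i) sample(genes, sample(3:20, 1)))
  names(smap) <- paste0("pw", 1:15)
  changed <- sample(genes, 60)
  fl <- pathway_flags(changed, smap, "fraction", 0.45)
  for (i in seq_along(smap)) {
    fr <- length(intersect(smap[[fl$set_id[i]]], changed)) /
      length(smap[[fl$set_id[i]]])
    expect_equal(fl$fraction[i], fr)
    expect_equal(fl$flagged[i], fr > 0.45)
  }
  expect_warning(pathway_flags("g1", list(pw = "zzz"), universe = "g1"),
                 "skipped")
})
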