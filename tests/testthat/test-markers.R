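fake_de <- function(probes, ratio, p) {
  structure(data.frame(probe_id = probes, log2_ratio = ratio, p_value = p,
                       call = "NS", stringsAsFactors = FALSE),
            class = c("DifferentialResult", "data.frame"))
}

test_that("sequential filtering is nested and rejects decoys at the right step", {
  probes <- sprintf("P%02d", 1:40)
  # planted: P01-P10 pass all three criteria. Decoys fail exactly one:
  # P11-P20 fail step 1, P21-P30 fail step 2, P31-P40 fail step 3.
  r1 <- ifelse(probes %in% sprintf("P%02d", 11:20), 0, -1)
  r2 <- ifelse(probes %in% sprintf("P%02d", 21:30), 0, -1)
  de <- list(t1 = fake_de(probes, r1, 0.001), t2 = fake_de(probes, r2, 0.001))
  calls <- as_calls_df(matrix(
    ifelse(rep(probes %in% sprintf("P%02d", 31:40), 1), "ON", "OFF"),
    40, 1, dimnames = list(probes, "late")))
  crit <- list(
    marker_criterion("log2_below", transition = "t1", threshold = -0.58),
    marker_criterion("log2_below", transition = "t2", threshold = -0.58),
    marker_criterion("call_is", stage = "late", call = "OFF"))
  res <- sequential_filter(probes, crit, de = de, calls = calls)
  expect_setequal(res$final, sprintf("P%02d", 1:10))
  # each decoy family is rejected exactly at its intended step
  expect_false(any(sprintf("P%02d", 11:20) %in% res$steps[[1]]))
  expect_true(all(sprintf("P%02d", 21:30) %in% res$steps[[1]]))
  expect_false(any(sprintf("P%02d", 21:30) %in% res$steps[[2]]))
  expect_true(all(sprintf("P%02d", 31:40) %in% res$steps[[2]]))
  # nesting
  expect_true(all(res$steps[[2]] %in% res$steps[[1]]))
  expect_true(all(res$steps[[3]] %in% res$steps[[2]]))
  # degenerate cases
  expect_equal(sequential_filter(character(0), crit, de, calls)$final,
               character(0))
  expect_equal(sequential_filter(probes, list())$final, probes)
  expect_error(sequential_filter(probes, list(
    marker_criterion("log2_below", transition = "zzz", threshold = 0)),
    de = de), "zzz")
})

test_that("pluripotency-decline probes survive the three-step filter end to end", {
  fx <- staged_fixture()
  norm <- fx$norm
  s <- lapply(c("0.15", "0.25", "0.4"), function(x)
    sample_ids(norm, stage = x, genotype = "wild-type"))
  de <- list("0.15->0.25" = de_test(norm, s[[2]], s[[1]]),
             "0.25->0.4" = de_test(norm, s[[3]], s[[2]]))
  crit <- list(
    marker_criterion("log2_below", transition = "0.15->0.25",
                     threshold = -fold_to_log2(1.5)),
    marker_criterion("log2_below", transition = "0.25->0.4",
                     threshold = -fold_to_log2(1.5)),
    marker_criterion("low_or_off", stages = c("0.7", "1.0")))
  res <- sequential_filter(fx$truth$probe_id, crit, de = de,
                           calls = fx$calls, em = norm)
  planted <- fx$truth$probe_id[fx$truth$class == "pluripotency_decline"]
  expect_gte(sum(planted %in% res$final), 0.9 * length(planted))
  # survivors are overwhelmingly the planted class
  expect_lte(sum(!(res$final %in% planted)), 3)
})

test_that("constitutive fraction reproduces the curated-list arithmetic", {
  # 222 genes with probes, 172 of them constitutive
  genes <- sprintf("G%03d", 1:222)
  ann <- data.frame(probe_id = sprintf("P%03d", 1:222), gene_id = genes,
                    is_negative_control = FALSE, tf_family = NA)
  pats <- data.frame(probe_id = ann$probe_id,
                     pattern = c(rep("constitutive_on", 172),
                                 rep("other", 50)),
                     anchor_stage = NA_character_)
  res <- constitutive_fraction(genes, pats, ann)
  expect_equal(res$n_constitutive, 172L)
  expect_equal(res$n_total, 222L)
  expect_equal(res$percentage, 77.5)
  # zero constitutive
  pats$pattern <- "other"
  expect_equal(constitutive_fraction(genes[1:10], pats, ann)$percentage, 0)
  # every gene off-array: defined undefined marker
  res_na <- constitutive_fraction(c("nope1", "nope2"), pats, ann)
  expect_equal(res_na$n_total, 0L)
  expect_equal(res_na$n_na, 2L)
  expect_true(is.na(res_na$percentage))
  expect_error(constitutive_fraction(character(0), pats, ann), "empty")
})

test_that("array representation reproduces the TF-locus arithmetic", {
  loci <- sprintf("TF%04d", 1:2298)
  ann <- data.frame(probe_id = sprintf("P%04d", 1:1208),
                    gene_id = loci[1:1208],
                    is_negative_control = FALSE, tf_family = NA)
  res <- array_representation(loci, ann)
  expect_equal(res$n_on_array, 1208L)
  expect_equal(res$percentage, 52.6)
})

test_that("persistence fraction reproduces the mutant arithmetic", {
  probes <- sprintf("P%04d", 1:3871)
  mcalls <- as_calls_df(matrix(c(rep("ON", 3252), rep("OFF", 619)), 3871, 1,
                               dimnames = list(probes, "0.4")),
                        genotype = "mac1")
  res <- persistence_fraction(probes, mcalls, "0.4")
  expect_equal(res$n_on, 3252L)
  expect_equal(res$percentage, 84.0)
  expect_gte(res$percentage, 84)
  # empty reference set is an explicit empty result
  empty <- persistence_fraction(character(0), mcalls, "0.4")
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$percentage))
})

test_that("a mutant retaining 80% of the trough is recovered near 80%", {
  res <- fixture("persistence_recovery", {
    cfg <- sim_config(n_probes = 2500, seed = 12, mutant_stages = "0.4",
                      pattern_fractions = c(constitutive_on = 0.68,
                                            constitutive_off = 0.12,
                                            trough_0.4 = 0.04,
                                            mutant_persistent = 0.16))
    g <- generate_experiment(cfg)
    norm <- normalize_experiment(g$matrix)
    calls <- call_detection(norm)
    ref <- off_after_on_set(calls, c("0.15", "0.25"), "0.4")
    persistence_fraction(ref, calls, "0.4", genotype = "mac1")
  })
  expect_gte(res$n_total, 400)
  expect_gt(res$percentage, 75)
  expect_lt(res$percentage, 85)
})

test_that("wild-type-identical mutant calls yield zero persistence", {
  probes <- c("P1", "P2")
  wt <- matrix("OFF", 2, 1, dimnames = list(probes, "0.4"))
  res <- persistence_fraction(probes, as_calls_df(wt, genotype = "mac1"),
                              "0.4")
  expect_equal(res$n_on, 0L)
  expect_equal(res$percentage, 0)
})

test_that("direct-target overlap equals brute-force set algebra", {
  d1 <- fake_de(sprintf("P%02d", 1:20), 0, 1)
  d2 <- fake_de(sprintf("P%02d", 1:20), 0, 1)
  set.seed(77)
  d1$call <- sample(c("UP", "DOWN", "NS"), 20, TRUE)
  d2$call <- sample(c("UP", "DOWN", "NS"), 20, TRUE)
  ov <- direct_target_overlap(d1, d2)
  expect_setequal(ov$down, intersect(d1$probe_id[d1$call == "DOWN"],
                                     d2$probe_id[d2$call == "DOWN"]))
  expect_setequal(ov$up, intersect(d1$probe_id[d1$call == "UP"],
                                   d2$probe_id[d2$call == "UP"]))
  d3 <- d1; d3$call <- "NS"
  ov0 <- direct_target_overlap(d1, d3)
  expect_length(ov0$down, 0)
  expect_length(ov0$up, 0)
  ov_same <- direct_target_overlap(d1, d1)
  expect_setequal(ov_same$up, d1$probe_id[d1$call == "UP"])
})
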