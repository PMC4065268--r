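test_that("a zone identical to whole anther shows no enrichment", {
  set.seed(41)
  n <- 120
  base <- 2^stats::rnorm(n, 9, 1)
  v <- matrix(rep(base, 8), n, 8)
  dimnames(v) <- list(sprintf("P%04d", 1:n),
                      sprintf("c%d.%s", 1:8, rep(c("Cy5", "Cy3"), 4)))
  em <- make_em(v, tissue = rep(c("AR", "whole"), 4), stage = "0.7")
  calls <- call_detection(em, thresholds = data.frame(
    sample_id = colnames(v), threshold = 1),
    group_by = c("stage", "genotype", "tissue"))
  enr <- enrichment_vs_whole(em, calls, zones = "AR", stage = "0.7")
  expect_false(any(enr$table$enriched_AR))
  expect_error(enrichment_vs_whole(em, calls, zones = "AR", whole = "zzz"),
               "whole")
})

test_that("planted zone-enriched probes are recovered zone-exclusively", {
  fx <- lcm_fixture()
  m <- sapply(fx$enr$zone_cols, function(z)
    fx$enr$table[[paste0("enriched_", z)]])
  rownames(m) <- fx$enr$table$probe_id
  for (k in seq_along(fx$enr$zones)) {
    z <- fx$enr$zones[k]
    planted <- fx$truth$probe_id[fx$truth$class == z]
    excl <- rowSums(m[planted, , drop = FALSE]) == 1 & m[planted, k]
    expect_gte(sum(excl), 0.9 * length(planted))
  }
  # partition regions are disjoint, exhaustive over enriched probes
  part <- zone_partition(fx$enr)
  ids <- unlist(part)
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(length(ids), sum(rowSums(m) > 0))
})

test_that("non-lobe assignment unions its two disjoint reasons", {
  # constructed sets of the published sizes: 811 DOWN-in-all plus 14
  # whole-specific above the median give 825
  n <- 7000
  probes <- sprintf("P%05d", 1:n)
  down <- probes[1:811]
  spec <- probes[812:825]
  enriched <- matrix(FALSE, n, 3)
  detected <- matrix(TRUE, n, 3)
  detected[812:1000, ] <- FALSE  # absent from every collection
  calls3 <- matrix("NS", n, 3)
  calls3[1:811, ] <- "DOWN"
  enr <- fake_enr(probes, enriched, detected, calls3)
  wint <- stats::setNames(seq_len(n) / 100, probes)
  wint[spec] <- max(wint) + 1:14  # the 14 sit above the median
  wcalls <- as_calls_df(matrix("ON", n, 1, dimnames = list(probes, "0.7")),
                        tissue = "whole")
  res <- nonlobe_assignment(enr, wcalls, wint)
  expect_equal(res$n_down_all, 811L)
  expect_equal(res$n_absent_above_median, 14L)
  expect_equal(res$n_total, 825L)
  expect_false(anyDuplicated(res$assigned$probe_id) > 0)
  # with no absent probes the assignment is DOWN-in-all-three only
  detected2 <- matrix(TRUE, n, 3)
  res2 <- nonlobe_assignment(fake_enr(probes, enriched, detected2, calls3),
                             wcalls, wint)
  expect_equal(res2$n_total, 811L)
  expect_equal(res2$n_absent_above_median, 0L)
})

test_that("planted non-lobe probes are assigned, zone probes never are", {
  fx <- lcm_fixture()
  res <- nonlobe_assignment(fx$enr, fx$whole_calls, fx$whole_int)
  planted <- fx$truth$probe_id[fx$truth$class %in%
                                 c("non_lobe", "non_lobe_specific")]
  expect_gte(sum(planted %in% res$assigned$probe_id), 0.9 * length(planted))
  zone_planted <- fx$truth$probe_id[fx$truth$class %in% fx$enr$zones]
  expect_equal(sum(zone_planted %in% res$assigned$probe_id), 0L)
})

test_that("absent-set placement reproduces the quartile arithmetic", {
  # 6728 absent probes of which 235 above Q1 and 14 above the median
  n_universe <- 26471
  probes <- sprintf("P%05d", 1:n_universe)
  wint <- stats::setNames(seq_len(n_universe), probes)
  wcalls <- as_calls_df(matrix("ON", n_universe, 1,
                               dimnames = list(probes, "0.7")),
                        tissue = "whole")
  q1_rank <- floor(0.25 * n_universe)
  med_rank <- floor(0.5 * n_universe)
  query <- c(probes[1:(6728 - 235)],              # at or below Q1
             probes[(q1_rank + 2):(q1_rank + 222)],  # above Q1, below median
             probes[(med_rank + 2):(med_rank + 15)])  # 14 above the median
  res <- absent_set_placement(query, wcalls, wint)
  expect_equal(res$n, 6728L)
  expect_equal(round(100 * res$frac_above_q1, 1), 3.5)
  expect_equal(round(100 * res$frac_above_median, 1), 0.2)
  # a query drawn from the top quartile is 100% above Q1
  top <- probes[(n_universe - 99):n_universe]
  expect_equal(absent_set_placement(top, wcalls, wint)$frac_above_q1, 1)
})

test_that("family tabulation equals a direct group-by count", {
  set.seed(55)
  n <- 200
  probes <- sprintf("P%04d", 1:n)
  enriched <- matrix(stats::runif(3 * n) < 0.2, n, 3)
  enr <- fake_enr(probes, enriched)
  fam <- sample(c("Myb", "WRKY", "bZIP", NA), n, TRUE)
  ann <- data.frame(probe_id = probes, gene_id = probes,
                    is_negative_control = FALSE, tf_family = fam)
  tab <- family_tabulation(enr, ann)
  for (k in 1:3) {
    for (f in colnames(tab)) {
      expected <- sum(rowSums(enriched) == 1 & enriched[, k] &
                        !is.na(fam) & fam == f)
      expect_equal(unname(tab[enr$zones[k], f]), expected)
    }
  }
  # no labelled probes: empty table
  ann$tf_family <- NA
  expect_equal(ncol(family_tabulation(enr, ann)), 0)
})

test_that("trough refinement partitions exhaustively and recovers truth", {
  fx <- lcm_fixture()
  tr <- fx$truth
  query <- tr$probe_id[tr$class %in% c("AR", "ML/TAP", "EPI/EN", "broad",
                                       "off")]
  ref <- trough_refinement(query, fx$enr)
  expect_equal(sum(ref$fractions), 1)
  expect_setequal(unlist(ref$partition), query)
  # planted zone classes land in their own one-zone category
  for (z in c("AR", "ML/TAP", "EPI/EN")) {
    planted <- tr$probe_id[tr$class == z]
    expect_gte(sum(planted %in% ref$partition[[z]]), 0.9 * length(planted))
  }
  # planted off probes land in the off category
  off <- tr$probe_id[tr$class == "off"]
  expect_gte(sum(off %in% ref$partition[["off"]]), 0.9 * length(off))
  # empty query is an explicit empty result
  empty <- trough_refinement(character(0), fx$enr)
  expect_length(empty$partition, 0)
})
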