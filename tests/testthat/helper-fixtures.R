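# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small fast configuration for structural tests
quick_config <- function(...) {
  args <- list(n_probes = 300, n_negctrl = 40, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a bare ExpressionMatrix built from a values matrix; every probe whose id
# starts with "NEG" is a negative control, one array per column pair
make_em <- function(values, stage = NULL, genotype = "wild-type",
                    tissue = "whole", replicate = NULL) {
  n <- ncol(values)
  if (is.null(stage)) stage <- rep("s1", n)
  if (is.null(replicate)) replicate <- seq_len(n)
  ids <- colnames(values)
  samples <- data.frame(
    sample_id = ids,
    array_id = sprintf("AR%02d", ceiling(seq_len(n) / 2)),
    channel = rep(c("Cy5", "Cy3"), length.out = n),
    stage = rep(stage, length.out = n),
    genotype = rep(genotype, length.out = n),
    tissue = rep(tissue, length.out = n),
    replicate = replicate, stringsAsFactors = FALSE)
  pid <- rownames(values)
  ann <- data.frame(probe_id = pid,
                    gene_id = ifelse(startsWith(pid, "NEG"), NA_character_,
                                     paste0("g_", pid)),
                    is_negative_control = startsWith(pid, "NEG"),
                    tf_family = NA_character_, stringsAsFactors = FALSE)
  expression_matrix(values, samples, ann)
}

# DetectionTable-shaped data.frame from a probe x stage character call matrix
as_calls_df <- function(m, genotype = "wild-type", tissue = "whole", n = 4) {
  do.call(rbind, lapply(colnames(m), function(s) {
    data.frame(probe_id = rownames(m), stage = s, genotype = genotype,
               tissue = tissue, n = n,
               support = ifelse(m[, s] == "ON", 1,
                                ifelse(m[, s] == "OFF", 0, 0.5)),
               call = m[, s], stringsAsFactors = FALSE)
  }))
}

# random ON/OFF call matrix
random_calls <- function(n_probes, stages, p_on = 0.5) {
  m <- matrix(ifelse(stats::runif(n_probes * length(stages)) < p_on,
                     "ON", "OFF"),
              n_probes, length(stages),
              dimnames = list(sprintf("P%04d", seq_len(n_probes)), stages))
  m
}

# default-condition staged experiment with mutant arrays, fully processed
staged_fixture <- function() {
  fixture("staged", {
    cfg <- sim_config(n_probes = 2000, seed = 1,
                      mutant_stages = c("0.25", "0.4"))
    g <- generate_experiment(cfg)
    norm <- normalize_experiment(g$matrix)
    calls <- call_detection(norm)
    list(cfg = cfg, truth = g$truth, raw = g$matrix, norm = norm,
         calls = calls,
         patterns = classify_patterns(calls, cfg$stages))
  })
}

# all-constitutive experiment used for protein-pairing tests
prot_base_fixture <- function() {
  fixture("prot_base", {
    cfg <- sim_config(n_probes = 2000, seed = 5,
                      pattern_fractions = c(constitutive_on = 1),
                      stage_effect_sd = 0.6)
    list(cfg = cfg, g = generate_experiment(cfg))
  })
}

# LCM experiment with planted zone and non-lobe classes, processed
lcm_fixture <- function() {
  fixture("lcm", {
    cfg <- sim_config(n_probes = 1500, seed = 2)
    g <- generate_lcm_experiment(cfg)
    norm <- normalize_experiment(g$matrix)
    calls <- call_detection(norm)
    enr <- enrichment_vs_whole(norm, calls, stage = cfg$lcm_stage)
    list(cfg = cfg, truth = g$truth, norm = norm, calls = calls, enr = enr,
         whole_calls = calls[calls$tissue == "whole", ],
         whole_int = mean_log2(norm, sample_ids(norm, tissue = "whole")))
  })
}

# hand-built ZoneEnrichment for oracle tests
fake_enr <- function(probes, enriched, detected = NULL, calls = NULL) {
  zones <- c("AR", "ML/TAP", "EPI/EN")
  zcols <- c("AR", "MLTAP", "EPIEN")
  tab <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  for (k in 1:3) {
    tab[[paste0("ratio_", zcols[k])]] <- 0
    tab[[paste0("p_", zcols[k])]] <- 1
    tab[[paste0("call_", zcols[k])]] <-
      if (is.null(calls)) "NS" else calls[, k]
    tab[[paste0("detected_", zcols[k])]] <-
      if (is.null(detected)) enriched[, k] else detected[, k]
    tab[[paste0("enriched_", zcols[k])]] <- enriched[, k]
  }
  structure(list(table = tab, zones = zones, zone_cols = zcols,
                 fold = 1.5, alpha = 0.05), class = "ZoneEnrichment")
}

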