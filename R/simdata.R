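# Synthetic two-color microarray experiments with planted, recoverable truth.
#
# The generator emulates the study design: an ordered five-stage anther
# series hybridized in dye-swapped loops (each array pairs consecutive
# stages), a mutant condition co-hybridized against wild-type at two stages,
# an LCM design comparing three lobe cell types to whole anthers, and a
# companion protein table with a tunable RNA-protein ratio correlation.
#
# Noise model: log2-scale additive Gaussian replicate noise on expressed
# probes (log-normal intensities); negative controls and OFF probes draw
# linear-scale Gaussian background, so the mean + 3 SD detection rule has an
# analytically known false-ON rate. ON levels are planted relative to the
# detection point log2(mean + 3 SD), so sensitivity is controlled by one
# offset parameter. Dye bias is a smooth function of A with opposite sample
# sign in swapped pairs, exercising the within-array loess correction.

.PATTERN_SIMPLE <- c("constitutive_on", "constitutive_off",
                     "pluripotency_decline", "mutant_persistent",
                     "mutant_direct_up", "mutant_direct_down")
.LCM_ZONES <- c("AR", "ML/TAP", "EPI/EN")
.LCM_LABELS <- c(.LCM_ZONES, "whole", "non-lobe")

#' Molecular-weight fraction bins of the size-fractionated protein samples
#'
#' The 11 gel-slice size classes used to fractionate anther proteins.
#'
#' @return data.frame with columns `label`, `lo`, `hi` (kD)
#' @export
mw_bins <- function() {
  lo <- c(3.5, 10, 15, 20, 30, 40, 50, 60, 80, 110, 160)
  hi <- c(10, 15, 20, 30, 40, 50, 60, 80, 110, 160, 260)
  data.frame(label = sprintf("%g-%g kD", lo, hi), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

.default_fractions <- function(stages, focal) {
  f <- c(constitutive_on = 0.49, constitutive_off = 0.12,
         pluripotency_decline = 0.02, mutant_persistent = 0.14,
         mutant_direct_up = 0.01, mutant_direct_down = 0.01)
  ss <- stats::setNames(rep(0.02, length(stages)),
                        paste0("stage_specific_", stages))
  tr <- stats::setNames(rep(0.02, length(stages)), paste0("trough_", stages))
  tr[paste0("trough_", focal)] <- 0.03
  out <- c(f, ss, tr)
  out / sum(out)
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: five ordered stages
#' (0.15-1.0 mm), four replicate measurements per stage arranged in two
#' dye-swapped hybridization loops, log2 replicate noise of 0.25, and a
#' planted-class mix in which most probes are constitutive, trough probes sit
#' at low abundance just above the detection point, and most probes OFF at
#' the focal (0.4 mm) stage persist in the mutant.
#'
#' @param n_probes number of non-control probes
#' @param n_negctrl number of negative-control probes (>= 30)
#' @param stages ordered stage labels
#' @param replicates_per_stage replicate measurements per stage (even, >= 2)
#' @param noise_sd log2-scale SD of replicate noise on expressed probes
#' @param negctrl_mean,negctrl_sd linear-scale Gaussian background parameters
#' @param pattern_fractions named fractions over planted classes
#'   (`constitutive_on`, `constitutive_off`, `stage_specific_<stage>`,
#'   `trough_<stage>`, `pluripotency_decline`, `mutant_persistent`,
#'   `mutant_direct_up`, `mutant_direct_down`); must sum to 1
#' @param expression_offset log2 units above the detection point for ON probes
#' @param trough_offset log2 offset for trough-class ON stages (low abundance;
#'   `NULL` uses `expression_offset`)
#' @param probe_level_sd per-probe symmetric log2 jitter of the planted level
#' @param level_spread mean of the right-skewed (exponential) per-probe log2
#'   spread added to planted ON levels, emulating the orders-of-magnitude
#'   dynamic range of real fluorescence intensities
#' @param stage_effect_sd per-probe per-stage log2 wiggle on constitutive
#'   probes (drives between-stage differential expression)
#' @param dye_bias_amplitude amplitude of the smooth intensity-dependent dye
#'   bias added to M
#' @param pluripotency_step log2 decline per early transition for the
#'   pluripotency class
#' @param direct_log2fc planted mutant-vs-wild-type log2 fold change for the
#'   direct-target classes
#' @param mutant_stages stages at which the mutant is co-hybridized
#' @param mutant_focal_stage stage whose trough the mutant perturbs
#' @param lcm_stage stage of the LCM design
#' @param seed master integer seed; per-array substreams are derived from it
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_probes = 2000, n_negctrl = 100,
                       stages = c("0.15", "0.25", "0.4", "0.7", "1.0"),
                       replicates_per_stage = 4, noise_sd = 0.25,
                       negctrl_mean = 100, negctrl_sd = 20,
                       pattern_fractions = NULL,
                       expression_offset = 2, trough_offset = 0.8,
                       probe_level_sd = 0.25, level_spread = 1.5,
                       stage_effect_sd = 0.3,
                       dye_bias_amplitude = 0.3,
                       pluripotency_step = 1.2, direct_log2fc = 2,
                       mutant_stages = character(0),
                       mutant_focal_stage = "0.4",
                       lcm_stage = "0.7", seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes), n_negctrl = as.integer(n_negctrl),
              stages = as.character(stages),
              replicates_per_stage = as.integer(replicates_per_stage),
              noise_sd = noise_sd, negctrl_mean = negctrl_mean,
              negctrl_sd = negctrl_sd,
              pattern_fractions = pattern_fractions %||%
                .default_fractions(stages, mutant_focal_stage),
              expression_offset = expression_offset,
              trough_offset = trough_offset %||% expression_offset,
              probe_level_sd = probe_level_sd, level_spread = level_spread,
              stage_effect_sd = stage_effect_sd,
              dye_bias_amplitude = dye_bias_amplitude,
              pluripotency_step = pluripotency_step,
              direct_log2fc = direct_log2fc,
              mutant_stages = as.character(mutant_stages),
              mutant_focal_stage = mutant_focal_stage,
              lcm_stage = lcm_stage, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config`
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) .stopf("invalid '%s': %s", field, msg)
  chk(cfg$n_probes >= 0, "n_probes", "must be >= 0")
  if (cfg$n_probes > 0)
    chk(cfg$n_negctrl >= 30, "n_negctrl",
        "needs >= 30 negative controls for a stable SD")
  chk(length(cfg$stages) >= 1 && !anyDuplicated(cfg$stages), "stages",
      "must be non-empty and unique")
  chk(cfg$replicates_per_stage >= 2 && cfg$replicates_per_stage %% 2 == 0,
      "replicates_per_stage", "must be even and >= 2 for dye-swap pairing")
  for (f in c("noise_sd", "negctrl_sd", "probe_level_sd", "level_spread",
              "stage_effect_sd", "dye_bias_amplitude"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "must be non-negative")
  chk(cfg$negctrl_mean > 0, "negctrl_mean", "must be positive")
  pf <- cfg$pattern_fractions
  chk(!is.null(names(pf)) && all(nzchar(names(pf))), "pattern_fractions",
      "must be named")
  chk(all(pf >= 0), "pattern_fractions", "fractions must be non-negative")
  chk(abs(sum(pf) - 1) <= 1e-9, "pattern_fractions", "must sum to 1")
  known <- c(.PATTERN_SIMPLE, paste0("stage_specific_", cfg$stages),
             paste0("trough_", cfg$stages))
  bad <- setdiff(names(pf), known)
  chk(length(bad) == 0, "pattern_fractions",
      paste("unknown class:", bad[1]))
  chk(cfg$mutant_focal_stage %in% cfg$stages, "mutant_focal_stage",
      "not in stage list")
  chk(all(cfg$mutant_stages %in% cfg$stages), "mutant_stages",
      "not in stage list")
  invisible(cfg)
}

# integer class counts from fractions: floor + largest remainders
.class_counts <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

.detection_point <- function(cfg) log2(cfg$negctrl_mean + 3 * cfg$negctrl_sd)

# per-probe baseline jitter: symmetric wobble plus a right-skewed spread so
# planted levels span a realistic dynamic range (never below the offset)
.level_jitter <- function(n, cfg) {
  out <- stats::rnorm(n, 0, cfg$probe_level_sd)
  if (cfg$level_spread > 0) out <- out + stats::rexp(n, 1 / cfg$level_spread)
  out
}

.bg_draw <- function(n, cfg) {
  pmax(stats::rnorm(n, cfg$negctrl_mean, cfg$negctrl_sd), 1e-6)
}

.dye_bias <- function(A, amp) amp * sin(A / 1.5)

.probe_annotation <- function(cfg) {
  n <- cfg$n_probes
  ids <- c(sprintf("P%05d", seq_len(n)),
           if (cfg$n_negctrl > 0 && n > 0) sprintf("NEG%04d", seq_len(cfg$n_negctrl)))
  nneg <- length(ids) - n
  fam_pool <- c("Myb", "bHLH", "WRKY", "MADS", "bZIP", "HD", "C2H2")
  fam <- rep(NA_character_, n)
  if (n > 0) {
    n_tf <- round(0.06 * n)
    if (n_tf > 0)
      fam[sample.int(n, n_tf)] <- sample(fam_pool, n_tf, replace = TRUE)
  }
  data.frame(probe_id = ids,
             gene_id = c(if (n > 0) sprintf("G%05d", seq_len(n)),
                         rep(NA_character_, nneg)),
             is_negative_control = c(rep(FALSE, n), rep(TRUE, nneg)),
             tf_family = c(fam, rep(NA_character_, nneg)),
             stringsAsFactors = FALSE)
}

# per-probe planted wild-type log2 level matrix (NA = background/OFF) plus
# mutant levels at the configured mutant stages
.plant_levels <- function(cfg) {
  n <- cfg$n_probes
  S <- length(cfg$stages)
  T0 <- .detection_point(cfg)
  classes <- names(cfg$pattern_fractions)
  cnt <- .class_counts(cfg$pattern_fractions, n)
  class_of <- rep(classes, cnt)
  j <- .level_jitter(n, cfg)
  delta <- matrix(stats::rnorm(n * S, 0, cfg$stage_effect_sd), n, S)
  L <- matrix(NA_real_, n, S, dimnames = list(NULL, cfg$stages))
  anchor <- rep(NA_character_, n)
  base_on <- T0 + cfg$expression_offset + j
  base_tr <- T0 + cfg$trough_offset + j
  focal <- match(cfg$mutant_focal_stage, cfg$stages)
  for (k in seq_along(classes)) {
    idx <- which(class_of == classes[k])
    if (!length(idx)) next
    cl <- classes[k]
    if (cl %in% c("constitutive_on", "mutant_direct_up", "mutant_direct_down")) {
      L[idx, ] <- base_on[idx] + delta[idx, ]
    } else if (cl == "constitutive_off") {
      # background everywhere
    } else if (cl == "pluripotency_decline") {
      L[idx, 1] <- T0 + cfg$expression_offset + 1.5 + j[idx]
      if (S >= 2) L[idx, 2] <- L[idx, 1] - cfg$pluripotency_step
    } else if (cl == "mutant_persistent") {
      L[idx, ] <- base_tr[idx] + delta[idx, ]
      L[idx, focal] <- NA_real_
      anchor[idx] <- cfg$mutant_focal_stage
    } else if (startsWith(cl, "stage_specific_")) {
      s <- match(sub("^stage_specific_", "", cl), cfg$stages)
      L[idx, s] <- base_on[idx] + delta[idx, s]
      anchor[idx] <- cfg$stages[s]
    } else if (startsWith(cl, "trough_")) {
      s <- match(sub("^trough_", "", cl), cfg$stages)
      L[idx, ] <- base_tr[idx] + delta[idx, ]
      L[idx, s] <- NA_real_
      anchor[idx] <- cfg$stages[s]
    }
  }
  Lmut <- NULL
  if (length(cfg$mutant_stages)) {
    Lmut <- L[, cfg$mutant_stages, drop = FALSE]
    for (ms in cfg$mutant_stages) {
      mi <- which(class_of == "mutant_persistent")
      if (ms == cfg$mutant_focal_stage && length(mi))
        Lmut[mi, ms] <- base_tr[mi]
      pi <- which(class_of == "pluripotency_decline")
      if (length(pi) && S >= 2)
        Lmut[pi, ms] <- L[pi, 2]
      up <- which(class_of == "mutant_direct_up")
      if (length(up)) Lmut[up, ms] <- Lmut[up, ms] + cfg$direct_log2fc
      dn <- which(class_of == "mutant_direct_down")
      if (length(dn)) Lmut[dn, ms] <- Lmut[dn, ms] - cfg$direct_log2fc
    }
  }
  list(class_of = class_of, anchor = anchor, L = L, Lmut = Lmut)
}

.truth_table <- function(cfg, ann, plant) {
  n <- cfg$n_probes
  sig <- !ann$is_negative_control
  tt <- data.frame(probe_id = ann$probe_id[sig], gene_id = ann$gene_id[sig],
                   class = plant$class_of, anchor_stage = plant$anchor,
                   stringsAsFactors = FALSE)
  for (s in cfg$stages) {
    tt[[paste0("on_", s)]] <- !is.na(plant$L[, s])
    tt[[paste0("level_", s)]] <- plant$L[, s]
  }
  for (ms in cfg$mutant_stages) {
    tt[[paste0("mut_on_", ms)]] <- !is.na(plant$Lmut[, ms])
    tt[[paste0("mut_level_", ms)]] <- plant$Lmut[, ms]
  }
  tt
}

# one channel's log2 measurements for a (stage, genotype) sample
.measure_log2 <- function(cfg, ann, plant, stage, genotype) {
  nsig <- cfg$n_probes
  lev <- if (genotype == "wild-type" || is.null(plant$Lmut) ||
             !stage %in% colnames(plant$Lmut)) {
    if (nsig > 0) plant$L[, stage] else numeric(0)
  } else plant$Lmut[, stage]
  out <- numeric(nrow(ann))
  sig <- which(!ann$is_negative_control)
  on <- sig[!is.na(lev)]
  off <- sig[is.na(lev)]
  neg <- which(ann$is_negative_control)
  if (length(on))
    out[on] <- lev[!is.na(lev)] + stats::rnorm(length(on), 0, cfg$noise_sd)
  if (length(off)) out[off] <- log2(.bg_draw(length(off), cfg))
  if (length(neg)) out[neg] <- log2(.bg_draw(length(neg), cfg))
  out
}

.assemble_matrix <- function(cfg, ann, plant, layout) {
  ncols <- 2L * nrow(layout)
  vals <- matrix(NA_real_, nrow(ann), ncols)
  samp <- vector("list", ncols)
  col <- 0L
  for (a in seq_len(nrow(layout))) {
    set.seed(.derive_seed(cfg$seed, a))
    l2_1 <- .measure_log2(cfg, ann, plant, layout$stage1[a], layout$geno1[a])
    l2_2 <- .measure_log2(cfg, ann, plant, layout$stage2[a], layout$geno2[a])
    if (cfg$dye_bias_amplitude > 0 && nrow(ann) > 0) {
      A0 <- (l2_1 + l2_2) / 2
      b <- .dye_bias(A0, cfg$dye_bias_amplitude)
      # channel 1 is always the Cy5 channel: dye bias is dye-attached, so a
      # swapped pair carries the opposite sample-wise sign
      l2_1 <- l2_1 + b / 2
      l2_2 <- l2_2 - b / 2
    }
    aid <- sprintf("A%03d", a)
    for (ch in 1:2) {
      col <- col + 1L
      vals[, col] <- 2^(if (ch == 1) l2_1 else l2_2)
      samp[[col]] <- data.frame(
        sample_id = sprintf("%s.%s", aid, c("Cy5", "Cy3")[ch]),
        array_id = aid, channel = c("Cy5", "Cy3")[ch],
        stage = if (ch == 1) layout$stage1[a] else layout$stage2[a],
        genotype = if (ch == 1) layout$geno1[a] else layout$geno2[a],
        tissue = if (ch == 1) layout$tissue1[a] else layout$tissue2[a],
        replicate = if (ch == 1) layout$rep1[a] else layout$rep2[a],
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samp)
  dimnames(vals) <- list(ann$probe_id, samples$sample_id)
  expression_matrix(vals, samples, ann)
}

#' Generate a staged whole-anther experiment with planted truth
#'
#' Arrays are arranged in dye-swapped loops over the ordered stage series:
#' within each loop every array co-hybridizes two consecutive stages, and
#' alternate loops reverse the dye assignment. If `mutant_stages` is set,
#' additional dye-swapped arrays co-hybridize mutant and wild-type samples at
#' those stages. The same configuration and seed always yield bit-identical
#' output.
#'
#' @param config a [sim_config()]
#' @return list with elements `matrix` (ExpressionMatrix) and `truth`
#'   (data.frame: one row per non-control probe with planted class, anchor
#'   stage, per-stage ON state and true log2 level)
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  cfg <- config
  S <- length(cfg$stages)
  n_loops <- cfg$replicates_per_stage %/% 2L
  rows <- list()
  repct <- stats::setNames(integer(S), cfg$stages)
  for (l in seq_len(n_loops)) {
    for (i in seq_len(S)) {
      s1 <- cfg$stages[i]
      s2 <- cfg$stages[if (i == S) 1L else i + 1L]
      if (S == 1L) s2 <- s1
      r1 <- repct[s1] <- repct[s1] + 1L
      r2 <- repct[s2] <- repct[s2] + 1L
      swap <- l %% 2L == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        stage1 = if (swap) s2 else s1, stage2 = if (swap) s1 else s2,
        geno1 = "wild-type", geno2 = "wild-type",
        tissue1 = "whole", tissue2 = "whole",
        rep1 = if (swap) r2 else r1, rep2 = if (swap) r1 else r2,
        stringsAsFactors = FALSE)
    }
  }
  mrep <- stats::setNames(integer(length(cfg$mutant_stages)), cfg$mutant_stages)
  for (ms in cfg$mutant_stages) {
    for (r in seq_len(cfg$replicates_per_stage)) {
      mrep[ms] <- mrep[ms] + 1L
      repct[ms] <- repct[ms] + 1L
      swap <- r %% 2L == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        stage1 = ms, stage2 = ms,
        geno1 = if (swap) "wild-type" else "mac1",
        geno2 = if (swap) "mac1" else "wild-type",
        tissue1 = "whole", tissue2 = "whole",
        rep1 = if (swap) repct[ms] else mrep[ms],
        rep2 = if (swap) mrep[ms] else repct[ms],
        stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, rows)
  set.seed(.derive_seed(cfg$seed, 0L))
  ann <- .probe_annotation(cfg)
  plant <- .plant_levels(cfg)
  em <- .assemble_matrix(cfg, ann, plant, layout)
  list(matrix = em, truth = .truth_table(cfg, ann, plant))
}

#' Generate an LCM cell-type experiment with planted zone truth
#'
#' Emulates the design comparing laser-microdissected archesporial (AR),
#' inner somatic (ML/TAP) and outer somatic (EPI/EN) cell collections to
#' equivalently staged whole anthers. Whole-anther intensities are mixtures
#' of the zone signals plus a non-lobe (connective/vasculature) component
#' weighted by `zone_fractions`. Planted classes: `broad` (expressed
#' everywhere), `off`, one zone-enriched class per profiled zone,
#' `non_lobe` (expressed in lobes but strongly elevated in the non-lobe
#' component, hence DOWN in every LCM collection relative to whole) and
#' `non_lobe_specific` (absent from every LCM collection yet high in whole).
#'
#' @param config a [sim_config()]; `lcm_stage`, sizes and noise are used
#' @param zone_fractions named mixing fractions of the whole-anther signal;
#'   names must be among AR, ML/TAP, EPI/EN, whole, non-lobe. Zones with
#'   fraction zero are not profiled.
#' @param class_fractions named fractions over `broad`, `off`, the zone
#'   labels, `non_lobe` and `non_lobe_specific`; must sum to 1
#' @param zone_log2_enrichment planted log2 elevation of a zone-enriched
#'   probe in its own zone (default 2, i.e. 4-fold)
#' @param nonlobe_log2_boost log2 elevation of non_lobe probes in the
#'   non-lobe component
#' @return list with `matrix` and `truth` (truth carries `zone` membership
#'   and per-tissue ON states)
#' @export
generate_lcm_experiment <- function(config,
                                    zone_fractions = c("AR" = 0.25,
                                                       "ML/TAP" = 0.30,
                                                       "EPI/EN" = 0.35,
                                                       "non-lobe" = 0.10),
                                    class_fractions = NULL,
                                    zone_log2_enrichment = 2,
                                    nonlobe_log2_boost = 4) {
  validate_sim_config(config)
  cfg <- config
  bad <- setdiff(names(zone_fractions), .LCM_LABELS)
  if (length(bad)) .stopf("invalid 'zone_fractions': unknown zone label '%s'", bad[1])
  if (any(zone_fractions < 0)) .stopf("invalid 'zone_fractions': negative fraction")
  zones <- intersect(.LCM_ZONES, names(zone_fractions)[zone_fractions > 0])
  f_nl <- unname(zone_fractions["non-lobe"])
  if (is.na(f_nl)) f_nl <- 0
  cf <- class_fractions %||% c(broad = 0.55, off = 0.15,
                               stats::setNames(rep(0.06, 3), .LCM_ZONES),
                               non_lobe = 0.10, non_lobe_specific = 0.02)
  bad <- setdiff(names(cf), c("broad", "off", .LCM_ZONES,
                              "non_lobe", "non_lobe_specific"))
  if (length(bad)) .stopf("invalid 'class_fractions': unknown class '%s'", bad[1])
  if (abs(sum(cf) - 1) > 1e-9) .stopf("invalid 'class_fractions': must sum to 1")
  set.seed(.derive_seed(cfg$seed, 0L))
  ann <- .probe_annotation(cfg)
  n <- cfg$n_probes
  T0 <- .detection_point(cfg)
  cnt <- .class_counts(cf, n)
  class_of <- rep(names(cf), cnt)
  j <- .level_jitter(n, cfg)
  base <- T0 + cfg$expression_offset + j
  tissues <- c(zones, "whole")
  L <- matrix(NA_real_, n, length(tissues), dimnames = list(NULL, tissues))
  zf <- stats::setNames(rep(0, length(.LCM_ZONES)), .LCM_ZONES)
  zf[names(zone_fractions)[names(zone_fractions) %in% .LCM_ZONES]] <-
    zone_fractions[names(zone_fractions) %in% .LCM_ZONES]
  for (k in seq_len(n)) {
    cl <- class_of[k]
    if (cl == "off") next
    if (cl == "broad") {
      L[k, ] <- base[k]
    } else if (cl %in% .LCM_ZONES) {
      L[k, zones] <- base[k]
      if (cl %in% zones) L[k, cl] <- base[k] + zone_log2_enrichment
      L[k, "whole"] <- base[k] +
        log2(1 + zf[cl] * (2^zone_log2_enrichment - 1))
    } else if (cl == "non_lobe") {
      L[k, zones] <- base[k]
      L[k, "whole"] <- base[k] + log2(1 + f_nl * (2^nonlobe_log2_boost - 1))
    } else if (cl == "non_lobe_specific") {
      L[k, "whole"] <- log2((1 - f_nl) * cfg$negctrl_mean +
                              f_nl * 2^(base[k] + 6))
    }
  }
  plant <- list(
    class_of = class_of,
    L = L,
    zones = zones,
    zone = ifelse(class_of %in% .LCM_ZONES, class_of,
                  ifelse(class_of %in% c("non_lobe", "non_lobe_specific"),
                         "non-lobe", NA_character_)))
  # arrays: each profiled zone vs whole, dye-swapped alternately
  rows <- list()
  wrep <- 0L
  for (z in zones) {
    for (r in seq_len(cfg$replicates_per_stage)) {
      wrep <- wrep + 1L
      swap <- r %% 2L == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        stage1 = cfg$lcm_stage, stage2 = cfg$lcm_stage,
        geno1 = "wild-type", geno2 = "wild-type",
        tissue1 = if (swap) "whole" else z,
        tissue2 = if (swap) z else "whole",
        rep1 = if (swap) wrep else r, rep2 = if (swap) r else wrep,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    for (r in seq_len(cfg$replicates_per_stage %/% 2L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage1 = cfg$lcm_stage, stage2 = cfg$lcm_stage,
        geno1 = "wild-type", geno2 = "wild-type",
        tissue1 = "whole", tissue2 = "whole",
        rep1 = 2L * r - 1L, rep2 = 2L * r, stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, rows)
  # measurements keyed by tissue rather than stage/genotype
  measure <- function(tissue) {
    out <- numeric(nrow(ann))
    sig <- which(!ann$is_negative_control)
    lev <- if (n > 0) L[, tissue] else numeric(0)
    on <- sig[!is.na(lev)]
    off <- sig[is.na(lev)]
    neg <- which(ann$is_negative_control)
    if (length(on))
      out[on] <- lev[!is.na(lev)] + stats::rnorm(length(on), 0, cfg$noise_sd)
    if (length(off)) out[off] <- log2(.bg_draw(length(off), cfg))
    if (length(neg)) out[neg] <- log2(.bg_draw(length(neg), cfg))
    out
  }
  ncols <- 2L * nrow(layout)
  vals <- matrix(NA_real_, nrow(ann), ncols)
  samp <- vector("list", ncols)
  col <- 0L
  for (a in seq_len(nrow(layout))) {
    set.seed(.derive_seed(cfg$seed, a))
    l2_1 <- measure(layout$tissue1[a])
    l2_2 <- measure(layout$tissue2[a])
    if (cfg$dye_bias_amplitude > 0 && nrow(ann) > 0) {
      b <- .dye_bias((l2_1 + l2_2) / 2, cfg$dye_bias_amplitude)
      l2_1 <- l2_1 + b / 2
      l2_2 <- l2_2 - b / 2
    }
    aid <- sprintf("L%03d", a)
    for (ch in 1:2) {
      col <- col + 1L
      vals[, col] <- 2^(if (ch == 1) l2_1 else l2_2)
      samp[[col]] <- data.frame(
        sample_id = sprintf("%s.%s", aid, c("Cy5", "Cy3")[ch]),
        array_id = aid, channel = c("Cy5", "Cy3")[ch],
        stage = cfg$lcm_stage, genotype = "wild-type",
        tissue = if (ch == 1) layout$tissue1[a] else layout$tissue2[a],
        replicate = if (ch == 1) layout$rep1[a] else layout$rep2[a],
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samp)
  dimnames(vals) <- list(ann$probe_id, samples$sample_id)
  em <- expression_matrix(vals, samples, ann)
  sig <- !ann$is_negative_control
  tt <- data.frame(probe_id = ann$probe_id[sig], gene_id = ann$gene_id[sig],
                   class = class_of, zone = plant$zone,
                   stringsAsFactors = FALSE)
  for (tis in tissues)
    tt[[paste0("on_", gsub("[^A-Za-z]", "", tis))]] <- !is.na(L[, tis])
  for (tis in tissues)
    tt[[paste0("level_", gsub("[^A-Za-z]", "", tis))]] <- L[, tis]
  list(matrix = em, truth = tt)
}

#' Generate a companion protein abundance table
#'
#' Builds per-stage protein log2 levels from the planted RNA levels so that
#' the Pearson correlation between paired consecutive-stage log2 ratios
#' (protein vs RNA) equals `rna_protein_corr` in expectation: the base-stage
#' protein level copies the RNA level and each subsequent stage adds
#' `c * dRNA + sqrt(1 - c^2) * sd(dRNA) * z`. Only genes whose probes are ON
#' at every compared stage receive a protein (constitutively present
#' proteins). Each protein carries one of the 11 molecular-weight fraction
#' bins.
#'
#' @param truth truth table from [generate_experiment()]
#' @param config the same [sim_config()]
#' @param rna_protein_corr target ratio correlation in `[-1, 1]`
#' @param stages stages to profile (default: last three of the series)
#' @param n_replicates replicate samples per stage
#' @param protein_noise_sd log2-scale replicate noise on abundances
#' @return data.frame: `protein_id`, `gene_id`, `mw_fraction`, `stage`,
#'   `replicate`, `abundance`
#' @export
generate_protein_table <- function(truth, config, rna_protein_corr,
                                   stages = utils::tail(config$stages, 3),
                                   n_replicates = 2, protein_noise_sd = 0.05) {
  validate_sim_config(config)
  if (!is.numeric(rna_protein_corr) || abs(rna_protein_corr) > 1)
    .stopf("invalid 'rna_protein_corr': must be in [-1, 1]")
  if (!all(stages %in% config$stages))
    .stopf("invalid 'stages': not in the configured stage list")
  on_cols <- paste0("on_", stages)
  lev_cols <- paste0("level_", stages)
  keep <- !is.na(truth$gene_id) & Reduce(`&`, truth[on_cols])
  R <- as.matrix(truth[keep, lev_cols, drop = FALSE])
  genes <- truth$gene_id[keep]
  m <- nrow(R)
  if (m == 0L)
    return(data.frame(protein_id = character(0), gene_id = character(0),
                      mw_fraction = character(0), stage = character(0),
                      replicate = integer(0), abundance = numeric(0)))
  set.seed(.derive_seed(config$seed, 9901L))
  cc <- rna_protein_corr
  P <- matrix(NA_real_, m, length(stages))
  P[, 1] <- R[, 1]
  if (length(stages) > 1) {
    for (t in 2:length(stages)) {
      dR <- R[, t] - R[, t - 1]
      sdd <- stats::sd(dR)
      if (!is.finite(sdd)) sdd <- 0
      P[, t] <- P[, t - 1] + cc * dR +
        sqrt(1 - cc^2) * sdd * stats::rnorm(m)
    }
  }
  mw <- sample(mw_bins()$label, m, replace = TRUE)
  out <- expand.grid(i = seq_len(m), stage = stages, replicate = seq_len(n_replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lvl <- P[cbind(out$i, match(out$stage, stages))]
  noise <- if (protein_noise_sd > 0)
    stats::rnorm(nrow(out), 0, protein_noise_sd) else 0
  data.frame(protein_id = paste0("PR_", genes[out$i]),
             gene_id = genes[out$i], mw_fraction = mw[out$i],
             stage = out$stage, replicate = out$replicate,
             abundance = 2^(lvl + noise), stringsAsFactors = FALSE)
}
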