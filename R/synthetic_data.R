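#' Sweep specification for the planted inflammation-linked mutation
#'
#' Describes the logistic trajectory of a beneficial allele rising toward
#' fixation in the target host genotype. The defaults emulate the canonical
#' within-host sweep of an intergenic SNP upstream of a stress-response
#' regulator: undetectable (< 0.05) one week after gavage, intermediate
#' frequency by week 4, and fixation or near-fixation from week 8 onward in
#' inflamed hosts only.
#'
#' @param locus_id locus label carrying the sweep.
#' @param target_genotype host genotype in which the sweep rises, `"WT"` or
#'   `"KO"`.
#' @param midpoint_week week at which the trajectory crosses half its final
#'   frequency.
#' @param rate logistic slope per week (> 0).
#' @param final_frequency asymptotic allele frequency in `[0, 1]`.
#' @param position 1-based genomic coordinate of the planted SNP.
#' @param ref,alt reference and alternate alleles.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(locus_id = "mprA_upstream",
                       target_genotype = c("KO", "WT"),
                       midpoint_week = 5.5,
                       rate = 0.9,
                       final_frequency = 1.0,
                       position = 3009211L,
                       ref = "C", alt = "T") {
  target_genotype <- match.arg(target_genotype)
  if (rate <= 0) stop_invalid("sweep rate must be > 0")
  if (final_frequency < 0 || final_frequency > 1)
    stop_invalid("final_frequency must lie in [0, 1]")
  structure(list(locus_id = locus_id, target_genotype = target_genotype,
                 midpoint_week = midpoint_week, rate = rate,
                 final_frequency = final_frequency,
                 position = as.integer(position), ref = ref, alt = alt),
            class = "sweep_spec")
}

#' Simulation configuration for the synthetic cohort
#'
#' Bundles every knob of the synthetic-data module. Defaults reproduce the
#' study conditions: 14 wild-type (WT) and 11 IL10-deficient (KO) mice
#' monocolonized with a single strain, fecal sampling at weeks 1, 4, 8 and
#' 12, a background of selectively neutral de-novo mutations, one planted
#' inflammation-linked sweep, and a fecal inflammation marker
#' (lipocalin-2-like, ng per g feces) that rises in KO mice only.
#'
#' Background mutation frequencies are drawn from a Beta law with most mass
#' below 0.3 so that neutral loci never mimic a sweep. Each generated object
#' consumes a private random stream derived from `seed` and a stable label,
#' so enlarging the cohort never shifts the draws of existing mice.
#'
#' @param seed master seed; identical configs give byte-identical output.
#' @param n_wt,n_ko number of WT and KO mice (>= 1).
#' @param timepoints sampling weeks, strictly increasing.
#' @param n_background_loci number of neutral candidate loci.
#' @param background_rate probability that a given mouse ever acquires a
#'   given background locus.
#' @param background_shape1,background_shape2 Beta parameters of the
#'   background frequency law.
#' @param n_inoculum_variants ancestral standing variants per inoculum that
#'   de-novo filtering must subtract.
#' @param sweep a [sweep_spec()].
#' @param sweep_noise_sd sd of the truncated-Gaussian noise on the sweep
#'   trajectory.
#' @param inflammation_baseline named numeric, marker level (per gram) at
#'   week 0 for `WT` and `KO`.
#' @param inflammation_slope named numeric, marker units per week.
#' @param inflammation_sd sd of the Gaussian noise on the marker.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort)  # 25
#' @export
sim_config <- function(seed = 1L,
                       n_wt = 14L, n_ko = 11L,
                       timepoints = c(1, 4, 8, 12),
                       n_background_loci = 200L,
                       background_rate = 0.2,
                       background_shape1 = 1.5,
                       background_shape2 = 8,
                       n_inoculum_variants = 30L,
                       sweep = sweep_spec(),
                       sweep_noise_sd = 0.05,
                       inflammation_baseline = c(WT = 20, KO = 20),
                       inflammation_slope = c(WT = 0, KO = 15),
                       inflammation_sd = 15) {
  if (n_wt < 1 || n_ko < 1) stop_invalid("n_wt and n_ko must be >= 1")
  if (length(timepoints) >= 2 && any(diff(timepoints) <= 0))
    stop_invalid("timepoints must be strictly increasing")
  if (!inherits(sweep, "sweep_spec")) stop_invalid("sweep must be a sweep_spec")
  structure(list(seed = as.integer(seed), n_wt = as.integer(n_wt),
                 n_ko = as.integer(n_ko), timepoints = timepoints,
                 n_background_loci = as.integer(n_background_loci),
                 background_rate = background_rate,
                 background_shape1 = background_shape1,
                 background_shape2 = background_shape2,
                 n_inoculum_variants = as.integer(n_inoculum_variants),
                 sweep = sweep, sweep_noise_sd = sweep_noise_sd,
                 inflammation_baseline = inflammation_baseline,
                 inflammation_slope = inflammation_slope,
                 inflammation_sd = inflammation_sd),
            class = "sim_config")
}

#' Generate the mouse cohort
#'
#' Two independent experiments are emulated: experiment 1 mice share a single
#' inoculum, experiment 2 mice each receive an independent inoculum (the
#' design that makes parallel-mutation calls robust to ancestral standing
#' variation). Mice of each genotype are split between the experiments, the
#' first half (rounded up) into experiment 1.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `mouse_id`, `genotype`, `inoculum_id`,
#'   `experiment_id`, one row per mouse.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- c(rep("WT", config$n_wt), rep("KO", config$n_ko))
  idx <- c(seq_len(config$n_wt), seq_len(config$n_ko))
  mouse_id <- sprintf("%s%02d", geno, idx)
  in_exp1 <- c(seq_len(config$n_wt) <= ceiling(config$n_wt / 2),
               seq_len(config$n_ko) <= ceiling(config$n_ko / 2))
  experiment_id <- ifelse(in_exp1, "Exp1", "Exp2")
  inoculum_id <- ifelse(in_exp1, "inoc_shared", paste0("inoc_", mouse_id))
  data.frame(mouse_id = mouse_id, genotype = geno,
             inoculum_id = inoculum_id, experiment_id = experiment_id,
             stringsAsFactors = FALSE)
}

#' Generate per-mouse variant tables with a planted sweep
#'
#' Produces one long table of variant calls keyed by `(mouse_id, week)`,
#' plus per-inoculum standing-variant tables. Three classes of calls are
#' planted: (i) ancestral standing variants inherited from the mouse's
#' inoculum, present at every week (these must disappear after inoculum
#' subtraction); (ii) neutral background de-novo mutations, sprinkled
#' independently of host genotype with Beta-law frequencies mostly below
#' 0.3; (iii) the sweep locus, whose frequency in target-genotype mice
#' follows a noisy logistic rise truncated to `[0, 1]` and which is absent
#' from all other mice.
#'
#' @param config a [sim_config()].
#' @param cohort output of [generate_cohort()].
#' @return A list with elements `calls` (data.frame: `mouse_id`, `week`,
#'   `locus_id`, `position`, `ref`, `alt`, `frequency`), `inoculum_calls`
#'   (data.frame: `inoculum_id`, `locus_id`, `position`, `ref`, `alt`,
#'   `frequency`), and `truth` (planted sweep locus/position and the
#'   background locus labels), so recovery tests are self-grading.
#' @export
generate_mutation_tables <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$timepoints) == 0) stop_invalid("timepoints must be non-empty")
  sw <- config$sweep
  genome_len <- 5e6
  bg_ids <- sprintf("bg%04d", seq_len(config$n_background_loci))
  if (sw$locus_id %in% bg_ids)
    stop_invalid("sweep locus must not be a background locus")

  bg_pos <- with_local_seed(derive_seed(config$seed, "bg_positions"), {
    pos <- sample(genome_len, config$n_background_loci + 1000)
    setdiff(pos, sw$position)[seq_len(config$n_background_loci)]
  })
  bases <- c("A", "C", "G", "T")

  # per-inoculum ancestral standing variants
  inocs <- unique(cohort$inoculum_id)
  inoculum_calls <- do.call(rbind, lapply(inocs, function(ic) {
    with_local_seed(derive_seed(config$seed, paste0("inoc:", ic)), {
      n <- config$n_inoculum_variants
      pos <- sample(setdiff(seq(1e6, 2e6), c(sw$position, bg_pos)), n)
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      data.frame(inoculum_id = ic,
                 locus_id = sprintf("anc_%s_%02d", ic, seq_len(n)),
                 position = pos, ref = ref, alt = unname(alt),
                 frequency = round(runif(n, 0.1, 0.9), 4),
                 stringsAsFactors = FALSE)
    })
  }))

  weeks <- config$timepoints
  calls <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    m <- cohort$mouse_id[i]
    with_local_seed(derive_seed(config$seed, paste0("mouse:", m)), {
      out <- list()
      # inherited standing variants, redrawn around their inoculum frequency
      anc <- inoculum_calls[inoculum_calls$inoculum_id == cohort$inoculum_id[i], ]
      for (w in weeks) {
        f <- clamp(anc$frequency + rnorm(nrow(anc), 0, 0.02), 0.01, 1)
        out[[length(out) + 1L]] <- data.frame(
          mouse_id = m, week = w, locus_id = anc$locus_id,
          position = anc$position, ref = anc$ref, alt = anc$alt,
          frequency = round(f, 4), stringsAsFactors = FALSE)
      }
      # neutral background mutations: onset week, then persistence
      acquired <- which(runif(config$n_background_loci) < config$background_rate)
      if (length(acquired)) {
        onset <- sample(seq_along(weeks), length(acquired), replace = TRUE)
        f0 <- rbeta(length(acquired), config$background_shape1,
                    config$background_shape2)
        ref <- sample(bases, length(acquired), replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
        for (j in seq_along(acquired)) {
          wk <- weeks[seq(onset[j], length(weeks))]
          f <- clamp(f0[j] + rnorm(length(wk), 0, 0.02), 0.005, 1)
          out[[length(out) + 1L]] <- data.frame(
            mouse_id = m, week = wk, locus_id = bg_ids[acquired[j]],
            position = bg_pos[acquired[j]], ref = ref[j], alt = unname(alt[j]),
            frequency = round(f, 4), stringsAsFactors = FALSE)
        }
      }
      # planted sweep in target-genotype mice only
      if (cohort$genotype[i] == sw$target_genotype) {
        f <- clamp(logistic_freq(weeks, sw$midpoint_week, sw$rate,
                                 sw$final_frequency) +
                     rnorm(length(weeks), 0, config$sweep_noise_sd), 0, 1)
        keep <- f > 0
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.frame(
            mouse_id = m, week = weeks[keep], locus_id = sw$locus_id,
            position = sw$position, ref = sw$ref, alt = sw$alt,
            frequency = round(f[keep], 4), stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, out)
    })
  }))
  rownames(calls) <- NULL
  list(calls = calls,
       inoculum_calls = inoculum_calls[, c("inoculum_id", "locus_id",
                                           "position", "ref", "alt",
                                           "frequency")],
       truth = list(sweep_locus = sw$locus_id, sweep_position = sw$position,
                    sweep_alt = sw$alt, background_loci = bg_ids))
}

#' Generate per-mouse inflammation-marker time series
#'
#' KO mice receive a linear upward trend (slope in marker units per week)
#' plus Gaussian noise floored at zero; WT mice fluctuate around their
#' baseline. Emulates a fecal lipocalin-2 readout normalized per gram of
#' feces.
#'
#' @inheritParams generate_mutation_tables
#' @return data.frame with columns `mouse_id`, `genotype`, `week`,
#'   `marker_per_gram`.
#' @export
generate_inflammation_series <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$timepoints) == 0) stop_invalid("timepoints must be non-empty")
  weeks <- config$timepoints
  do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    g <- cohort$genotype[i]
    mu <- config$inflammation_baseline[[g]] + config$inflammation_slope[[g]] * weeks
    val <- with_local_seed(
      derive_seed(config$seed, paste0("lcn2:", cohort$mouse_id[i])),
      pmax(0, mu + rnorm(length(weeks), 0, config$inflammation_sd)))
    data.frame(mouse_id = cohort$mouse_id[i], genotype = g, week = weeks,
               marker_per_gram = val, stringsAsFactors = FALSE)
  }))
}

#' Generate a feature matrix with planted group differences
#'
#' Log-normal abundances for `n_features` features over all cohort mice;
#' `n_shifted` randomly chosen features have their log-mean shifted by
#' `effect_size` (in units of the within-group log-SD, which is 1) in KO
#' samples, with a random direction per feature. The remaining features are
#' exchangeable between groups. Used to emulate both NMR metabolome tables
#' and Biolog-style AUC panels.
#'
#' @inheritParams generate_mutation_tables
#' @param n_features number of features (columns).
#' @param n_shifted number of features with a planted KO shift
#'   (`<= n_features`).
#' @param effect_size nonnegative shift on the log scale.
#' @param label stream label so several matrices can be drawn from one
#'   config without sharing randomness.
#' @return list with `matrix` (samples x features, rownames = mouse ids),
#'   `groups` (named genotype factor), `shifted_features`, and `direction`
#'   (+1 = higher in KO) — the ground truth for recovery tests.
#' @export
generate_feature_matrix <- function(config, cohort, n_features = 77L,
                                    n_shifted = 0L, effect_size = 0,
                                    label = "features") {
  stopifnot(inherits(config, "sim_config"))
  if (effect_size < 0) stop_invalid("effect_size must be nonnegative")
  if (n_shifted > n_features) stop_invalid("n_shifted must be <= n_features")
  n <- nrow(cohort)
  with_local_seed(derive_seed(config$seed, paste0("fm:", label)), {
    mu <- runif(n_features, 1, 3)
    x <- matrix(rnorm(n * n_features), n, n_features)
    x <- sweep(x, 2, mu, "+")
    shifted <- sort(sample(n_features, n_shifted))
    direction <- integer(0)
    if (n_shifted > 0) {
      direction <- sample(c(-1L, 1L), n_shifted, replace = TRUE)
      ko <- cohort$genotype == "KO"
      for (j in seq_along(shifted))
        x[ko, shifted[j]] <- x[ko, shifted[j]] + direction[j] * effect_size
    }
    m <- exp(x)
    dimnames(m) <- list(cohort$mouse_id,
                        sprintf("feat%03d", seq_len(n_features)))
    list(matrix = m,
         groups = stats::setNames(factor(cohort$genotype, c("WT", "KO")),
                                  cohort$mouse_id),
         shifted_features = colnames(m)[shifted],
         direction = direction)
  })
}

#' Generate logistic growth curves
#'
#' Plate-reader-style OD time series: logistic growth with per-replicate
#' noise, sampled on a regular grid (default every 15 min over 36 h).
#'
#' @inheritParams generate_mutation_tables
#' @param sample_ids samples (e.g. evolved populations) to simulate.
#' @param condition_ids conditions (e.g. carbon sources) per sample.
#' @param n_replicates replicates per (sample, condition).
#' @param times acquisition times in hours.
#' @param od_max,rate_per_h,midpoint_h logistic parameters.
#' @param noise_sd sd of the additive OD noise (floored at zero).
#' @return Long-format data.frame: `sample_id`, `condition_id`,
#'   `replicate_id`, `time`, `od`.
#' @export
generate_growth_curves <- function(config, sample_ids = c("s1", "s2"),
                                   condition_ids = "cond1",
                                   n_replicates = 3,
                                   times = seq(0, 36, by = 0.25),
                                   od_max = 1.0, rate_per_h = 0.5,
                                   midpoint_h = 12, noise_sd = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(sample_id = sample_ids, condition_id = condition_ids,
                      replicate_id = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    lbl <- paste("gc", grid$sample_id[i], grid$condition_id[i],
                 grid$replicate_id[i], sep = ":")
    od <- with_local_seed(derive_seed(config$seed, lbl),
      pmax(0, od_max / (1 + exp(-rate_per_h * (times - midpoint_h))) +
             rnorm(length(times), 0, noise_sd)))
    data.frame(sample_id = grid$sample_id[i],
               condition_id = grid$condition_id[i],
               replicate_id = grid$replicate_id[i],
               time = times, od = od, stringsAsFactors = FALSE)
  }))
}

#' Build a toy stoichiometric model with known ground truth
#'
#' Four small models (<= 15 reactions, each with a biomass and exchange
#' reactions) exercise the producibility screen and the metabolite-graph
#' analyses:
#' \describe{
#'   \item{linear_chain}{`A -> B -> C -> biomass`; from source A both B and
#'     C are producible under every oxygen scenario.}
#'   \item{branched}{adds `B -> D` and `D + o2 -> F`, so F is producible
#'     only when oxygen uptake is allowed.}
#'   \item{blocked_target}{adds a metabolite `T` with no producing reaction
#'     (a taurine analog: consumed by `T -> U` but never made), so neither T
#'     nor U is ever producible.}
#'   \item{currency_hub}{a high-degree cofactor `h` (degree 4x the
#'     peripheral nodes) offers a 2-hop shortcut between `S` and `C` that
#'     degree-sum edge weighting must avoid in favor of the 3-hop chain.}
#' }
#'
#' @param spec_name one of `"linear_chain"`, `"branched"`,
#'   `"blocked_target"`, `"currency_hub"`.
#' @return A [metabolic_model()] whose `ground_truth` attribute lists the
#'   intended source, producible and blocked targets (per oxygen scenario),
#'   and — for `currency_hub` — the hub and the peripheral query pair.
#' @export
generate_toy_model <- function(spec_name = c("linear_chain", "branched",
                                             "blocked_target",
                                             "currency_hub")) {
  spec_name <- match.arg(spec_name)
  rx <- function(id, stoich, lb = 0, ub = 1000)
    list(id = id, stoich = stoich, lb = lb, ub = ub)
  common <- list(rx("EX_A", c(A = -1), lb = -1000),
                 rx("EX_o2", c(o2 = -1), lb = -1000),
                 rx("R1", c(A = -1, B = 1)),
                 rx("R2", c(B = -1, C = 1)),
                 rx("BIOMASS", c(C = -1)))
  gt_common <- list(source = "A", oxygen_independent = TRUE)
  model <- switch(spec_name,
    linear_chain = {
      m <- metabolic_model(spec_name, common, biomass = "BIOMASS",
                           exchanges = c(A = "EX_A", o2 = "EX_o2"))
      attr(m, "ground_truth") <- c(gt_common, list(
        producible = list(anoxic = c("B", "C"), microaerobic = c("B", "C"),
                          aerobic = c("B", "C")),
        blocked = character(0), targets = c("B", "C")))
      m
    },
    branched = {
      rxns <- c(common, list(rx("R3", c(B = -1, D = 1)),
                             rx("R4", c(D = -1, o2 = -1, F = 1))))
      m <- metabolic_model(spec_name, rxns, biomass = "BIOMASS",
                           exchanges = c(A = "EX_A", o2 = "EX_o2"))
      attr(m, "ground_truth") <- c(gt_common, list(
        producible = list(anoxic = c("B", "C", "D"),
                          microaerobic = c("B", "C", "D", "F"),
                          aerobic = c("B", "C", "D", "F")),
        blocked = character(0), targets = c("B", "C", "D", "F")))
      m
    },
    blocked_target = {
      rxns <- c(common, list(rx("RT", c(T = -1, U = 1))))
      m <- metabolic_model(spec_name, rxns, biomass = "BIOMASS",
                           exchanges = c(A = "EX_A", o2 = "EX_o2"))
      attr(m, "ground_truth") <- c(gt_common, list(
        producible = list(anoxic = c("B", "C"), microaerobic = c("B", "C"),
                          aerobic = c("B", "C")),
        blocked = c("T", "U"), targets = c("B", "C", "T", "U")))
      m
    },
    currency_hub = {
      rxns <- list(rx("EX_S", c(S = -1), lb = -1000),
                   rx("EX_o2", c(o2 = -1), lb = -1000),
                   rx("R1", c(S = -1, A = 1)),
                   rx("R2", c(A = -1, B = 1)),
                   rx("R3", c(B = -1, C = 1)),
                   rx("RH1", c(S = -1, h = 1)),
                   rx("RH2", c(h = -1, C = 1)),
                   rx("RP1", c(h = -1, P1 = 1)),
                   rx("RP2", c(h = -1, P2 = 1)),
                   rx("RP3", c(h = -1, P3 = 1)),
                   rx("RP4", c(P4 = -1, h = 1)),
                   rx("RP5", c(P5 = -1, h = 1)),
                   rx("RP6", c(h = -1, P6 = 1)),
                   rx("BIOMASS", c(C = -1)))
      m <- metabolic_model(spec_name, rxns, biomass = "BIOMASS",
                           exchanges = c(S = "EX_S", o2 = "EX_o2"))
      attr(m, "ground_truth") <- list(
        source = "S", hub = "h", peripheral_pair = c("S", "C"),
        producible = list(anoxic = c("A", "B", "C", "h", "P1", "P2", "P3", "P6"),
                          microaerobic = c("A", "B", "C", "h", "P1", "P2", "P3", "P6"),
                          aerobic = c("A", "B", "C", "h", "P1", "P2", "P3", "P6")),
        blocked = c("P4", "P5"),
        targets = c("A", "B", "C", "h", "P1", "P2", "P3", "P4", "P5", "P6"))
      m
    })
  model
}

#' Write synthetic fixtures to disk
#'
#' Emits the full fixture set for one configuration: cohort TSV, variant and
#' inoculum TSVs, inflammation TSV, a metabolome-style CSV feature matrix,
#' and the four toy models as JSON.
#'
#' @inheritParams generate_mutation_tables
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  mut <- generate_mutation_tables(config, cohort)
  infl <- generate_inflammation_series(config, cohort)
  fm <- generate_feature_matrix(config, cohort, n_features = 77,
                                n_shifted = 59, effect_size = 3)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             calls = file.path(dir, "variants.tsv"),
             inoc = file.path(dir, "inoculum_variants.tsv"),
             infl = file.path(dir, "inflammation.tsv"),
             fm = file.path(dir, "metabolome.csv"))
  utils::write.table(cohort, paths["cohort"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(mut$calls, paths["calls"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(mut$inoculum_calls, paths["inoc"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(infl, paths["infl"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(fm$matrix, paths["fm"])
  for (nm in c("linear_chain", "branched", "blocked_target", "currency_hub")) {
    p <- file.path(dir, paste0(nm, ".json"))
    write_model_json(generate_toy_model(nm), p)
    paths[nm] <- p
  }
  invisible(paths)
}
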