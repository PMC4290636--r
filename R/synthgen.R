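# Deterministic synthetic-data generator: paired untreated/AP-treated peak
# lists, identification tables and quantification tables with planted ground
# truth, so every pipeline stage is testable without instrument data.

#' Configuration of the synthetic phosphoproteome generator
#'
#' The generator emulates the statistical structure of an AP-assisted
#' experiment: phosphopeptide-enriched samples in which planted
#' phosphopeptides lose `n * 79.966` Da upon alkaline-phosphatase treatment,
#' among an abundant non-shifting background. Peptide neutral masses are
#' sampled in the tryptic range 800-3500 Da (full-scan m/z 300-2000 at
#' charges 1-3); planted and background masses are rejection-sampled so that
#' no cross-pair mass difference falls within `2 * decoy_margin` of any
#' multiple of the phosphate mass — background peaks can never masquerade as
#' dephosphorylation pairs.
#'
#' @param n_phospho Number of planted phosphopeptides.
#' @param n_decoys Number of non-shifting background peaks (present in both
#'   the untreated and treated lists).
#' @param mods_distribution Probabilities over 1..5 phosphate groups.
#' @param mz_noise_sd Gaussian m/z noise SD (Th); mass noise scales with
#'   charge.
#' @param rt_noise_sd Gaussian retention-time noise SD (minutes).
#' @param rt_range Elution range (minutes).
#' @param charge_distribution Probabilities over charges 1..3. The default
#'   puts no weight on 1+: tryptic phosphopeptides of 800-3500 Da are
#'   essentially always multiply charged.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param dephospho_efficiency Probability that a planted phosphopeptide's
#'   dephosphorylated form appears in a given AP-treated run (< 1 models
#'   incomplete digestion).
#' @param n_replicates Number of untreated/treated replicate run pairs (1-6).
#' @param effect Per-peptide control/treatment abundance fold changes,
#'   recycled over planted peptides.
#' @param residue_probs Probabilities of S/T/Y for each planted phosphosite;
#'   the default models a pTyr-enriched (anti-phosphotyrosine
#'   immunoprecipitation) sample.
#' @param n_quant_runs Quantification runs per condition group.
#' @param quant_noise_sdlog Log-normal SD of per-run abundance noise.
#' @param id_fraction Fraction of planted peptides that receive an
#'   identification row.
#' @param id_score_mean,id_score_sd Normal parameters of the simulated ion
#'   scores.
#' @param decoy_margin Minimum distance (Da) of any cross-pair mass
#'   difference from every multiple of the phosphate mass; default twice the
#'   miner's default mass tolerance.
#' @param seed Integer seed; the same seed reproduces byte-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_phospho = 20L, n_decoys = 200L,
                         mods_distribution = c(0.55, 0.25, 0.12, 0.05, 0.03),
                         mz_noise_sd = 0.005, rt_noise_sd = 0.5,
                         rt_range = c(10, 60),
                         charge_distribution = c(0, 0.7, 0.3),
                         intensity_meanlog = log(1e6), intensity_sdlog = 1,
                         dephospho_efficiency = 1, n_replicates = 3L,
                         effect = 1, residue_probs = c(S = 0, T = 0, Y = 1),
                         n_quant_runs = 3L, quant_noise_sdlog = 0.05,
                         id_fraction = 1, id_score_mean = 40,
                         id_score_sd = 5, decoy_margin = 0.1,
                         seed = 1L) {
  stopifnot(abs(sum(mods_distribution) - 1) < 1e-8,
            abs(sum(charge_distribution) - 1) < 1e-8,
            abs(sum(residue_probs) - 1) < 1e-8,
            mz_noise_sd >= 0, rt_noise_sd >= 0,
            dephospho_efficiency >= 0, dephospho_efficiency <= 1,
            n_replicates %in% 1:6, length(rt_range) == 2,
            rt_range[1] < rt_range[2])
  structure(as.list(environment()), class = "synth_config")
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)))
  }
  set.seed(seed)
  force(code)
}

# Rejection-sample n peptide masses in [800, 3500] so that every pairwise
# difference (including against `existing`) stays > margin away from every
# m * delta for m in -max_mods..max_mods (m = 0 forbids near-identical
# masses).
sample_masses <- function(n, existing = numeric(), delta = PHOSPHO_MASS,
                          max_mods = 5L, margin = 0.1) {
  mults <- (-max_mods):max_mods * delta
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L * n)
      stop("mass sampling failed to converge; relax decoy_margin",
           call. = FALSE)
    m <- stats::runif(1, 800, 3500)
    d <- m - c(existing, out)
    if (length(d) == 0L || all(abs(outer(d, mults, "-")) > margin))
      out <- c(out, m)
  }
  out
}

amino_acids <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]] # no S/T/Y here

# Random peptide sequence of given length with phospho residues planted at
# the requested positions.
random_sequence <- function(len, sites) {
  chars <- sample(amino_acids, len, replace = TRUE)
  chars[sites$position] <- sites$residue
  paste(chars, collapse = "")
}

#' Generate paired untreated / AP-treated peak lists with ground truth
#'
#' Planted phosphopeptides appear in every untreated replicate at their
#' neutral mass (with Gaussian m/z and RT jitter) and in the AP-treated
#' replicates at `mass - n_mods * 79.966` Da (subject to
#' `dephospho_efficiency`); background peaks appear in both lists at
#' non-shifting masses. Intensities are log-normal per peak per run.
#'
#' @param config A [synth_config()].
#' @return A list with elements `untreated` and `treated` (lists of
#'   `peaklist`, one per replicate) and `truth`, a data frame of class
#'   `ground_truth` with one row per planted peptide: `peptide`, `sequence`,
#'   `sites`, `residues`, `mass`, `charge`, `mz`, `rt`, `n_mods`,
#'   `fold_change`, and logical `in_treated_rep<k>` presence flags.
#' @export
generate_pairs <- function(config = synth_config()) {
  with_seed(config$seed, {
    np <- config$n_phospho; nd <- config$n_decoys
    masses <- sample_masses(np + nd, delta = PHOSPHO_MASS,
                            max_mods = length(config$mods_distribution),
                            margin = config$decoy_margin)
    p_mass <- masses[seq_len(np)]
    d_mass <- masses[np + seq_len(nd)]
    n_mods <- if (np > 0)
      sample(seq_along(config$mods_distribution), np, replace = TRUE,
             prob = config$mods_distribution) else integer(0)
    charge_of <- function(n) sample(1:3, n, replace = TRUE,
                                    prob = config$charge_distribution)
    p_charge <- charge_of(np); d_charge <- charge_of(nd)
    rt_of <- function(n) stats::runif(n, config$rt_range[1] + 1,
                                      config$rt_range[2] - 1)
    p_rt <- rt_of(np); d_rt <- rt_of(nd)
    fold <- rep_len(config$effect, np)
    seq_len_of <- if (np > 0) sample(10:16, np, replace = TRUE) else integer(0)
    sites_list <- lapply(seq_len(np), function(i) {
      pos <- sort(sample(seq_len(seq_len_of[i]), n_mods[i]))
      res <- sample(names(config$residue_probs), n_mods[i], replace = TRUE,
                    prob = config$residue_probs)
      data.frame(residue = res, position = pos, stringsAsFactors = FALSE)
    })
    seqs <- vapply(seq_len(np), function(i)
      random_sequence(seq_len_of[i], sites_list[[i]]), character(1))
    present <- matrix(stats::runif(np * config$n_replicates) <=
                        config$dephospho_efficiency,
                      nrow = np, ncol = config$n_replicates)

    noisy_peaks <- function(mass, charge, rt, run_id, condition, replicate) {
      n <- length(mass)
      if (n == 0L)
        return(peaklist(numeric(0), numeric(0), numeric(0), run_id = run_id,
                        condition = condition, replicate = replicate))
      m_obs <- mass + stats::rnorm(n, 0, config$mz_noise_sd * charge)
      rt_obs <- pmax(0, rt + stats::rnorm(n, 0, config$rt_noise_sd))
      inten <- stats::rlnorm(n, config$intensity_meanlog,
                             config$intensity_sdlog)
      peaklist(mz = mz_from_mass(m_obs, charge), rt = rt_obs,
               intensity = inten, charge = charge, mass = m_obs,
               run_id = run_id, condition = condition, replicate = replicate)
    }
    untreated <- vector("list", config$n_replicates)
    treated <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      untreated[[r]] <- noisy_peaks(
        c(p_mass, d_mass), c(p_charge, d_charge), c(p_rt, d_rt),
        sprintf("ctrl_rep%d", r), "untreated", r)
      keep <- which(present[, r])
      treated[[r]] <- noisy_peaks(
        c(p_mass[keep] - n_mods[keep] * PHOSPHO_MASS, d_mass),
        c(p_charge[keep], d_charge), c(p_rt[keep], d_rt),
        sprintf("ap_rep%d", r), "ap_treated", r)
    }
    truth <- data.frame(
      peptide = sprintf("SYNP%03d", seq_len(np)),
      sequence = seqs,
      sites = vapply(sites_list, function(s)
        paste0("p", s$residue, s$position, collapse = ";"), character(1)),
      residues = vapply(sites_list, function(s)
        paste(sort(unique(s$residue)), collapse = ";"), character(1)),
      mass = p_mass, charge = p_charge,
      mz = mz_from_mass(p_mass, p_charge),
      rt = p_rt, n_mods = n_mods, fold_change = fold,
      stringsAsFactors = FALSE)
    for (r in seq_len(config$n_replicates))
      truth[[sprintf("in_treated_rep%d", r)]] <- present[, r]
    class(truth) <- c("ground_truth", "data.frame")
    list(untreated = untreated, treated = treated, truth = truth)
  })
}

#' Generate identification and quantification tables from ground truth
#'
#' Produces a Mascot-style identification table (one row per identified
#' planted peptide, with phosphosite tokens in the `mascot_csv` dialect and
#' ion scores drawn from the configured normal) and a label-free
#' quantification feature table (one feature per planted peptide plus
#' non-differential background features, with per-run log-normal abundances
#' reflecting each peptide's configured control/treatment fold change).
#'
#' @param config A [synth_config()].
#' @param truth The `ground_truth` from [generate_pairs()].
#' @return A list with `ids` (a `peptide_ids` table), `features` (a
#'   `quant_features` table) and `run_groups`.
#' @export
generate_id_quant <- function(config, truth) {
  with_seed(config$seed + 1L, {
    np <- nrow(truth)
    identified <- stats::runif(np) <= config$id_fraction
    idx <- which(identified)
    ids <- data.frame(
      sequence = truth$sequence[idx],
      mod_string = truth$sites[idx],
      mz = truth$mz[idx] + stats::rnorm(length(idx), 0, config$mz_noise_sd),
      charge = truth$charge[idx],
      rt = truth$rt[idx] + stats::rnorm(length(idx), 0, config$rt_noise_sd),
      score = stats::rnorm(length(idx), config$id_score_mean,
                           config$id_score_sd),
      accession = truth$peptide[idx],
      stringsAsFactors = FALSE)
    ids <- annotate_peptide_ids(ids)

    runs <- c(sprintf("ctrl_%d", seq_len(config$n_quant_runs)),
              sprintf("trt_%d", seq_len(config$n_quant_runs)))
    run_groups <- stats::setNames(
      rep(c("control", "treatment"), each = config$n_quant_runs), runs)
    base <- stats::rlnorm(np, config$intensity_meanlog,
                          config$intensity_sdlog)
    feats <- data.frame(
      feature_id = truth$peptide,
      mz = truth$mz + stats::rnorm(np, 0, config$mz_noise_sd),
      charge = truth$charge,
      rt = truth$rt + stats::rnorm(np, 0, config$rt_noise_sd),
      stringsAsFactors = FALSE)
    for (k in seq_len(config$n_quant_runs))
      feats[[sprintf("ctrl_%d", k)]] <-
        base * stats::rlnorm(np, 0, config$quant_noise_sdlog)
    for (k in seq_len(config$n_quant_runs))
      feats[[sprintf("trt_%d", k)]] <-
        base / truth$fold_change * stats::rlnorm(np, 0,
                                                 config$quant_noise_sdlog)
    list(ids = ids, features = quant_features(feats, run_groups),
         run_groups = run_groups)
  })
}

#' Write a complete synthetic fixture set to a directory
#'
#' Writes per-replicate peak lists in the msInspect-style dialect
#' (`scan, time [s], mz, mass, intensity, charge`, tab-delimited; file names
#' `ctrl_rep<k>.tsv` / `ap_rep<k>.tsv` so [read_peaklist_dir()] defaults
#' apply), plus `ids.csv`, `quant.csv`, `run_groups.yaml`, and
#' `ground_truth.tsv`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of paths written.
#' @export
write_synth_fixtures <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_pairs(config)
  iq <- generate_id_quant(config, sim$truth)
  write_ms <- function(pl, path) {
    df <- as.data.frame(pl)
    out <- data.frame(scan = seq_len(nrow(df)), time = df$rt * 60,
                      mz = df$mz, mass = df$mass,
                      intensity = df$intensity, charge = df$charge)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  }
  paths <- character(0)
  for (r in seq_along(sim$untreated)) {
    paths <- c(paths,
               write_ms(sim$untreated[[r]],
                        file.path(out_dir, sprintf("ctrl_rep%d.tsv", r))),
               write_ms(sim$treated[[r]],
                        file.path(out_dir, sprintf("ap_rep%d.tsv", r))))
  }
  idp <- file.path(out_dir, "ids.csv")
  utils::write.csv(as.data.frame(iq$ids)[, c("sequence", "mod_string", "mz",
                                             "charge", "rt", "score",
                                             "accession")],
                   idp, row.names = FALSE)
  qp <- file.path(out_dir, "quant.csv")
  utils::write.csv(as.data.frame(iq$features), qp, row.names = FALSE)
  rg <- file.path(out_dir, "run_groups.yaml")
  yaml::write_yaml(as.list(iq$run_groups), rg)
  tp <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(as.data.frame(sim$truth), tp, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(paths, idp, qp, rg, tp))
}
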