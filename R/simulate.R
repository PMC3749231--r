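#' Configuration for the synthetic PSM generator
#'
#' Describes a simulated iTRAQ 4-plex experiment on a xenograft-style
#' sample: a proteome with a small differential fraction, per-channel
#' loading bias, per-measurement technical noise, per-tumor-per-protein
#' biological variation, and the nuisance records a real search produces
#' (decoy matches, unlabeled peptides, low-confidence and degenerate
#' matches, out-of-range intensities).
#'
#' Noise model, per protein p, peptide i, channel X of tumor j (log2
#' scale):
#' `mu_p + eps_i + delta_p * [X is treatment] + b_pj + log2(bias_X) + e`,
#' with `b_pj ~ N(0, biological_sd^2)` drawn once per protein per tumor
#' (technical replicate channels of the same tumor share it) and
#' `e ~ N(0, technical_sd^2)` independent per measurement.  Intensities
#' are emitted on the linear ion-count scale.
#'
#' Defaults reflect a realistic xenograft study: about 5% truly
#' differential proteins with fold changes around 2.3x, >99% labeling
#' efficiency, low-percent decoy and degenerate rates, moderate (<= 15%)
#' channel loading bias, and technical/biological log2 standard
#' deviations of 0.3473 and 0.2461.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_dist `"geometric"` (shifted geometric, minimum
#'   `peptides_min`) or `"fixed"` (`peptides_mean` peptides each).
#' @param peptides_mean mean peptides per protein.
#' @param peptides_min minimum peptides per protein (geometric case).
#' @param frac_differential fraction of proteins with nonzero true fold
#'   change.
#' @param fc_mean,fc_sd mean and sd of |delta_p| (log2) for differential
#'   proteins.
#' @param fc_sign `"both"` (random sign) or `"positive"`.
#' @param base_log2_mean,base_log2_sd protein base abundance (log2 ion
#'   counts).
#' @param peptide_log2_sd per-peptide ionization-efficiency spread (log2).
#' @param channel_bias 4 multiplicative loading biases, channel order
#'   114, 115, 116, 117.
#' @param technical_sd per-measurement log2 noise (tau).
#' @param biological_sd per-tumor-per-protein log2 variation (beta).
#' @param frac_mouse fraction of mouse-only proteins (host contamination).
#' @param frac_shared fraction of proteins whose peptides match both
#'   species.
#' @param decoy_rate fraction of decoy PSMs appended (relative to real
#'   PSM count).
#' @param unlabeled_rate fraction of real PSMs flagged unlabeled.
#' @param low_confidence_rate fraction with ion score at or below the
#'   identity threshold.
#' @param degenerate_rate fraction flagged non-unique.
#' @param low_intensity_rate fraction rescaled below the 30-count mean
#'   intensity rule.
#' @param design_kind `"biological"` (C1/C2/T1/T2, four animals) or
#'   `"technical"` (C1a/C1b/T1a/T1b, two animals split in two).
#' @param seed integer seed; the generator is deterministic given the
#'   seed.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_proteins = 2000,
                              peptides_dist = c("geometric", "fixed"),
                              peptides_mean = 4,
                              peptides_min = 1,
                              frac_differential = 0.054,
                              fc_mean = 1.2,
                              fc_sd = 0.3,
                              fc_sign = c("both", "positive"),
                              base_log2_mean = 9,
                              base_log2_sd = 2,
                              peptide_log2_sd = 0.8,
                              channel_bias = c(1, 1.15, 0.92, 1.08),
                              technical_sd = 0.3473,
                              biological_sd = 0.2461,
                              frac_mouse = 0.05,
                              frac_shared = 0.30,
                              decoy_rate = 0.025,
                              unlabeled_rate = 0.004,
                              low_confidence_rate = 0.01,
                              degenerate_rate = 0.01,
                              low_intensity_rate = 0.03,
                              design_kind = c("biological", "technical"),
                              seed = 42) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_dist = match.arg(peptides_dist),
    peptides_mean = peptides_mean, peptides_min = as.integer(peptides_min),
    frac_differential = frac_differential,
    fc_mean = fc_mean, fc_sd = fc_sd, fc_sign = match.arg(fc_sign),
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    peptide_log2_sd = peptide_log2_sd,
    channel_bias = channel_bias,
    technical_sd = technical_sd, biological_sd = biological_sd,
    frac_mouse = frac_mouse, frac_shared = frac_shared,
    decoy_rate = decoy_rate, unlabeled_rate = unlabeled_rate,
    low_confidence_rate = low_confidence_rate,
    degenerate_rate = degenerate_rate,
    low_intensity_rate = low_intensity_rate,
    design_kind = match.arg(design_kind),
    seed = as.integer(seed)
  )
  fracs <- c(cfg$frac_differential, cfg$frac_mouse, cfg$frac_shared,
             cfg$decoy_rate, cfg$unlabeled_rate, cfg$low_confidence_rate,
             cfg$degenerate_rate, cfg$low_intensity_rate)
  if (any(fracs < 0 | fracs > 1)) stop("rates/fractions must be in [0, 1]")
  if (cfg$frac_mouse + cfg$frac_shared > 1)
    stop("frac_mouse + frac_shared must not exceed 1")
  sds <- c(cfg$peptide_log2_sd, cfg$technical_sd, cfg$biological_sd,
           cfg$base_log2_sd, cfg$fc_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (cfg$n_proteins < 1L) stop("need at least one protein")
  if (length(cfg$channel_bias) != 4L || any(cfg$channel_bias <= 0))
    stop("channel_bias must be 4 positive factors")
  class(cfg) <- "simulation_config"
  cfg
}

# Proteome-level truth shared between linked experiments: identity,
# species, abundance and true fold change of every protein.
draw_proteome <- function(cfg) {
  n <- cfg$n_proteins
  n_mouse <- round(cfg$frac_mouse * n)
  n_shared <- round(cfg$frac_shared * n)
  species <- sample(c(rep("mouse_only", n_mouse), rep("shared", n_shared),
                      rep("human_only", n - n_mouse - n_shared)))
  hum <- sprintf("HP%05d", seq_len(n))
  mou <- sprintf("MP%05d", seq_len(n))
  accessions <- ifelse(
    species == "human_only", paste0(hum, "|human"),
    ifelse(species == "mouse_only", paste0(mou, "|mouse"),
           paste0(hum, "|human;", mou, "|mouse")))
  protein_id <- ifelse(species == "mouse_only", mou, hum)

  n_diff <- round(cfg$frac_differential * n)
  is_diff <- seq_len(n) %in% sample.int(n, n_diff)
  mag <- abs(stats::rnorm(n, cfg$fc_mean, cfg$fc_sd))
  sgn <- if (cfg$fc_sign == "positive") 1
         else sample(c(-1, 1), n, replace = TRUE)
  delta <- ifelse(is_diff, sgn * mag, 0)

  n_pep <- if (cfg$peptides_dist == "fixed") {
    rep(as.integer(round(cfg$peptides_mean)), n)
  } else {
    extra_mean <- max(cfg$peptides_mean - cfg$peptides_min, 0)
    cfg$peptides_min + stats::rgeom(n, prob = 1 / (1 + extra_mean))
  }

  data.frame(
    protein_id = protein_id, accessions = accessions,
    species_class = species, delta = delta, is_differential = is_diff,
    mu = stats::rnorm(n, cfg$base_log2_mean, cfg$base_log2_sd),
    n_peptides = n_pep, stringsAsFactors = FALSE
  )
}

random_peptide <- function(n, len_range = c(8L, 20L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1L), replace = TRUE),
          collapse = "")
  }, "")
}

# Emit the PSM rows of one 4-plex experiment for a drawn proteome.
simulate_experiment <- function(cfg, proteome, design) {
  n <- nrow(proteome)
  is_treat <- design$channels$group == "treatment"
  # tumor index per channel: biological = 4 animals; technical = 2 animals
  tumor_of <- if (cfg$design_kind == "technical" ||
                  design$replicate_kind == "technical") c(1L, 1L, 2L, 2L)
              else c(1L, 2L, 3L, 4L)
  n_tumors <- max(tumor_of)
  b <- matrix(stats::rnorm(n * n_tumors, 0, cfg$biological_sd), n, n_tumors)

  pep_protein <- rep(seq_len(n), proteome$n_peptides)
  n_rows <- length(pep_protein)
  eps <- stats::rnorm(n_rows, 0, cfg$peptide_log2_sd)

  log2_int <- matrix(0, n_rows, 4L)
  for (x in 1:4) {
    log2_int[, x] <- proteome$mu[pep_protein] + eps +
      proteome$delta[pep_protein] * is_treat[x] +
      b[cbind(pep_protein, tumor_of[x])] +
      log2(cfg$channel_bias[x]) +
      stats::rnorm(n_rows, 0, cfg$technical_sd)
  }
  ints <- pmax(2^log2_int, 0)

  identity_threshold <- 30
  psm <- data.frame(
    spectrum_id = sprintf("S%06d", seq_len(n_rows)),
    peptide = random_peptide(n_rows),
    ion_score = stats::runif(n_rows, identity_threshold + 1, 100),
    identity_threshold = identity_threshold,
    is_decoy = FALSE, itraq_labeled = TRUE, is_unique = TRUE,
    accessions = proteome$accessions[pep_protein],
    stringsAsFactors = FALSE
  )
  psm[intensity_cols()] <- as.data.frame(ints)

  # nuisance records: disjoint index sets so per-criterion failure counts
  # in the qualification report match these counts exactly
  n_unlab <- round(cfg$unlabeled_rate * n_rows)
  n_lowconf <- round(cfg$low_confidence_rate * n_rows)
  n_degen <- round(cfg$degenerate_rate * n_rows)
  n_lowint <- round(cfg$low_intensity_rate * n_rows)
  n_bad <- n_unlab + n_lowconf + n_degen + n_lowint
  if (n_bad > n_rows) stop("nuisance rates exceed the number of PSMs")
  bad <- sample.int(n_rows, n_bad)
  idx_unlab <- bad[seq_len(n_unlab)]
  idx_lowconf <- bad[n_unlab + seq_len(n_lowconf)]
  idx_degen <- bad[n_unlab + n_lowconf + seq_len(n_degen)]
  idx_lowint <- bad[n_unlab + n_lowconf + n_degen + seq_len(n_lowint)]

  psm$itraq_labeled[idx_unlab] <- FALSE
  psm$ion_score[idx_lowconf] <-
    stats::runif(n_lowconf, identity_threshold - 10, identity_threshold)
  psm$is_unique[idx_degen] <- FALSE
  if (n_lowint > 0L) {
    cur <- rowMeans(as.matrix(psm[idx_lowint, intensity_cols()]))
    target <- stats::runif(n_lowint, 5, 25)
    for (cc in intensity_cols())
      psm[[cc]][idx_lowint] <- psm[[cc]][idx_lowint] * target / cur
  }

  n_decoy <- round(cfg$decoy_rate * n_rows)
  if (n_decoy > 0L) {
    decoys <- data.frame(
      spectrum_id = sprintf("D%06d", seq_len(n_decoy)),
      peptide = random_peptide(n_decoy),
      ion_score = stats::runif(n_decoy, identity_threshold + 1, 45),
      identity_threshold = identity_threshold,
      is_decoy = TRUE, itraq_labeled = TRUE, is_unique = TRUE,
      accessions = "", stringsAsFactors = FALSE
    )
    decoys[intensity_cols()] <-
      as.data.frame(matrix(2^stats::rnorm(n_decoy * 4, 7, 1), n_decoy, 4L))
    psm <- rbind(psm, decoys)
  }

  list(psm = validate_psm_table(psm),
       counts = list(n_real = n_rows, n_decoy = n_decoy,
                     n_unlabeled = n_unlab, n_low_confidence = n_lowconf,
                     n_degenerate = n_degen, n_low_intensity = n_lowint))
}

#' Simulate an iTRAQ 4-plex PSM table with known ground truth
#'
#' @param config a [simulation_config()].
#' @return A list of class `itraq_simulation`:
#'   * `psm` -- the PSM table ([read_psm_table()] schema);
#'   * `truth` -- list with `proteins` (per-protein `delta`,
#'     `species_class`, `is_differential`), the generator parameters
#'     (`technical_sd`, `biological_sd`, `channel_bias`) and the exact
#'     nuisance-record `counts`;
#'   * `design` -- the matching [channel_design()].
#' @examples
#' sim <- simulate_psm(simulation_config(n_proteins = 50, seed = 7))
#' nrow(sim$psm)
#' @export
simulate_psm <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  design <- if (config$design_kind == "technical") design_technical()
            else design_biological()
  proteome <- draw_proteome(config)
  exp1 <- simulate_experiment(config, proteome, design)
  structure(
    list(psm = exp1$psm,
         truth = list(proteins = proteome,
                      technical_sd = config$technical_sd,
                      biological_sd = config$biological_sd,
                      channel_bias = config$channel_bias,
                      counts = exp1$counts),
         design = design, config = config),
    class = "itraq_simulation"
  )
}

#' Simulate a linked technical + biological duplicate pair
#'
#' Generates two experiments on the same simulated proteome (same protein
#' abundances, species classes and true fold changes): a
#' technical-duplicate run, whose alpha/beta channels share all biology
#' and differ only in measurement noise and channel bias, and a
#' biological-duplicate run with four animals.  The pair supports the
#' variance decomposition: sigma_S from the biological run carries
#' technical + biological error, sigma_S(t) from the technical run
#' carries technical error only.
#'
#' @param config a [simulation_config()]; `design_kind` is overridden per
#'   experiment.
#' @return List with elements `technical` and `biological`, each an
#'   `itraq_simulation` as from [simulate_psm()].
#' @export
make_duplicate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  proteome <- draw_proteome(config)

  cfg_t <- config; cfg_t$design_kind <- "technical"
  exp_t <- simulate_experiment(cfg_t, proteome, design_technical())
  cfg_b <- config; cfg_b$design_kind <- "biological"
  exp_b <- simulate_experiment(cfg_b, proteome, design_biological())

  wrap <- function(exp, design, cfg) {
    structure(
      list(psm = exp$psm,
           truth = list(proteins = proteome,
                        technical_sd = cfg$technical_sd,
                        biological_sd = cfg$biological_sd,
                        channel_bias = cfg$channel_bias,
                        counts = exp$counts),
           design = design, config = cfg),
      class = "itraq_simulation")
  }
  list(technical = wrap(exp_t, design_technical(), cfg_t),
       biological = wrap(exp_b, design_biological(), cfg_b))
}

#' Write the ground-truth table of a simulation
#'
#' @param sim an `itraq_simulation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(sim, path) {
  utils::write.table(
    format(sim$truth$proteins, digits = 17, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
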