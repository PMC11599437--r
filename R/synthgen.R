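PHENOTYPES <- c("FW_RESIDENT", "ANADROMOUS", "CROSS_HABITAT", "BRACKISH_RESIDENT")
GENOTYPES <- c("FW_GENO", "ANAD_GENO", "BRACKISH1", "BRACKISH2")

#' Configuration of the synthetic population generator
#'
#' Returns the default generator configuration, optionally overridden. The
#' generator emulates a coastal population sampled along a salinity
#' gradient: four behavioral archetypes of lifelong Sr:Ca / delta-18O
#' trajectories, annual increment widths driven by age, sex, temperature and
#' salinity on the log10 scale, radius-at-age from gamma-distributed von
#' Bertalanffy parameters, and Dirichlet ancestry vectors concentrated on
#' the true genotype.
#'
#' Key defaults: Sr:Ca freshwater baseline 0.5 mg/g, brackish 3.0 mg/g,
#' freshwater threshold 1.5 mg/g (midpoint; the proxy separates habitats
#' clearly at these values and all three are configuration, not claims about
#' any particular system); 14 measurement points per annulus with the
#' isotope channel on every second point; increment coefficients and von
#' Bertalanffy group means set to field-calibrated values for a brackish
#' lagoon pike population; ages drawn uniformly on 4-13 years (adult,
#' length-stratified sampling -- a 1-2 year old fish has no post-natal
#' trajectory from which a migratory phenotype could be identified).
#'
#' @param ... named overrides of any default field.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_fish = c(FW_RESIDENT = 20, ANADROMOUS = 20, CROSS_HABITAT = 20,
               BRACKISH_RESIDENT = 20),
    age_range = c(4L, 13L),
    points_per_annulus = 14L,
    d18o_every = 2L,                 # isotope spot on every k-th elemental point
    sr_base_fw = 0.5,                # mg/g
    sr_base_bw = 3.0,
    sr_base_mid = 2.0,               # cross-habitat baseline
    fw_threshold = 1.5,              # mg/g, freshwater/brackish boundary
    brackish_threshold = 2.5,        # natal-origin brackish bound
    sr_noise_sd = 0.15,
    ch_osc_amp = 0.4,                # cross-habitat oscillation, mg/g
    ch_osc_cycles = 2,               # oscillations per lifetime
    # anadromous brackish residence windows, as fractions of post-natal life
    anad_windows = list(c(0.15, 0.45), c(0.65, 1.0)),
    # total ontogenetic delta-18O shift over the lifetime (warm -> cold), permil
    d18o_shift = c(FW_RESIDENT = 1.2, ANADROMOUS = 0.8,
                   CROSS_HABITAT = 2.0, BRACKISH_RESIDENT = 0.2),
    d18o_intercept = -6,
    d18o_sr_coef = 0.3,              # permil per mg/g salinity covariation
    d18o_noise_sd = 0.15,
    increment_coefs = c(intercept = 2.76, age = -0.15, age2 = 0.01,
                        sex_male = -0.03, d18o_res = -0.03, srca_z = -0.04,
                        pheno_bw = -0.02, pheno_fw = -0.08, pheno_ch = 0.04,
                        age_bw = 0.01, age_fw = 0.01, age_ch = 0.01),
    increment_id_sd = 0.032,         # individual random intercept, log10 scale
    increment_resid_sd = 0.11,
    vb_mu = list(Rinf = c(FW_RESIDENT = 2.85, ANADROMOUS = 2.85,
                          CROSS_HABITAT = 2.96, BRACKISH_RESIDENT = 2.68),
                 k = c(FW_RESIDENT = 0.12, ANADROMOUS = 0.12,
                       CROSS_HABITAT = 0.12, BRACKISH_RESIDENT = 0.11),
                 s0 = c(FW_RESIDENT = 0.62, ANADROMOUS = 0.63,
                        CROSS_HABITAT = 0.64, BRACKISH_RESIDENT = 0.81)),
    vb_tau = c(Rinf = 45, k = 4000, s0 = 150),  # gamma precisions (1/variance)
    radius_noise_sd = 0.04,          # mm
    q_alpha_own = 8,
    q_alpha_other = 0.5,
    genotype_mix = list(
      FW_RESIDENT = c(FW_GENO = 0.55, ANAD_GENO = 0.45, BRACKISH1 = 0, BRACKISH2 = 0),
      ANADROMOUS = c(FW_GENO = 0.45, ANAD_GENO = 0.55, BRACKISH1 = 0, BRACKISH2 = 0),
      CROSS_HABITAT = c(FW_GENO = 0, ANAD_GENO = 0.5, BRACKISH1 = 0.25, BRACKISH2 = 0.25),
      BRACKISH_RESIDENT = c(FW_GENO = 0, ANAD_GENO = 0, BRACKISH1 = 0.4, BRACKISH2 = 0.6)),
    fw_nonspawning_frac = 0.25,      # freshwater residents captured in July
    anad_lagoon_frac = 0.2,
    ch_lagoon_frac = 0.6,
    p_female = 0.66,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0)
    stop_named(unknown[1], "unknown synth_config field")
  cfg[names(ov)] <- ov
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (any(cfg$n_fish < 1)) stop_named("n_fish", "all counts must be >= 1")
  if (!setequal(names(cfg$n_fish), PHENOTYPES))
    stop_named("n_fish", "must be named by the four phenotypes")
  if (cfg$age_range[1] < 1 || cfg$age_range[2] < cfg$age_range[1])
    stop_named("age_range", "need 1 <= min <= max")
  if (cfg$points_per_annulus < 1) stop_named("points_per_annulus", "must be >= 1")
  for (f in c("sr_noise_sd", "d18o_noise_sd", "increment_id_sd",
              "increment_resid_sd", "radius_noise_sd"))
    if (cfg[[f]] < 0) stop_named(f, "sd must be >= 0")
  if (cfg$sr_base_fw >= cfg$sr_base_bw)
    stop_named("sr_base_fw", "freshwater baseline must be below brackish baseline")
  if (cfg$fw_threshold >= cfg$brackish_threshold)
    stop_named("fw_threshold", "must be below brackish_threshold")
  if (cfg$q_alpha_own <= 0 || cfg$q_alpha_other <= 0)
    stop_named("q_alpha_own", "Dirichlet concentrations must be > 0")
  invisible(cfg)
}

# Planted annulus-level Sr:Ca for one phenotype (deterministic schedule;
# the excursion tests check against this). Archetype trajectories are
# defined in relative life time: the annulus' life fraction
# f = (a - 1)/(n - 1) drives migratory features, so trajectories of fish of
# different ages share one shape under the proportional time compression
# that band-constrained dynamic time warping performs.
sr_annulus_level <- function(phenotype, annuli, cfg, n_annuli = max(annuli)) {
  f <- if (n_annuli > 1) (annuli - 1) / (n_annuli - 1) else rep(0, length(annuli))
  switch(phenotype,
    FW_RESIDENT = rep(cfg$sr_base_fw, length(annuli)),
    BRACKISH_RESIDENT = rep(cfg$sr_base_bw, length(annuli)),
    ANADROMOUS = {
      in_window <- Reduce(`|`, lapply(cfg$anad_windows, function(w)
        f >= w[1] & f <= w[2]))
      ifelse(annuli == 1, cfg$sr_base_fw,
             ifelse(in_window, cfg$sr_base_bw, cfg$sr_base_fw))
    },
    CROSS_HABITAT = cfg$sr_base_mid +
      cfg$ch_osc_amp * sin(2 * pi * cfg$ch_osc_cycles * f),
    stop_named("phenotype", paste("unknown phenotype label:", phenotype)))
}

#' Planted brackish excursion count for a synthetic phenotype
#'
#' The number of habitat excursions the generator plants in a transect of
#' `n_annuli` years, against which excursion detection can be checked.
#'
#' @param phenotype archetype label.
#' @param n_annuli number of annuli.
#' @param config a [synth_config()].
#' @return Integer count of planted cross-threshold runs after the natal year.
#' @export
planted_excursions <- function(phenotype, n_annuli, config = synth_config()) {
  lev <- sr_annulus_level(phenotype, seq_len(n_annuli), config, n_annuli)
  natal_high <- lev[1] > config$fw_threshold
  opposite <- (lev > config$fw_threshold) != natal_high
  r <- rle(opposite)
  sum(r$values & r$lengths >= 1L)
}

#' Simulate one otolith transect
#'
#' Generates a core-to-edge transect for one fish of a given archetype:
#' freshwater residents sit at the freshwater Sr:Ca baseline for life;
#' anadromous fish start at the freshwater baseline and then oscillate
#' across the freshwater/brackish boundary on a fixed schedule; brackish
#' residents sit at the brackish baseline; the cross-habitat archetype
#' oscillates around an intermediate baseline without ever dropping below
#' the freshwater threshold. delta-18O tracks Sr:Ca (salinity covariation)
#' plus a phenotype-specific ontogenetic trend (warm juvenile to cold adult
#' habitats) and is sampled on a coarser grid than the elemental channel.
#' The spatial grid follows an individual von Bertalanffy radius curve.
#'
#' @param phenotype one of `FW_RESIDENT`, `ANADROMOUS`, `CROSS_HABITAT`,
#'   `BRACKISH_RESIDENT`.
#' @param n_annuli number of annuli (>= 1).
#' @param config a [synth_config()].
#' @param fish_id id string for the output rows.
#' @param vb optional named vector `c(Rinf=, k=, s0=)` of individual growth
#'   parameters; drawn from the group-level gamma distributions if `NULL`.
#' @return A `transect` data frame (`fish_id`, `distance_um`, `annulus`,
#'   `sr_ca`, `d18o` with `NA` on elemental-only rows).
#' @export
simulate_transect <- function(phenotype, n_annuli, config = synth_config(),
                              fish_id = "F001", vb = NULL) {
  if (n_annuli < 1) stop_named("n_annuli", "must be >= 1")
  if (!phenotype %in% PHENOTYPES)
    stop_named("phenotype", paste("unknown phenotype label:", phenotype))
  cfg <- config
  if (is.null(vb)) vb <- draw_vb_individual(phenotype, cfg)
  radii <- vb_radius(0:n_annuli, vb["Rinf"], vb["k"], -vb["s0"]) * 1000  # um
  ppa <- cfg$points_per_annulus
  ann <- rep(seq_len(n_annuli), each = ppa)
  frac <- rep((seq_len(ppa) - 0.5) / ppa, n_annuli)
  dist_um <- radii[ann] + frac * (radii[ann + 1] - radii[ann])
  lev <- sr_annulus_level(phenotype, seq_len(n_annuli), cfg, n_annuli)
  sr <- pmax(0, lev[ann] + rnorm(length(ann), 0, cfg$sr_noise_sd))
  f_life <- ((ann - 1) + frac) / n_annuli  # life fraction of each point
  iso_rows <- seq(1, length(ann), by = cfg$d18o_every)
  d18o <- rep(NA_real_, length(ann))
  d18o[iso_rows] <- cfg$d18o_intercept + cfg$d18o_sr_coef * lev[ann[iso_rows]] +
    cfg$d18o_shift[[phenotype]] * f_life[iso_rows] +
    rnorm(length(iso_rows), 0, cfg$d18o_noise_sd)
  structure(data.frame(fish_id = fish_id, distance_um = dist_um, annulus = ann,
                       sr_ca = sr, d18o = d18o, stringsAsFactors = FALSE),
            class = c("transect", "data.frame"))
}

draw_vb_individual <- function(phenotype, cfg) {
  draw <- function(mu, tau) rgamma(1, shape = mu^2 * tau, rate = mu * tau)
  c(Rinf = draw(cfg$vb_mu$Rinf[[phenotype]], cfg$vb_tau[["Rinf"]]),
    k = draw(cfg$vb_mu$k[[phenotype]], cfg$vb_tau[["k"]]),
    s0 = draw(cfg$vb_mu$s0[[phenotype]], cfg$vb_tau[["s0"]]))
}

#' Simulate annual increment widths from the log10 growth model
#'
#' One row per fish-year. The generative model is the linear predictor of
#' the increment growth model (intercept, age, age squared, sex, annual
#' delta-18O residual, annual Sr:Ca z-score, phenotype contrasts against the
#' anadromous reference and age-by-phenotype interactions) plus an
#' individual random intercept and residual noise, all on the log10 scale;
#' increment widths are back-transformed to micrometres.
#'
#' @param fish fish table with `fish_id`, `age`, `sex`, `phenotype`.
#' @param covariates fish-year table with `fish_id`, `annulus`, `d18o_res`,
#'   `srca_z` (e.g. from [annual_means_table()]).
#' @param config a [synth_config()].
#' @return Growth-record data frame: `fish_id`, `lifeyear`, `increment_um`,
#'   `annual_d18o_res`, `annual_srca_z`, `sex`, `phenotype`.
#' @export
simulate_increments <- function(fish, covariates, config = synth_config()) {
  cfg <- config
  b <- cfg$increment_coefs
  rows <- merge(fish[, c("fish_id", "age", "sex", "phenotype")],
                covariates[, c("fish_id", "annulus", "d18o_res", "srca_z")],
                by = "fish_id")
  if (any(rows$annulus > rows$age))
    stop_named("covariates", "fish-year beyond the fish's age")
  if (any(!is.finite(rows$d18o_res)) || any(!is.finite(rows$srca_z)))
    stop_named("covariates", "non-finite covariate")
  b_id <- setNames(rnorm(nrow(fish), 0, cfg$increment_id_sd), fish$fish_id)
  a <- rows$annulus
  lp <- b["intercept"] + b["age"] * a + b["age2"] * a^2 +
    b["sex_male"] * (rows$sex == "M") +
    b["d18o_res"] * rows$d18o_res + b["srca_z"] * rows$srca_z +
    b["pheno_bw"] * (rows$phenotype == "BRACKISH_RESIDENT") +
    b["pheno_fw"] * (rows$phenotype == "FW_RESIDENT") +
    b["pheno_ch"] * (rows$phenotype == "CROSS_HABITAT") +
    b["age_bw"] * a * (rows$phenotype == "BRACKISH_RESIDENT") +
    b["age_fw"] * a * (rows$phenotype == "FW_RESIDENT") +
    b["age_ch"] * a * (rows$phenotype == "CROSS_HABITAT") +
    b_id[rows$fish_id]
  log10_inc <- lp + rnorm(nrow(rows), 0, cfg$increment_resid_sd)
  out <- data.frame(fish_id = rows$fish_id, lifeyear = rows$annulus,
                    increment_um = 10^log10_inc,
                    annual_d18o_res = rows$d18o_res,
                    annual_srca_z = rows$srca_z,
                    sex = rows$sex, phenotype = rows$phenotype,
                    stringsAsFactors = FALSE)
  out[order(out$fish_id, out$lifeyear), ]
}

#' Simulate one ancestry (Q) vector
#'
#' Dirichlet draw over the four genetic clusters, with concentration
#' `q_alpha_own` on the true genotype and `q_alpha_other` elsewhere, so the
#' expected mass on the own cluster is `alpha_own / sum(alpha)`.
#'
#' @param true_genotype one of the four genotype labels.
#' @param config a [synth_config()].
#' @return Numeric probability vector of length 4 (sums to 1), named by
#'   genotype.
#' @export
simulate_q_vector <- function(true_genotype, config = synth_config()) {
  if (!true_genotype %in% GENOTYPES)
    stop_named("true_genotype", paste("unknown genotype:", true_genotype))
  alpha <- setNames(rep(config$q_alpha_other, 4), GENOTYPES)
  alpha[true_genotype] <- config$q_alpha_own
  if (any(alpha <= 0)) stop_named("q_alpha_other", "concentrations must be > 0")
  g <- rgamma(4, shape = alpha, rate = 1)
  setNames(g / sum(g), GENOTYPES)
}

#' Simulate a complete synthetic dataset with known ground truth
#'
#' Generates all tables of the study design in one deterministic draw: fish
#' metadata (capture habitat/season assigned per phenotype: brackish
#' residents in lagoons, freshwater residents in tributaries — a configured
#' fraction of them outside the spawning season — and anadromous /
#' cross-habitat fish split between lagoon and tributary captures by
#' configurable mixing proportions), otolith transects, annual growth
#' records, radius-at-age observations, the ancestry Q-matrix, and a truth
#' table holding each fish's planted phenotype, genotype and von Bertalanffy
#' parameters.
#'
#' @param config a [synth_config()]; `config$seed` fully determines the
#'   output.
#' @return A list of class `synth_dataset` with elements `fish`,
#'   `transects` (a `transect_set`), `growth`, `radii`, `qmat`, `truth`,
#'   `config`.
#' @export
simulate_population <- function(config = synth_config()) {
  cfg <- if (inherits(config, "synth_config")) config else
    do.call(synth_config, config)
  set.seed(cfg$seed)
  n_total <- sum(cfg$n_fish)
  phenos <- rep(names(cfg$n_fish), cfg$n_fish)
  ids <- sprintf("F%03d", seq_len(n_total))
  ages <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n_total, replace = TRUE)
  sex <- ifelse(runif(n_total) < cfg$p_female, "F", "M")
  lagoons <- c("NRBC", "WRBC", "GB")
  tribs <- c("BARTHE", "SEHROWBACH", "PEENE", "ZIESE")
  habitat <- character(n_total); season <- character(n_total)
  location <- character(n_total)
  for (i in seq_len(n_total)) {
    p <- phenos[i]
    if (p == "BRACKISH_RESIDENT") {
      habitat[i] <- "lagoon"; season[i] <- "non_spawning"
      location[i] <- sample(lagoons, 1)
    } else if (p == "FW_RESIDENT") {
      habitat[i] <- "tributary"
      season[i] <- if (runif(1) < cfg$fw_nonspawning_frac) "non_spawning" else "spawning"
      location[i] <- sample(tribs, 1)
    } else {
      frac <- if (p == "ANADROMOUS") cfg$anad_lagoon_frac else cfg$ch_lagoon_frac
      if (runif(1) < frac) {
        habitat[i] <- "lagoon"; season[i] <- "non_spawning"
        location[i] <- sample(lagoons, 1)
      } else {
        habitat[i] <- "tributary"; season[i] <- "spawning"
        location[i] <- sample(tribs, 1)
      }
    }
  }
  fish <- data.frame(fish_id = ids, sex = sex, age = ages,
                     total_length_mm = round(350 + 45 * ages + rnorm(n_total, 0, 40)),
                     capture_location = location, capture_habitat = habitat,
                     capture_season = season, phenotype = phenos,
                     stringsAsFactors = FALSE)

  vb_truth <- t(vapply(seq_len(n_total),
                       function(i) draw_vb_individual(phenos[i], cfg), numeric(3)))
  transects <- lapply(seq_len(n_total), function(i)
    simulate_transect(phenos[i], ages[i], cfg, fish_id = ids[i], vb = vb_truth[i, ]))
  names(transects) <- ids
  transects <- structure(transects, class = "transect_set")

  radii <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    t <- seq_len(ages[i])
    data.frame(fish_id = ids[i], age = t,
               radius = vb_radius(t, vb_truth[i, "Rinf"], vb_truth[i, "k"],
                                  -vb_truth[i, "s0"]) +
                 rnorm(length(t), 0, cfg$radius_noise_sd),
               stringsAsFactors = FALSE)
  }))

  paired <- lapply(transects, pair_channels)
  corrected <- correct_temperature_proxy(paired)
  annual <- annual_means_table(corrected)
  growth <- simulate_increments(fish, annual, cfg)

  genotype <- vapply(phenos, function(p)
    sample(GENOTYPES, 1, prob = cfg$genotype_mix[[p]]), character(1))
  qmat <- t(vapply(genotype, function(g) simulate_q_vector(g, cfg), numeric(4)))
  qmat <- data.frame(fish_id = ids, qmat, stringsAsFactors = FALSE)
  names(qmat) <- c("fish_id", paste0("q", 1:4))

  truth <- data.frame(fish_id = ids, true_phenotype = phenos,
                      true_genotype = unname(genotype),
                      R_inf = vb_truth[, "Rinf"], k = vb_truth[, "k"],
                      t0 = -vb_truth[, "s0"], stringsAsFactors = FALSE)

  structure(list(fish = fish, transects = transects, growth = growth,
                 radii = radii, qmat = qmat, truth = truth, config = cfg),
            class = "synth_dataset")
}

#' Write a synthetic dataset as CSV files
#'
#' Writes `transects.csv`, `fish.csv`, `increments.csv`, `radii.csv`,
#' `qmatrix.csv` and `truth.csv` in the dialects the readers of this package
#' consume (UTF-8, comma-separated, dot decimal).
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("transects.csv", "fish.csv", "increments.csv",
                            "radii.csv", "qmatrix.csv", "truth.csv"))
  write.csv(do.call(rbind, dataset$transects), paths[1], row.names = FALSE)
  fishcols <- setdiff(names(dataset$fish), "phenotype")
  write.csv(dataset$fish[, fishcols], paths[2], row.names = FALSE)
  gcols <- c("fish_id", "lifeyear", "increment_um", "annual_d18o_res", "annual_srca_z")
  write.csv(dataset$growth[, gcols], paths[3], row.names = FALSE)
  write.csv(dataset$radii, paths[4], row.names = FALSE)
  write.csv(dataset$qmat, paths[5], row.names = FALSE)
  write.csv(dataset$truth, paths[6], row.names = FALSE)
  invisible(paths)
}
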