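pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = TRUE,                       # generate inputs with synth_config()
    synth = list(),                        # overrides for synth_config()
    paths = list(transects = NULL, fish = NULL, increments = NULL,
                 radii = NULL, qmatrix = NULL, out = "otomigrate_out"),
    thresholds = list(fw_srca = 1.5, brackish_srca = 2.5, tau = 0.7,
                      fdr_alpha = 0.05, min_run = 2),
    dtw = list(window_frac = 0.05, k_min = 2, k_max = 10),
    permanova = list(n_perm = 9999),
    mcmc = list(chains = 2, iter = 8000, burnin = 4000, thin = 4),
    stages = c("transects", "cluster", "phenotype", "growth_lmm",
               "growth_vb", "genetics"))
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop_named(paste0(path, k), "unknown configuration key")
    if (is.list(base[[k]]) && is.list(override[[k]]) && k != "synth") {
      base[[k]] <- merge_config(base[[k]], override[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list), fills defaults
#' (DTW window 0.05, cluster range 2-10, assignment threshold 0.7, 9999
#' permutations, FDR alpha 0.05), rejects unknown keys, and checks value
#' ranges. An empty file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL`.
#' @param config optional list of overrides (applied after the file).
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(path = NULL, config = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_named("path", paste("missing file:", path))
    from_file <- yaml::read_yaml(path)
    if (!is.null(from_file)) cfg <- merge_config(cfg, from_file)
  }
  cfg <- merge_config(cfg, config)
  th <- cfg$thresholds
  if (!(th$tau > 0.5 && th$tau <= 1))
    stop_named("thresholds.tau", "must be in (0.5, 1]")
  if (th$fw_srca >= th$brackish_srca)
    stop_named("thresholds.fw_srca", "must be below brackish_srca")
  if (!(cfg$dtw$window_frac > 0 && cfg$dtw$window_frac <= 1))
    stop_named("dtw.window_frac", "must be in (0, 1]")
  if (cfg$dtw$k_min < 2 || cfg$dtw$k_max < cfg$dtw$k_min)
    stop_named("dtw.k_min", "need 2 <= k_min <= k_max")
  if (cfg$permanova$n_perm < 1) stop_named("permanova.n_perm", "must be >= 1")
  if (th$min_run < 1) stop_named("thresholds.min_run", "must be >= 1")
  bad_stage <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stage) > 0)
    stop_named("stages", paste("unknown stage:", bad_stage[1]))
  if (!cfg$simulate) {
    for (f in c("transects", "fish")) {
      if (is.null(cfg$paths[[f]]) || !file.exists(cfg$paths[[f]]))
        stop_named(paste0("paths.", f), "input file required when simulate is false")
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — read/simulate inputs, pair and
#' salinity-correct transects, cluster lifelong trajectories per capture
#' pool (lagoon and tributary fish separately), assign phenotypes and
#' validate them by jackknife reclassification, fit the increment mixed
#' model, fit the hierarchical von Bertalanffy model per phenotype, run the
#' genetics stage (threshold assignment, PERMANOVA, pairwise follow-up,
#' ecotype delimitation) — writing each stage's CSV/JSON artifacts into the
#' output directory plus a machine-readable run manifest (config, seeds,
#' artifact checksums, package version). The manifest hash is
#' deterministic: the same configuration and seed reproduce it exactly.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a list,
#'   validated on the way in).
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a report list with the stage results and
#'   `manifest` (including `manifest_hash`).
#' @export
run_pipeline <- function(config = validate_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    config <- validate_config(config = config)
  cfg <- config
  out_dir <- cfg$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_names <- pipeline_defaults()$stages
  stage_seeds <- setNames(derive_seeds(cfg$seed, length(stage_names)), stage_names)
  report <- list()
  artifacts <- character(0)
  keep <- function(path) artifacts <<- c(artifacts, path)
  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(NULL)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial artifacts in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  # inputs
  if (isTRUE(cfg$simulate)) {
    synth_args <- cfg$synth
    if (is.null(synth_args$seed)) synth_args$seed <- stage_seeds[["transects"]]
    scfg <- do.call(synth_config, synth_args)
    ds <- simulate_population(scfg)
    write_dataset(ds, out_dir)
    keep(file.path(out_dir, c("transects.csv", "fish.csv", "increments.csv",
                              "radii.csv", "qmatrix.csv", "truth.csv")))
    transects <- ds$transects
    fish <- ds$fish
    growth <- ds$growth
    radii <- ds$radii
    qmat <- ds$qmat
    say("inputs: simulated %d fish (%d transect points)",
        nrow(fish), sum(vapply(transects, nrow, integer(1))))
  } else {
    transects <- read_transects(cfg$paths$transects)
    fish <- read_fish_records(cfg$paths$fish)
    growth <- if (!is.null(cfg$paths$increments)) read.csv(cfg$paths$increments) else NULL
    radii <- if (!is.null(cfg$paths$radii)) read.csv(cfg$paths$radii) else NULL
    qmat <- if (!is.null(cfg$paths$qmatrix)) read_q_matrix(cfg$paths$qmatrix) else NULL
    say("inputs: read %d fish, %d transects", nrow(fish), length(transects))
  }

  annual <- NULL
  corrected <- NULL
  report$transects <- run_stage("transects", function() {
    paired <- lapply(transects, pair_channels)
    corrected <<- correct_temperature_proxy(paired)
    annual <<- annual_means_table(corrected)
    write.csv(annual, file.path(out_dir, "annual_means.csv"), row.names = FALSE)
    keep(file.path(out_dir, "annual_means.csv"))
    say("transects: %d fish in, %d fish-years out",
        length(transects), nrow(annual))
    list(n_fish = length(transects), n_fish_years = nrow(annual),
         correction = attr(corrected, "correction_fit"))
  })

  report$cluster <- run_stage("cluster", function() {
    if (is.null(corrected)) stop("transects stage disabled")
    series <- as_multiseries(corrected)
    pools <- split(fish$fish_id, fish$capture_habitat)
    res <- lapply(names(pools), function(pool) {
      ids <- intersect(pools[[pool]], names(series))
      if (length(ids) < 3) return(NULL)
      s <- series[ids]
      k_max <- min(cfg$dtw$k_max, length(ids) - 1)
      sel <- suppressWarnings(
        select_k(s, k_min = cfg$dtw$k_min, k_max = k_max,
                 window_frac = cfg$dtw$window_frac))
      dm <- distance_matrix(s, cfg$dtw$window_frac)
      write.csv(as.data.frame(dm), file.path(out_dir, paste0("dtw_", pool, ".csv")))
      write.csv(merge_list(sel$hclust),
                file.path(out_dir, paste0("dendrogram_", pool, ".csv")),
                row.names = FALSE)
      keep(file.path(out_dir, paste0(c("dtw_", "dendrogram_"), pool, ".csv")))
      say("cluster[%s]: %d fish, k = %d", pool, length(ids), sel$k_best)
      sel
    })
    names(res) <- names(pools)
    labels <- unlist(lapply(names(res), function(pool) {
      if (is.null(res[[pool]])) return(NULL)
      setNames(paste0(substr(pool, 1, 3), res[[pool]]$labels),
               names(res[[pool]]$labels))
    }))
    cl <- data.frame(fish_id = names(labels), cluster = unname(labels))
    write.csv(cl, file.path(out_dir, "clusters.csv"), row.names = FALSE)
    keep(file.path(out_dir, "clusters.csv"))
    list(per_pool = lapply(res, function(r)
      if (is.null(r)) NULL else r[c("k_best", "votes", "tied")]),
      labels = labels)
  })

  calls <- NULL
  report$phenotype <- run_stage("phenotype", function() {
    if (is.null(annual)) stop("transects stage disabled")
    labels <- if (!is.null(report$cluster)) report$cluster$labels else
      setNames(rep(NA_character_, nrow(fish)), fish$fish_id)
    calls <<- assign_phenotypes(labels, annual, fish,
                                fw_threshold = cfg$thresholds$fw_srca,
                                brackish_threshold = cfg$thresholds$brackish_srca,
                                min_run = cfg$thresholds$min_run)
    write.csv(calls, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
    keep(file.path(out_dir, "phenotypes.csv"))
    feats <- stage_features(annual)
    ok <- stats::complete.cases(feats[, -1])
    jk <- jackknife_lda(feats[ok, -1],
                        calls$phenotype[match(feats$fish_id[ok], calls$fish_id)])
    write.csv(as.data.frame(jk$confusion),
              file.path(out_dir, "confusion.csv"), row.names = FALSE)
    freq <- phenotype_frequency_report(calls, fish)
    write.csv(as.data.frame(freq$table),
              file.path(out_dir, "phenotype_frequencies.csv"), row.names = FALSE)
    keep(file.path(out_dir, c("confusion.csv", "phenotype_frequencies.csv")))
    say("phenotype: %d calls, jackknife rate %.3f", nrow(calls), jk$rate)
    list(calls = calls, jackknife = jk[c("rate", "per_class_recall", "n")],
         frequency = freq)
  })

  report$growth_lmm <- run_stage("growth_lmm", function() {
    if (is.null(growth)) stop("no increment data")
    g <- growth
    if (!"phenotype" %in% names(g)) {
      if (is.null(calls)) stop("phenotype stage disabled and no phenotype column")
      g$phenotype <- calls$phenotype[match(g$fish_id, calls$fish_id)]
    }
    if (!"sex" %in% names(g)) g$sex <- fish$sex[match(g$fish_id, fish$fish_id)]
    fit <- fit_increment_lmm(g)
    tests <- llr_term_tests(fit)
    res <- list(coefficients = fit$coefficients, varcomp = as.list(fit$varcomp),
                r2 = as.list(fit$r2), llr_tests = tests)
    write_json_artifact(res, file.path(out_dir, "lmm_summary.json"))
    keep(file.path(out_dir, "lmm_summary.json"))
    say("growth_lmm: marginal R2 %.3f, conditional %.3f",
        fit$r2["marginal"], fit$r2["conditional"])
    c(res, list(fit = fit))
  })

  report$growth_vb <- run_stage("growth_vb", function() {
    if (is.null(radii)) stop("no radius-at-age data")
    grouping <- if (!is.null(calls))
      setNames(calls$phenotype, calls$fish_id) else
      setNames(fish$phenotype, fish$fish_id)
    post <- suppressWarnings(
      fit_vb_hierarchical(radii, grouping, n_chains = cfg$mcmc$chains,
                          n_iter = cfg$mcmc$iter, n_burnin = cfg$mcmc$burnin,
                          thin = cfg$mcmc$thin,
                          seed = stage_seeds[["growth_vb"]]))
    write.csv(post$summary, file.path(out_dir, "vb_summary.csv"), row.names = FALSE)
    m <- as.matrix(post$draws)
    dr <- data.frame(chain = rep(seq_along(post$draws),
                                 each = nrow(post$draws[[1]])),
                     iter = rep(seq_len(nrow(post$draws[[1]])),
                                length(post$draws)))
    write.csv(cbind(dr, m), file.path(out_dir, "vb_draws.csv"), row.names = FALSE)
    diffs <- group_differences(post)
    write.csv(diffs, file.path(out_dir, "vb_differences.csv"), row.names = FALSE)
    keep(file.path(out_dir, c("vb_summary.csv", "vb_draws.csv",
                              "vb_differences.csv")))
    say("growth_vb: %d groups, converged = %s",
        length(post$groups), post$converged)
    list(summary = post$summary, converged = post$converged, differences = diffs)
  })

  report$genetics <- run_stage("genetics", function() {
    if (is.null(qmat)) stop("no Q-matrix data")
    if (is.null(calls)) stop("phenotype stage disabled")
    ids <- intersect(qmat$fish_id, calls$fish_id)
    Y <- as.matrix(qmat[match(ids, qmat$fish_id), grep("^q", names(qmat))])
    phen <- calls$phenotype[match(ids, calls$fish_id)]
    keep_fish <- phen != "UNCLASSIFIED"
    Y <- Y[keep_fish, , drop = FALSE]; phen <- phen[keep_fish]
    omni <- permanova(Y, phen, n_perm = cfg$permanova$n_perm,
                      seed = stage_seeds[["genetics"]])
    pw <- pairwise_permanova(Y, phen, n_perm = cfg$permanova$n_perm,
                             seed = stage_seeds[["genetics"]],
                             fdr_alpha = cfg$thresholds$fdr_alpha)
    eco <- infer_ecotypes(pw, sort(unique(phen)),
                          alpha = cfg$thresholds$fdr_alpha)
    geno <- threshold_assign(qmat[match(ids, qmat$fish_id), ][keep_fish, ],
                             tau = cfg$thresholds$tau)
    loc <- fish$capture_location[match(ids[keep_fish], fish$fish_id)]
    loc_test <- tryCatch(genotype_location_test(geno, loc),
                         error = function(e) list(error = conditionMessage(e)))
    res <- list(permanova = unclass(omni), n_ecotypes = length(eco$blocks),
                ecotypes = lapply(eco$blocks, identity),
                genotype_counts = as.list(table(geno)),
                location_test = loc_test[setdiff(names(loc_test), "expected")])
    write_json_artifact(res, file.path(out_dir, "genetics.json"))
    write.csv(pw, file.path(out_dir, "pairwise_permanova.csv"), row.names = FALSE)
    keep(file.path(out_dir, c("genetics.json", "pairwise_permanova.csv")))
    say("genetics: F = %.2f, R2 = %.3f, %d ecotypes",
        omni$pseudo_F, omni$r_squared, length(eco$blocks))
    c(res, list(pairwise = pw, partition = eco))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("otomigrate")),
    seed = cfg$seed, stage_seeds = as.list(stage_seeds),
    config = unclass(cfg),
    artifacts = {
      rel <- sort(basename(artifacts))
      md5 <- tools::md5sum(file.path(out_dir, rel))
      as.list(setNames(unname(md5), rel))
    })
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE, force = TRUE)
  tmp <- tempfile(); writeLines(manifest_json, tmp)
  manifest$manifest_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  write_json_artifact(manifest, file.path(out_dir, "manifest.json"))
  say("pipeline done: manifest %s", manifest$manifest_hash)
  report$manifest <- manifest
  invisible(report)
}
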