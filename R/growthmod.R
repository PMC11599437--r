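#' Fit the random-intercept mixed model of log10 increment widths
#'
#' REML fit of `log10(increment) ~ age + age^2 + sex + d18o_res + srca_z +
#' phenotype + age:phenotype + (1 | fish_id)` with treatment contrasts
#' against the anadromous phenotype and female sex (an ML refit is retained
#' for likelihood-ratio testing). Age enters uncentred with an explicit
#' quadratic term. Optional terms can be switched off for reduced models.
#'
#' @param records growth-record data frame with columns `fish_id`,
#'   `lifeyear`, `increment_um`, `annual_d18o_res`, `annual_srca_z`, `sex`,
#'   `phenotype`.
#' @param phenotype_ref,sex_ref reference levels for the treatment
#'   contrasts.
#' @param include_phenotype include phenotype main effect and the
#'   age-by-phenotype interaction (default `TRUE`).
#' @return Object of class `increment_lmm`: list with `reml` and `ml`
#'   (`lme4::lmerMod` fits), `coefficients` (estimate/SE/t table),
#'   `varcomp` (random-intercept and residual variances), `r2` (marginal,
#'   conditional), `formula`.
#' @export
fit_increment_lmm <- function(records, phenotype_ref = "ANADROMOUS",
                              sex_ref = "F", include_phenotype = TRUE) {
  d <- records
  need <- c("fish_id", "lifeyear", "increment_um", "annual_d18o_res",
            "annual_srca_z", "sex")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop_named("records", paste("missing column(s):",
                                paste(missing_cols, collapse = ", ")))
  if (any(d$increment_um <= 0)) stop_named("increment_um", "must be > 0")
  nrec <- table(d$fish_id)
  if (sum(nrec >= 2) < 2)
    stop_named("records", "need >= 2 fish with >= 2 records each")
  d$log10_inc <- log10(d$increment_um)
  d$age <- d$lifeyear
  d$sex <- stats::relevel(factor(d$sex), ref = sex_ref)
  if (include_phenotype) {
    if (length(unique(d$phenotype)) < 2)
      stop_named("phenotype", "constant phenotype: non-identifiable design")
    d$phenotype <- stats::relevel(factor(d$phenotype), ref = phenotype_ref)
    f <- log10_inc ~ age + I(age^2) + sex + annual_d18o_res + annual_srca_z +
      phenotype + age:phenotype + (1 | fish_id)
  } else {
    f <- log10_inc ~ age + I(age^2) + sex + annual_d18o_res + annual_srca_z +
      (1 | fish_id)
  }
  reml <- lme4::lmer(f, data = d, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
  ml <- lme4::lmer(f, data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(reml)$coefficients
  vc <- as.data.frame(lme4::VarCorr(reml))
  varcomp <- c(id = vc$vcov[vc$grp == "fish_id"],
               residual = vc$vcov[vc$grp == "Residual"])
  out <- list(reml = reml, ml = ml,
              coefficients = data.frame(term = rownames(sm),
                                        estimate = sm[, "Estimate"],
                                        se = sm[, "Std. Error"],
                                        t_value = sm[, "t value"],
                                        row.names = NULL),
              varcomp = varcomp, formula = f, data = d)
  class(out) <- "increment_lmm"
  out$r2 <- nakagawa_r2(out)
  out
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared for a Gaussian random-intercept model:
#' marginal = var(fixed-effect predictor) / (var(fixed) + random-intercept
#' variance + residual variance); conditional adds the random-intercept
#' variance to the numerator. Conditional >= marginal always.
#'
#' @param fit an `increment_lmm` (or a bare `lmerMod`).
#' @return Named vector `c(marginal=, conditional=)`.
#' @export
nakagawa_r2 <- function(fit) {
  mod <- if (inherits(fit, "increment_lmm")) fit$reml else fit
  X <- lme4::getME(mod, "X")
  var_f <- var(as.vector(X %*% lme4::fixef(mod)))
  vc <- as.data.frame(lme4::VarCorr(mod))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Log-likelihood-ratio tests of the fixed terms
#'
#' Each reported term is dropped in turn from the ML fit and the full and
#' reduced models compared by LLR = 2 * (logLik_full - logLik_reduced),
#' with df the parameter difference and p from the upper chi-squared tail.
#' The age-by-phenotype interaction is dropped on its own; dropping a
#' marginal term that participates in the interaction (`age`, `phenotype`)
#' removes the interaction with it, keeping the comparison nested.
#'
#' @param fit an `increment_lmm`.
#' @return Data frame `term`, `llr`, `df`, `p_value`.
#' @export
llr_term_tests <- function(fit) {
  ml <- fit$ml
  d <- fit$data
  has_pheno <- "phenotype" %in% all.vars(fit$formula)
  drops <- list(
    `I(age^2)` = . ~ . - I(age^2),
    sex = . ~ . - sex,
    annual_d18o_res = . ~ . - annual_d18o_res,
    annual_srca_z = . ~ . - annual_srca_z)
  if (has_pheno) {
    drops <- c(list(`age:phenotype` = . ~ . - age:phenotype,
                    phenotype = . ~ . - phenotype - age:phenotype),
               drops,
               list(age = . ~ . - age - age:phenotype))
  } else {
    drops <- c(drops, list(age = . ~ . - age))
  }
  rows <- lapply(names(drops), function(term) {
    red <- stats::update(ml, drops[[term]], data = d,
                         control = lme4::lmerControl(check.conv.singular = "ignore"))
    llr <- as.numeric(2 * (logLik(ml) - logLik(red)))
    df <- attr(logLik(ml), "df") - attr(logLik(red), "df")
    if (df <= 0) stop_named("term", paste("non-nested comparison for", term))
    data.frame(term = term, llr = llr, df = df,
               p_value = pchisq(llr, df, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' von Bertalanffy radius at age
#'
#' `R(t) = R_inf * (1 - exp(-k * (t - t0)))`: asymptotic radius `R_inf`,
#' growth completion coefficient `k`, theoretical age at radius zero `t0`
#' (usually negative for otoliths, which have a positive radius at hatch).
#' Strictly increasing in `t`, zero at `t = t0`, asymptote `R_inf`.
#'
#' @param t age (years); vectorized.
#' @param Rinf,k,t0 growth parameters, `Rinf > 0`, `k > 0`.
#' @return Radius in the units of `Rinf`.
#' @export
vb_radius <- function(t, Rinf, k, t0) {
  if (any(Rinf <= 0) || any(k <= 0)) stop_named("Rinf", "Rinf and k must be > 0")
  Rinf * (1 - exp(-k * (t - t0)))
}

# Crude pooled von Bertalanffy start values from the radius-at-age table:
# Rinf a little above the largest radius, k and s0 from a log-linear
# regression of 1 - R/Rinf on age. Used to center hyperpriors and
# initialize chains.
vb_crude_start <- function(radii) {
  Rinf0 <- 1.05 * max(radii$radius)
  frac <- pmin(pmax(1 - radii$radius / Rinf0, 1e-4), 1 - 1e-4)
  fit <- lm(log(frac) ~ radii$age)
  k0 <- max(-coef(fit)[2], 0.01)
  # log(1 - R/Rinf) = -k * s0 - k * t, so s0 = -intercept / k
  s00 <- max(-coef(fit)[1] / k0, 0.05)
  c(Rinf = Rinf0, k = unname(k0), s0 = unname(s00))
}

#' Hierarchical Bayesian von Bertalanffy growth model
#'
#' Fits individual-level von Bertalanffy curves to radius-at-age data with
#' radii nested in individuals and individuals nested in groups
#' (phenotypes, genotypes or ecotypes). Individual parameters are
#' gamma-distributed around group-level means with group-level precisions
#' (gamma(mean mu, precision tau) parameterized as shape = mu^2 tau, rate =
#' mu tau). Because otolith `t0` estimates are negative while the gamma
#' support is positive, the model works with `s0 = -t0 ~ gamma` and reports
#' `t0 = -s0`. Observation error on radius is Gaussian with a half-normal
#' prior on its sd scaled to the data range; hyperpriors on the group means
#' are weakly-informative gammas centred on pooled crude estimates, and
#' half-normal on the precisions.
#'
#' Sampling is by an adaptive Metropolis-within-Gibbs MCMC: because the von
#' Bertalanffy curve is far from its asymptote over observable ages, each
#' fish's (Rinf, k, s0) posterior is a strongly correlated ridge, so the
#' three parameters of a fish are proposed as one joint block (on the log
#' scale) with a covariance adapted from the chain history during burn-in;
#' group-level (mean, precision) pairs and the observation sd get their own
#' adaptive blocks. Group-level quantities are summarized with 95% credible
#' intervals, R-hat and effective sample size, and the fit is flagged
#' non-converged (never silently accepted) unless all group-level R-hat
#' < 1.01 and ESS > 400.
#'
#' @param radii data frame `fish_id`, `age`, `radius`; every fish needs at
#'   least 2 observations.
#' @param groups named vector mapping fish id to group label.
#' @param n_chains,n_iter,n_burnin MCMC configuration; `n_iter` counts
#'   post-burn-in iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer; fixes the per-chain RNG streams, so identical seeds
#'   give identical draws.
#' @return Object of class `vb_posterior`: list with `draws`
#'   (`coda::mcmc.list` of group-level parameters and `sd_obs`), `summary`
#'   (per group and parameter: posterior median and 95% credible interval,
#'   R-hat, ESS; `t0` rows are reported on the `t0 = -s0` scale),
#'   `converged`, `groups`, `mcmc` settings.
#' @export
fit_vb_hierarchical <- function(radii, groups, n_chains = 2, n_iter = 10000,
                                n_burnin = 5000, thin = 5, seed = 1) {
  if (!all(c("fish_id", "age", "radius") %in% names(radii)))
    stop_named("radii", "need columns fish_id, age, radius")
  radii <- radii[order(match(radii$fish_id, unique(radii$fish_id)), radii$age), ]
  cnt <- table(radii$fish_id)
  if (any(cnt < 2)) stop_named("radii", "every fish needs >= 2 radius observations")
  ids <- unique(radii$fish_id)
  if (!all(ids %in% names(groups)))
    stop_named("groups", "every fish needs a group label")
  grp_f <- factor(unname(groups[ids]))
  if (any(table(grp_f) == 0)) stop_named("groups", "empty group")
  glev <- levels(grp_f)
  G <- length(glev)
  start <- vb_crude_start(radii)
  centers <- unname(start[c("Rinf", "k", "s0")])
  ht <- 10 / (0.05 * centers)^2  # half-normal sd on group precisions
  obs_scale <- 0.1 * diff(range(radii$radius)) + 1e-6
  sub_seeds <- derive_seeds(seed, n_chains)
  par_names <- c(paste0("mu_Rinf[", seq_len(G), "]"),
                 paste0("mu_k[", seq_len(G), "]"),
                 paste0("mu_s0[", seq_len(G), "]"),
                 paste0("tau_Rinf[", seq_len(G), "]"),
                 paste0("tau_k[", seq_len(G), "]"),
                 paste0("tau_s0[", seq_len(G), "]"), "sd_obs")
  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(sub_seeds[ch])
    jit <- exp(rnorm(3, 0, 0.05))
    res <- vb_chain_cpp(R = radii$radius, age = radii$age,
                        fish = as.integer(factor(radii$fish_id, levels = ids)),
                        grp = as.integer(grp_f), G = G, centers = centers,
                        ht = ht, obs_scale = obs_scale,
                        init_ind = c(rep(centers[1] * jit[1], length(ids)),
                                     rep(centers[2] * jit[2], length(ids)),
                                     rep(centers[3] * jit[3], length(ids))),
                        init_grp = c(rep(centers[1] * jit[1], G),
                                     rep(centers[2] * jit[2], G),
                                     rep(centers[3] * jit[3], G)),
                        init_sd = obs_scale / 2,
                        n_iter = n_iter + n_burnin, n_burnin = n_burnin,
                        thin = thin)
    d <- res$draws
    colnames(d) <- par_names
    coda::mcmc(d, start = n_burnin + 1, thin = thin)
  })
  draws <- coda::mcmc.list(chains)
  m <- as.matrix(draws)
  rhat <- tryCatch(
    coda::gelman.diag(draws, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) setNames(rep(NA_real_, ncol(m)), colnames(m)))
  ess <- coda::effectiveSize(draws)
  summarize <- function(par, label, flip = FALSE) {
    cols <- grep(paste0("^", par, "\\["), colnames(m))
    do.call(rbind, lapply(seq_along(cols), function(j) {
      x <- m[, cols[j]]
      if (flip) x <- -x
      q <- quantile(x, c(0.025, 0.5, 0.975))
      data.frame(group = glev[j], parameter = label,
                 median = unname(q[2]),
                 lower = unname(min(q[1], q[3])), upper = unname(max(q[1], q[3])),
                 rhat = unname(rhat[cols[j]]), ess = unname(ess[cols[j]]),
                 stringsAsFactors = FALSE)
    }))
  }
  summ <- rbind(summarize("mu_Rinf", "Rinf"), summarize("mu_k", "k"),
                summarize("mu_s0", "t0", flip = TRUE))
  grp_cols <- grep("^mu_", colnames(m))
  converged <- all(rhat[grp_cols] < 1.01, na.rm = FALSE) &&
    all(ess[grp_cols] > 400)
  if (is.na(converged)) converged <- FALSE
  if (!converged)
    warning("MCMC not converged at R-hat < 1.01 / ESS > 400 for group-level quantities; result flagged")
  structure(list(draws = draws, summary = summ, converged = converged,
                 groups = glev,
                 mcmc = list(n_chains = n_chains, n_iter = n_iter,
                             n_burnin = n_burnin, thin = thin, seed = seed)),
            class = "vb_posterior")
}

#' Pairwise credible-interval comparisons of group growth parameters
#'
#' For every parameter and pair of groups, reports the 95% credible
#' intervals of the group-level means and whether they overlap;
#' non-overlapping (disjoint) intervals are flagged as a difference in
#' lifelong growth.
#'
#' @param posterior a `vb_posterior`.
#' @return Data frame `parameter`, `group_a`, `group_b`, interval bounds,
#'   `overlap` (logical), `different` (= !overlap).
#' @export
group_differences <- function(posterior) {
  s <- posterior$summary
  glev <- posterior$groups
  if (length(glev) < 2) stop_named("posterior", "need >= 2 groups")
  rows <- list()
  for (par in unique(s$parameter)) {
    sp <- s[s$parameter == par, ]
    for (i in seq_len(nrow(sp) - 1)) for (j in (i + 1):nrow(sp)) {
      overlap <- sp$lower[i] <= sp$upper[j] && sp$lower[j] <= sp$upper[i]
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, group_a = sp$group[i], group_b = sp$group[j],
        lower_a = sp$lower[i], upper_a = sp$upper[i],
        lower_b = sp$lower[j], upper_b = sp$upper[j],
        overlap = overlap, different = !overlap, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
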