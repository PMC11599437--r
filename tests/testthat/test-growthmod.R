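sim_growth <- function(seed, n_fish = 60, ages = 4:10, id_sd = 0.03,
                       resid_sd = 0.11, sex_beta = -0.03) {
  cfg <- synth_config(increment_id_sd = id_sd, increment_resid_sd = resid_sd)
  cfg$increment_coefs[["sex_male"]] <- sex_beta
  set.seed(seed)
  phen <- sample(c("FW_RESIDENT", "ANADROMOUS", "CROSS_HABITAT",
                   "BRACKISH_RESIDENT"), n_fish, replace = TRUE)
  fish <- data.frame(fish_id = sprintf("G%03d", seq_len(n_fish)),
                     age = sample(ages, n_fish, replace = TRUE),
                     sex = sample(c("F", "M"), n_fish, replace = TRUE),
                     phenotype = phen, stringsAsFactors = FALSE)
  cov <- do.call(rbind, lapply(seq_len(n_fish), function(i)
    data.frame(fish_id = fish$fish_id[i], annulus = seq_len(fish$age[i]),
               d18o_res = rnorm(fish$age[i], 0, 0.3),
               srca_z = rnorm(fish$age[i]))))
  list(records = simulate_increments(fish, cov, cfg), cfg = cfg)
}

test_that("REML fit collapses to OLS when the random variance is zero", {
  g <- sim_growth(seed = 301, id_sd = 0)
  fit <- fit_increment_lmm(g$records)
  ols <- lm(log10(increment_um) ~ age + I(age^2) + sex + annual_d18o_res +
              annual_srca_z + phenotype + age:phenotype,
            data = transform(g$records,
                             age = lifeyear,
                             sex = relevel(factor(sex), "F"),
                             phenotype = relevel(factor(phenotype), "ANADROMOUS")))
  expect_lt(max(abs(fit$coefficients$estimate - unname(coef(ols)))), 1e-6)
  expect_equal(fit$varcomp[["id"]], 0)
})

test_that("fixed effects match an independent mixed-model implementation", {
  g <- sim_growth(seed = 42)
  fit <- fit_increment_lmm(g$records)
  d <- fit$data
  ref <- nlme::lme(log10_inc ~ age + I(age^2) + sex + annual_d18o_res +
                     annual_srca_z + phenotype + age:phenotype,
                   random = ~ 1 | fish_id, data = d, method = "REML")
  expect_equal(fit$coefficients$estimate, unname(nlme::fixef(ref)),
               tolerance = 1e-4)
  vc <- nlme::VarCorr(ref)
  expect_equal(fit$varcomp[["id"]], as.numeric(vc["(Intercept)", "Variance"]),
               tolerance = 1e-4)
  expect_equal(fit$varcomp[["residual"]], as.numeric(vc["Residual", "Variance"]),
               tolerance = 1e-4)
})

test_that("simulated coefficients are recovered with the planted signs", {
  g <- sim_growth(seed = 43, n_fish = 200)
  fit <- fit_increment_lmm(g$records)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(est[["age"]], 0)
  expect_gt(est[["I(age^2)"]], 0)
  expect_lt(est[["annual_d18o_res"]], 0)
  expect_lt(est[["annual_srca_z"]], 0)
  expect_lt(est[["sexM"]], 0)
  expect_error(fit_increment_lmm(transform(g$records, phenotype = "ANADROMOUS")),
               "phenotype")
})

test_that("likelihood-ratio tests detect planted and null effects", {
  g <- sim_growth(seed = 44, n_fish = 150, sex_beta = -0.15)
  fit <- fit_increment_lmm(g$records)
  tests <- llr_term_tests(fit)
  expect_true(all(tests$llr >= 0))
  expect_true(all(tests$df >= 1))
  sex_row <- tests[tests$term == "sex", ]
  expect_lt(sex_row$p_value, 0.001)
  age_row <- tests[tests$term == "age", ]
  expect_lt(age_row$p_value, 1e-10)
  # the interaction is dropped before its marginal age terms (larger df)
  expect_equal(tests$df[tests$term == "age:phenotype"], 3)
  expect_equal(tests$df[tests$term == "age"], 4)
})

test_that("marginal and conditional R2 obey the variance partition", {
  g <- sim_growth(seed = 45)
  fit <- fit_increment_lmm(g$records)
  r2 <- nakagawa_r2(fit)
  expect_true(r2["conditional"] >= r2["marginal"])
  expect_true(all(r2 >= 0 & r2 <= 1))
  # recomputed by hand from the fit components
  X <- lme4::getME(fit$reml, "X")
  vf <- var(as.vector(X %*% lme4::fixef(fit$reml)))
  expect_equal(unname(r2["marginal"]),
               vf / (vf + fit$varcomp[["id"]] + fit$varcomp[["residual"]]),
               tolerance = 1e-10)
  # nearly-noiseless case: both approach 1
  g0 <- sim_growth(seed = 46, id_sd = 1e-4, resid_sd = 1e-4)
  r20 <- fit_increment_lmm(g0$records)$r2
  expect_gt(r20["marginal"], 0.999)
  expect_gt(r20["conditional"], 0.999)
})

test_that("the growth curve evaluates exactly and is monotone", {
  expect_equal(vb_radius(-0.5, 2, 0.3, -0.5), 0)
  expect_equal(vb_radius(1e6, 2.5, 0.5, 0), 2.5, tolerance = 1e-9)
  # brackish-resident medians at age 1
  expect_equal(vb_radius(1, 2.68, 0.11, -0.81), 2.68 * (1 - exp(-0.11 * 1.81)))
  set.seed(47)
  for (r in 1:50) {
    Rinf <- runif(1, 1, 5); k <- runif(1, 0.05, 0.5); t0 <- runif(1, -1.5, 0)
    t <- sort(runif(6, 0, 20))
    v <- vb_radius(t, Rinf, k, t0)
    expect_true(all(diff(v) > 0))
    expect_true(all(v < Rinf))
  }
  expect_error(vb_radius(1, -1, 0.1, 0), "Rinf")
})

sim_radii <- function(seed, n_per_group = 12, groups = c("A", "B"),
                      mu = list(A = c(2.85, 0.12, 0.62), B = c(2.68, 0.11, 0.81)),
                      ages = 1:8, noise = 0.04, tau = c(45, 4000, 150)) {
  set.seed(seed)
  ids <- sprintf("R%03d", seq_len(n_per_group * length(groups)))
  grp <- rep(groups, each = n_per_group)
  radii <- do.call(rbind, lapply(seq_along(ids), function(i) {
    m <- mu[[grp[i]]]
    p <- c(rgamma(1, m[1]^2 * tau[1], rate = m[1] * tau[1]),
           rgamma(1, m[2]^2 * tau[2], rate = m[2] * tau[2]),
           rgamma(1, m[3]^2 * tau[3], rate = m[3] * tau[3]))
    data.frame(fish_id = ids[i], age = ages,
               radius = vb_radius(ages, p[1], p[2], -p[3]) +
                 rnorm(length(ages), 0, noise))
  }))
  list(radii = radii, groups = setNames(grp, ids))
}

test_that("hierarchical growth model recovers shared parameters from clean data", {
  # all fish share one parameter set; tiny noise pins the posterior
  set.seed(48)
  ids <- sprintf("S%02d", 1:15)
  radii <- do.call(rbind, lapply(ids, function(id)
    data.frame(fish_id = id, age = 1:10,
               radius = vb_radius(1:10, 2.85, 0.12, -0.62) + rnorm(10, 0, 0.002))))
  post <- suppressWarnings(
    fit_vb_hierarchical(radii, setNames(rep("one", 15), ids),
                        n_iter = 20000, n_burnin = 10000, thin = 10, seed = 2))
  s <- post$summary
  expect_lt(abs(s$median[s$parameter == "Rinf"] - 2.85), 0.02 * 2.85)
  expect_lt(abs(s$median[s$parameter == "k"] - 0.12), 0.02 * 0.12)
  expect_lt(abs(s$median[s$parameter == "t0"] + 0.62), 0.02 * 0.62)
})

test_that("identical seeds reproduce identical posterior draws", {
  d <- sim_radii(seed = 49, n_per_group = 6, ages = 1:5)
  a <- suppressWarnings(fit_vb_hierarchical(d$radii, d$groups, n_iter = 2000,
                                            n_burnin = 1000, thin = 2, seed = 5))
  b <- suppressWarnings(fit_vb_hierarchical(d$radii, d$groups, n_iter = 2000,
                                            n_burnin = 1000, thin = 2, seed = 5))
  expect_identical(as.matrix(a$draws), as.matrix(b$draws))
  c <- suppressWarnings(fit_vb_hierarchical(d$radii, d$groups, n_iter = 2000,
                                            n_burnin = 1000, thin = 2, seed = 6))
  expect_false(identical(as.matrix(a$draws), as.matrix(c$draws)))
})

test_that("posterior agrees with an independent MCMC engine on a small instance", {
  # sub-annual early ages and a wide true s0 spread pin every individual
  # curve, so the group-level posterior is unimodal and both engines'
  # posteriors concentrate on the same values
  d <- sim_radii(seed = 50, n_per_group = 8, groups = "A",
                 ages = seq(0.5, 10, by = 0.5), noise = 0.005,
                 tau = c(45, 4000, 25))
  post <- suppressWarnings(fit_vb_hierarchical(d$radii, d$groups,
                                               n_iter = 40000, n_burnin = 20000,
                                               thin = 20, seed = 3))
  model <- "
  model {
    for (i in 1:Nobs) {
      mu[i] <- Rinf[fish[i]] * (1 - exp(-k[fish[i]] * (age[i] + s0[fish[i]])))
      R[i] ~ dnorm(mu[i], pow(sd_obs, -2))
    }
    for (f in 1:Nfish) {
      Rinf[f] ~ dgamma(mu_R^2 * tau_R, mu_R * tau_R)
      k[f] ~ dgamma(mu_k^2 * tau_k, mu_k * tau_k)
      s0[f] ~ dgamma(mu_s^2 * tau_s, mu_s * tau_s)
    }
    mu_R ~ dgamma(4, 4 / c_R); mu_k ~ dgamma(4, 4 / c_k); mu_s ~ dgamma(4, 4 / c_s)
    tau_R ~ dnorm(0, pow(ht_R, -2)) T(0,)
    tau_k ~ dnorm(0, pow(ht_k, -2)) T(0,)
    tau_s ~ dnorm(0, pow(ht_s, -2)) T(0,)
    sd_obs ~ dnorm(0, pow(obs_scale, -2)) T(0,)
  }"
  start <- otomigrate:::vb_crude_start(d$radii)
  ids <- unique(d$radii$fish_id)
  data <- list(Nobs = nrow(d$radii), Nfish = length(ids),
               R = d$radii$radius, age = d$radii$age,
               fish = as.integer(factor(d$radii$fish_id, levels = ids)),
               c_R = start[["Rinf"]], c_k = start[["k"]], c_s = start[["s0"]],
               ht_R = 10 / (0.05 * start[["Rinf"]])^2,
               ht_k = 10 / (0.05 * start[["k"]])^2,
               ht_s = 10 / (0.05 * start[["s0"]])^2,
               obs_scale = 0.1 * diff(range(d$radii$radius)))
  conn <- textConnection(model)
  jm <- rjags::jags.model(conn, data = data, n.chains = 2, n.adapt = 2000,
                          quiet = TRUE,
                          inits = list(
                            list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
                            list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)))
  close(conn)
  stats::update(jm, n.iter = 40000, progress.bar = "none")
  ref <- rjags::coda.samples(jm, c("mu_R", "mu_k", "mu_s"), n.iter = 100000,
                             thin = 50, progress.bar = "none")
  rm <- as.matrix(ref)
  s <- post$summary
  expect_lt(abs(s$median[s$parameter == "Rinf"] - median(rm[, "mu_R"])),
            0.03 * median(rm[, "mu_R"]))
  expect_lt(abs(s$median[s$parameter == "k"] - median(rm[, "mu_k"])),
            0.05 * median(rm[, "mu_k"]))
  expect_lt(abs(s$median[s$parameter == "t0"] + median(rm[, "mu_s"])),
            0.08 * median(rm[, "mu_s"]))
})

test_that("credible-interval comparisons flag only disjoint intervals", {
  d <- sim_radii(seed = 51, n_per_group = 8,
                 mu = list(A = c(2.85, 0.12, 0.62), B = c(2.85, 0.12, 0.62)),
                 ages = 1:6)
  post <- suppressWarnings(fit_vb_hierarchical(d$radii, d$groups, n_iter = 4000,
                                               n_burnin = 2000, thin = 2, seed = 7))
  gd <- group_differences(post)
  expect_equal(nrow(gd), 3)  # three parameters, one group pair
  # identical generative parameters: intervals overlap
  expect_true(all(gd$overlap))
  expect_true(all(gd$different == !gd$overlap))
  # hand-constructed disjoint intervals
  fake <- post
  fake$summary <- data.frame(group = c("A", "B"), parameter = "Rinf",
                             median = c(1.5, 3.5), lower = c(1, 3),
                             upper = c(2, 4), rhat = 1, ess = 1000)
  gd2 <- group_differences(fake)
  expect_true(all(gd2$different))
})
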