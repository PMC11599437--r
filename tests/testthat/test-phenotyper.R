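test_that("natal origin classifies against both thresholds", {
  expect_equal(natal_origin(0.3, 1.0, 2.0), "FRESH")
  expect_equal(natal_origin(2.5, 1.0, 2.0), "BRACKISH")
  expect_equal(natal_origin(1.5, 1.0, 2.0), "INTERMEDIATE")
  expect_equal(natal_origin(c(1.0, 2.0), 1.0, 2.0), c("FRESH", "BRACKISH"))
  expect_error(natal_origin(1, 2, 2), "thresholds inverted")
})

test_that("brackish-born synthetic fish read as brackish natal origin", {
  cfg <- synth_config(seed = 31)
  set.seed(31)
  hits <- replicate(40, {
    tr <- simulate_transect("BRACKISH_RESIDENT", 5, cfg)
    natal_origin(mean(tr$sr_ca[tr$annulus == 1]),
                 cfg$fw_threshold, cfg$brackish_threshold) == "BRACKISH"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("excursion counting is a run-length computation with a noise guard", {
  expect_equal(count_excursions(rep(0.5, 6), 1.5), 0)
  # natal side low, series L H H L H H, min_run 2: two excursions
  expect_equal(count_excursions(c(0.5, 3, 3, 0.5, 3, 3), 1.5, min_run = 2), 2)
  # short blips below min_run are ignored
  expect_equal(count_excursions(c(0.5, 3, 0.5, 3, 0.5), 1.5, min_run = 2), 0)
  expect_equal(count_excursions(c(0.5, 3, 0.5, 3, 0.5), 1.5, min_run = 1), 2)
  # min_run longer than the series
  expect_equal(count_excursions(c(0.5, 3), 1.5, min_run = 5), 0)
  # natal side above: excursions are dips below
  expect_equal(count_excursions(c(3, 0.5, 0.5, 3), 1.5, min_run = 2), 1)
  expect_error(count_excursions(1:3, 1.5, min_run = 0), "min_run")
})

make_annual <- function(id, sr) {
  data.frame(fish_id = id, annulus = seq_along(sr), sr_ca = sr,
             d18o_res = 0, n_points = 1, srca_z = 0)
}

test_that("decision rules fire in order and every call carries its trace", {
  fish <- data.frame(
    fish_id = c("BR", "AN", "CH", "FWG", "UNK"),
    sex = "F", age = 6, total_length_mm = 800,
    capture_location = c("NRBC", "BARTHE", "WRBC", "SEHROWBACH", "GB"),
    capture_habitat = c("lagoon", "tributary", "lagoon", "tributary", "lagoon"),
    capture_season = c("non_spawning", "spawning", "non_spawning",
                       "non_spawning", "non_spawning"),
    stringsAsFactors = FALSE)
  annual <- rbind(
    make_annual("BR", c(3, 3, 3, 3)),            # R1
    make_annual("AN", c(0.5, 3, 3, 0.5)),        # R3
    make_annual("CH", c(2, 2.3, 1.8, 2.2)),      # R4 (natal intermediate)
    make_annual("FWG", c(0.5, 0.6, 0.5, 0.4)),   # R5 guard then R2
    make_annual("UNK", c(3, 0.4, 0.4, 3)))       # brackish natal with dip: no rule
  calls <- assign_phenotypes(setNames(1:5, fish$fish_id), annual, fish)
  got <- setNames(calls$phenotype, calls$fish_id)
  expect_equal(got[["BR"]], "BRACKISH_RESIDENT")
  expect_equal(got[["AN"]], "ANADROMOUS")
  expect_equal(got[["CH"]], "CROSS_HABITAT")
  expect_equal(got[["FWG"]], "FW_RESIDENT")
  expect_equal(got[["UNK"]], "UNCLASSIFIED")
  tr <- setNames(calls$rule_trace, calls$fish_id)
  expect_match(tr[["BR"]], "R1")
  expect_match(tr[["AN"]], "R3")
  expect_match(tr[["CH"]], "R4")
  expect_match(tr[["FWG"]], "^R5.*R2")
  expect_match(tr[["UNK"]], "none_fired")
  expect_true(all(nchar(calls$rule_trace) > 0))
})

test_that("phenotype calls are re-derivable from their rule traces", {
  ds <- small_synth(seed = 32)
  corr <- correct_temperature_proxy(lapply(ds$transects, pair_channels))
  annual <- annual_means_table(corr)
  calls <- assign_phenotypes(setNames(seq_len(nrow(ds$fish)), ds$fish$fish_id),
                             annual, ds$fish)
  decisive <- vapply(strsplit(calls$rule_trace, ";"), function(x)
    x[length(x)], character(1))
  expected <- c(`R1:natal_brackish_no_fw_excursion` = "BRACKISH_RESIDENT",
                `R2:natal_fresh_all_below` = "FW_RESIDENT",
                `R3:natal_fresh_brackish_excursion` = "ANADROMOUS",
                `R4:intermediate_or_minima_above_fw` = "CROSS_HABITAT",
                none_fired = "UNCLASSIFIED")
  expect_equal(calls$phenotype, unname(expected[decisive]))
  # and the framework is a pure function: same inputs, same calls
  again <- assign_phenotypes(setNames(seq_len(nrow(ds$fish)), ds$fish$fish_id),
                             annual, ds$fish)
  expect_identical(calls, again)
})

test_that("jackknife LDA is exact under perfect separation and matches MASS", {
  set.seed(33)
  X <- rbind(matrix(rnorm(60, 0, 1), 30, 2), matrix(rnorm(60, 20, 1), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  jk <- jackknife_lda(X, y)
  expect_equal(jk$rate, 1.0)
  expect_equal(sum(jk$confusion), 60)
  expect_equal(unname(jk$per_class_recall), c(1, 1))

  # agreement with the classical implementation's leave-one-out mode on
  # overlapping classes
  set.seed(34)
  X2 <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 1.2), 40, 2))
  y2 <- factor(rep(c("a", "b"), each = 40))
  jk2 <- jackknife_lda(X2, y2)
  ref <- MASS::lda(X2, grouping = y2, CV = TRUE)$class
  expect_equal(mean(ref == y2), jk2$rate, tolerance = 1e-12)
})

test_that("jackknife equals a naive refit-per-fold oracle", {
  set.seed(35)
  X <- matrix(rnorm(28 * 3), 28, 3)
  y <- factor(rep(c("a", "b", "c", "d"), each = 7))
  X[y == "b", 1] <- X[y == "b", 1] + 1
  X[y == "c", 2] <- X[y == "c", 2] + 1.5
  jk <- jackknife_lda(X, y)
  pred <- vapply(seq_len(nrow(X)), function(i) {
    fit <- MASS::lda(X[-i, ], grouping = y[-i])  # proportional priors default
    as.character(predict(fit, X[i, , drop = FALSE])$class)
  }, character(1))
  expect_equal(jk$rate, mean(pred == as.character(y)), tolerance = 1e-12)
})

test_that("jackknife on permuted labels is at chance level", {
  set.seed(36)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- sample(rep(c("a", "b", "c", "d"), each = 30))
  jk <- jackknife_lda(X, y)
  expect_gt(jk$rate, 0.25 - 0.10)
  expect_lt(jk$rate, 0.25 + 0.10)
})

test_that("chi-squared test matches closed forms", {
  r <- chisq_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # [[20,5],[5,20]]: every expected count 12.5, statistic 4 * 7.5^2 / 12.5 = 18
  r2 <- chisq_test(matrix(c(20, 5, 5, 20), 2))
  expect_equal(r2$statistic, 18)
  expect_equal(r2$df, 1)
  expect_equal(unique(as.vector(r2$expected)), 12.5)
  expect_error(chisq_test(matrix(0, 2, 2)), "counts")
  # all-zero margins are dropped before testing
  m <- rbind(c(8, 2, 0), c(3, 9, 0))
  expect_message(r3 <- chisq_test(m), "all-zero")
  expect_equal(r3$df, 1)
})

test_that("chi-squared statistic is calibrated against a permutation null", {
  set.seed(37)
  x <- sample(1:3, 300, replace = TRUE)
  y <- sample(1:3, 300, replace = TRUE)
  obs <- chisq_test(table(x, y))
  perm <- replicate(400, chisq_test(table(sample(x), y))$statistic)
  # null mean of the statistic approximates its df
  expect_equal(mean(perm), obs$df, tolerance = 0.6)
  expect_gt(mean(perm >= obs$statistic), 0.01)
})

test_that("frequency report excludes non-spawning tributary fish and tests the rest", {
  ds <- small_synth(seed = 38, n = 12)
  corr <- correct_temperature_proxy(lapply(ds$transects, pair_channels))
  annual <- annual_means_table(corr)
  calls <- assign_phenotypes(setNames(seq_len(nrow(ds$fish)), ds$fish$fish_id),
                             annual, ds$fish)
  rep <- phenotype_frequency_report(calls, ds$fish)
  manual <- ds$fish$fish_id[ds$fish$capture_habitat == "tributary" &
                              ds$fish$capture_season == "non_spawning"]
  expect_setequal(rep$excluded, manual)
  expect_equal(sum(rep$table), nrow(ds$fish) - length(manual))
  expect_true(!is.null(rep$test))
  # one-phenotype scope is reported untestable, not crashed
  one <- calls[calls$phenotype == "BRACKISH_RESIDENT", ]
  rep1 <- phenotype_frequency_report(one, ds$fish)
  expect_null(rep1$test)
  expect_match(rep1$untestable_reason, "degenerate")
})
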