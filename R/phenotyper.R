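#' Natal origin from the otolith core chemistry
#'
#' Classifies the first year of life from the annulus-1 mean Sr:Ca:
#' `FRESH` at or below the freshwater threshold, `BRACKISH` at or above the
#' brackish threshold, `INTERMEDIATE` between them.
#'
#' @param natal_sr annulus-1 mean Sr:Ca (mg/g); scalar or vector.
#' @param fw_threshold,brackish_threshold Sr:Ca bounds (mg/g),
#'   `fw_threshold < brackish_threshold`.
#' @return Character vector in \{FRESH, BRACKISH, INTERMEDIATE\}.
#' @export
natal_origin <- function(natal_sr, fw_threshold = 1.5, brackish_threshold = 2.5) {
  if (fw_threshold >= brackish_threshold)
    stop_named("fw_threshold", "thresholds inverted (fw >= brackish)")
  ifelse(natal_sr <= fw_threshold, "FRESH",
         ifelse(natal_sr >= brackish_threshold, "BRACKISH", "INTERMEDIATE"))
}

#' Count habitat excursions in a series of annual means
#'
#' Number of maximal runs of at least `min_run` consecutive annual values on
#' the opposite side of the threshold from the natal (first) value. Runs
#' shorter than `min_run` are ignored as noise. Values exactly at the
#' threshold count as the freshwater side.
#'
#' @param series per-annulus means, in annulus order.
#' @param threshold habitat boundary (e.g. the freshwater Sr:Ca threshold).
#' @param min_run minimum run length in years (>= 1; default 2).
#' @return Integer excursion count.
#' @export
count_excursions <- function(series, threshold, min_run = 2) {
  if (min_run < 1) stop_named("min_run", "must be >= 1")
  if (length(series) == 0) return(0L)
  high <- series > threshold
  opposite <- high != high[1]
  r <- rle(opposite)
  sum(r$values & r$lengths >= min_run)
}

#' Assign behavioral phenotypes by the decision framework
#'
#' Collapses fine-grained trajectory clusters into four behavioral
#' phenotypes with an explicit ordered rule set over natal origin, lifelong
#' habitat use and capture context. Per fish, rules are evaluated in order
#' and every rule consulted is logged in the rule trace, so each call is
#' re-derivable from its trace:
#'
#' * R5 (capture-context guard, checked first): a tributary capture outside
#'   the spawning season is screened for freshwater residency before
#'   anything else — such fish cannot be brackish residents.
#' * R1: natal BRACKISH and no freshwater excursion -> `BRACKISH_RESIDENT`.
#' * R2: natal FRESH and all annual Sr:Ca means at or below the freshwater
#'   threshold -> `FW_RESIDENT`.
#' * R3: natal FRESH and at least one brackish excursion -> `ANADROMOUS`.
#' * R4: natal INTERMEDIATE, or oscillations whose minima stay above the
#'   freshwater threshold -> `CROSS_HABITAT`.
#'
#' A fish failing every rule is returned `UNCLASSIFIED` with its trace,
#' never silently dropped.
#'
#' @param cluster_labels named vector of trajectory cluster labels (carried
#'   into the output; the rules, not the raw clusters, decide the
#'   phenotype).
#' @param annual fish-year table from [annual_means_table()].
#' @param fish fish-record table (capture habitat/season used by R5).
#' @param fw_threshold,brackish_threshold Sr:Ca bounds (mg/g).
#' @param min_run excursion noise guard in years, see [count_excursions()].
#' @return Data frame with one row per fish: `fish_id`, `cluster`,
#'   `phenotype`, `natal_origin`, `excursions`, `rule_trace`
#'   (semicolon-separated rules fired, last one decisive).
#' @export
assign_phenotypes <- function(cluster_labels, annual, fish,
                              fw_threshold = 1.5, brackish_threshold = 2.5,
                              min_run = 2) {
  out <- lapply(unique(annual$fish_id), function(id) {
    d <- annual[annual$fish_id == id, ]
    d <- d[order(d$annulus), ]
    sr <- d$sr_ca
    natal <- natal_origin(sr[1], fw_threshold, brackish_threshold)
    exc <- count_excursions(sr, fw_threshold, min_run)
    rec <- fish[fish$fish_id == id, ]
    trace <- character(0)
    phen <- NA_character_
    fw_check <- function() natal == "FRESH" && all(sr <= fw_threshold)
    if (nrow(rec) == 1 && rec$capture_habitat == "tributary" &&
        rec$capture_season == "non_spawning") {
      trace <- c(trace, "R5:tributary_non_spawning_guard")
      if (fw_check()) {
        trace <- c(trace, "R2:natal_fresh_all_below")
        phen <- "FW_RESIDENT"
      }
    }
    if (is.na(phen)) {
      if (natal == "BRACKISH" && exc == 0) {
        trace <- c(trace, "R1:natal_brackish_no_fw_excursion")
        phen <- "BRACKISH_RESIDENT"
      } else if (fw_check()) {
        trace <- c(trace, "R2:natal_fresh_all_below")
        phen <- "FW_RESIDENT"
      } else if (natal == "FRESH" && exc >= 1) {
        trace <- c(trace, "R3:natal_fresh_brackish_excursion")
        phen <- "ANADROMOUS"
      } else if (natal == "INTERMEDIATE" ||
                 (length(sr) > 1 && min(sr) > fw_threshold && sd(sr) > 0)) {
        trace <- c(trace, "R4:intermediate_or_minima_above_fw")
        phen <- "CROSS_HABITAT"
      } else {
        trace <- c(trace, "none_fired")
        phen <- "UNCLASSIFIED"
      }
    }
    data.frame(fish_id = id,
               cluster = if (id %in% names(cluster_labels))
                 unname(cluster_labels[id]) else NA_integer_,
               phenotype = phen, natal_origin = natal,
               excursions = exc, rule_trace = paste(trace, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Pooled-covariance Gaussian linear discriminant classifier. Priors are
# proportional to class counts. If the pooled covariance is singular it is
# ridge-regularized and the epsilon used is recorded on the result.
lda_train <- function(X, y) {
  y <- factor(y)
  classes <- levels(y)
  n <- nrow(X); p <- ncol(X)
  mu <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                 numeric(p)))
  Sp <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) > 1) Sp <- Sp + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  Sp <- Sp / (n - length(classes))
  eps <- 0
  Si <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(Si) || rcond(Sp) < 1e-12) {
    eps <- 1e-6 * mean(diag(Sp)) + 1e-12
    Si <- solve(Sp + diag(eps, p))
  }
  prior <- as.vector(table(y)) / n
  list(classes = classes, mu = mu, Sinv = Si, log_prior = log(prior), eps = eps)
}

lda_predict <- function(model, X) {
  scores <- vapply(seq_along(model$classes), function(j) {
    m <- model$mu[j, ]
    drop(X %*% model$Sinv %*% m) - 0.5 * drop(m %*% model$Sinv %*% m) +
      model$log_prior[j]
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(X))
  model$classes[max.col(scores, ties.method = "first")]
}

#' Jackknife (leave-one-out) discriminant reclassification
#'
#' Validates phenotype assignments: for each fish, a linear discriminant
#' (class-conditional Gaussians with pooled covariance, priors proportional
#' to class counts) is fitted on all other fish from the life-stage features
#' and the held-out fish is predicted; the reported rate is the fraction
#' predicted correctly. Fish with undefined stages (young fish) must be
#' handled by the caller (rows with `NA` features are dropped with a
#' message).
#'
#' @param features numeric matrix or data frame of life-stage features (six
#'   columns from [stage_features()], fish in rows).
#' @param labels phenotype labels, one per row.
#' @return List: `rate` (overall correct fraction), `confusion`
#'   (cross-table of truth vs prediction), `per_class_recall`, `n`,
#'   `ridge_eps` (0 unless the pooled covariance needed regularization).
#' @export
jackknife_lda <- function(features, labels) {
  X <- as.matrix(features)
  if (!is.null(colnames(X)) && "fish_id" %in% colnames(X))
    X <- X[, colnames(X) != "fish_id", drop = FALSE]
  storage.mode(X) <- "double"
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sprintf("dropping %d fish with undefined life stages", sum(!keep)))
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stop_named("labels", "need >= 2 classes")
  if (any(table(y) < 2)) stop_named("labels", "each class needs n >= 2")
  n <- nrow(X)
  pred <- character(n)
  eps_used <- 0
  for (i in seq_len(n)) {
    m <- lda_train(X[-i, , drop = FALSE], y[-i])
    eps_used <- max(eps_used, m$eps)
    pred[i] <- lda_predict(m, X[i, , drop = FALSE])
  }
  confusion <- table(truth = y, predicted = factor(pred, levels = levels(y)))
  rate <- mean(pred == as.character(y))
  recall <- diag(prop.table(confusion, 1))
  if (eps_used > 0) message(sprintf("ridge epsilon %.3g used", eps_used))
  list(rate = rate, confusion = confusion, per_class_recall = recall,
       n = n, ridge_eps = eps_used)
}

#' Pearson chi-squared test of a contingency table
#'
#' Pearson statistic with expected counts from the margins, no continuity
#' correction; all-zero rows and columns are dropped first (with a message).
#'
#' @param counts matrix or table of nonnegative counts.
#' @return List `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_test <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop_named("counts", "all counts zero")
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c))
    message(sprintf("dropping %d all-zero row(s) and %d all-zero column(s)",
                    sum(!keep_r), sum(!keep_c)))
  counts <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop_named("counts", "need >= 2 rows and columns after dropping zero margins")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Phenotype frequency distributions across capture pools
#'
#' Tabulates phenotype calls by capture pool and tests the distribution with
#' a Pearson chi-squared test. Fish captured in tributaries outside the
#' spawning season are excluded from the test (their capture design makes
#' them freshwater residents by construction, so they carry no frequency
#' information); the exclusion list is reported.
#'
#' @param calls data frame from [assign_phenotypes()].
#' @param fish fish-record table.
#' @param pool_by fish column defining the pools (default
#'   `"capture_habitat"`).
#' @return List: `table` (pool x phenotype counts over tested fish),
#'   `excluded` (fish ids left out), `test` (from [chisq_test()], or `NULL`
#'   with `untestable_reason` when the table is degenerate).
#' @export
phenotype_frequency_report <- function(calls, fish, pool_by = "capture_habitat") {
  fish_cols <- c("fish_id", setdiff(names(fish), names(calls)))
  d <- merge(calls, fish[, fish_cols], by = "fish_id")
  if (nrow(d) == 0) stop_named("calls", "empty scope")
  excl <- d$capture_habitat == "tributary" & d$capture_season == "non_spawning"
  tested <- d[!excl, ]
  tab <- table(pool = tested[[pool_by]], phenotype = tested$phenotype)
  test <- NULL; reason <- NULL
  if (nrow(tab) >= 2 && ncol(tab) >= 2 &&
      sum(rowSums(tab) > 0) >= 2 && sum(colSums(tab) > 0) >= 2) {
    test <- chisq_test(tab)
  } else {
    reason <- "degenerate table (fewer than 2 non-empty pools or phenotypes)"
  }
  list(table = tab, excluded = d$fish_id[excl], test = test,
       untestable_reason = reason)
}
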