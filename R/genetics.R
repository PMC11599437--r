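#' Read an ancestry (Q) matrix
#'
#' Reads per-fish assignment probabilities to K genetic clusters, either
#' from CSV (`fish_id,q1..qK`) or from a STRUCTURE-style output file, whose
#' whitespace-aligned cluster-membership block (rows like
#' `1 FISH01 (0) 1 :  0.971 0.020 0.005 0.004`) is parsed into the same
#' matrix. Rows summing to 1 within 1e-3 are renormalized; rows outside
#' that tolerance, negative entries and duplicate ids are rejected.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"structure_outfile"`.
#' @return Data frame `fish_id`, `q1`..`qK` with rows summing to 1, of
#'   class `q_matrix`.
#' @export
read_q_matrix <- function(path, dialect = c("csv", "structure_outfile")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    qcols <- grep("^q[0-9]+$", names(df), value = TRUE)
    if (!"fish_id" %in% names(df) || length(qcols) < 2)
      stop_named("columns", "need fish_id and q1..qK columns")
    q <- as.matrix(df[, qcols])
    ids <- df$fish_id
  } else {
    lines <- readLines(path)
    rows <- grep(":", lines, value = TRUE)
    rows <- rows[grepl("^\\s*[0-9]+\\s+\\S+", rows)]
    if (length(rows) == 0)
      stop_named("path", "no cluster-membership rows found")
    parsed <- lapply(rows, function(l) {
      parts <- strsplit(l, ":")[[1]]
      left <- strsplit(trimws(parts[1]), "\\s+")[[1]]
      vals <- as.numeric(strsplit(trimws(parts[2]), "\\s+")[[1]])
      list(id = left[2], q = vals)
    })
    ids <- vapply(parsed, `[[`, character(1), "id")
    q <- do.call(rbind, lapply(parsed, `[[`, "q"))
  }
  if (anyDuplicated(ids))
    stop_named("fish_id", paste("duplicate fish id:", ids[duplicated(ids)][1]))
  if (any(!is.finite(q)) || any(q < 0))
    stop_named("q", "negative or non-finite assignment probability")
  rs <- rowSums(q)
  bad <- abs(rs - 1) > 1e-3
  if (any(bad))
    stop_named("q", sprintf("row sum %.4f outside tolerance for fish '%s'",
                            rs[bad][1], ids[bad][1]))
  q <- q / rs
  out <- data.frame(fish_id = ids, q, stringsAsFactors = FALSE)
  names(out) <- c("fish_id", paste0("q", seq_len(ncol(q))))
  class(out) <- c("q_matrix", "data.frame")
  out
}

#' Discrete genotype assignment by probability threshold
#'
#' A fish is assigned to its argmax cluster iff that cluster's probability
#' reaches the threshold (inclusive), else `UNASSIGNED`. The threshold must
#' exceed 0.5 so at most one cluster can qualify.
#'
#' @param q a `q_matrix` (or data frame with `q1..qK`).
#' @param tau assignment threshold, in (0.5, 1]; default 0.7.
#' @param labels optional cluster names (default `q1..qK` column names).
#' @return Named character vector of labels (or `UNASSIGNED`) per fish.
#' @export
threshold_assign <- function(q, tau = 0.7, labels = NULL) {
  if (!(tau > 0.5 && tau <= 1))
    stop_named("tau", "must be in (0.5, 1]: lower values allow ambiguous assignment")
  qm <- as.matrix(q[, grep("^q[0-9]+$", names(q)), drop = FALSE])
  if (is.null(labels)) labels <- colnames(qm)
  best <- max.col(qm, ties.method = "first")
  best_p <- qm[cbind(seq_len(nrow(qm)), best)]
  out <- ifelse(best_p >= tau, labels[best], "UNASSIGNED")
  names(out) <- q$fish_id
  out
}

# Within-group sum of squares from a squared-distance matrix.
ss_within <- function(D2, groups) {
  s <- 0
  for (lv in unique(groups)) {
    i <- which(groups == lv)
    s <- s + sum(D2[i, i]) / (2 * length(i))
  }
  s
}

#' PERMANOVA on assignment probabilities
#'
#' One-way permutational multivariate analysis of variance on Euclidean
#' distances between rows of `Y`: pseudo-F = (SS_between/(g-1)) /
#' (SS_within/(N-g)) with sums of squares from the distance matrix, and a
#' permutation p-value under whole-row permutation of the group labels.
#' The observed statistic is included in the null set, so
#' p = (1 + #\{permuted F >= observed\}) / (n_perm + 1) and the smallest
#' attainable p is 1/(n_perm + 1). In the univariate case the pseudo-F
#' equals the classical one-way ANOVA F.
#'
#' @param Y numeric matrix (rows = fish, columns = assignment
#'   probabilities or any responses).
#' @param groups group labels, >= 2 groups with >= 2 members each.
#' @param n_perm number of permutations (default 9999).
#' @param seed permutation RNG seed.
#' @return List of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_perm`, `seed`, `df` (between, within), `ss` (between,
#'   within, total).
#' @export
permanova <- function(Y, groups, n_perm = 9999, seed = 1) {
  Y <- as.matrix(Y)
  groups <- as.character(groups)
  # canonical content order (group, then row values): the seeded
  # permutation stream is then independent of the input row order
  o <- do.call(order, c(list(groups), lapply(seq_len(ncol(Y)), function(j) Y[, j])))
  Y <- Y[o, , drop = FALSE]
  groups <- groups[o]
  tab <- table(groups)
  if (length(tab) < 2) stop_named("groups", "need >= 2 groups")
  if (any(tab < 2)) stop_named("groups",
                               paste("group with < 2 members:",
                                     names(tab)[tab < 2][1]))
  if (any(!is.finite(Y))) stop_named("Y", "Y must be complete")
  N <- nrow(Y); g <- length(tab)
  D2 <- as.matrix(dist(Y))^2
  ss_total <- sum(D2) / (2 * N)
  ss_w <- ss_within(D2, groups)
  ss_b <- ss_total - ss_w
  F_obs <- (ss_b / (g - 1)) / (ss_w / (N - g))
  set.seed(seed)
  count <- 0L
  for (p in seq_len(n_perm)) {
    perm <- sample(groups)
    ss_wp <- ss_within(D2, perm)
    F_p <- ((ss_total - ss_wp) / (g - 1)) / (ss_wp / (N - g))
    if (F_p >= F_obs - 1e-12) count <- count + 1L
  }
  structure(list(pseudo_F = F_obs, r_squared = ss_b / ss_total,
                 p_value = (1 + count) / (n_perm + 1), n_perm = n_perm,
                 seed = seed, df = c(between = g - 1, within = N - g),
                 ss = c(between = ss_b, within = ss_w, total = ss_total)),
            class = "permanova_result")
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Runs [permanova()] on every pair of groups and adjusts the permutation
#' p-values across pairs by the Benjamini-Hochberg false-discovery-rate
#' procedure.
#'
#' @inheritParams permanova
#' @param fdr_alpha significance level applied to the adjusted p-values.
#' @return Data frame `group_a`, `group_b`, `pseudo_F`, `r_squared`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
pairwise_permanova <- function(Y, groups, n_perm = 9999, seed = 1,
                               fdr_alpha = 0.05) {
  Y <- as.matrix(Y)
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  pair_seeds <- derive_seeds(seed, choose(length(glev), 2))
  rows <- list()
  idx <- 0
  for (i in seq_len(length(glev) - 1)) for (j in (i + 1):length(glev)) {
    idx <- idx + 1
    sel <- groups %in% c(glev[i], glev[j])
    r <- permanova(Y[sel, , drop = FALSE], groups[sel], n_perm = n_perm,
                   seed = pair_seeds[idx])
    rows[[idx]] <- data.frame(group_a = glev[i], group_b = glev[j],
                              pseudo_F = r$pseudo_F, r_squared = r$r_squared,
                              p_value = r$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < fdr_alpha
  out
}

#' Delimit ecotypes from pairwise phenotype-genotype tests
#'
#' Builds a graph over phenotypes with an edge wherever the adjusted
#' pairwise p-value is at or above `alpha` (the pair is not genetically
#' distinguishable) and returns its connected components as ecotypes: a
#' phenotype that differs significantly from all others forms a singleton
#' ecotype; indistinguishable phenotypes share one.
#'
#' @param pairwise data frame from [pairwise_permanova()] covering all
#'   phenotype pairs.
#' @param phenotypes character vector of all phenotype labels.
#' @param alpha significance level (default 0.05).
#' @return List of class `ecotype_partition`: `ecotypes` (named integer
#'   vector phenotype -> ecotype id), `blocks` (list of phenotype sets),
#'   `alpha`.
#' @export
infer_ecotypes <- function(pairwise, phenotypes, alpha = 0.05) {
  for (i in seq_len(length(phenotypes) - 1))
    for (j in (i + 1):length(phenotypes)) {
      hit <- (pairwise$group_a == phenotypes[i] & pairwise$group_b == phenotypes[j]) |
        (pairwise$group_a == phenotypes[j] & pairwise$group_b == phenotypes[i])
      if (!any(hit))
        stop_named("pairwise", sprintf("missing pair %s-%s",
                                       phenotypes[i], phenotypes[j]))
    }
  comp <- setNames(seq_along(phenotypes), phenotypes)
  for (r in seq_len(nrow(pairwise))) {
    if (pairwise$p_adjusted[r] >= alpha) {
      a <- comp[pairwise$group_a[r]]; b <- comp[pairwise$group_b[r]]
      if (a != b) comp[comp == max(a, b)] <- min(a, b)
    }
  }
  ids <- as.integer(factor(comp, levels = unique(comp)))
  names(ids) <- phenotypes
  blocks <- split(phenotypes, ids)
  structure(list(ecotypes = ids, blocks = blocks, alpha = alpha),
            class = "ecotype_partition")
}

#' Association of discrete genotypes with capture location
#'
#' Pearson chi-squared test on the genotype-by-location contingency table.
#' Unassigned fish are excluded by default (the choice is logged in the
#' result).
#'
#' @param labels genotype labels (possibly containing `UNASSIGNED`).
#' @param locations capture locations, same length.
#' @param include_unassigned keep `UNASSIGNED` as a genotype row.
#' @return As [chisq_test()], plus `include_unassigned` and the table.
#' @export
genotype_location_test <- function(labels, locations, include_unassigned = FALSE) {
  keep <- include_unassigned | labels != "UNASSIGNED"
  tab <- table(genotype = labels[keep], location = locations[keep])
  if (ncol(tab) < 2)
    stop_named("locations", "single location: association untestable")
  if (nrow(tab) < 2)
    stop_named("labels", "single genotype: association untestable")
  out <- chisq_test(tab)
  out$include_unassigned <- include_unassigned
  out$table <- tab
  out
}
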