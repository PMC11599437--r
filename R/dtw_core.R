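#' Build z-scored multichannel series for trajectory clustering
#'
#' Converts corrected transects into per-fish matrices with two channels
#' (Sr:Ca, delta-18O residual) on the paired spot positions. Channels are
#' z-scored globally (one mean/sd per channel across all fish), not per
#' series: global scaling preserves between-fish differences in mean level,
#' which carry ecological signal (e.g. residents of lagoons of different
#' mean salinity). The scaling used is recorded as an attribute.
#'
#' @param transects corrected `transect_set`.
#' @return Named list of numeric matrices (rows = points, columns
#'   `sr_ca`, `d18o_res`), with attribute `scaling`.
#' @export
as_multiseries <- function(transects) {
  rows <- lapply(transects, function(tr) {
    ok <- is.finite(tr$sr_ca) & is.finite(tr$d18o_res)
    tr[ok, c("sr_ca", "d18o_res"), drop = FALSE]
  })
  pooled <- do.call(rbind, rows)
  mu <- colMeans(pooled)
  sg <- apply(pooled, 2, sd)
  if (any(sg == 0)) stop_named("transects", "a channel is globally constant")
  out <- lapply(rows, function(d) {
    m <- cbind(sr_ca = (d$sr_ca - mu[1]) / sg[1],
               d18o_res = (d$d18o_res - mu[2]) / sg[2])
    if (nrow(m) < 2) stop_named("series", "each series needs >= 2 points")
    m
  })
  names(out) <- names(transects)
  attr(out, "scaling") <- list(mean = mu, sd = sg)
  out
}

#' Windowed dynamic time warping distance
#'
#' Dynamic-programming DTW cost between two multichannel series of possibly
#' unequal length, with local cost the Euclidean norm across channels, unit
#' step weights over steps (i-1,j-1), (i-1,j), (i,j-1), no path-length
#' normalization, and a slanted-band warping window around the alignment
#' diagonal whose half-width is `ceiling(window_frac * max(n, m))` diagonal
#' units (symmetrized across argument order). Channels are expected to be
#' globally z-scored (see [as_multiseries()]).
#'
#' @param a,b numeric matrices (or vectors, treated as one channel) with the
#'   same number of columns.
#' @param window_frac band width as a fraction of the longer series length,
#'   in (0, 1]. `window_frac = 1` is unconstrained DTW.
#' @return A single nonnegative number; 0 iff the series are identical.
#' @export
dtw_distance <- function(a, b, window_frac = 0.05) {
  if (is.null(dim(a))) a <- matrix(as.numeric(a), ncol = 1)
  if (is.null(dim(b))) b <- matrix(as.numeric(b), ncol = 1)
  if (!(window_frac > 0 && window_frac <= 1))
    stop_named("window_frac", "must be in (0, 1]")
  d <- dtw_cost_cpp(a, b, window_frac)
  if (!is.finite(d))
    stop_named("window_frac", "window admits no warping path")  # guarded; unreachable
  d
}

#' All-pairs DTW distance matrix
#'
#' @param series list of series (see [as_multiseries()]); names are fish ids.
#' @param window_frac see [dtw_distance()].
#' @return Symmetric matrix with zero diagonal and fish ids as dimnames;
#'   attribute `window_frac` records the window used.
#' @export
distance_matrix <- function(series, window_frac = 0.05) {
  if (length(series) < 2) stop_named("series", "need >= 2 series")
  series <- lapply(series, function(s) if (is.null(dim(s)))
    matrix(as.numeric(s), ncol = 1) else s)
  m <- dtw_pairwise_cpp(series, window_frac)
  ids <- names(series) %||% as.character(seq_along(series))
  dimnames(m) <- list(ids, ids)
  if (any(!is.finite(m))) stop_named("window_frac", "window admits no warping path")
  attr(m, "window_frac") <- window_frac
  m
}

#' Ward agglomerative clustering of a distance matrix
#'
#' Agglomerative hierarchical clustering under the Ward criterion, computed
#' by the Lance-Williams update on squared dissimilarities with merge
#' heights reported on the distance scale (`stats::hclust`, method
#' `"ward.D2"`), cut at `k` clusters.
#'
#' @param dmat symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param k number of clusters, 1..n.
#' @return Integer label vector named by fish id; the full `hclust` tree is
#'   attached as attribute `hclust` (merge order and heights).
#' @export
ward_cluster <- function(dmat, k) {
  n <- nrow(dmat)
  if (k < 1 || k > n) stop_named("k", sprintf("k must be in 1..%d", n))
  hc <- hclust(as.dist(dmat), method = "ward.D2")
  labels <- cutree(hc, k = k)
  names(labels) <- rownames(dmat)
  attr(labels, "hclust") <- hc
  labels
}

#' Export a dendrogram as a merge list
#'
#' @param hc an `hclust` object (e.g. `attr(ward_cluster(...), "hclust")`).
#' @return Data frame `step`, `left`, `right`, `height` (negative entries in
#'   left/right are singleton observations, positive are earlier steps, as
#'   in `hclust$merge`).
#' @export
merge_list <- function(hc) {
  data.frame(step = seq_len(nrow(hc$merge)), left = hc$merge[, 1],
             right = hc$merge[, 2], height = hc$height)
}

medoid_of <- function(dmat, idx) idx[which.min(rowSums(dmat[idx, idx, drop = FALSE]))]

#' Six internal cluster validity indices from a distance matrix
#'
#' Computes silhouette, Dunn, Calinski-Harabasz, Davies-Bouldin, modified
#' Davies-Bouldin (DB*) and COP for one clustering, all from the distance
#' matrix alone; where an index needs a centroid, the cluster medoid (point
#' minimizing the sum of within-cluster distances) is used. Orientation is
#' recorded per index: silhouette, Dunn and CH are higher-better; DB, DB*
#' and COP are lower-better. An index that is undefined for the given
#' partition (e.g. all clusters singletons) is reported `NA` and excluded
#' from the vote in [select_k()].
#'
#' @param dmat symmetric distance matrix.
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @return Named numeric vector of the six index values, with attribute
#'   `higher_better` (named logical vector).
#' @export
cvi_suite <- function(dmat, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(dmat)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) stop_named("labels", "need >= 2 clusters")
  if (any(tabulate(labels) == 0)) stop_named("labels", "empty cluster")
  idx <- lapply(ks, function(g) which(labels == g))
  sizes <- lengths(idx)
  med <- vapply(idx, function(i) medoid_of(dmat, i), integer(1))
  med_all <- medoid_of(dmat, seq_len(n))

  sil <- mean(cluster::silhouette(labels, as.dist(dmat))[, "sil_width"])

  # Dunn: min between-cluster single-linkage distance / max cluster diameter
  diam <- vapply(idx, function(i) if (length(i) > 1)
    max(dmat[i, i]) else 0, numeric(1))
  sep <- Inf
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    sep <- min(sep, min(dmat[idx[[i]], idx[[j]]]))
  dunn <- if (max(diam) > 0) sep / max(diam) else NA_real_

  # Calinski-Harabasz, medoid form
  W <- sum(vapply(seq_len(k), function(g) sum(dmat[idx[[g]], med[g]]^2), numeric(1)))
  B <- sum(sizes * dmat[med, med_all]^2)
  ch <- if (W > 0 && n > k) (B / (k - 1)) / (W / (n - k)) else NA_real_

  # Davies-Bouldin and DB*, medoid form
  S <- vapply(seq_len(k), function(g) mean(dmat[idx[[g]], med[g]]), numeric(1))
  M <- dmat[med, med, drop = FALSE]
  db_terms <- dbstar_terms <- numeric(k)
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    db_terms[i] <- max((S[i] + S[others]) / M[i, others])
    dbstar_terms[i] <- max(S[i] + S[others]) / min(M[i, others])
  }
  db <- if (all(is.finite(db_terms))) mean(db_terms) else NA_real_
  dbstar <- if (all(is.finite(dbstar_terms))) mean(dbstar_terms) else NA_real_

  # COP: size-weighted mean of within-cluster cohesion over separation,
  # cohesion = mean distance to medoid, separation = min over outside
  # points of the max distance to the cluster's points
  cop_terms <- vapply(seq_len(k), function(g) {
    outside <- setdiff(seq_len(n), idx[[g]])
    if (length(outside) == 0) return(NA_real_)
    inter <- min(apply(dmat[idx[[g]], outside, drop = FALSE], 2, max))
    if (inter == 0) return(NA_real_)
    sizes[g] * S[g] / inter
  }, numeric(1))
  cop <- if (all(is.finite(cop_terms))) sum(cop_terms) / n else NA_real_

  out <- c(silhouette = sil, dunn = dunn, calinski_harabasz = ch,
           davies_bouldin = db, davies_bouldin_star = dbstar, cop = cop)
  attr(out, "higher_better") <- c(silhouette = TRUE, dunn = TRUE,
                                  calinski_harabasz = TRUE, davies_bouldin = FALSE,
                                  davies_bouldin_star = FALSE, cop = FALSE)
  out
}

#' Choose the number of clusters by majority vote of six validity indices
#'
#' Clusters the distance matrix with Ward linkage at each `k` in
#' `k_min..k_max`, scores each partition with [cvi_suite()], lets each
#' defined index vote for its best `k` by its own orientation, and returns
#' the modal vote. Ties are broken toward smaller `k` (parsimony) and
#' flagged in the report.
#'
#' @param series list of z-scored series, or `NULL` if `dmat` is given.
#' @param k_min,k_max tested range of cluster counts (default 2-10).
#' @param window_frac DTW window (default 0.05).
#' @param dmat optional precomputed distance matrix (skips DTW).
#' @return List with `k_best`, `votes` (named tally), `tied` flag, `report`
#'   (data frame of index values per k) and `labels` (partition at
#'   `k_best`).
#' @export
select_k <- function(series = NULL, k_min = 2, k_max = 10, window_frac = 0.05,
                     dmat = NULL) {
  if (is.null(dmat)) dmat <- distance_matrix(series, window_frac)
  n <- nrow(dmat)
  if (k_max >= n) {
    warning(sprintf("k_max truncated from %d to %d (n = %d)", k_max, n - 1, n))
    k_max <- n - 1
  }
  if (k_min > k_max) stop_named("k_min", "empty k range after truncation")
  hc <- hclust(as.dist(dmat), method = "ward.D2")
  kk <- k_min:k_max
  vals <- t(vapply(kk, function(k) cvi_suite(dmat, cutree(hc, k)), numeric(6)))
  report <- data.frame(k = kk, vals)
  hb <- attr(cvi_suite(dmat, cutree(hc, k_min)), "higher_better")
  best_k <- vapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    if (all(is.na(v))) return(NA_integer_)
    if (hb[j]) kk[which.max(v)] else kk[which.min(v)]
  }, integer(1))
  names(best_k) <- colnames(vals)
  votes <- table(factor(best_k[!is.na(best_k)], levels = kk))
  winners <- as.integer(names(votes)[votes == max(votes)])
  k_best <- min(winners)
  labels <- cutree(hc, k_best)
  names(labels) <- rownames(dmat)
  list(k_best = k_best, votes = votes, tied = length(winners) > 1,
       per_index_best = best_k, report = report, labels = labels, hclust = hc)
}
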