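# Independent oracles used across test files. These deliberately re-derive
# results by brute force or from first principles, sharing no code with the
# implementation they check.

# All monotone warping paths from (1,1) to (n,m) over admissible cells,
# minimizing summed Euclidean local cost. `admissible` is an n x m logical
# matrix. Exponential-time recursion: only for tiny series.
brute_force_dtw <- function(a, b, admissible = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  if (is.null(admissible)) admissible <- matrix(TRUE, n, m)
  local_cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- function(i, j) {
    if (!admissible[i, j]) return(Inf)
    c0 <- local_cost(i, j)
    if (i == 1 && j == 1) return(c0)
    prev <- Inf
    if (i > 1 && j > 1) prev <- min(prev, best(i - 1, j - 1))
    if (i > 1) prev <- min(prev, best(i - 1, j))
    if (j > 1) prev <- min(prev, best(i, j - 1))
    c0 + prev
  }
  best(n, m)
}

# The slanted-band admissibility rule, re-derived independently: a cell is
# admissible if the band condition holds in either argument order.
band_cells <- function(n, m, window_frac) {
  if (n == 1 || m == 1) return(matrix(TRUE, n, m))
  w <- ceiling(window_frac * max(n, m))
  adm <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    a_ok <- abs((j - 1) - (i - 1) * (m - 1) / (n - 1)) <= w + 1e-9
    b_ok <- abs((i - 1) - (j - 1) * (n - 1) / (m - 1)) <= w + 1e-9
    adm[i, j] <- a_ok || b_ok
  }
  adm
}

# Greedy Ward agglomeration recomputing the merge cost from scratch at
# every step: ESS(C) = sum of pairwise squared distances within C over |C|;
# merge the pair minimizing ESS(A u B) - ESS(A) - ESS(B). Returns the
# partition (as labels) at each k from n down to 1.
greedy_ward <- function(dmat) {
  d2 <- dmat^2
  n <- nrow(d2)
  ess <- function(members) {
    if (length(members) < 2) return(0)
    sum(d2[members, members]) / (2 * length(members))
  }
  clusters <- as.list(seq_len(n))
  partitions <- list()
  labels <- seq_len(n)
  partitions[[n]] <- labels
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < best[1]) best <- c(cost, i, j)
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    labels <- integer(n)
    for (c_i in seq_along(clusters)) labels[clusters[[c_i]]] <- c_i
    partitions[[length(clusters)]] <- labels
  }
  partitions
}

# Two partitions agree up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) && adjusted_rand_index(a, b) == 1
}

# A small corrected transect set built from raw values (bypasses CSV)
make_transect <- function(fish_id, annulus, sr, d18o = NULL, dist = NULL) {
  n <- length(sr)
  if (is.null(dist)) dist <- seq(10, by = 10, length.out = n)
  if (is.null(d18o)) d18o <- rep(NA_real_, n)
  structure(data.frame(fish_id = fish_id, distance_um = dist,
                       annulus = annulus, sr_ca = sr, d18o = d18o,
                       stringsAsFactors = FALSE),
            class = c("transect", "data.frame"))
}

small_synth <- function(seed = 1, n = 5) {
  simulate_population(synth_config(
    seed = seed,
    n_fish = c(FW_RESIDENT = n, ANADROMOUS = n, CROSS_HABITAT = n,
               BRACKISH_RESIDENT = n)))
}
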