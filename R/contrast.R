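#' Paired t-statistic map over electrodes and time
#'
#' For participant stacks of active and sham evoked potentials, computes per
#' (electrode, time) element the dependent-samples t-statistic of the
#' active-minus-sham differences: `t = mean(d) / (sd(d)/sqrt(n))`, sd with
#' divisor `n - 1`. Elements with zero variance get signed infinity (positive
#' infinity for a zero mean) and are excluded from cluster thresholding
#' downstream.
#'
#' @param active,sham lists of [eeg_evoked()], one per participant, same order
#'   and identical channels/times.
#' @return List with `t` (channels x samples matrix), `n`, `channels`,
#'   `times`, `zero_var` (logical matrix).
#' @export
dependent_t_map <- function(active, sham) {
  n <- length(active)
  if (length(sham) != n) stop("stacks must contain the same participants")
  if (n < 2L) stop("need at least 2 participants")
  for (i in seq_len(n)) check_matched_evoked(active[[i]], sham[[i]])
  check_matched_evoked(active[[1L]], sham[[1L]])
  d1 <- active[[1L]]$data - sham[[1L]]$data
  s <- d1
  ss <- d1^2
  for (i in seq_len(n)[-1L]) {
    di <- active[[i]]$data - sham[[i]]$data
    s <- s + di
    ss <- ss + di^2
  }
  m <- s / n
  v <- (ss - n * m^2) / (n - 1L)
  v[v < 0] <- 0
  zero_var <- v <= .Machine$double.eps * pmax(ss, 1)
  t <- m / sqrt(v / n)
  t[zero_var] <- ifelse(m[zero_var] >= 0, Inf, -Inf)
  t[zero_var & m == 0] <- 0
  list(t = t, n = n, channels = active[[1L]]$channels,
       times = active[[1L]]$times, zero_var = zero_var)
}

# element graph of a channels x times lattice: spatial neighbors at the same
# sample, plus temporal contiguity at the same channel. Elements are indexed
# column-major: e = (time_index - 1) * K + channel.
element_edges <- function(adjacency, n_ch, n_time) {
  pairs <- which(adjacency$matrix & upper.tri(adjacency$matrix),
                 arr.ind = TRUE)
  sp_a <- rep(pairs[, 1L], n_time) +
    rep((seq_len(n_time) - 1L) * n_ch, each = nrow(pairs))
  sp_b <- rep(pairs[, 2L], n_time) +
    rep((seq_len(n_time) - 1L) * n_ch, each = nrow(pairs))
  if (n_time > 1L) {
    tm_a <- rep(seq_len(n_ch), n_time - 1L) +
      rep((seq_len(n_time - 1L) - 1L) * n_ch, each = n_ch)
    tm_b <- tm_a + n_ch
  } else {
    tm_a <- tm_b <- integer(0)
  }
  cbind(a = c(sp_a, tm_a), b = c(sp_b, tm_b))
}

#' Supra-threshold spatiotemporal clusters
#'
#' Groups elements with `t > threshold` (positive family) and `t < -threshold`
#' (negative family) into connected components of the spatiotemporal graph:
#' two elements are connected iff they share a time sample and are spatial
#' neighbors, or share an electrode and are one sample apart. The cluster mass
#' is the sum of member t-values. Non-finite elements never enter a cluster.
#'
#' @param t_map channels x samples t matrix (or output of
#'   [dependent_t_map()]).
#' @param threshold positive cluster-forming threshold.
#' @param adjacency an `eeg_adjacency` matching the channel order.
#' @return List of clusters, each a list with `sign` (+1/-1), `mass`,
#'   `elements` (data.frame `channel`, `time_index`), ordered by decreasing
#'   `|mass|`.
#' @export
find_clusters <- function(t_map, threshold, adjacency) {
  if (is.list(t_map) && !is.null(t_map$t)) t_map <- t_map$t
  if (threshold <= 0) stop("threshold must be > 0")
  n_ch <- nrow(t_map)
  n_time <- ncol(t_map)
  if (nrow(adjacency$matrix) != n_ch)
    stop("adjacency does not match the channel dimension")
  edges <- element_edges(adjacency, n_ch, n_time)
  vals <- as.numeric(t_map)
  vals[!is.finite(vals)] <- 0
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) vals > threshold else vals < -threshold
    if (!any(mask)) next
    # BFS over the induced subgraph
    nb <- vector("list", length(vals))
    keep <- mask[edges[, 1L]] & mask[edges[, 2L]]
    for (r in which(keep)) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
    visited <- !mask
    for (e0 in which(mask)) {
      if (visited[e0]) next
      comp <- integer(0)
      queue <- e0
      visited[e0] <- TRUE
      while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        comp <- c(comp, v)
        for (w in nb[[v]]) if (!visited[w]) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
      out[[length(out) + 1L]] <- list(
        sign = sgn, mass = sum(vals[comp]),
        elements = data.frame(channel = (comp - 1L) %% n_ch + 1L,
                              time_index = (comp - 1L) %/% n_ch + 1L))
    }
  }
  out[order(-vapply(out, function(cl) abs(cl$mass), numeric(1)))]
}

#' Cluster-based permutation test of active vs sham, per TOI
#'
#' Within each time window of interest, compares the participant stacks of
#' active and sham evoked potentials with a dependent-samples cluster-based
#' permutation test: the cluster-forming threshold is the two-sided t critical
#' value at `cluster_p` with `n - 1` degrees of freedom; the null distribution
#' is built by randomly exchanging condition labels within participants (sign
#' flips of the differences), recording per permutation the maximum cluster
#' mass of each sign family; a cluster's p-value is
#' `(1 + #(perm max >= observed)) / (1 + n_perm)` against its own sign's
#' distribution. Significance is declared at `(alpha/2) / n_tois` per tail:
#' two tails at level `alpha`, Bonferroni-corrected over TOIs because each
#' window is tested separately (testing per window prevents large late
#' clusters from masking small early ones).
#'
#' @param active,sham participant stacks (lists of [eeg_evoked()]).
#' @param tois a `toi_set`.
#' @param adjacency an `eeg_adjacency`.
#' @param n_perm randomizations (default 2000).
#' @param alpha two-tailed significance level before Bonferroni
#'   (default 0.05).
#' @param cluster_p cluster-forming threshold p (default 0.05).
#' @param seed RNG seed.
#' @return A `cluster_result`: list of per-TOI results (`toi`, `threshold`,
#'   `clusters` with p-values and significance, `max_mass_dist`), plus
#'   `alpha_corrected`, `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(active, sham, tois, adjacency,
                                     n_perm = 2000, alpha = 0.05,
                                     cluster_p = 0.05, seed = 1) {
  n <- length(active)
  if (n < 2L) stop("need at least 2 participants")
  n_tois <- nrow(tois)
  alpha_corr <- (alpha / 2) / n_tois
  threshold <- stats::qt(1 - cluster_p / 2, df = n - 1L)
  times <- active[[1L]]$times
  n_ch <- nrow(active[[1L]]$data)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  per_toi <- vector("list", n_tois)
  for (k in seq_len(n_tois)) {
    idx <- window_index(times, c(tois$start[k], tois$end[k]))
    if (!length(idx)) stop("TOI ", k, " outside the data time range")
    D <- t(vapply(seq_len(n), function(i)
      as.numeric(active[[i]]$data[, idx] - sham[[i]]$data[, idx]),
      numeric(n_ch * length(idx))))           # participants x elements
    ss <- colSums(D^2)
    m_obs <- colMeans(D)
    v_obs <- pmax((ss - n * m_obs^2) / (n - 1L), 0)
    t_obs <- m_obs / sqrt(v_obs / n)
    t_map <- matrix(t_obs, n_ch, length(idx))
    clusters <- find_clusters(t_map, threshold, adjacency)
    M <- (signs %*% D) / n
    Tm <- M / sqrt(pmax(sweep(-n * M^2, 2, ss, `+`), 0) / (n - 1L) / n)
    edges <- element_edges(adjacency, n_ch, length(idx))
    mx <- perm_max_cluster_mass(Tm, threshold,
                                as.integer(edges[, 1L] - 1L),
                                as.integer(edges[, 2L] - 1L))
    for (j in seq_along(clusters)) {
      cl <- clusters[[j]]
      dist <- if (cl$sign > 0) mx[, 1L] else mx[, 2L]
      cl$p <- (1 + sum(dist >= abs(cl$mass))) / (1 + n_perm)
      cl$significant <- cl$p < alpha_corr
      cl$elements$time <- times[idx[cl$elements$time_index]]
      clusters[[j]] <- cl
    }
    per_toi[[k]] <- list(toi = k, window = c(tois$start[k], tois$end[k]),
                         threshold = threshold, clusters = clusters,
                         max_mass_dist = mx)
  }
  structure(list(tois = per_toi, alpha = alpha,
                 alpha_corrected = alpha_corr, n_perm = n_perm,
                 threshold = threshold, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$tois), " TOI(s), threshold |t| > ",
      signif(x$threshold, 4), ", per-tail alpha ", signif(x$alpha_corrected, 4),
      "\n", sep = "")
  for (res in x$tois) {
    sig <- vapply(res$clusters, function(cl) cl$significant, logical(1))
    cat("  TOI ", res$toi, " [", res$window[1L], ", ", res$window[2L],
        ") ms: ", length(res$clusters), " cluster(s), ", sum(sig),
        " significant\n", sep = "")
  }
  invisible(x)
}
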