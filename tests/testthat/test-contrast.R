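mk_stack <- function(n, n_ch, n_time, gen, channels = paste0("c", 1:n_ch)) {
  lapply(seq_len(n), function(i)
    eeg_evoked(gen(i), seq(0, n_time - 1), 1000, channels, 10, "active"))
}

test_that("the paired t map is zero under identity and antisymmetric", {
  set.seed(20)
  dat <- lapply(1:5, function(i) matrix(rnorm(6 * 10), 6))
  act <- mk_stack(5, 6, 10, function(i) dat[[i]])
  tm <- dependent_t_map(act, act)
  expect_true(all(tm$t == 0))
  shm <- mk_stack(5, 6, 10, function(i) matrix(0, 6, 10))
  t1 <- dependent_t_map(act, shm)$t
  t2 <- dependent_t_map(shm, act)$t
  expect_equal(t1, -t2)
  expect_error(dependent_t_map(act[1], shm[1]), "2 participants")
})

test_that("the paired t map has the expected magnitude for a unit effect", {
  set.seed(21)
  act <- mk_stack(24, 10, 10, function(i) matrix(rnorm(100, mean = 1), 10))
  shm <- mk_stack(24, 10, 10, function(i) matrix(0, 10, 10))
  tm <- dependent_t_map(act, shm)
  expect_gt(mean(tm$t), 3.9)
  expect_lt(mean(tm$t), 5.9)
})

test_that("clusters are connected components of the element graph", {
  mon <- fixture_montage
  adj <- build_adjacency(mon, 0.05)
  # no supra-threshold elements
  expect_length(find_clusters(matrix(0, 63, 10), 2, adj), 0L)
  # a 3-electrode x 10-sample block among spatial neighbors
  nb <- c("Cz", adj$neighbors$Cz[1:2])
  tmap <- matrix(0, 63, 20)
  tmap[match(nb, mon$labels), 6:15] <- 3
  cl <- find_clusters(tmap, 2.09, adj)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$elements), 30L)
  expect_equal(cl[[1]]$mass, sum(tmap))
  # two supra-threshold electrodes that are not neighbors split
  far <- c("Cz", "O1")
  expect_false(adj$matrix[match("Cz", mon$labels), match("O1", mon$labels)])
  tmap2 <- matrix(0, 63, 5)
  tmap2[match(far, mon$labels), 2] <- c(3, -3)
  cl2 <- find_clusters(tmap2, 2, adj)
  expect_length(cl2, 2L)
  expect_setequal(vapply(cl2, `[[`, 0, "sign"), c(1, -1))
})

test_that("cluster membership matches an independent graph library", {
  mon <- mini_montage()
  adj <- build_adjacency(mon, 0.05)
  n_ch <- 8; n_time <- 12
  set.seed(22)
  for (rep in 1:5) {
    tmap <- matrix(rnorm(n_ch * n_time, sd = 2), n_ch)
    cl <- find_clusters(tmap, 1.5, adj)
    # oracle: connected components via igraph on the explicit element graph
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) tmap > 1.5 else tmap < -1.5
      idx <- which(mask)
      if (!length(idx)) next
      edges <- c()
      for (a in idx) for (b in idx) if (a < b) {
        ca <- (a - 1) %% n_ch + 1; ta <- (a - 1) %/% n_ch + 1
        cb <- (b - 1) %% n_ch + 1; tb <- (b - 1) %/% n_ch + 1
        if ((ta == tb && adj$matrix[ca, cb]) ||
            (ca == cb && abs(ta - tb) == 1)) edges <- c(edges, a, b)
      }
      g <- igraph::make_empty_graph(length(idx), directed = FALSE)
      if (length(edges))
        g <- igraph::add_edges(g, match(edges, idx))
      comp <- igraph::components(g)
      oracle_masses <- sort(vapply(seq_len(comp$no), function(k)
        sum(tmap[idx[comp$membership == k]]), numeric(1)))
      got <- sort(vapply(Filter(function(x) x$sign == sgn, cl),
                         `[[`, 0, "mass"))
      expect_equal(got, oracle_masses, tolerance = 1e-12)
    }
  }
})

test_that("the compiled permutation max-mass agrees with find_clusters", {
  mon <- mini_montage()
  adj <- build_adjacency(mon, 0.05)
  n_ch <- 8; n_time <- 15
  set.seed(23)
  tmat <- matrix(rnorm(20 * n_ch * n_time, sd = 1.5), 20)
  edges <- tepkit:::element_edges(adj, n_ch, n_time)
  mx <- tepkit:::perm_max_cluster_mass(tmat, 1.8,
                                       as.integer(edges[, 1] - 1L),
                                       as.integer(edges[, 2] - 1L))
  for (p in 1:20) {
    cl <- find_clusters(matrix(tmat[p, ], n_ch), 1.8, adj)
    pos <- vapply(Filter(function(x) x$sign > 0, cl), `[[`, 0, "mass")
    neg <- vapply(Filter(function(x) x$sign < 0, cl), `[[`, 0, "mass")
    expect_equal(mx[p, 1], if (length(pos)) max(pos) else 0)
    expect_equal(mx[p, 2], if (length(neg)) max(abs(neg)) else 0)
  }
})

test_that("cluster permutation is deterministic and detects a planted blob", {
  mon <- fixture_montage
  adj <- build_adjacency(mon, 0.05)
  tois <- data.frame(start = 100, end = 180, peak_latency = 140,
                     source = "gmfa")
  class(tois) <- c("toi_set", "data.frame")
  times <- seq(80, 199)
  blob_ch <- match(c("P3", adj$neighbors$P3[1:4]), mon$labels)
  blob_t <- times >= 120 & times < 160
  set.seed(24)
  gen <- function(blob) function(i) {
    m <- matrix(rnorm(63 * 120, sd = 0.08), 63)
    if (blob) m[blob_ch, blob_t] <- m[blob_ch, blob_t] + 2
    m
  }
  act <- mk_stack(20, 63, 120, gen(TRUE), channels = mon$labels)
  shm <- mk_stack(20, 63, 120, gen(FALSE), channels = mon$labels)
  for (i in 1:20) act[[i]]$times <- shm[[i]]$times <- times
  r1 <- cluster_permutation_test(act, shm, tois, adj, n_perm = 500, seed = 9)
  r2 <- cluster_permutation_test(act, shm, tois, adj, n_perm = 500, seed = 9)
  expect_identical(vapply(r1$tois[[1]]$clusters, `[[`, 0, "p"),
                   vapply(r2$tois[[1]]$clusters, `[[`, 0, "p"))
  top <- r1$tois[[1]]$clusters[[1]]
  expect_true(top$significant)
  expect_equal(top$sign, 1)
  planted <- length(blob_ch) * sum(blob_t)
  hit <- sum(top$elements$channel %in% blob_ch &
             top$elements$time %in% times[blob_t])
  expect_gte(hit / planted, 0.8)
})

test_that("Bonferroni over TOIs is no more liberal than a single TOI", {
  mon <- mini_montage()
  adj <- build_adjacency(mon, 0.05)
  times <- seq(0, 299)
  set.seed(25)
  act <- mk_stack(10, 8, 300, function(i)
    matrix(rnorm(8 * 300, sd = 1), 8) +
      outer(rep(0.8, 8), as.numeric(times >= 30 & times < 80)))
  shm <- mk_stack(10, 8, 300, function(i) matrix(rnorm(8 * 300, sd = 1), 8))
  toi1 <- data.frame(start = 20, end = 300, peak_latency = 50,
                     source = "gmfa")
  toi5 <- data.frame(start = c(20, 76, 132, 188, 244),
                     end = c(76, 132, 188, 244, 300),
                     peak_latency = c(50, 100, 160, 200, 260),
                     source = "gmfa")
  class(toi1) <- class(toi5) <- c("toi_set", "data.frame")
  r1 <- cluster_permutation_test(act, shm, toi1, adj, n_perm = 300, seed = 1)
  r5 <- cluster_permutation_test(act, shm, toi5, adj, n_perm = 300, seed = 1)
  expect_lt(r5$alpha_corrected, r1$alpha_corrected)
  expect_equal(r5$alpha_corrected * 5, r1$alpha_corrected)
})
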