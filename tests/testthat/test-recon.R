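test_that("the encoding operator passes the adjoint test on random shapes", {
  set.seed(4)
  for (dims in list(c(8, 7, 6), c(6, 6, 5))) {
    nc <- 3; ncard <- 4
    maps <- array(complex(real = rnorm(prod(dims) * nc),
                          imaginary = rnorm(prod(dims) * nc)), c(dims, nc))
    rss <- array(sqrt(rowSums(matrix(Mod(maps)^2, prod(dims), nc))), dims)
    for (c in seq_len(nc)) maps[, , , c] <- maps[, , , c] / rss
    idx <- lapply(seq_len(ncard), function(p) sort(sample(prod(dims), 100)))
    E <- make_encoding_operator(maps, idx, dims)
    x <- array(complex(real = rnorm(prod(dims) * ncard),
                       imaginary = rnorm(prod(dims) * ncard)), c(dims, ncard))
    y <- lapply(seq_len(ncard), function(p)
      matrix(complex(real = rnorm(100 * nc), imaginary = rnorm(100 * nc)), 100, nc))
    ip1 <- sum(vapply(seq_len(ncard), function(p)
      sum(E$forward(x)[[p]] * Conj(y[[p]])), complex(1)))
    ip2 <- sum(x * Conj(E$adjoint(y)))
    expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-6)
  }
})

test_that("coil maps are recovered from the scan data", {
  s <- small_scan()
  maps <- estimate_coil_maps(s$bundle)
  supp <- attr(maps, "support")
  rss_map <- sqrt(rowSums(matrix(Mod(maps)^2, prod(s$config$matrix_size),
                                 s$config$n_coils)))
  expect_equal(unname(rss_map[as.vector(supp)]), rep(1, sum(supp)), tolerance = 1e-6)
  # magnitudes match the normalised true maps on strong support
  tm <- s$phantom$coil_maps
  rss_t <- array(sqrt(rowSums(matrix(Mod(tm)^2, prod(dim(tm)[1:3]), dim(tm)[4]))),
                 dim(tm)[1:3])
  vol <- s$phantom$render_state(0.25, c(0, 0, 0))
  strong <- vol > 0.2
  for (c in c(1, 3)) {
    rel <- Mod(maps[, , , c])[strong] / (Mod(tm[, , , c])[strong] / rss_t[strong])
    expect_lt(median(abs(rel - 1)), 0.05)
    expect_gt(cor(Mod(maps[, , , c])[strong],
                  (Mod(tm[, , , c]) / rss_t)[strong]), 0.95)
  }
})

test_that("binned cells conserve lines and match hand-counted occupancy", {
  s <- small_scan()
  binning <- kmeans4(s$trace, seed = 3)
  pa <- cardiac_phase_assign(s$bundle, s$beats)
  cells <- lapply(c("EE", "mid-expiration", "mid-inspiration", "EI"),
                  function(p) bin_kspace(s$bundle, s$beats, binning, pa, p))
  total_assigned <- sum(!is.na(pa$phase) & !is.na(pa$beat))
  expect_equal(sum(vapply(cells, function(c) c$n_lines, 1L)), total_assigned)
  # hand-computed occupancy of one cell
  ee_cl <- which(binning$phase_names == "EE")
  ee_beats <- binning$beat_ids[binning$labels == ee_cl]
  hand <- sum(pa$beat %in% ee_beats & pa$phase == 0, na.rm = TRUE)
  expect_equal(length(cells[[1]]$idx[[1]]) / length(s$bundle$readout_keep0) >=
                 0.5 * hand, TRUE)  # duplicates averaged, so <= hand positions
  expect_equal(cells[[1]]$n_card, pa$n_phases)
})

test_that("with zero TV weight and full sampling the solver returns the SENSE image", {
  p <- cine_problem()
  n <- p$cell$dims
  full_idx <- lapply(1:2, function(q) seq_len(prod(n)))
  yfull <- lapply(1:2, function(q) {
    K <- array(0i, c(n, 4))
    for (c in 1:4) K[, , , c] <- cine5d:::fftc(p$truth[, , , q] * p$maps[, , , c])
    matrix(K, ncol = 4)
  })
  cellf <- list(idx = full_idx, y = yfull, dims = n, n_card = 2, n_coils = 4,
                resp_phase = "full")
  rec <- ktss_reconstruct(cellf, p$maps, lambda_t = 0, max_iter = 8)
  expect_lt(cine5d:::nrmse(rec$cine[, , , 1], p$truth[, , , 1]), 1e-3)
})

test_that("a very large TV weight collapses the cine to its temporal mean", {
  p <- cine_problem()
  rec <- ktss_reconstruct(p$cell, p$maps, lambda_t = 1e4, max_iter = 25)
  m <- Mod(rec$cine)
  spread <- apply(m, 4, function(v) v[p$support])
  expect_lt(max(apply(spread, 1, function(r) diff(range(r)))), 0.02 * max(m))
})

test_that("the objective is monotone and compressed sensing beats zero-filling by >= 30%", {
  p <- cine_problem()
  expect_gt(p$R, 6)   # strongly undersampled
  E <- make_encoding_operator(p$maps, p$cell$idx, p$cell$dims)
  x0 <- E$adjoint(p$cell$y)
  rec <- ktss_reconstruct(p$cell, p$maps, max_iter = 60)
  expect_false(rec$diverged)
  expect_true(all(diff(rec$objective) <= abs(rec$objective[-length(rec$objective)]) * 1e-8))
  nr_zf <- cine5d:::nrmse(Mod(x0), Mod(p$truth))
  nr_cs <- cine5d:::nrmse(Mod(rec$cine), Mod(p$truth))
  expect_lt(nr_cs, 0.7 * nr_zf)
  # data consistency: sampled-location residual decreases vs zero-filled
  res0 <- sum(vapply(seq_along(p$cell$y), function(q)
    sum(Mod(E$forward(x0)[[q]] - p$cell$y[[q]])^2), 1))
  res1 <- sum(vapply(seq_along(p$cell$y), function(q)
    sum(Mod(E$forward(rec$cine)[[q]] - p$cell$y[[q]])^2), 1))
  expect_lt(res1, res0)
})

test_that("the cyclic TV proximal map lowers the TV objective", {
  set.seed(6)
  v <- array(complex(real = rnorm(240), imaginary = rnorm(240)), c(5, 4, 2, 6))
  lam <- 0.3
  obj <- function(z) 0.5 * sum(Mod(z - v)^2) + lam * cine5d:::tv_cyclic_norm(z)
  z <- cine5d:::tv_prox_cyclic(v, lam, iters = 60)
  expect_lt(obj(z), obj(v))
  for (i in 1:5) {
    pert <- z + array(complex(real = rnorm(240, 0, 0.01),
                              imaginary = rnorm(240, 0, 0.01)), dim(z))
    expect_gte(obj(pert), obj(z) - 1e-8)
  }
})
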