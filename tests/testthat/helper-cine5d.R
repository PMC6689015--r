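# Shared fixtures, built in code and cached across test files within a run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# truly static phantom: no respiration, no contraction, no noise
static_config <- function(n = c(16, 16, 16), fov = c(160, 160, 160), coils = 1) {
  phantom_config(matrix_size = n, fov_mm = fov, n_coils = coils,
                 resp_depth_mm = 0, rsa_amplitude = 0, resp_jitter_frac = 0,
                 lv_radii_ed = c(25, 25, 35), lv_radii_es = c(24.99, 24.99, 34.99),
                 rv_geometry = list(center = c(0, -42, 0),
                                    radii_ed = c(28, 18, 30),
                                    radii_es = c(27.99, 17.99, 29.99),
                                    wall_mm = 4),
                 noise_sigma = 0, seed = 42)
}

# small dynamic free-breathing scan reused by gating / motion / binning tests
small_scan <- function() {
  cached_fixture("small_scan", {
    cfg <- phantom_config(matrix_size = c(48, 48, 16), fov_mm = c(192, 192, 96),
                          n_coils = 4, seed = 1)
    ph <- make_phantom(cfg)
    sch <- circus_schedule(cfg$matrix_size[2:3])
    bundle <- simulate_acquisition(ph, sch, duration_s = 45)
    beats <- sort_beats(bundle)
    low <- lowres_beat_volumes(bundle, beats)
    trace <- track_motion(low$volumes, low$spacing)
    list(config = cfg, phantom = ph, schedule = sch, bundle = bundle,
         beats = beats, low = low, trace = trace,
         truth = true_beat_displacement(ph, beats))
  })
}

# simple in-plane test image stack: fun(X, Y, slice) on an n1 x n2 grid
image_stack <- function(n = c(96, 96, 3), fun) {
  X <- matrix(seq_len(n[1]), n[1], n[2])
  Y <- matrix(seq_len(n[2]), n[1], n[2], byrow = TRUE)
  a <- array(0, n)
  for (s in seq_len(n[3])) a[, , s] <- fun(X, Y, s)
  a
}

dice_masks <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# exhaustive minimum total within-cluster variance over all partitions of the
# rows of X into exactly k non-empty blocks (restricted-growth enumeration);
# independent oracle for the k-means inertia
exhaustive_min_inertia <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  assign <- integer(n)
  inertia_of <- function(a) {
    tot <- 0
    for (c in seq_len(k)) {
      sel <- a == c
      m <- X[sel, , drop = FALSE]
      ctr <- colMeans(m)
      tot <- tot + sum(sweep(m, 2, ctr)^2)
    }
    tot
  }
  rec <- function(i, maxused) {
    if (i > n) {
      if (maxused == k) {
        v <- inertia_of(assign)
        if (v < best) best <<- v
      }
      return(invisible())
    }
    # prune: cannot reach k blocks with remaining items
    if (maxused + (n - i + 1) < k) return(invisible())
    for (c in seq_len(min(maxused + 1L, k))) {
      assign[i] <<- c
      rec(i + 1L, max(maxused, c))
    }
  }
  rec(1L, 0L)
  best
}

# brute-force DC-centered unitary 3D DFT sample at (kx, ky, kz) (0-based)
brute_dft_line <- function(vol, ky, kz) {
  n <- dim(vol)
  cx <- floor(n / 2)
  x0 <- seq_len(n[1]) - 1
  y0 <- seq_len(n[2]) - 1
  z0 <- seq_len(n[3]) - 1
  phy <- exp(-2i * pi * (ky - cx[2]) * y0 / n[2])
  phz <- exp(-2i * pi * (kz - cx[3]) * z0 / n[3])
  vapply(seq_len(n[1]) - 1, function(kx) {
    phx <- exp(-2i * pi * (kx - cx[1]) * x0 / n[1])
    sum(vol * outer(outer(phx, phy), phz)) / sqrt(prod(n))
  }, complex(1))
}

# small retrospectively undersampled dynamic acquisition built from the
# phantom renderer: known cine truth, known maps; R ~ 8 at the defaults
cine_problem <- function(ncard = 6, interleaves_per_phase = 2, seed = 5) {
  cached_fixture(paste("cineprob", ncard, interleaves_per_phase, seed), {
    cfg <- phantom_config(matrix_size = c(32, 32, 8), fov_mm = c(192, 192, 80),
                          n_coils = 4, resp_depth_mm = 0, noise_sigma = 0,
                          seed = seed)
    ph <- make_phantom(cfg)
    n <- cfg$matrix_size
    vols <- lapply(seq_len(ncard), function(p)
      ph$render_state((p - 0.5) / ncard, c(0, 0, 0)))
    maps <- ph$coil_maps
    rss <- array(sqrt(rowSums(matrix(Mod(maps)^2, prod(n), 4))), n)
    for (c in 1:4) maps[, , , c] <- maps[, , , c] / pmax(rss, 1e-6)
    sch <- circus_schedule(n[2:3], partial_fourier = 1)
    nil <- max(sch$interleave) + 1
    idx <- list(); y <- list()
    for (p in seq_len(ncard)) {
      ils <- ((p - 1) * interleaves_per_phase + seq_len(interleaves_per_phase) - 1) %% nil
      sel <- sch$interleave %in% ils
      pos <- unique(sch$ky[sel] + n[2] * sch$kz[sel])
      ii <- as.vector(outer(seq_len(n[1]), pos * n[1], `+`))
      K <- array(0i, c(n, 4))
      for (c in 1:4) K[, , , c] <- cine5d:::fftc(vols[[p]] * maps[, , , c])
      yy <- matrix(0i, length(ii), 4)
      for (c in 1:4) { Kc <- K[, , , c]; yy[, c] <- Kc[ii] }
      idx[[p]] <- ii; y[[p]] <- yy
    }
    truth <- array(0, c(n, ncard))
    for (p in seq_len(ncard)) truth[, , , p] <- vols[[p]]
    first <- sch$interleave %in% (seq_len(interleaves_per_phase) - 1)
    R <- prod(n[2:3]) / length(unique(sch$ky[first] + n[2] * sch$kz[first]))
    list(cell = list(idx = idx, y = y, dims = n, n_card = ncard, n_coils = 4,
                     resp_phase = "test"),
         maps = maps, truth = truth, R = R,
         support = array(sqrt(rowSums(matrix(Mod(maps)^2, prod(n), 4))), n) > 0.5)
  })
}

# scaled-down end-to-end study shared by the acceptance tests: the default
# phantom geometry with fewer coils and a shorter scan
acceptance_e2e <- function() {
  cached_fixture("acceptance_e2e", {
    cfg <- phantom_config(n_coils = 4)
    run_end_to_end(cfg, seed = 1, duration_s = 60, verbose = FALSE)
  })
}
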