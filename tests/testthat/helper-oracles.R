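# Independent oracles and shared fixtures. The direct non-uniform DFT
# below is the reference for the gridding NUFFT; it never shares code
# with the implementation under test.

# exact NDFT: s(k) = sum_p x[p] exp(-2i pi k . p / n), centered voxels
ndft_forward <- function(coords, x, grid, fov_mm) {
  nd <- length(grid)
  pos <- lapply(grid, function(m) seq_len(m) - 1 - m %/% 2)
  P <- as.matrix(do.call(expand.grid, pos))
  ph <- matrix(0, nrow(coords), nrow(P))
  for (ax in seq_len(nd))
    ph <- ph + outer(coords[, ax] * fov_mm, P[, ax]) / grid[ax]
  as.vector(exp(-2i * pi * ph) %*% as.vector(x))
}

# brute-force 0.01-degree grid search for the matched flip angle
grid_search_flip <- function(phantom, reference, alpha_ref) {
  target <- bssfp_signal_tr0(reference, alpha_ref)
  a <- seq(0.01, alpha_ref, by = 0.01)
  a[which.min(abs(bssfp_signal_tr0(phantom, a) - target))]
}

# all matching angles on the grid (the equality can have two roots when
# the phantom's signal peaks inside [0, alpha_ref])
grid_search_flip_all <- function(phantom, reference, alpha_ref) {
  target <- bssfp_signal_tr0(reference, alpha_ref)
  a <- seq(0.01, alpha_ref, by = 0.01)
  r <- bssfp_signal_tr0(phantom, a) - target
  cross <- which(r[-1] * r[-length(r)] <= 0)
  unique(c(a[cross], a[which.min(abs(r))]))
}

# minimal hand-built phantom: uniform tissue on a tiny grid, optionally
# a single active voxel
tiny_phantom <- function(n = 16, ndim = 2, voxel = 2, T1 = 450, T2 = 90,
                         PD = 0.7, mtr = 0, off_res = 0,
                         single_voxel = FALSE) {
  shape <- rep(n, ndim)
  pd <- array(PD, shape)
  if (single_voxel) {
    pd <- array(0, shape)
    ctr <- as.list(shape %/% 2 + 1)
    pd <- do.call(`[<-`, c(list(pd), ctr, PD))
  }
  lab <- array(ifelse(pd > 0, 3L, 0L), shape)
  structure(list(
    T1 = array(T1, shape), T2 = array(T2, shape), PD = pd,
    mtr_true = array(mtr, shape), off_res = array(off_res, shape),
    label = lab, voxel_size = voxel,
    tissues = data.frame(label = 3L, name = "wm", T1 = T1, T2 = T2,
                         PD = PD, mtr_true = mtr),
    coil_maps = NULL, frac = list(wm = array(as.numeric(pd > 0), shape)),
    meta = list(kind = "tiny", fov_mm = n * voxel)
  ), class = "digital_phantom")
}

# lazily-built shared fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

brain64 <- function() fixture("brain64", function() {
  make_brain_phantom(3, fov_mm = 192, ndim = 2, seed = 1)
})

brain64_onres <- function() fixture("brain64_onres", function() {
  make_brain_phantom(3, fov_mm = 192, ndim = 2, seed = 1,
                     offres_peak_hz = 0, offres_bulk_hz = 0)
})

coils64 <- function() fixture("coils64", function() {
  make_coil_maps(c(64, 64), 6, seed = 2)
})

proto2d <- function(preset = "hr_nonmt", n = 64, R = 3) {
  scale_protocol_2d(load_protocol(preset), n, 192, undersampling = R)
}

traj64 <- function() fixture("traj64", function() {
  build_bstar_trajectory(proto2d(), ndim = 2)
})

kspace64 <- function() fixture("kspace64", function() {
  simulate_bstar(brain64_onres(), traj64(), proto2d(), noise_sd = 0,
                 seed = 1, coil_maps = coils64())
})

maps64 <- function() fixture("maps64", function() {
  estimate_coil_sensitivities(kspace64(), c(64L, 64L), 192)
})
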