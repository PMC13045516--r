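# Seeded digital-phantom generators. Every generator is a pure function of
# (spec, seed): identical inputs give bit-identical outputs, and ground truth
# is recorded before noise corruption.

#' Phantom specification
#'
#' Describes a blockwise phantom: the spatial grid is split into `length(regions)`
#' equal slabs along the first axis, each slab carrying one ground-truth
#' parameter set; the mask labels all slabs with `label`.
#'
#' @param grid_shape spatial dimensions, length 3.
#' @param regions list of named parameter lists (model-dependent:
#'   `S0`/`ADC`, `S0`/`f`/`Dstar`/`D`/`K`, or `Ktrans`/`ve`/`vp`).
#' @param acquisition b-values (s/mm^2) for DWI or frame times (min) for DCE.
#' @param noise list `model` (`"none"`, `"gaussian"`, `"rician"`) and
#'   `sd_frac` (noise SD as a fraction of the voxel's true S0/baseline).
#' @param seed integer RNG seed; mandatory whenever noise is not `"none"`.
#' @param label mask label assigned to all regions.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, regions, acquisition,
                         noise = list(model = "none", sd_frac = 0),
                         seed = NULL, label = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    stop("phantom_spec: grid_shape must be 3 positive integers")
  }
  if (!length(regions)) stop("phantom_spec: at least one region required")
  if (is.null(noise$model)) noise$model <- "none"
  if (is.null(noise$sd_frac)) noise$sd_frac <- 0
  if (!noise$model %in% c("none", "gaussian", "rician")) {
    stop("phantom_spec: unknown noise model '", noise$model, "'")
  }
  if (noise$sd_frac < 0) stop("phantom_spec: noise sd must be >= 0")
  if (noise$model != "none" && is.null(seed)) {
    stop("phantom_spec: a seed is mandatory whenever noise is applied")
  }
  structure(list(grid_shape = as.integer(grid_shape), regions = regions,
                 acquisition = acquisition, noise = noise,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 label = as.integer(label)),
            class = "phantom_spec")
}

# Region index (1..R) per voxel: equal slabs along the first axis.
region_index_array <- function(grid_shape, n_regions) {
  nx <- grid_shape[1]
  slab <- ceiling(seq_len(nx) / (nx / n_regions))
  slab <- pmin(slab, n_regions)
  array(rep(slab, times = prod(grid_shape[2:3])), dim = grid_shape)
}

apply_phantom_noise <- function(signal_4d, s0_3d, noise, seed) {
  if (noise$model == "none" || noise$sd_frac == 0) return(signal_4d)
  rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(seed)
  sdv <- array(rep(s0_3d, times = dim(signal_4d)[4]), dim = dim(signal_4d)) * noise$sd_frac
  n1 <- array(rnorm(length(signal_4d)), dim = dim(signal_4d)) * sdv
  if (noise$model == "gaussian") return(signal_4d + n1)
  n2 <- array(rnorm(length(signal_4d)), dim = dim(signal_4d)) * sdv
  sqrt((signal_4d + n1)^2 + n2^2)   # magnitude of complex Gaussian noise
}

#' Generate a DWI phantom
#'
#' Noiseless voxel signals equal the forward model of the region's ground
#' truth exactly ([ngivim_signal()] when the region has `f`/`Dstar`/`K`
#' entries, [monoexp_signal()] otherwise); Rician or Gaussian noise is then
#' applied with the spec's seed.
#'
#' @param spec a [phantom_spec] whose `acquisition` lists b-values including 0.
#' @return list `volume` (4D [image_volume]), `mask` ([roi_mask]),
#'   `truth` (named list of 3D ground-truth maps), `bvalues`.
#' @export
make_dwi_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  b <- spec$acquisition
  if (!any(b == 0)) stop("make_dwi_phantom: acquisition must include b = 0")
  shp <- spec$grid_shape
  R <- length(spec$regions)
  reg <- region_index_array(shp, R)
  is_ngivim <- all(c("f", "Dstar", "D", "K") %in% names(spec$regions[[1]]))
  par_names <- if (is_ngivim) c("S0", "f", "Dstar", "D", "K") else c("S0", "ADC")
  for (r in spec$regions) {
    if (!all(par_names %in% names(r))) stop("make_dwi_phantom: region missing parameters")
  }
  curves <- lapply(spec$regions, function(p) {
    if (is_ngivim) ngivim_signal(p$S0, p$f, p$Dstar, p$D, p$K, b)
    else monoexp_signal(p$S0, p$ADC, b)
  })
  vol <- array(0, dim = c(shp, length(b)))
  truth <- setNames(lapply(par_names, function(pn) array(NaN, shp)), par_names)
  for (ri in seq_len(R)) {
    in_r <- reg == ri
    for (fi in seq_along(b)) {
      frame <- vol[, , , fi]; frame[in_r] <- curves[[ri]][fi]; vol[, , , fi] <- frame
    }
    for (pn in par_names) truth[[pn]][in_r] <- spec$regions[[ri]][[pn]]
  }
  vol <- apply_phantom_noise(vol, truth$S0, spec$noise, spec$seed)
  list(volume = image_volume(vol),
       mask = roi_mask(array(spec$label, shp)),
       truth = truth, bvalues = b)
}

#' Bi-exponential population arterial input function
#'
#' `Cp(t) = A1 exp(-m1 dt) + A2 exp(-m2 dt)` with `dt = t - bolus_arrival`
#' and `Cp = 0` before bolus arrival; a standard fast-plus-slow washout shape.
#' Defaults give a dynamic plasma curve over a ~3 min acquisition.
#'
#' @param t_min time grid (min), strictly increasing.
#' @param A1,A2 compartment amplitudes (mM, > 0).
#' @param m1,m2 decay rates (1/min, > 0).
#' @param bolus_arrival_min bolus arrival time (min).
#' @return an [aif].
#' @export
biexponential_aif <- function(t_min, A1 = 5, m1 = 3, A2 = 1, m2 = 0.05,
                              bolus_arrival_min = 0.25) {
  if (any(c(A1, A2, m1, m2) <= 0)) stop("biexponential_aif: amplitudes and rates must be > 0")
  if (any(diff(t_min) <= 0)) stop("biexponential_aif: time grid must be strictly increasing")
  dt <- t_min - bolus_arrival_min
  Cp <- ifelse(dt < 0, 0, A1 * exp(-m1 * dt) + A2 * exp(-m2 * dt))
  aif(t_min, Cp)
}

#' Generate a DCE phantom
#'
#' Per voxel: tissue concentration from [ext_tofts_forward()] on the region's
#' (Ktrans, ve, vp) truth, relaxation rate `R1(t) = 1/T10 + r1 Ct(t)`, then
#' the SPGR signal. Default timing is 35 frames at 5 s/phase. Noise is
#' applied to the magnitude signal with the spec's seed.
#'
#' @param spec a [phantom_spec] with `acquisition` = frame times (min) and
#'   regions holding `Ktrans`, `ve`, `vp`.
#' @param aif an [aif] on the same frame grid.
#' @param conversion a [conversion_settings].
#' @param T10_truth pre-contrast T1 (s), scalar.
#' @param M0 equilibrium signal scale.
#' @return list `volume` (4D signal), `mask`, `truth` (Ktrans/ve/vp/kep maps
#'   plus `T10`), `frame_times_min`, `aif`, `settings`, `M0`.
#' @export
make_dce_phantom <- function(spec, aif, conversion = conversion_settings(),
                             T10_truth = 1.16, M0 = 1000) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(aif, "aif"))
  t <- spec$acquisition
  if (!isTRUE(all.equal(as.numeric(t), aif$t_min))) {
    stop("make_dce_phantom: frame grid must match the AIF")
  }
  shp <- spec$grid_shape
  R <- length(spec$regions)
  reg <- region_index_array(shp, R)
  for (r in spec$regions) {
    if (!all(c("Ktrans", "ve", "vp") %in% names(r))) {
      stop("make_dce_phantom: regions need Ktrans, ve and vp")
    }
    if (r$ve <= 0 || r$ve > 1 || r$vp < 0 || r$vp > 1 || r$Ktrans < 0) {
      stop("make_dce_phantom: region parameters outside extended Tofts bounds")
    }
  }
  curves <- lapply(spec$regions, function(p) {
    Ct <- ext_tofts_forward(p$Ktrans, p$ve, p$vp, aif)
    concentration_to_signal(Ct, T10_truth, conversion, M0 = M0)
  })
  vol <- array(0, dim = c(shp, length(t)))
  par_names <- c("Ktrans", "ve", "vp")
  truth <- setNames(lapply(par_names, function(pn) array(NaN, shp)), par_names)
  for (ri in seq_len(R)) {
    in_r <- reg == ri
    for (fi in seq_along(t)) {
      frame <- vol[, , , fi]; frame[in_r] <- curves[[ri]][fi]; vol[, , , fi] <- frame
    }
    for (pn in par_names) truth[[pn]][in_r] <- spec$regions[[ri]][[pn]]
  }
  truth$kep <- truth$Ktrans / truth$ve
  truth$T10 <- array(T10_truth, shp)
  base <- array(vol[, , , 1], shp)
  vol <- apply_phantom_noise(vol, base, spec$noise, spec$seed)
  list(volume = image_volume(vol), mask = roi_mask(array(spec$label, shp)),
       truth = truth, frame_times_min = t, aif = aif,
       settings = conversion, M0 = M0)
}

#' Generate a variable-flip-angle series phantom
#'
#' Noiseless signals equal [spgr_signal()] exactly; Gaussian/Rician noise is
#' seeded.
#'
#' @param T10_truth pre-contrast T1 values (s); scalar or vector (one series
#'   per value).
#' @param M0 equilibrium signal scale.
#' @param flip_angles_deg flip angles (degrees); default the three-angle
#'   scheme `{2, 10, 15}`.
#' @param TR_s repetition time (s).
#' @param noise list as in [phantom_spec()].
#' @param seed RNG seed (mandatory with noise).
#' @return list of series: each has `flip_angles_deg`, `signals`, `TR_s`,
#'   `T10_truth`.
#' @export
make_vfa_phantom <- function(T10_truth = 1.16, M0 = 1000,
                             flip_angles_deg = c(2, 10, 15), TR_s = 0.005,
                             noise = list(model = "none", sd_frac = 0),
                             seed = NULL) {
  if (is.null(noise$model)) noise$model <- "none"
  if (noise$model != "none" && is.null(seed)) stop("make_vfa_phantom: seed required with noise")
  if (!is.null(seed)) {
    rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
  }
  lapply(T10_truth, function(T10) {
    s <- spgr_signal(M0, T10, flip_angles_deg, TR_s)
    if (noise$model == "gaussian") {
      s <- s + rnorm(length(s), sd = noise$sd_frac * M0)
    } else if (noise$model == "rician") {
      s <- sqrt((s + rnorm(length(s), sd = noise$sd_frac * M0))^2 +
                rnorm(length(s), sd = noise$sd_frac * M0)^2)
    }
    list(flip_angles_deg = flip_angles_deg, signals = s, TR_s = TR_s,
         T10_truth = T10)
  })
}

#' Generate a labelled synthetic feature dataset
#'
#' Two balanced classes; the first `n_informative` features carry a
#' class-mean offset of `class_separation` standard deviations, the rest are
#' i.i.d. standard normal noise. Which indices are informative is recorded in
#' the `informative` attribute.
#'
#' @param n_samples total samples (split evenly across classes).
#' @param n_features total features.
#' @param n_informative number of class-separating features (<= n_features).
#' @param class_separation offset between class means in SD units (>= 0).
#' @param seed RNG seed.
#' @return a [feature_matrix] with attribute `informative` (integer indices).
#' @export
make_feature_dataset <- function(n_samples = 200L, n_features = 50L,
                                 n_informative = 5L, class_separation = 2,
                                 seed = 1L) {
  if (n_informative > n_features) stop("make_feature_dataset: n_informative > n_features")
  if (class_separation < 0) stop("make_feature_dataset: class_separation must be >= 0")
  rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(seed)
  n1 <- floor(n_samples / 2); n0 <- n_samples - n1
  y <- c(rep(0L, n0), rep(1L, n1))
  X <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
  if (n_informative > 0) {
    X[y == 1L, seq_len(n_informative)] <-
      X[y == 1L, seq_len(n_informative)] + class_separation
  }
  fm <- feature_matrix(X, y)
  attr(fm, "informative") <- seq_len(n_informative)
  fm
}

#' Write a phantom to disk as NIfTI + sidecars
#'
#' Lays the phantom out exactly like real inputs: signal volume and mask as
#' NIfTI, the acquisition sidecar (b-values or frame times) as JSON, ground
#' truth as one NIfTI map per parameter plus a JSON manifest recording the
#' seed.
#'
#' @param phantom result of [make_dwi_phantom()] or [make_dce_phantom()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @param spec the generating [phantom_spec] (for the manifest).
#' @return named list of paths written, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom", spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$volume <- file.path(dir, paste0(stem, ".nii.gz"))
  write_volume(phantom$volume, paths$volume)
  paths$mask <- file.path(dir, paste0(stem, "_mask.nii.gz"))
  write_volume(image_volume(array(as.double(phantom$mask$data),
                                  dim = dim(phantom$mask$data)),
                            affine = phantom$volume$affine), paths$mask)
  sidecar <- if (!is.null(phantom$bvalues)) {
    list(bvalues_s_mm2 = phantom$bvalues)
  } else {
    list(frame_times_min = phantom$frame_times_min)
  }
  paths$sidecar <- file.path(dir, paste0(stem, "_acquisition.json"))
  jsonlite::write_json(sidecar, paths$sidecar, auto_unbox = FALSE, digits = NA)
  if (!is.null(phantom$aif)) {
    paths$aif <- file.path(dir, paste0(stem, "_aif.csv"))
    write.csv(data.frame(t_min = phantom$aif$t_min, Cp_mM = phantom$aif$Cp_mM),
              paths$aif, row.names = FALSE)
  }
  for (pn in names(phantom$truth)) {
    p <- file.path(dir, paste0(stem, "_truth_", pn, ".nii.gz"))
    write_volume(image_volume(phantom$truth[[pn]], affine = phantom$volume$affine), p)
    paths[[paste0("truth_", pn)]] <- p
  }
  manifest <- list(stem = stem,
                   seed = if (!is.null(spec) && !is.null(spec$seed)) spec$seed else NULL,
                   noise = if (!is.null(spec)) spec$noise else NULL,
                   truth_parameters = names(phantom$truth))
  paths$manifest <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(paths)
}
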