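# Diffusion parameter bounds (mm^2/s unless unitless). These are physiological
# ranges for pelvic tumour tissue; they also keep the slow (D) and fast (D*)
# compartments from swapping roles during optimisation.
DWI_BOUNDS <- list(
  ADC = c(1e-6, 4e-3),
  D = c(1e-6, 4e-3),
  Dstar = c(4e-3, 0.2),
  f = c(0, 1),
  K = c(0, 3)
)

# Flag bits shared by the voxelwise fitters (diagnostics maps are bit masks).
FIT_FLAGS <- c(ok = 0L, bound_hit = 1L, not_converged = 2L, fallback = 4L,
               kurtosis_clamped = 8L, perfusion_unidentifiable = 16L,
               input_invalid = 32L)

#' Monoexponential diffusion signal
#'
#' `S(b) = S0 * exp(-b * ADC)`: Gaussian diffusion decay of the DW signal with
#' b-value.
#'
#' @param S0 signal at b = 0 (arbitrary units, >= 0).
#' @param ADC apparent diffusion coefficient (mm^2/s, >= 0).
#' @param b diffusion weighting (s/mm^2, >= 0); may be a vector.
#' @return signal at each `b`.
#' @export
monoexp_signal <- function(S0, ADC, b) {
  if (any(S0 < 0) || any(ADC < 0) || any(b < 0)) {
    stop("monoexp_signal: S0, ADC and b must be non-negative")
  }
  S0 * exp(-b * ADC)
}

#' Non-Gaussian IVIM diffusion signal
#'
#' Two-compartment signal with a kurtosis-corrected tissue term:
#' `S(b) = S0 * (f * exp(-b*D*) + (1-f) * exp(-b*D + K*(b*D)^2/6))`.
#' The quadratic kurtosis term is a truncated cumulant expansion that
#' eventually turns upward at very large `b*D`; past the turning point
#' `b = 3/(K*D)` the tissue exponent is held at its minimum so the signal stays
#' non-increasing, and the result carries a `clamped` attribute.
#'
#' @param S0 signal at b = 0.
#' @param f perfusion (pseudo-diffusion) fraction in \[0, 1\].
#' @param Dstar pseudo-diffusion coefficient (mm^2/s).
#' @param D true diffusion coefficient (mm^2/s).
#' @param K kurtosis coefficient (unitless, \[0, 3\]).
#' @param b diffusion weighting (s/mm^2); may be a vector.
#' @return signal at each `b`, with attribute `clamped` (logical).
#' @export
ngivim_signal <- function(S0, f, Dstar, D, K, b) {
  if (any(b < 0)) stop("ngivim_signal: b must be non-negative")
  if (S0 < 0) stop("ngivim_signal: S0 must be non-negative")
  if (f < DWI_BOUNDS$f[1] || f > DWI_BOUNDS$f[2]) stop("ngivim_signal: f outside [0, 1]")
  if (K < DWI_BOUNDS$K[1] || K > DWI_BOUNDS$K[2]) stop("ngivim_signal: K outside [0, 3]")
  if (D < DWI_BOUNDS$D[1] || D > DWI_BOUNDS$D[2]) stop("ngivim_signal: D outside bounds")
  if (Dstar < DWI_BOUNDS$Dstar[1] || Dstar > DWI_BOUNDS$Dstar[2]) {
    stop("ngivim_signal: Dstar outside bounds")
  }
  if (D > Dstar) stop("ngivim_signal: require D <= Dstar")
  s <- ngivim_signal_unchecked(S0, f, Dstar, D, K, b)
  s
}

# Same model without argument validation; used inside optimiser residuals where
# the parameter box already enforces the bounds.
ngivim_signal_unchecked <- function(S0, f, Dstar, D, K, b) {
  expo <- -b * D + (K * (b * D)^2) / 6
  clamped <- FALSE
  if (K > 0 && D > 0) {
    b_turn <- 3 / (K * D)
    over <- b > b_turn
    if (any(over)) {
      expo[over] <- -b_turn * D + (K * (b_turn * D)^2) / 6
      clamped <- TRUE
    }
  }
  out <- S0 * (f * exp(-b * Dstar) + (1 - f) * exp(expo))
  attr(out, "clamped") <- clamped
  out
}

validate_dwi_series <- function(bvalues, signals) {
  if (length(bvalues) != length(signals)) stop("b-value and signal lengths differ")
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (any(signals < 0)) stop("signals must be non-negative")
  o <- order(bvalues)
  list(b = bvalues[o], s = signals[o])
}

#' Fit the monoexponential ADC model
#'
#' Weighted log-linear least squares (weights proportional to squared signal,
#' the first-order variance correction for log-transformed data). Non-positive
#' signals force a bounded nonlinear fallback fit, which is flagged. ADC is
#' clamped to \[1e-6, 4e-3\] mm^2/s and flagged when a bound is hit.
#'
#' @param bvalues diffusion weightings (s/mm^2), >= 2 distinct values.
#' @param signals per-voxel signal at each b.
#' @return list `S0`, `ADC`, `rss` (signal-domain residual sum of squares),
#'   `converged`, `flags` (integer bit mask).
#' @export
fit_monoexp <- function(bvalues, signals) {
  ser <- validate_dwi_series(bvalues, signals)
  b <- ser$b; s <- ser$s
  if (length(unique(b)) < 2L) stop("fit_monoexp: need >= 2 distinct b-values (insufficient data)")
  flags <- 0L
  if (all(s > 0)) {
    fit <- lm(log(s) ~ b, weights = s^2)
    adc <- -coef(fit)[[2]]
    S0 <- exp(coef(fit)[[1]])
    converged <- TRUE
  } else {
    # log transform unavailable: bounded Levenberg-Marquardt on the raw signal
    flags <- flags + FIT_FLAGS[["fallback"]]
    start <- c(S0 = max(s, 1e-6), ADC = 1e-3)
    res <- minpack.lm::nls.lm(
      par = start,
      lower = c(1e-9, DWI_BOUNDS$ADC[1]), upper = c(Inf, DWI_BOUNDS$ADC[2]),
      fn = function(p) s - p[[1]] * exp(-b * p[[2]]))
    S0 <- res$par[[1]]; adc <- res$par[[2]]
    converged <- res$info %in% 1:4
  }
  lo <- DWI_BOUNDS$ADC[1]; hi <- DWI_BOUNDS$ADC[2]
  if (adc < lo || adc > hi) {
    adc <- min(max(adc, lo), hi)
    flags <- flags + FIT_FLAGS[["bound_hit"]]
  }
  pred <- S0 * exp(-b * adc)
  list(S0 = S0, ADC = adc, rss = sum((s - pred)^2),
       converged = converged, flags = flags)
}

#' Fit the non-Gaussian IVIM model
#'
#' Default `segmented` strategy: (1) a log-quadratic kurtosis fit on the
#' high-b tail (`b >= b_split`) gives D, K and the tissue-only intercept; (2)
#' the perfusion fraction follows from the measured S0 versus that intercept
#' and D* is fitted on the full curve with the tail parameters held; (3) one
#' bounded joint Levenberg-Marquardt refinement of all five parameters.
#' `joint` skips the segmented initialisation and refines from a generic start.
#'
#' @param bvalues diffusion weightings; need >= 6 distinct values spanning
#'   b < 100 and b >= 800 s/mm^2.
#' @param signals per-voxel signal at each b.
#' @param strategy `"segmented"` (default) or `"joint"`.
#' @param b_split tail threshold for the segmented step (s/mm^2); above this
#'   the pseudo-diffusion term is essentially fully decayed for D* ~ 25e-3.
#' @return list `S0`, `f`, `Dstar`, `D`, `K`, `rss`, `converged`, `flags`.
#' @export
fit_ngivim <- function(bvalues, signals, strategy = c("segmented", "joint"),
                       b_split = 200) {
  strategy <- match.arg(strategy)
  ser <- validate_dwi_series(bvalues, signals)
  b <- ser$b; s <- ser$s
  if (length(unique(b)) < 6L || min(b) >= 100 || max(b) < 800) {
    stop("fit_ngivim: need >= 6 distinct b-values spanning b < 100 and b >= 800 (insufficient data)")
  }
  flags <- 0L
  lower <- c(S0 = 1e-9, f = DWI_BOUNDS$f[1], Dstar = DWI_BOUNDS$Dstar[1],
             D = DWI_BOUNDS$D[1], K = DWI_BOUNDS$K[1])
  upper <- c(S0 = Inf, f = DWI_BOUNDS$f[2], Dstar = DWI_BOUNDS$Dstar[2],
             D = DWI_BOUNDS$D[2], K = DWI_BOUNDS$K[2])

  S0_obs <- mean(s[b == min(b)])
  if (strategy == "segmented" && all(s > 0)) {
    tail_i <- b >= b_split
    bt <- b[tail_i]; st <- s[tail_i]
    if (length(unique(bt)) >= 3L) {
      qfit <- lm(log(st) ~ bt + I(bt^2))
      a <- coef(qfit)
      D0 <- -a[[2]]
      K0 <- if (D0 > 0) 6 * a[[3]] / D0^2 else 0
      S0t <- exp(a[[1]])
    } else {
      lfit <- lm(log(st) ~ bt)
      D0 <- -coef(lfit)[[2]]; K0 <- 0; S0t <- exp(coef(lfit)[[1]])
    }
    D0 <- min(max(D0, lower[["D"]]), upper[["D"]])
    K0 <- min(max(K0, lower[["K"]]), upper[["K"]])
    f0 <- min(max(1 - S0t / S0_obs, 0), 0.6)
    # perfusion-compartment fit on the full curve, tail parameters held
    pf <- minpack.lm::nls.lm(
      par = c(f = max(f0, 1e-3), Dstar = 20e-3),
      lower = c(lower[["f"]], lower[["Dstar"]]),
      upper = c(upper[["f"]], upper[["Dstar"]]),
      fn = function(p) {
        s - ngivim_signal_unchecked(S0_obs, p[[1]], p[[2]], D0, K0, b)
      })
    start <- c(S0 = S0_obs, f = pf$par[[1]], Dstar = pf$par[[2]], D = D0, K = K0)
  } else {
    if (strategy == "segmented") flags <- flags + FIT_FLAGS[["fallback"]]
    start <- c(S0 = S0_obs, f = 0.1, Dstar = 20e-3, D = 1e-3, K = 0.5)
  }
  start <- pmin(pmax(start, lower + 1e-12), pmin(upper, 1e12))
  joint <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) s - ngivim_signal_unchecked(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]], b),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- joint$par
  pred <- ngivim_signal_unchecked(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]], b)
  if (isTRUE(attr(pred, "clamped"))) flags <- flags + FIT_FLAGS[["kurtosis_clamped"]]
  interior <- c(f = FALSE, Dstar = TRUE, D = TRUE, K = FALSE)  # f=0, K=0 are valid
  hit <- (abs(p[2:5] - lower[2:5]) < 1e-10 & interior) |
         (abs(p[2:5] - upper[2:5]) < 1e-10)
  if (any(hit)) flags <- flags + FIT_FLAGS[["bound_hit"]]
  if (p[[3]] < 2 * p[[4]]) flags <- flags + FIT_FLAGS[["perfusion_unidentifiable"]]
  converged <- joint$info %in% 1:4
  if (!converged) flags <- flags + FIT_FLAGS[["not_converged"]]
  list(S0 = p[[1]], f = p[[2]], Dstar = p[[3]], D = p[[4]], K = p[[5]],
       rss = sum((s - pred)^2), converged = converged, flags = flags)
}

#' Voxelwise DWI model fitting over a masked volume
#'
#' Fits every voxel of `mask` label `label` independently; unmasked voxels are
#' NaN in the output maps. Per-voxel failures are flagged in the diagnostics
#' map and never abort the volume.
#'
#' @param volume 4D [image_volume]; frame count must equal `length(bvalues)`.
#' @param bvalues diffusion weightings (s/mm^2), one per frame (any order;
#'   sorted internally with frames permuted to match).
#' @param mask an [roi_mask] on the same spatial grid.
#' @param model `"monoexp"` or `"ngivim"`.
#' @param label mask label to fit (default 1).
#' @param ... passed to the per-voxel fitter.
#' @return list of 3D [image_volume] maps: `S0` and `ADC` (monoexp) or `S0`,
#'   `f`, `Dstar`, `D`, `K` (ngivim), plus `flags` (integer diagnostics map;
#'   see `FIT_FLAGS`) and `n_fitted`.
#' @export
fit_dwi_volume <- function(volume, bvalues, mask, model = c("monoexp", "ngivim"),
                           label = 1L, ...) {
  model <- match.arg(model)
  stopifnot(inherits(volume, "image_volume"))
  if (dim(volume$data)[4L] != length(bvalues)) {
    stop("fit_dwi_volume: frame count does not equal b-value count")
  }
  check_alignment(volume, mask)
  shape <- spatial_shape(volume)
  par_names <- if (model == "monoexp") c("S0", "ADC") else c("S0", "f", "Dstar", "D", "K")
  maps <- setNames(lapply(par_names, function(p) array(NaN, shape)), par_names)
  flags_map <- array(NaN, shape)
  n_fitted <- 0L
  if (any(mask$data == label)) {
    rois <- extract_roi_signals(volume, mask, label)
    for (i in seq_len(nrow(rois$index))) {
      sig <- rois$signals[i, ]
      res <- tryCatch(
        if (model == "monoexp") fit_monoexp(bvalues, sig, ...)
        else fit_ngivim(bvalues, sig, ...),
        error = function(e) NULL)
      ix <- rois$index[i, , drop = FALSE]
      if (is.null(res)) {
        flags_map[ix] <- FIT_FLAGS[["input_invalid"]]
      } else {
        for (p in par_names) maps[[p]][ix] <- res[[p]]
        flags_map[ix] <- res$flags
        n_fitted <- n_fitted + 1L
      }
    }
  }
  out <- lapply(maps, image_volume, affine = volume$affine, spacing = volume$spacing)
  out$flags <- image_volume(flags_map, affine = volume$affine, spacing = volume$spacing)
  out$n_fitted <- n_fitted
  out
}

#' Write DWI parametric maps to NIfTI files
#'
#' @param maps result of [fit_dwi_volume()].
#' @param stem output path stem; files are named `<stem>_<param>.nii.gz`.
#' @return character vector of paths written, invisibly.
#' @export
write_dwi_maps <- function(maps, stem) {
  nm <- setdiff(names(maps), "n_fitted")
  paths <- vapply(nm, function(p) {
    path <- paste0(stem, "_", p, ".nii.gz")
    write_volume(maps[[p]], path)
    path
  }, character(1))
  invisible(paths)
}
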