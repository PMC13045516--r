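# Tracer-kinetic and relaxometry models for DCE-MRI quantification.
# Time is handled in minutes internally; Ktrans and kep are reported in 1/min.
# T1/TR are in seconds (relaxometry convention), concentrations in mM.

T10_BOUNDS <- c(0.05, 10)          # s
EXT_TOFTS_LOWER <- c(Ktrans = 0, ve = 1e-6, vp = 0)
EXT_TOFTS_UPPER <- c(Ktrans = 5, ve = 1, vp = 1)

#' Spoiled gradient-echo steady-state signal
#'
#' `S = M0 * sin(a) * (1 - E) / (1 - E cos(a))` with `E = exp(-TR/T1)`; the
#' signal model behind variable-flip-angle T1 mapping and DCE signal
#' conversion.
#'
#' @param M0 equilibrium signal scale.
#' @param T1_s longitudinal relaxation time (s, > 0).
#' @param flip_angle_deg flip angle in degrees, in (0, 90\] (0 allowed: sin 0 = 0).
#' @param TR_s repetition time (s, > 0).
#' @return steady-state signal (vectorised over any argument).
#' @export
spgr_signal <- function(M0, T1_s, flip_angle_deg, TR_s) {
  if (any(T1_s <= 0)) stop("spgr_signal: T1_s must be > 0")
  if (any(TR_s <= 0)) stop("spgr_signal: TR_s must be > 0")
  if (any(flip_angle_deg < 0) || any(flip_angle_deg > 90)) {
    stop("spgr_signal: flip angle must lie in [0, 90] degrees")
  }
  a <- flip_angle_deg * pi / 180
  E <- exp(-TR_s / T1_s)
  M0 * sin(a) * (1 - E) / (1 - E * cos(a))
}

#' Variable-flip-angle T1 fit
#'
#' Linearises the SPGR equation as `S/sin(a) = E * S/tan(a) + M0 (1-E)` so the
#' slope over flip angles is `E = exp(-TR/T10)`, then applies one bounded
#' nonlinear refinement. A slope outside (0, 1) is non-physical: the fit is
#' flagged and T10 clamped to \[0.05, 10\] s.
#'
#' @param flip_angles_deg >= 2 distinct flip angles (degrees, in (0, 90\]).
#' @param signals measured signal at each angle (> 0).
#' @param TR_s repetition time (s).
#' @return list `T10_s`, `M0`, `converged`, `flags`.
#' @export
fit_t10_vfa <- function(flip_angles_deg, signals, TR_s) {
  if (length(flip_angles_deg) != length(signals)) stop("fit_t10_vfa: length mismatch")
  if (length(unique(flip_angles_deg)) < 2L) stop("fit_t10_vfa: need >= 2 distinct flip angles")
  if (any(flip_angles_deg <= 0) || any(flip_angles_deg > 90)) {
    stop("fit_t10_vfa: flip angles must lie in (0, 90] degrees")
  }
  if (any(signals <= 0)) stop("fit_t10_vfa: signals must be positive")
  if (TR_s <= 0) stop("fit_t10_vfa: TR_s must be > 0")
  a <- flip_angles_deg * pi / 180
  degenerate <- sd(signals) < 1e-12 * mean(signals)  # angle-independent signal
  y <- signals / sin(a)
  x <- signals / tan(a)
  lf <- lm(y ~ x)
  E <- coef(lf)[[2]]
  flags <- if (degenerate) FIT_FLAGS[["input_invalid"]] else 0L
  if (!is.finite(E) || E <= 0 || E >= 1) {
    flags <- flags + FIT_FLAGS[["bound_hit"]]
    T10 <- if (is.finite(E) && E >= 1) T10_BOUNDS[2] else T10_BOUNDS[1]
    M0 <- max(signals) / spgr_signal(1, T10, flip_angles_deg[which.max(signals)], TR_s)
    return(list(T10_s = T10, M0 = M0, converged = FALSE, flags = flags))
  }
  T10 <- -TR_s / log(E)
  M0 <- coef(lf)[[1]] / (1 - E)
  clamped <- FALSE
  if (T10 < T10_BOUNDS[1] || T10 > T10_BOUNDS[2]) {
    T10 <- min(max(T10, T10_BOUNDS[1]), T10_BOUNDS[2])
    clamped <- TRUE
  }
  ref <- minpack.lm::nls.lm(
    par = c(T10 = T10, M0 = max(M0, 1e-9)),
    lower = c(T10_BOUNDS[1], 1e-12), upper = c(T10_BOUNDS[2], Inf),
    fn = function(p) signals - spgr_signal(p[[2]], p[[1]], flip_angles_deg, TR_s))
  T10 <- ref$par[[1]]; M0 <- ref$par[[2]]
  if (clamped || abs(T10 - T10_BOUNDS[1]) < 1e-9 || abs(T10 - T10_BOUNDS[2]) < 1e-9) {
    flags <- flags + FIT_FLAGS[["bound_hit"]]
  }
  list(T10_s = T10, M0 = M0, converged = ref$info %in% 1:4, flags = flags)
}

#' Conversion settings for DCE signal-concentration mapping
#'
#' @param r1_mM_s contrast-agent longitudinal relaxivity (1/mM/s, > 0).
#' @param n_baseline number of pre-contrast frames used for calibration (>= 1).
#' @param TR_s repetition time of the dynamic acquisition (s).
#' @param flip_angle_deg flip angle of the dynamic acquisition (degrees).
#' @return a `conversion_settings` list.
#' @export
conversion_settings <- function(r1_mM_s = 3.9, n_baseline = 3L, TR_s = 0.005,
                                flip_angle_deg = 25) {
  if (r1_mM_s <= 0) stop("conversion_settings: r1 must be > 0")
  if (n_baseline < 1) stop("conversion_settings: n_baseline must be >= 1")
  structure(list(r1_mM_s = r1_mM_s, n_baseline = as.integer(n_baseline),
                 TR_s = TR_s, flip_angle_deg = flip_angle_deg),
            class = "conversion_settings")
}

#' Arterial input function container
#'
#' @param t_min frame times (min), strictly increasing.
#' @param Cp_mM plasma contrast concentration (mM, >= 0).
#' @return an `aif` list.
#' @export
aif <- function(t_min, Cp_mM) {
  if (length(t_min) != length(Cp_mM)) stop("aif: length mismatch")
  if (any(diff(t_min) <= 0)) stop("aif: time grid must be strictly increasing")
  if (any(Cp_mM < 0)) stop("aif: Cp must be non-negative")
  structure(list(t_min = as.numeric(t_min), Cp_mM = as.numeric(Cp_mM)), class = "aif")
}

# Invert the SPGR equation for E = exp(-TR/T1) given the signal.
spgr_invert_E <- function(S, M0, flip_angle_deg) {
  a <- flip_angle_deg * pi / 180
  (M0 * sin(a) - S) / (M0 * sin(a) - S * cos(a))
}

#' Convert a dynamic signal curve to contrast-agent concentration
#'
#' Calibrates M0 from the pre-contrast baseline (mean of the first
#' `n_baseline` frames, with `R10 = 1/T10`), inverts the SPGR equation for
#' `R1(t)` frame by frame, and applies the fast-exchange-limit linear relation
#' `Ct(t) = (R1(t) - R10) / r1`. Frames whose signal cannot be inverted
#' (saturation) get non-finite Ct and a flag.
#'
#' @param signal_t dynamic signal values, one per frame.
#' @param t_min frame times (min).
#' @param T10_s pre-contrast T1 (s, > 0).
#' @param settings a [conversion_settings] object.
#' @param method `"spgr"` (exact inversion, default) or `"linear"` — the
#'   small-enhancement approximation `dR1 = (S - S_base)/S_base / T10`,
#'   offered for comparison; it is accurate only while `r1 Ct T10 << 1`.
#' @return list `t_min`, `Ct_mM`, `R1_t` (1/s), `flags` (per-frame logical:
#'   TRUE where inversion failed).
#' @export
signal_to_concentration <- function(signal_t, t_min, T10_s, settings,
                                    method = c("spgr", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(settings, "conversion_settings"))
  if (T10_s <= 0) stop("signal_to_concentration: T10 must be > 0")
  if (length(signal_t) != length(t_min)) stop("signal_to_concentration: length mismatch")
  nb <- settings$n_baseline
  if (nb >= length(signal_t)) stop("signal_to_concentration: n_baseline >= number of frames")
  S_base <- mean(signal_t[seq_len(nb)])
  if (!is.finite(S_base) || S_base <= 0) {
    stop("signal_to_concentration: non-positive baseline signal (conversion error)")
  }
  R10 <- 1 / T10_s
  if (method == "linear") {
    dR1 <- (signal_t - S_base) / S_base * R10
    return(list(t_min = t_min, Ct_mM = dR1 / settings$r1_mM_s, R1_t = R10 + dR1,
                flags = rep(FALSE, length(signal_t))))
  }
  M0 <- S_base / spgr_signal(1, T10_s, settings$flip_angle_deg, settings$TR_s)
  E <- spgr_invert_E(signal_t, M0, settings$flip_angle_deg)
  bad <- !is.finite(E) | E <= 0 | E >= 1
  R1 <- rep(NaN, length(signal_t))
  R1[!bad] <- -log(E[!bad]) / settings$TR_s
  Ct <- (R1 - R10) / settings$r1_mM_s
  list(t_min = t_min, Ct_mM = Ct, R1_t = R1, flags = bad)
}

#' Convert a concentration curve back to dynamic signal
#'
#' Inverse helper of [signal_to_concentration()]: `R1(t) = R10 + r1 Ct(t)`
#' then the SPGR forward model with the given M0.
#'
#' @param Ct_mM concentration values (mM).
#' @param T10_s pre-contrast T1 (s).
#' @param settings a [conversion_settings] object.
#' @param M0 equilibrium signal scale.
#' @return signal vector, one per frame.
#' @export
concentration_to_signal <- function(Ct_mM, T10_s, settings, M0 = 1000) {
  stopifnot(inherits(settings, "conversion_settings"))
  R1 <- 1 / T10_s + settings$r1_mM_s * Ct_mM
  spgr_signal(M0, 1 / R1, settings$flip_angle_deg, settings$TR_s)
}

#' Patlak graphical fit
#'
#' Ordinary least squares of `Ct(t)/Cp(t)` against the normalised cumulative
#' plasma exposure `int_0^t Cp dtau / Cp(t)` (trapezoidal integration). The
#' slope is Ktrans (1/min) and the intercept the plasma volume fraction vp,
#' under the unidirectional (no-backflux) assumption. Frames before bolus
#' arrival or with Cp below `cp_floor` times the Cp peak are excluded and
#' counted.
#'
#' @param Ct_mM tissue concentration (mM), one per frame.
#' @param t_min frame times (min) shared with the AIF.
#' @param aif an [aif] on the same time grid.
#' @param t_window optional `c(t_start, t_end)` (min) restricting the fit.
#' @param cp_floor exclusion threshold as a fraction of peak Cp.
#' @return list `Ktrans_per_min`, `vp`, `r2`, `n_used`, `n_excluded`.
#' @export
patlak_fit <- function(Ct_mM, t_min, aif, t_window = NULL, cp_floor = 0.05) {
  stopifnot(inherits(aif, "aif"))
  if (length(Ct_mM) != length(t_min)) stop("patlak_fit: Ct/t length mismatch")
  if (!isTRUE(all.equal(t_min, aif$t_min))) {
    stop("patlak_fit: curve and AIF must share the time grid (resample beforehand)")
  }
  Cp <- aif$Cp_mM
  cum <- pracma::cumtrapz(t_min, Cp)[, 1]
  use <- is.finite(Ct_mM) & Cp > cp_floor * max(Cp)
  if (!is.null(t_window)) use <- use & t_min >= t_window[1] & t_min <= t_window[2]
  if (sum(use) < 3L) stop("patlak_fit: fewer than 3 usable frames (insufficient data)")
  x <- cum[use] / Cp[use]
  y <- Ct_mM[use] / Cp[use]
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(Ktrans_per_min = coef(fit)[[2]], vp = coef(fit)[[1]], r2 = r2,
       n_used = sum(use), n_excluded = sum(!use))
}

#' Extended Tofts forward model
#'
#' `Ct(t) = Ktrans * int_0^t exp(-kep (t - tau)) Cp(tau) dtau + vp Cp(t)` with
#' `kep = Ktrans/ve`, evaluated on the AIF time grid by trapezoidal
#' quadrature. The `kep -> 0` limit (plain cumulative integral) is taken when
#' `Ktrans > 0` and `ve` is at its upper bound or `kep` underflows.
#'
#' @param Ktrans volume transfer constant (1/min, >= 0).
#' @param ve extravascular-extracellular volume fraction (0 < ve <= 1 whenever
#'   Ktrans > 0).
#' @param vp plasma volume fraction (\[0, 1\]).
#' @param aif an [aif] object.
#' @return tissue concentration (mM) on `aif$t_min`.
#' @export
ext_tofts_forward <- function(Ktrans, ve, vp, aif) {
  stopifnot(inherits(aif, "aif"))
  if (Ktrans < 0) stop("ext_tofts_forward: Ktrans must be >= 0")
  if (vp < 0 || vp > 1) stop("ext_tofts_forward: vp outside [0, 1]")
  if (Ktrans > 0 && (ve <= 0 || ve > 1)) stop("ext_tofts_forward: ve outside (0, 1] with Ktrans > 0")
  ext_tofts_forward_unchecked(Ktrans, ve, vp, aif$t_min, aif$Cp_mM)
}

ext_tofts_forward_unchecked <- function(Ktrans, ve, vp, t, Cp) {
  n <- length(t)
  if (Ktrans <= 0) return(vp * Cp)
  kep <- Ktrans / ve
  if (kep < 1e-12) {
    conv <- pracma::cumtrapz(t, Cp)[, 1]
  } else {
    # exp(-kep(t_i - tau)) Cp(tau) integrated by trapezoid; O(n) via the
    # exponential's semigroup property on successive intervals
    conv <- numeric(n)
    for (i in 2:n) {
      dt <- t[i] - t[i - 1]
      ek <- exp(-kep * dt)
      conv[i] <- conv[i - 1] * ek + dt * (Cp[i] + Cp[i - 1] * ek) / 2
    }
  }
  Ktrans * conv + vp * Cp
}

#' Fit the extended Tofts model
#'
#' Bounded nonlinear least squares over (Ktrans, ve, vp) with three starts: a
#' Patlak-informed start plus two generic ones; the best residual wins. kep is
#' derived as Ktrans/ve, never fitted independently.
#'
#' @param Ct_mM tissue concentration (mM); >= 10 frames.
#' @param t_min frame times (min).
#' @param aif an [aif] on the same grid.
#' @return list `Ktrans_per_min`, `ve`, `vp`, `kep_per_min`, `rss`,
#'   `converged`, `flags`.
#' @export
fit_ext_tofts <- function(Ct_mM, t_min, aif) {
  stopifnot(inherits(aif, "aif"))
  ok <- is.finite(Ct_mM)
  if (sum(ok) < 10L) stop("fit_ext_tofts: fewer than 10 usable frames (insufficient data)")
  if (!isTRUE(all.equal(t_min, aif$t_min))) {
    stop("fit_ext_tofts: curve and AIF must share the time grid")
  }
  t <- t_min; Cp <- aif$Cp_mM
  resid_fn <- function(p) {
    pred <- ext_tofts_forward_unchecked(p[[1]], p[[2]], p[[3]], t, Cp)
    (Ct_mM - pred)[ok]
  }
  starts <- list(c(Ktrans = 0.1, ve = 0.2, vp = 0.02),
                 c(Ktrans = 0.5, ve = 0.5, vp = 0.05))
  pk <- tryCatch(patlak_fit(Ct_mM, t_min, aif), error = function(e) NULL)
  if (!is.null(pk)) {
    starts <- c(list(c(Ktrans = min(max(pk$Ktrans_per_min, 0.01), 2),
                       ve = 0.3,
                       vp = min(max(pk$vp, 0.001), 0.5))), starts)
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(minpack.lm::nls.lm(
      par = st, lower = EXT_TOFTS_LOWER, upper = EXT_TOFTS_UPPER,
      fn = resid_fn, control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("fit_ext_tofts: optimiser failed from all starts")
  p <- best$par
  flags <- 0L
  if (p[[2]] + p[[3]] > 1 + 1e-9) flags <- flags + FIT_FLAGS[["bound_hit"]]
  converged <- best$info %in% 1:4
  if (!converged) flags <- flags + FIT_FLAGS[["not_converged"]]
  list(Ktrans_per_min = p[[1]], ve = p[[2]], vp = p[[3]],
       kep_per_min = if (p[[2]] > 0) p[[1]] / p[[2]] else NaN,
       rss = best$deviance, converged = converged, flags = flags)
}

#' Voxelwise DCE model fitting over a masked volume
#'
#' Converts every masked voxel's dynamic signal to concentration via
#' [signal_to_concentration()], then fits the chosen tracer-kinetic model.
#' Unmasked voxels are NaN; per-voxel failures are flagged, never fatal.
#'
#' @param volume 4D dynamic [image_volume].
#' @param frame_times_min frame times (min), one per frame.
#' @param aif an [aif] on the frame-time grid.
#' @param T10 scalar pre-contrast T1 (s) or a 3D map ([image_volume]/array).
#' @param settings a [conversion_settings] object.
#' @param mask an [roi_mask].
#' @param model `"patlak"` or `"ext_tofts"`.
#' @param label mask label to fit.
#' @return list of 3D maps: `Ktrans`, `vp` (+ `ve`, `kep` for ext_tofts),
#'   `flags`, and `n_fitted`.
#' @export
fit_dce_volume <- function(volume, frame_times_min, aif, T10, settings, mask,
                           model = c("patlak", "ext_tofts"), label = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(volume, "image_volume"))
  if (dim(volume$data)[4L] != length(frame_times_min)) {
    stop("fit_dce_volume: frame count does not equal frame-time count")
  }
  if (!isTRUE(all.equal(as.numeric(frame_times_min), aif$t_min))) {
    stop("fit_dce_volume: AIF time grid must match the frame times")
  }
  check_alignment(volume, mask)
  shape <- spatial_shape(volume)
  t10_arr <- if (inherits(T10, "image_volume")) T10$data
             else if (is.array(T10)) T10 else array(T10, shape)
  par_names <- if (model == "patlak") c("Ktrans", "vp") else c("Ktrans", "ve", "vp", "kep")
  maps <- setNames(lapply(par_names, function(p) array(NaN, shape)), par_names)
  flags_map <- array(NaN, shape)
  n_fitted <- 0L
  if (any(mask$data == label)) {
    rois <- extract_roi_signals(volume, mask, label)
    for (i in seq_len(nrow(rois$index))) {
      ix <- rois$index[i, , drop = FALSE]
      res <- tryCatch({
        conv <- signal_to_concentration(rois$signals[i, ], frame_times_min,
                                        t10_arr[ix], settings)
        if (model == "patlak") {
          pk <- patlak_fit(conv$Ct_mM, frame_times_min, aif)
          list(Ktrans = pk$Ktrans_per_min, vp = pk$vp,
               flags = if (any(conv$flags)) FIT_FLAGS[["input_invalid"]] else 0L)
        } else {
          et <- fit_ext_tofts(conv$Ct_mM, frame_times_min, aif)
          list(Ktrans = et$Ktrans_per_min, ve = et$ve, vp = et$vp,
               kep = et$kep_per_min,
               flags = et$flags + if (any(conv$flags)) FIT_FLAGS[["input_invalid"]] else 0L)
        }
      }, error = function(e) NULL)
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
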