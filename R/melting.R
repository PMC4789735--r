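# Junction melting analysis: distance-based single-strand fraction, the
# tetramolecular two-state van't Hoff model
#   K(T) = exp(dS/R - dH/(R T)) = alpha^4 (C/4)^3 / (1 - alpha),
# its least-squares fit, the alpha(T_M) = 1/2 identity, and Debye-Hueckel
# screening lengths.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.987204e-3

# CODATA physical constants (SI)
.KB <- 1.380649e-23
.E_CHARGE <- 1.602176634e-19
.EPS0 <- 8.8541878128e-12
.N_AVOGADRO <- 6.02214076e23

#' Criteria defining intact base pairs and single strands
#'
#' A base-pair bond is intact when the base-site separation is below `cutoff`
#' (default 10 Angstrom); a strand is single when strictly more than
#' `threshold` of its possible base-pair links are broken.
#'
#' @param cutoff base-pair contact cutoff, Angstrom (5-15)
#' @param threshold broken-link fraction above which a strand is single,
#'   in (0, 1)
#' @return object of class `melting_criteria`
#' @export
melting_criteria <- function(cutoff = 10, threshold = 0.5) {
  if (cutoff < 5 || cutoff > 15) stop("cutoff must be in [5, 15] Angstrom")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(cutoff = cutoff, threshold = threshold),
            class = "melting_criteria")
}

# coerce trajectory / 3D array / list of matrices to a list of coordinate
# matrices
.frame_list <- function(frames) {
  if (inherits(frames, "trajectory")) frames <- frames$coords
  if (is.array(frames) && length(dim(frames)) == 3L) {
    return(lapply(seq_len(dim(frames)[3L]), function(f) frames[, , f]))
  }
  if (is.matrix(frames)) return(list(frames))
  if (is.list(frames)) return(frames)
  stop("frames must be a trajectory, a 3D array, a matrix or a list of matrices")
}

#' Is a strand single (melted) in a frame?
#'
#' Counts the strand's base pairs whose base-site separation is at or above
#' the cutoff as broken, and declares the strand single when strictly more
#' than `threshold` of its links are broken (so exactly half broken is not
#' single).
#'
#' @param frame n_sites x 3 coordinate matrix, Angstrom
#' @param topology a `junction_topology`
#' @param strand strand label (X, R, H or B)
#' @param criteria a `melting_criteria`
#' @return logical
#' @export
strand_is_single <- function(frame, topology, strand,
                             criteria = melting_criteria()) {
  stopifnot(inherits(topology, "junction_topology"))
  if (!strand %in% topology$strands$label) stop("unknown strand: ", strand)
  bp <- topology$base_pairs
  bp <- bp[bp$strand_a == strand | bp$strand_b == strand, ]
  d <- sqrt(rowSums((frame[bp$site_a, , drop = FALSE] -
                     frame[bp$site_b, , drop = FALSE])^2))
  sum(d >= criteria$cutoff) > criteria$threshold * nrow(bp)
}

#' Single-strand fraction of a frame ensemble at one temperature
#'
#' `alpha` = (number of single strands over all frames and all four strands) /
#' (4 x number of frames).
#'
#' @param frames a `trajectory`, 3D coordinate array, or list of frame
#'   matrices
#' @param topology a `junction_topology`
#' @param criteria a `melting_criteria`
#' @return alpha in `[0, 1]`
#' @export
single_strand_fraction <- function(frames, topology,
                                   criteria = melting_criteria()) {
  fl <- .frame_list(frames)
  if (!length(fl)) stop("empty frame set")
  strands <- topology$strands$label
  bp <- topology$base_pairs
  singles <- 0L
  for (fr in fl) {
    d <- sqrt(rowSums((fr[bp$site_a, , drop = FALSE] -
                       fr[bp$site_b, , drop = FALSE])^2))
    broken <- d >= criteria$cutoff
    for (s in strands) {
      sel <- bp$strand_a == s | bp$strand_b == s
      if (sum(broken[sel]) > criteria$threshold * sum(sel)) singles <- singles + 1L
    }
  }
  singles / (4 * length(fl))
}

#' Melting curve container
#'
#' @param temperature strictly increasing temperature grid, K
#' @param alpha single-strand fractions in `[0, 1]`
#' @param C total strand concentration, mol/L
#' @param n_frames optional per-point frame counts
#' @return object of class `melting_curve` (a data frame with attributes)
#' @export
melting_curve <- function(temperature, alpha, C, n_frames = NULL) {
  if (any(diff(temperature) <= 0)) stop("temperature grid must be strictly increasing")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  if (C <= 0) stop("C must be > 0")
  df <- data.frame(temperature = temperature, alpha = alpha)
  if (!is.null(n_frames)) df$n_frames <- n_frames
  structure(df, C = C, class = c("melting_curve", "data.frame"))
}

#' Single-strand fraction from the tetramolecular van't Hoff model
#'
#' Solves the two-state mass-action relation for a junction dissociating into
#' four distinct strands, each present at concentration C/4:
#' `K(T) = exp(dS/R - dH/(R T)) = alpha^4 (C/4)^3 / (1 - alpha)`.
#' The left side is strictly increasing in alpha, so the root in (0, 1) is
#' unique; it is found by a bracketed solver to 1e-12 and polished by Newton
#' steps. Numerically extreme parameters that cannot be bracketed return the
#' overflow-safe limit 0 or 1 with a warning.
#'
#' @param temperature temperature(s), K
#' @param dH melting enthalpy, kcal/mol
#' @param dS melting entropy, kcal/(mol K)
#' @param C total strand concentration, mol/L
#' @return alpha values in `[0, 1]`, same length as `temperature`
#' @export
vant_hoff_alpha <- function(temperature, dH, dS, C) {
  stopifnot(C > 0, all(temperature > 0))
  lnK <- dS / R_KCAL - dH / (R_KCAL * temperature)
  rhs <- lnK - 3 * log(C / 4)      # = 4 log(alpha) - log(1 - alpha) at the root
  vapply(rhs, .solve_alpha, numeric(1L))
}

.solve_alpha <- function(rhs) {
  h <- function(a) 4 * log(a) - log1p(-a) - rhs
  # asymptotic limits: alpha ~ exp(rhs/4) as alpha -> 0, 1 - alpha ~ exp(-rhs)
  if (rhs < -160) return(exp(rhs / 4))
  if (rhs > 160) return(1 - exp(-rhs))
  lo <- 1e-17; hi <- 1 - 1e-16
  flo <- h(lo); fhi <- h(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo > 0 || fhi < 0) {
    warning("vant_hoff_alpha: no bracketing possible; returning limiting alpha")
    return(if (rhs < 0) 0 else 1)
  }
  a <- stats::uniroot(h, c(lo, hi), tol = 1e-14)$root
  for (i in 1:3) {                               # Newton polish
    step <- h(a) / (4 / a + 1 / (1 - a))
    a_new <- a - step
    if (a_new > 0 && a_new < 1) a <- a_new
  }
  a
}

#' Melting enthalpy from the alpha(T_M) = 1/2 identity
#'
#' At the melting temperature, alpha = 1/2 gives
#' `K(T_M) = (1/2)^4 (C/4)^3 / (1/2) = (C/4)^3 / 8`, hence
#' `dH = T_M dS - R T_M log((C/4)^3 / 8)`.
#'
#' @param dS melting entropy, kcal/(mol K)
#' @param T_M melting temperature, K
#' @param C total strand concentration, mol/L
#' @return dH in kcal/mol
#' @export
enthalpy_entropy_identity <- function(dS, T_M, C) {
  stopifnot(dS > 0, T_M > 0, C > 0)
  T_M * dS - R_KCAL * T_M * (3 * log(C / 4) - log(8))
}

#' Melting temperature from a melting curve
#'
#' Linear interpolation of the alpha = 1/2 crossing. If the curve is not
#' monotone (noise), the crossing of the isotonic-regression smoothed curve is
#' used, which also resolves multiple crossings.
#'
#' @param curve a `melting_curve` (or data frame with `temperature`, `alpha`)
#' @return T_M in K
#' @export
melting_temperature <- function(curve) {
  Tg <- curve$temperature; a <- curve$alpha
  if (any(diff(a) < 0)) a <- stats::isoreg(Tg, a)$yf
  above <- a >= 0.5
  if (all(above) || all(!above))
    stop("curve incomplete: alpha does not cross 0.5 within the grid")
  i <- which(!above & c(above[-1L], TRUE))[1L]   # last point below the crossing
  if (a[i + 1L] == a[i]) return((Tg[i] + Tg[i + 1L]) / 2)
  Tg[i] + (0.5 - a[i]) / (a[i + 1L] - a[i]) * (Tg[i + 1L] - Tg[i])
}

#' Fit the tetramolecular van't Hoff model to a melting curve
#'
#' Nonlinear least squares of [vant_hoff_alpha()] over (dH, dS), restricted to
#' points with alpha strictly inside the fit window (default 0.1 < alpha <
#' 0.9). The window is applied iteratively on the fitted model's alpha rather
#' than on the observed values: selecting points by their noisy alpha couples
#' the selection to the noise and biases dH downward, whereas model-based
#' selection is noise-independent. On noiseless data both rules coincide.
#' Initial values come from a two-point van't Hoff line through the
#' interpolated alpha = 0.25 and alpha = 0.75 crossings. The melting
#' temperature is recovered in closed form from the fitted parameters via the
#' alpha(T_M) = 1/2 identity, so the fit satisfies that identity by
#' construction.
#'
#' @param curve a `melting_curve`
#' @param window fit window `c(alpha_lo, alpha_hi)`
#' @return object of class `vant_hoff_fit`: list with `dH` (kcal/mol), `dS`
#'   (kcal/(mol K)), `T_M` (K), `C`, `covariance` (2x2 for (dH, dS)),
#'   `residual_norm`, `n_used`, `window`, `extrapolated` (TRUE when T_M falls
#'   outside the data span)
#' @export
fit_vant_hoff <- function(curve, window = c(0.1, 0.9)) {
  C <- attr(curve, "C")
  if (is.null(C)) stop("curve must carry a strand concentration (attr C)")
  keep <- curve$alpha > window[1L] & curve$alpha < window[2L]
  if (sum(keep) < 4L)
    stop("fewer than 4 points with alpha inside (", window[1L], ", ", window[2L],
         "); use a denser temperature grid across the transition")

  start <- .vant_hoff_init(curve$temperature, curve$alpha, C)
  run_fit <- function(keep, par0) {
    Tg <- curve$temperature[keep]; a_obs <- curve$alpha[keep]
    minpack.lm::nls.lm(
      par = par0,
      fn = function(p) vant_hoff_alpha(Tg, p[1L], p[2L], C) - a_obs,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200L))
  }
  fit <- run_fit(keep, start)
  for (iter in 1:10) {                 # re-window on the model's alpha
    a_mod <- vant_hoff_alpha(curve$temperature, fit$par[1L], fit$par[2L], C)
    keep_new <- a_mod > window[1L] & a_mod < window[2L]
    if (identical(keep_new, keep) || sum(keep_new) < 4L) break
    keep <- keep_new
    fit <- run_fit(keep, fit$par)
  }
  Tg <- curve$temperature[keep]
  dH <- fit$par[1L]; dS <- fit$par[2L]
  T_M <- dH / (dS - R_KCAL * (3 * log(C / 4) - log(8)))
  n <- length(Tg)
  rss <- sum(fit$fvec^2)
  covar <- tryCatch({
    s2 <- rss / max(n - 2L, 1L)
    s2 * solve(fit$hessian)
  }, error = function(e) matrix(NA_real_, 2L, 2L))
  dimnames(covar) <- list(c("dH", "dS"), c("dH", "dS"))
  structure(list(dH = unname(dH), dS = unname(dS), T_M = unname(T_M), C = C,
                 covariance = covar, residual_norm = sqrt(rss), n_used = n,
                 window = window,
                 extrapolated = T_M < min(curve$temperature) ||
                                T_M > max(curve$temperature)),
            class = "vant_hoff_fit")
}

# two-point van't Hoff initialization through the 0.25 and 0.75 crossings
.vant_hoff_init <- function(Tg, a, C) {
  lnK_of <- function(alpha) 4 * log(alpha) + 3 * log(C / 4) - log1p(-alpha)
  cross_T <- function(level) {
    ai <- if (any(diff(a) < 0)) stats::isoreg(Tg, a)$yf else a
    above <- ai >= level
    if (all(above) || all(!above)) return(NA_real_)
    i <- which(!above & c(above[-1L], TRUE))[1L]
    if (ai[i + 1L] == ai[i]) return((Tg[i] + Tg[i + 1L]) / 2)
    Tg[i] + (level - ai[i]) / (ai[i + 1L] - ai[i]) * (Tg[i + 1L] - Tg[i])
  }
  T1 <- cross_T(0.25); T2 <- cross_T(0.75)
  if (is.na(T1) || is.na(T2) || T1 == T2) {
    # fall back to the two most extreme in-window points
    ok <- a > 0.02 & a < 0.98
    i1 <- which(ok)[1L]; i2 <- rev(which(ok))[1L]
    T1 <- Tg[i1]; T2 <- Tg[i2]
    k1 <- lnK_of(max(a[i1], 1e-6)); k2 <- lnK_of(min(a[i2], 1 - 1e-6))
  } else {
    k1 <- lnK_of(0.25); k2 <- lnK_of(0.75)
  }
  dH <- -R_KCAL * (k1 - k2) / (1 / T1 - 1 / T2)
  dS <- R_KCAL * k1 + dH / T1
  c(dH = dH, dS = dS)
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit (tetramolecular two-state, C = %.3g mol/L)\n", x$C))
  cat(sprintf("  dH  = %.3f kcal/mol\n  dS  = %.5f kcal/(mol K)\n  T_M = %.2f K%s\n",
              x$dH, x$dS, x$T_M, if (x$extrapolated) " [extrapolated]" else ""))
  cat(sprintf("  %d points in window (%.2g, %.2g), residual norm %.3g\n",
              x$n_used, x$window[1L], x$window[2L], x$residual_norm))
  invisible(x)
}

#' Absorbance curve container
#'
#' @param temperature increasing temperature grid, K
#' @param A260 buffer-subtracted absorbance at 260 nm, AU
#' @param lower_window,upper_window temperature ranges (K) used to fit the
#'   linear lower/upper baselines; must lie inside the grid span
#' @return object of class `absorbance_curve`
#' @export
absorbance_curve <- function(temperature, A260, lower_window, upper_window) {
  if (any(diff(temperature) <= 0)) stop("temperature grid must be strictly increasing")
  rng <- range(temperature)
  for (w in list(lower_window, upper_window)) {
    if (length(w) != 2L || w[1L] >= w[2L] || w[1L] < rng[1L] || w[2L] > rng[2L])
      stop("baseline windows must be increasing ranges inside the grid span")
  }
  structure(data.frame(temperature = temperature, A260 = A260),
            lower_window = lower_window, upper_window = upper_window,
            class = c("absorbance_curve", "data.frame"))
}

#' Convert an absorbance melting curve to single-strand fractions
#'
#' Fits linear lower and upper baselines on the declared windows and maps
#' `alpha(T) = (A - A_low) / (A_up - A_low)`, clipped to `[0, 1]`. When the
#' baseline coefficients are already known (e.g. from instrument calibration
#' or synthetic ground truth) they can be passed directly, making the
#' conversion the exact algebraic inverse of the forward model.
#'
#' @param curve an `absorbance_curve`
#' @param C total strand concentration, mol/L (recorded in the result for
#'   downstream fitting)
#' @param baselines optional list with `lower` and `upper` numeric
#'   `c(intercept, slope)`; skips baseline fitting when supplied
#' @return a `melting_curve`
#' @export
absorbance_to_alpha <- function(curve, C = 6e-7, baselines = NULL) {
  if (!is.null(baselines)) {
    A_low <- baselines$lower[1L] + baselines$lower[2L] * curve$temperature
    A_up <- baselines$upper[1L] + baselines$upper[2L] * curve$temperature
  } else {
    lw <- attr(curve, "lower_window"); uw <- attr(curve, "upper_window")
    in_lo <- curve$temperature >= lw[1L] & curve$temperature <= lw[2L]
    in_up <- curve$temperature >= uw[1L] & curve$temperature <= uw[2L]
    if (sum(in_lo) < 3L || sum(in_up) < 3L)
      stop("each baseline window must contain at least 3 points")
    fit_lo <- stats::lm(A260 ~ temperature, data = curve[in_lo, ])
    fit_up <- stats::lm(A260 ~ temperature, data = curve[in_up, ])
    A_low <- stats::predict(fit_lo, newdata = curve)
    A_up <- stats::predict(fit_up, newdata = curve)
  }
  if (any(A_up <= A_low))
    stop("fitted baselines cross inside the data span")
  alpha <- pmin(1, pmax(0, (curve$A260 - A_low) / (A_up - A_low)))
  melting_curve(curve$temperature, alpha, C = C)
}

#' Debye-Hueckel screening length
#'
#' `lambda_D = sqrt(eps0 eps_r k_B T / (2 N_A e^2 I))` with I the monovalent
#' ionic strength. Two relative-permittivity models are available: a fixed
#' `eps_r` (default 78.0), or the empirical temperature- and salt-dependent
#' model used by coarse-grained DNA force fields,
#' `eps(T, c) = (249.4 - 0.788 T + 7.2e-4 T^2) *
#'  (1 - 0.2551 c + 5.151e-2 c^2 - 6.889e-3 c^3)`
#' (water permittivity after Stogryn's fit of the dielectric data, with the
#' NaCl concentration correction), T in K and c in mol/L.
#'
#' @param temperature temperature, K
#' @param salt monovalent salt concentration, mol/L (> 0)
#' @param model `"fixed"` or `"empirical"`
#' @param epsilon relative permittivity for the fixed model
#' @return screening length in Angstrom
#' @examples
#' debye_length(300, 0.300)   # < 6 Angstrom at high salt
#' @export
debye_length <- function(temperature, salt, model = c("fixed", "empirical"),
                         epsilon = 78.0) {
  model <- match.arg(model)
  stopifnot(all(temperature > 0))
  if (any(salt <= 0)) stop("salt concentration must be > 0")
  eps_r <- switch(model,
    fixed = epsilon,
    empirical = (249.4 - 0.788 * temperature + 7.2e-4 * temperature^2) *
      (1 - 0.2551 * salt + 5.151e-2 * salt^2 - 6.889e-3 * salt^3))
  ionic <- salt * 1000 * .N_AVOGADRO          # ions per m^3 (1:1 electrolyte)
  lambda_m <- sqrt(.EPS0 * eps_r * .KB * temperature /
                   (2 * .E_CHARGE^2 * ionic))
  lambda_m * 1e10
}
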