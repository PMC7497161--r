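#' Fluorescence calibration line
#'
#' Least-squares line AU = slope * concentration + intercept through the
#' calibration points (fully converted substrate at known concentrations).
#'
#' @param points Data frame with columns `conc` (uM) and `au` (arbitrary
#'   units), >= 2 distinct concentrations.
#' @return Object of class `fret_calibration` with fields `slope` (AU/uM,
#'   > 0), `intercept` (AU) and the fitted `lm` model.
#' @export
calibrate <- function(points) {
  stopifnot(is.data.frame(points), all(c("conc", "au") %in% names(points)))
  if (length(unique(points$conc)) < 2L) {
    stop("at least 2 distinct concentrations are required")
  }
  fit <- stats::lm(au ~ conc, data = points)
  slope <- unname(stats::coef(fit)["conc"])
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be > 0")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 model = fit),
            class = "fret_calibration")
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat(sprintf("fret_calibration: AU = %.4g * uM + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Construct a calibration from known slope/intercept
#'
#' @param slope AU per uM (> 0).
#' @param intercept AU offset.
#' @return A `fret_calibration`.
#' @export
fret_calibration <- function(slope, intercept = 0) {
  if (slope <= 0) stop("slope must be > 0")
  structure(list(slope = slope, intercept = intercept, model = NULL),
            class = "fret_calibration")
}

#' FRET progress curve
#'
#' @param times Seconds, strictly increasing.
#' @param fluorescence Arbitrary units, same length.
#' @param substrate_conc Initial substrate concentration (uM, > 0).
#' @param enzyme_conc Enzyme concentration (uM, > 0).
#' @return Object of class `progress_curve`.
#' @export
progress_curve <- function(times, fluorescence, substrate_conc, enzyme_conc) {
  stopifnot(length(times) == length(fluorescence))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (substrate_conc <= 0 || enzyme_conc <= 0) {
    stop("concentrations must be > 0")
  }
  structure(list(times = times, fluorescence = fluorescence,
                 substrate_conc = substrate_conc, enzyme_conc = enzyme_conc),
            class = "progress_curve")
}

#' Initial reaction rate from a progress curve
#'
#' Converts fluorescence to product concentration through the calibration
#' line and takes the ordinary least-squares slope of concentration versus
#' time over the initial window, in uM product per second.
#'
#' @param curve A [progress_curve()].
#' @param calibration A `fret_calibration`.
#' @param window Length of the initial window in seconds (default 180).
#' @return Initial rate v in uM/s.
#' @export
initial_slope <- function(curve, calibration, window = 180) {
  stopifnot(inherits(curve, "progress_curve"),
            inherits(calibration, "fret_calibration"))
  sel <- curve$times <= curve$times[1] + window
  if (sum(sel) < 3L) stop("fewer than 3 points in the initial window")
  conc <- (curve$fluorescence[sel] - calibration$intercept) / calibration$slope
  unname(stats::coef(stats::lm(conc ~ t, data = data.frame(t = curve$times[sel],
                                                           conc = conc)))["t"])
}

#' Fit the Michaelis-Menten rate law to initial rates
#'
#' Nonlinear least squares of v = Vmax * S / (KM + S) over (S, v) pairs,
#' unweighted, with starting values Vmax = max(v) and KM = median(S).
#' 95% confidence intervals come from the linearized covariance at the
#' optimum (t quantile times the asymptotic standard error).
#'
#' @param rates Data frame with columns `S` (substrate, uM) and `v` (initial
#'   rate, uM/s), >= 3 distinct substrate concentrations.
#' @param enzyme_conc Enzyme concentration in uM (> 0), used for the
#'   catalytic constants.
#' @return Object of class `kinetics_fit` with fields `KM`, `Vmax` (each
#'   `c(estimate, lower, upper)`), `kcat` (1/s), `efficiency` (1/(M s)),
#'   `enzyme_conc` and the underlying `nls` model.
#' @export
fit_mm <- function(rates, enzyme_conc = 1) {
  stopifnot(is.data.frame(rates), all(c("S", "v") %in% names(rates)))
  if (length(unique(rates$S)) < 3L) {
    stop("at least 3 distinct substrate concentrations are required")
  }
  if (enzyme_conc <= 0) stop("enzyme_conc must be > 0")
  start <- list(Vmax = max(rates$v), KM = stats::median(rates$S))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (KM + S), data = rates, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  df <- stats::df.residual(fit)
  tq <- stats::qt(0.975, df)
  ci <- function(p) c(estimate = unname(est[p]),
                      lower = unname(est[p] - tq * se[p]),
                      upper = unname(est[p] + tq * se[p]))
  KM <- ci("KM"); Vmax <- ci("Vmax")
  if (KM[["estimate"]] <= 0 || Vmax[["estimate"]] <= 0) {
    stop("fit converged to non-positive parameters")
  }
  kcat <- Vmax[["estimate"]] / enzyme_conc
  structure(list(KM = KM, Vmax = Vmax, kcat = kcat,
                 efficiency = kcat / (KM[["estimate"]] * 1e-6),
                 enzyme_conc = enzyme_conc, model = fit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(paste0("kinetics_fit: KM = %.3g uM [%.3g, %.3g], ",
                     "Vmax = %.3g uM/s, kcat = %.3g 1/s, kcat/KM = %.3g 1/(M s)\n"),
              x$KM[["estimate"]], x$KM[["lower"]], x$KM[["upper"]],
              x$Vmax[["estimate"]], x$kcat, x$efficiency))
  invisible(x)
}

#' Construct a kinetics fit from known parameters
#'
#' For arithmetic on published or externally fitted parameters.
#'
#' @param KM Michaelis constant in uM.
#' @param Vmax Maximum rate in uM/s (give either `Vmax` or `kcat`).
#' @param kcat Turnover number in 1/s.
#' @param enzyme_conc Enzyme concentration in uM.
#' @return A `kinetics_fit`.
#' @export
kinetics_fit <- function(KM, Vmax = NULL, kcat = NULL, enzyme_conc = 1) {
  if (KM <= 0 || enzyme_conc <= 0) stop("KM and enzyme_conc must be > 0")
  if (is.null(Vmax) && is.null(kcat)) stop("give Vmax or kcat")
  if (is.null(Vmax)) Vmax <- kcat * enzyme_conc
  if (Vmax <= 0) stop("Vmax must be > 0")
  kcat <- Vmax / enzyme_conc
  structure(list(KM = c(estimate = KM, lower = NA, upper = NA),
                 Vmax = c(estimate = Vmax, lower = NA, upper = NA),
                 kcat = kcat, efficiency = kcat / (KM * 1e-6),
                 enzyme_conc = enzyme_conc, model = NULL),
            class = "kinetics_fit")
}

#' Catalytic constants from a kinetics fit
#'
#' kcat = Vmax / \[E\]; catalytic efficiency kcat / KM with KM converted
#' from uM to M.
#'
#' @param fit A `kinetics_fit`.
#' @return Named numeric vector `c(kcat = , efficiency = )` in 1/s and
#'   1/(M s).
#' @export
catalytic_constants <- function(fit) {
  stopifnot(inherits(fit, "kinetics_fit"))
  c(kcat = fit$kcat, efficiency = fit$efficiency)
}

#' Rate factor implied by a free-energy difference
#'
#' Multiplicative change in kcat/KM implied by a mutation free-energy
#' difference under transition-state theory: exp(|DDG| / RT).
#'
#' @param ddg Free-energy difference in kJ/mol.
#' @param temperature Temperature in K (default 298.15).
#' @return Dimensionless factor >= 1.
#' @export
ddg_to_rate_factor <- function(ddg, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be > 0")
  R <- 8.314e-3  # kJ / (mol K)
  exp(abs(ddg) / (R * temperature))
}

#' Read plate-reader progress curves from CSV
#'
#' Wide export: a `time` column (seconds) plus one fluorescence column per
#' well. The well map assigns each well its substrate concentration.
#'
#' @param path CSV file.
#' @param well_map Data frame with columns `well` (column name) and
#'   `substrate_conc` (uM).
#' @param enzyme_conc Enzyme concentration (uM) common to all wells.
#' @return List of [progress_curve()] objects named by well.
#' @export
read_progress_csv <- function(path, well_map, enzyme_conc) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must contain a 'time' column")
  stats::setNames(lapply(seq_len(nrow(well_map)), function(i) {
    w <- well_map$well[i]
    if (!w %in% names(df)) stop("well column not found: ", w)
    progress_curve(df$time, df[[w]], well_map$substrate_conc[i], enzyme_conc)
  }), well_map$well)
}
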