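#' Seeded generator of substrate tables
#'
#' Draws `n_substrates` substrate windows, sampling each subsite
#' independently from its true probability profile (multinomial sampling,
#' one amino acid per subsite per substrate). The generating profiles are
#' attached as the ground truth.
#'
#' @param true_profiles A [subsite_profile_set()].
#' @param n_substrates Number of substrates (>= 1).
#' @param seed Integer seed (mandatory).
#' @return A [substrate_table()] with attribute `truth` (the generating
#'   profile set).
#' @export
gen_substrate_counts <- function(true_profiles, n_substrates, seed) {
  stopifnot(inherits(true_profiles, "subsite_profile_set"))
  n_substrates <- as.integer(n_substrates)
  if (is.na(n_substrates) || n_substrates < 1L) stop("n_substrates must be >= 1")
  if (missing(seed)) stop("an explicit integer seed is required")
  draws <- withr::with_seed(as.integer(seed), {
    lapply(true_profiles, function(prof) {
      sample(aa_alphabet(), n_substrates, replace = TRUE, prob = prof$p)
    })
  })
  records <- data.frame(id = sprintf("synthetic_%05d", seq_len(n_substrates)))
  for (s in names(true_profiles)) records[[s]] <- draws[[s]]
  out <- substrate_table(records, subsites = names(true_profiles))
  attr(out, "truth") <- true_profiles
  out
}

#' Seeded generator of relative cleavage-time tables
#'
#' Emulates a triplicate 50%-cleavage assay: each replicate draws every
#' amino acid's time from a mean-preserving lognormal with coefficient of
#' variation `cv`, then normalises the replicate by its own Gly draw (as the
#' assay does). The table reports the replicate mean and standard deviation;
#' Gly is exactly 1 with sd 0.
#'
#' @param true_t50 Named numeric vector of true relative times (> 0; must
#'   include Gly).
#' @param cv Coefficient of variation per replicate (>= 0).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed (mandatory).
#' @param exclude Amino acids marked unmeasured in the output table.
#' @return A [cleavage_time_table()] with attribute `truth` (list with the
#'   generating `t50`, `cv`, `replicates`).
#' @export
gen_cleavage_times <- function(true_t50, cv, replicates = 3L, seed,
                               exclude = character()) {
  if (is.null(names(true_t50))) stop("true_t50 must be named by amino acid")
  names(true_t50) <- aa_one_letter(names(true_t50))
  if (any(true_t50 <= 0)) stop("true times must be > 0")
  if (!("G" %in% names(true_t50))) stop("the Gly reference must be present")
  if (cv < 0) stop("cv must be >= 0")
  if (missing(seed)) stop("an explicit integer seed is required")
  replicates <- as.integer(replicates)
  n <- length(true_t50)
  if (cv == 0) {
    rel <- matrix(rep(true_t50 / true_t50[["G"]], replicates), nrow = n)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(true_t50) - sdlog^2 / 2  # mean-preserving
    rel <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(replicates), function(r) {
        t <- stats::rlnorm(n, meanlog, sdlog)
        t / t[names(true_t50) == "G"]
      }, numeric(n))
    })
  }
  rownames(rel) <- names(true_t50)
  m <- rowMeans(rel)
  s <- apply(rel, 1, stats::sd)
  m["G"] <- 1; s["G"] <- 0
  out <- cleavage_time_table(variant = "synthetic", t50 = m, sd = s,
                             missing = exclude)
  attr(out, "truth") <- list(t50 = true_t50, cv = cv, replicates = replicates)
  out
}

#' Seeded generator of dH/dlambda time series
#'
#' Gaussian samples around a polynomial mean curve at each requested lambda.
#' The analytic integral of the polynomial over \[0, 1\] is attached as the
#' ground-truth free-energy difference:
#' dG = sum(coeffs\[k\] / k) for coefficients in ascending power order
#' (constant first).
#'
#' @param poly_coeffs Numeric vector of polynomial coefficients, ascending
#'   powers (c0, c1, c2, ...), in kJ/mol.
#' @param noise_sd Standard deviation of the Gaussian noise (kJ/mol, >= 0).
#' @param lambdas Lambda grid (default 11 equidistant points on \[0, 1\]).
#' @param n_samples Samples per lambda (default 250).
#' @param seed Integer seed (mandatory).
#' @param dt Sampling interval (ps).
#' @return List of [lambda_series()] with attribute `truth` (list with
#'   `dG` and the generating parameters).
#' @export
gen_dhdl <- function(poly_coeffs, noise_sd, lambdas = seq(0, 1, length.out = 11L),
                     n_samples = 250L, seed, dt = 0.04) {
  if (any(lambdas < 0 | lambdas > 1)) stop("lambdas must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing(seed)) stop("an explicit integer seed is required")
  n_samples <- as.integer(n_samples)
  mean_at <- function(l) sum(poly_coeffs * l^(seq_along(poly_coeffs) - 1L))
  series <- withr::with_seed(as.integer(seed), {
    lapply(lambdas, function(l) {
      lambda_series(l, mean_at(l) + stats::rnorm(n_samples, 0, noise_sd), dt = dt)
    })
  })
  attr(series, "truth") <- list(
    dG = sum(poly_coeffs / seq_along(poly_coeffs)),
    poly_coeffs = poly_coeffs, noise_sd = noise_sd, n_samples = n_samples)
  series
}

#' Seeded generator of FRET progress curves
#'
#' Integrates substrate depletion under the Michaelis-Menten rate law
#' dS/dt = -Vmax S / (KM + S) with a fixed-step fourth-order Runge-Kutta
#' scheme (platform-stable), converts the product concentration to
#' fluorescence through the calibration line and adds Gaussian noise.
#'
#' @param KM Michaelis constant (uM).
#' @param Vmax Maximum rate (uM/s).
#' @param S_list Initial substrate concentrations (uM, > 0); default is the
#'   standard assay ladder 200, 100, 50, 20, 10 uM.
#' @param calibration A `fret_calibration`.
#' @param noise_sd Additive fluorescence noise (AU, >= 0).
#' @param duration Curve length in seconds (default 900).
#' @param dt Integration and sampling step in seconds (default 1, must be
#'   <= 1 for the fixed-step integrator).
#' @param enzyme_conc Enzyme concentration (uM, default 1).
#' @param seed Integer seed (mandatory).
#' @return List of [progress_curve()] objects (one per S) with attribute
#'   `truth` (list with `KM`, `Vmax`, the noiseless initial rates `v0`, and
#'   the generator parameters).
#' @export
gen_progress_curves <- function(KM, Vmax, S_list = c(200, 100, 50, 20, 10),
                                calibration = fret_calibration(1),
                                noise_sd = 0, duration = 900, dt = 1,
                                enzyme_conc = 1, seed) {
  if (KM <= 0) stop("KM must be > 0")
  if (Vmax < 0) stop("Vmax must be >= 0")
  if (any(S_list <= 0)) stop("all substrate concentrations must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dt > 1) stop("dt must be <= 1 s")
  if (missing(seed)) stop("an explicit integer seed is required")
  times <- seq(0, duration, by = dt)
  rate <- function(t, y, parms) list(-Vmax * y[1] / (KM + y[1]))
  curves <- withr::with_seed(as.integer(seed), {
    lapply(S_list, function(S0) {
      sol <- deSolve::ode(y = c(S = S0), times = times, func = rate,
                          parms = NULL, method = "rk4")
      product <- S0 - sol[, "S"]
      au <- calibration$intercept + calibration$slope * product +
        stats::rnorm(length(times), 0, noise_sd)
      progress_curve(times, au, substrate_conc = S0,
                     enzyme_conc = enzyme_conc)
    })
  })
  attr(curves, "truth") <- list(KM = KM, Vmax = Vmax,
                                v0 = Vmax * S_list / (KM + S_list),
                                S_list = S_list, noise_sd = noise_sd,
                                enzyme_conc = enzyme_conc)
  curves
}
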