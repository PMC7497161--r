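#' One lambda point of an alchemical perturbation
#'
#' Time series of dH/dlambda samples collected at a single value of the
#' coupling parameter lambda.
#'
#' @param lam Lambda value in \[0, 1\].
#' @param samples Numeric vector of dH/dlambda values (kJ/mol), >= 2 values.
#' @param dt Sampling interval in ps (default 0.04 ps, i.e. every 40 fs).
#' @return Object of class `lambda_series`.
#' @export
lambda_series <- function(lam, samples, dt = 0.04) {
  lam <- as.numeric(lam)
  if (is.na(lam) || lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("at least 2 samples are required")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(lam = lam, samples = samples, dt = dt),
            class = "lambda_series")
}

#' Ensemble average of dH/dlambda with block-averaged uncertainty
#'
#' Discards an initial equilibration fraction, then returns the mean of the
#' retained samples and a standard error estimated by block averaging
#' (standard deviation of contiguous block means divided by sqrt of the
#' number of blocks), which is robust to the serial correlation of MD time
#' series.
#'
#' @param series A [lambda_series()].
#' @param discard_fraction Fraction of initial samples to drop (default 0;
#'   must be < 1).
#' @param n_blocks Number of contiguous blocks (default 10).
#' @return Named numeric vector `c(mean = , se = )` in kJ/mol.
#' @export
average_dhdl <- function(series, discard_fraction = 0, n_blocks = 10L) {
  stopifnot(inherits(series, "lambda_series"))
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must lie in [0, 1)")
  }
  x <- series$samples
  n0 <- floor(discard_fraction * length(x))
  x <- x[(n0 + 1L):length(x)]
  if (length(x) < 2L) stop("fewer than 2 samples remain after discarding")
  n_blocks <- max(2L, min(as.integer(n_blocks), length(x)))
  idx <- cut(seq_along(x), breaks = n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  c(mean = mean(x), se = stats::sd(bm) / sqrt(n_blocks))
}

#' Thermodynamic-integration profile
#'
#' Per-lambda means and standard errors of dH/dlambda, built from a list of
#' [lambda_series()] objects.
#'
#' @param series_list List of [lambda_series()] with strictly increasing,
#'   unique lambda values.
#' @param discard_fraction,n_blocks Passed to [average_dhdl()].
#' @return Object of class `ti_profile`: data frame `points` with columns
#'   `lambda`, `mean`, `se`, plus `n_simulated`.
#' @export
ti_profile <- function(series_list, discard_fraction = 0, n_blocks = 10L) {
  stopifnot(length(series_list) >= 2L,
            all(vapply(series_list, inherits, logical(1), "lambda_series")))
  lam <- vapply(series_list, `[[`, numeric(1), "lam")
  o <- order(lam)
  lam <- lam[o]
  if (anyDuplicated(lam)) stop("duplicated lambda values")
  ms <- t(vapply(series_list[o], average_dhdl, numeric(2),
                 discard_fraction = discard_fraction, n_blocks = n_blocks))
  structure(list(points = data.frame(lambda = lam, mean = ms[, "mean"],
                                     se = ms[, "se"]),
                 n_simulated = length(lam)),
            class = "ti_profile")
}

#' Build a TI profile directly from per-lambda means
#'
#' Convenience constructor when ensemble averages (and optionally their
#' standard errors) are already available.
#'
#' @param lambda,mean,se Numeric vectors (se defaults to 0).
#' @return A `ti_profile`.
#' @export
ti_profile_from_means <- function(lambda, mean, se = 0) {
  o <- order(lambda)
  structure(list(points = data.frame(lambda = lambda[o], mean = mean[o],
                                     se = rep_len(se, length(lambda))[o]),
                 n_simulated = length(lambda)),
            class = "ti_profile")
}

#' @export
print.ti_profile <- function(x, ...) {
  cat("ti_profile:", nrow(x$points), "lambda points on [",
      min(x$points$lambda), ",", max(x$points$lambda), "]\n")
  invisible(x)
}

#' One alchemical free-energy difference
#'
#' @param label State label (e.g. `"apo"`, `"bound"`, `"TI"`).
#' @param mutation Mutation name the leg belongs to.
#' @param dG Free-energy difference in kJ/mol.
#' @param sd Standard deviation in kJ/mol (>= 0).
#' @param replicates Optional vector of the individual replicate estimates;
#'   when given, `sd` must equal their sample standard deviation.
#' @return Object of class `free_energy_leg`.
#' @export
free_energy_leg <- function(label, mutation, dG, sd = 0, replicates = NULL) {
  if (sd < 0) stop("sd must be >= 0")
  if (!is.null(replicates)) {
    if (length(replicates) < 2L) stop("need >= 2 replicate estimates")
    if (abs(stats::sd(replicates) - sd) > 1e-6) {
      stop("sd is inconsistent with the replicate estimates")
    }
  }
  structure(list(label = label, mutation = mutation, dG = dG, sd = sd,
                 replicates = replicates),
            class = "free_energy_leg")
}

#' @export
print.free_energy_leg <- function(x, ...) {
  cat(sprintf("free_energy_leg [%s / %s]: %.3f +/- %.3f kJ/mol\n",
              x$mutation, x$label, x$dG, x$sd))
  invisible(x)
}

#' Integrate a TI profile into a free-energy difference
#'
#' `method = "spline-101"` reproduces the extended-TI workflow: a cubic
#' interpolating spline (Forsythe-Malcolm-Moler end conditions, exact for
#' polynomial mean curves up to degree three) is fitted through the
#' simulated per-lambda means, evaluated
#' on 101 equidistant lambda points, and integrated by the trapezoid rule.
#' `method = "trapezoid"` integrates the simulated points directly. In both
#' modes the uncertainty is propagated from the per-point standard errors
#' through the (linear) quadrature weights in quadrature.
#'
#' @param profile A `ti_profile` whose lambdas span \[0, 1\] (the endpoints
#'   must be simulated).
#' @param method `"spline-101"` (default) or `"trapezoid"`.
#' @param label,mutation Metadata for the returned leg.
#' @return A [free_energy_leg()] with `dG` (kJ/mol) and propagated `sd`.
#' @export
integrate_ti <- function(profile, method = c("spline-101", "trapezoid"),
                         label = "TI-state", mutation = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "ti_profile"))
  pts <- profile$points
  if (nrow(pts) < 2L) stop("at least 2 lambda points are required")
  if (any(pts$lambda < 0 | pts$lambda > 1)) stop("lambda values must lie in [0, 1]")
  if (abs(pts$lambda[1]) > 1e-12 || abs(pts$lambda[nrow(pts)] - 1) > 1e-12) {
    stop("the profile must span lambda = 0 to lambda = 1")
  }
  if (method == "trapezoid") {
    dG <- pracma::trapz(pts$lambda, pts$mean)
    w <- .trapz_weights(pts$lambda)
  } else {
    grid <- seq(0, 1, length.out = 101L)
    # composite Simpson on the dense grid: exact for the cubic interpolant,
    # so the quadrature adds no error beyond the spline fit itself
    ws <- c(1, rep(c(4, 2), 49), 4, 1) * (grid[2] - grid[1]) / 3
    f <- stats::splinefun(pts$lambda, pts$mean, method = "fmm")
    dG <- sum(ws * f(grid))
    # the spline value at each grid point is linear in the nodal means, so
    # per-node quadrature weights follow from propagating unit vectors
    w <- vapply(seq_len(nrow(pts)), function(j) {
      e <- numeric(nrow(pts)); e[j] <- 1
      sum(ws * stats::splinefun(pts$lambda, e, method = "fmm")(grid))
    }, numeric(1))
  }
  sd <- sqrt(sum((w * pts$se)^2))
  free_energy_leg(label, mutation, dG = dG, sd = sd)
}

.trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Difference of two alchemical legs
#'
#' DDG = dG(complex leg) - dG(apo leg), the mutation-induced change in the
#' corresponding binding quantity; uncertainties combine in quadrature.
#'
#' @param complex_leg,apo_leg [free_energy_leg()] objects for the same
#'   mutation.
#' @return List with `ddg`, `sd`, `mutation`.
#' @export
ddg_leg <- function(complex_leg, apo_leg) {
  stopifnot(inherits(complex_leg, "free_energy_leg"),
            inherits(apo_leg, "free_energy_leg"))
  if (!identical(complex_leg$mutation, apo_leg$mutation)) {
    stop("legs refer to different mutations: ", complex_leg$mutation,
         " vs ", apo_leg$mutation)
  }
  list(ddg = complex_leg$dG - apo_leg$dG,
       sd = sqrt(complex_leg$sd^2 + apo_leg$sd^2),
       mutation = complex_leg$mutation)
}

#' Thermodynamic-cycle ledger
#'
#' Ordered bookkeeping of the per-step DDG values along one path from the
#' starting protein to the endpoint mutant.
#'
#' @param steps Data frame with columns `mutation`, `ddg` and optionally `sd`
#'   (kJ/mol; `sd` defaults to 0).
#' @param path_id Path identifier (1 or 2 in a dual-path design).
#' @param raw Optional vector of uncorrected DDG_raw values (NA where the
#'   perturbation conserves net charge and needs no correction).
#' @return Object of class `cycle_ledger`.
#' @export
cycle_ledger <- function(steps, path_id = 1L, raw = NULL) {
  stopifnot(is.data.frame(steps), nrow(steps) >= 1L,
            all(c("mutation", "ddg") %in% names(steps)))
  if (is.null(steps$sd)) steps$sd <- 0
  if (any(steps$sd < 0)) stop("step sds must be >= 0")
  if (!is.null(raw) && length(raw) != nrow(steps)) {
    stop("raw must have one value (or NA) per step")
  }
  structure(list(steps = steps, path_id = path_id, raw = raw),
            class = "cycle_ledger")
}

#' @export
print.cycle_ledger <- function(x, ...) {
  tot <- cycle_total(x)
  cat(sprintf("cycle_ledger path %s: %d steps, total %.2f +/- %.2f kJ/mol\n",
              as.character(x$path_id), nrow(x$steps), tot["total"], tot["sd"]))
  invisible(x)
}

#' Path total of a cycle ledger
#'
#' Sum of the per-step DDG values; the combined uncertainty is the quadrature
#' sum of the step standard deviations.
#'
#' @param ledger A [cycle_ledger()].
#' @return Named numeric vector `c(total = , sd = )` in kJ/mol.
#' @export
cycle_total <- function(ledger) {
  stopifnot(inherits(ledger, "cycle_ledger"))
  c(total = sum(ledger$steps$ddg), sd = sqrt(sum(ledger$steps$sd^2)))
}

#' Cycle closure between two alternative paths
#'
#' Two paths that connect the same end states must give the same total DDG
#' up to sampling error; their absolute difference is a convergence
#' diagnostic.
#'
#' @param path1,path2 [cycle_ledger()] objects describing the same endpoint
#'   mutant (the same set of mutations, in any order).
#' @return Absolute difference of the two path totals (kJ/mol).
#' @export
cycle_closure <- function(path1, path2) {
  stopifnot(inherits(path1, "cycle_ledger"), inherits(path2, "cycle_ledger"))
  if (!setequal(path1$steps$mutation, path2$steps$mutation)) {
    stop("the two paths do not describe the same endpoint mutant")
  }
  abs(cycle_total(path1)[["total"]] - cycle_total(path2)[["total"]])
}

#' Catalytic-step free-energy difference
#'
#' DDG_cat = DDG_TI - DDG_bind: the part of the tetrahedral-intermediate
#' stabilisation not explained by noncovalent binding, i.e. the change in the
#' first catalytic step. Uncertainties combine in quadrature.
#'
#' @param ddg_ti,ddg_bind Numeric length-2 vectors `c(value, sd)` or lists
#'   with `ddg` and `sd` (as returned by [ddg_leg()]).
#' @param mutation Mutation name (checked for consistency when both inputs
#'   carry one).
#' @return Object of class `catalytic_delta` with fields `mutation`,
#'   `ddg_ti`, `ddg_bind`, `ddg_cat` (each `c(value, sd)`).
#' @export
ddg_catalytic <- function(ddg_ti, ddg_bind, mutation = NULL) {
  as_vs <- function(x) {
    if (is.list(x)) {
      c(value = x$ddg, sd = if (is.null(x$sd)) 0 else x$sd)
    } else {
      c(value = x[[1]], sd = if (length(x) > 1) x[[2]] else 0)
    }
  }
  muts <- c(if (is.list(ddg_ti)) ddg_ti$mutation, if (is.list(ddg_bind)) ddg_bind$mutation,
            mutation)
  muts <- unique(muts[!is.na(muts)])
  if (length(muts) > 1L) stop("inputs refer to different mutations")
  ti <- as_vs(ddg_ti); bind <- as_vs(ddg_bind)
  structure(list(
    mutation = if (length(muts)) muts else NA_character_,
    ddg_ti = ti, ddg_bind = bind,
    ddg_cat = c(value = ti[["value"]] - bind[["value"]],
                sd = sqrt(ti[["sd"]]^2 + bind[["sd"]]^2))),
    class = "catalytic_delta")
}

#' @export
print.catalytic_delta <- function(x, ...) {
  cat(sprintf("catalytic_delta [%s]: DDG_cat = %.2f +/- %.2f kJ/mol\n",
              x$mutation, x$ddg_cat[["value"]], x$ddg_cat[["sd"]]))
  invisible(x)
}

#' Combine replicate free-energy estimates
#'
#' Mean and sample standard deviation (n - 1 denominator) over all
#' replicate-by-site estimates, the scatter-based uncertainty convention for
#' independent repeats of the same perturbation.
#'
#' @param estimates Numeric vector of dG or DDG estimates (>= 2).
#' @param grouping Optional labels (e.g. `"rep1.siteA"`) recorded alongside;
#'   not used in the statistic.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
combine_replicates <- function(estimates, grouping = NULL) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 2L) stop("at least 2 estimates are required")
  if (!is.null(grouping) && length(grouping) != length(estimates)) {
    stop("grouping must match estimates in length")
  }
  c(mean = mean(estimates), sd = stats::sd(estimates))
}

#' Read dH/dlambda time series from TSV
#'
#' Expects columns `lambda`, `time` (or sample index) and `dhdl`; one block
#' of rows per simulated lambda.
#'
#' @param path TSV file.
#' @param dt Sampling interval in ps.
#' @return List of [lambda_series()], ordered by lambda.
#' @export
read_dhdl_tsv <- function(path, dt = 0.04) {
  df <- utils::read.delim(path)
  need <- c("lambda", "dhdl")
  if (!all(need %in% names(df))) stop("TSV must contain columns: lambda, dhdl")
  lams <- sort(unique(df$lambda))
  lapply(lams, function(l) lambda_series(l, df$dhdl[df$lambda == l], dt = dt))
}

#' Build dual-path cycle ledgers from a manifest
#'
#' The YAML manifest maps dH/dlambda TSV files to cycle positions:
#' ```
#' endpoint: <mutant name>
#' paths:
#'   - path_id: 1
#'     steps:
#'       - mutation: Asp323Thr
#'         complex: path1/step1_bound.tsv
#'         apo:     path1/step1_apo.tsv
#' ```
#' Each leg file is averaged, integrated ([integrate_ti()]) and differenced
#' ([ddg_leg()]) into one step of a [cycle_ledger()].
#'
#' @param path Manifest YAML file; leg paths are resolved relative to it.
#' @param method Integration method, see [integrate_ti()].
#' @param discard_fraction,n_blocks Passed to [ti_profile()].
#' @return Named list of [cycle_ledger()] objects, one per path.
#' @export
read_ti_manifest <- function(path, method = "spline-101",
                             discard_fraction = 0, n_blocks = 10L) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  leg_from_file <- function(f, label, mutation) {
    series <- read_dhdl_tsv(file.path(base, f))
    prof <- ti_profile(series, discard_fraction = discard_fraction,
                       n_blocks = n_blocks)
    integrate_ti(prof, method = method, label = label, mutation = mutation)
  }
  ledgers <- lapply(y$paths, function(p) {
    rows <- lapply(p$steps, function(s) {
      d <- ddg_leg(leg_from_file(s$complex, "complex", s$mutation),
                   leg_from_file(s$apo, "apo", s$mutation))
      data.frame(mutation = s$mutation, ddg = d$ddg, sd = d$sd)
    })
    cycle_ledger(do.call(rbind, rows), path_id = p$path_id)
  })
  stats::setNames(ledgers, paste0("path", vapply(y$paths, `[[`, numeric(1), "path_id")))
}
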