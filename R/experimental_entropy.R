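#' Relative cleavage-time table
#'
#' Times to cleave 50% of the substrate per P1' amino acid, relative to the
#' Gly substrate (Gly = 1 by construction, with zero spread), plus replicate
#' standard deviations. Amino acids that could not be measured (e.g. Pro,
#' cleaved too slowly to quantify) are listed in `missing` and excluded from
#' all downstream statistics.
#'
#' @param variant Label of the protease variant.
#' @param t50 Named numeric vector of relative 50%-cleavage times (> 0).
#' @param sd Named numeric vector of standard deviations (same names, >= 0).
#'   Defaults to zero.
#' @param missing Character vector of excluded amino acids.
#' @return Object of class `cleavage_time_table`.
#' @export
cleavage_time_table <- function(variant, t50, sd = NULL, missing = character()) {
  if (is.null(names(t50))) stop("t50 must be named by amino acid")
  names(t50) <- aa_one_letter(names(t50))
  if (anyDuplicated(names(t50))) stop("duplicated amino acids in t50")
  if (is.null(sd)) sd <- stats::setNames(numeric(length(t50)), names(t50))
  names(sd) <- aa_one_letter(names(sd))
  if (!setequal(names(sd), names(t50))) stop("t50 and sd must cover the same amino acids")
  sd <- sd[names(t50)]
  if (length(missing)) missing <- aa_one_letter(missing)
  if (any(!is.finite(t50)) || any(t50 <= 0)) stop("all t50 values must be finite and > 0")
  if (any(sd < 0)) stop("standard deviations must be >= 0")
  if (!("G" %in% names(t50))) stop("the Gly reference must be present")
  if (abs(t50[["G"]] - 1) > 1e-9 || sd[["G"]] != 0) {
    stop("Gly is the reference: t50 = 1 and sd = 0 by convention")
  }
  if (any(names(t50) %in% missing)) stop("missing amino acids must not carry t50 values")
  structure(list(variant = variant, t50 = t50, sd = sd, missing = missing),
            class = "cleavage_time_table")
}

#' @export
print.cleavage_time_table <- function(x, ...) {
  cat("cleavage_time_table [", x$variant, "]: ", length(x$t50),
      " amino acids (excluded: ",
      if (length(x$missing)) paste(x$missing, collapse = ",") else "none",
      ")\n", sep = "")
  invisible(x)
}

#' Read a relative cleavage-time table from TSV
#'
#' Supports two dialects: paired columns (`<variant>` and `<variant>_sd`) or
#' a single column with "value +/- sd" strings (the +/- may be the Unicode
#' plus-minus sign or the two characters `+-`).
#'
#' @param path TSV path; first column must hold the P1' amino acids.
#' @param variant Name of the variant column to read.
#' @param missing Amino acids to mark as unmeasured. Default `"P"`.
#' @return A [cleavage_time_table()].
#' @export
read_cleavage_times_tsv <- function(path, variant, missing = "P") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  aa <- aa_one_letter(df[[1L]])
  if (!variant %in% names(df)) stop("no column named ", variant)
  col <- df[[variant]]
  sd_col <- paste0(variant, "_sd")
  if (sd_col %in% names(df)) {
    t50 <- as.numeric(col)
    sdv <- as.numeric(df[[sd_col]])
  } else {
    parts <- strsplit(as.character(col), "±|\\+-|\\+/-")
    t50 <- vapply(parts, function(z) as.numeric(trimws(z[1])), numeric(1))
    sdv <- vapply(parts, function(z)
      if (length(z) > 1) as.numeric(trimws(z[2])) else 0, numeric(1))
  }
  keep <- !is.na(t50)
  cleavage_time_table(variant,
                      t50 = stats::setNames(t50[keep], aa[keep]),
                      sd = stats::setNames(sdv[keep], aa[keep]),
                      missing = missing)
}

#' Translate relative cleavage times into a probability profile
#'
#' Fast-cleaved amino acids are frequent cleavage partners: each observed
#' amino acid gets weight 1 / t50, renormalised over the observed support.
#' The common Gly normalisation cancels, so the profile is invariant to
#' rescaling all times by a constant.
#'
#' @param table A [cleavage_time_table()].
#' @return A [subsite_profile()] for the P1' subsite (excluded amino acids
#'   have probability zero).
#' @export
times_to_probabilities <- function(table) {
  stopifnot(inherits(table, "cleavage_time_table"))
  rate <- 1 / table$t50
  subsite_profile("P1'", rate / sum(rate))
}

#' Experimental cleavage entropy
#'
#' Base-20 entropy of the probability profile obtained from measured relative
#' cleavage times ([times_to_probabilities()]), computed over the observed
#' support only.
#'
#' @param table A [cleavage_time_table()].
#' @return Dimensionless entropy in \[0, 1\].
#' @export
experimental_entropy <- function(table) {
  stopifnot(inherits(table, "cleavage_time_table"))
  if (length(table$t50) < 2L) {
    stop("at least two observed amino acids are required")
  }
  cleavage_entropy(times_to_probabilities(table))
}

#' Monte-Carlo uncertainty of the experimental cleavage entropy
#'
#' Propagates the replicate standard deviations of the cleavage times into
#' the entropy by resampling each t50 from a normal distribution truncated at
#' zero (values are redrawn until positive) and recomputing the entropy per
#' draw.
#'
#' @param table A [cleavage_time_table()].
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed (mandatory; the draw is reproducible).
#' @return Object of class `experimental_entropy` with fields `point`,
#'   `mean_mc`, `sd_mc`, `n_draws`, `seed`.
#' @export
entropy_uncertainty <- function(table, n_draws = 10000L, seed) {
  stopifnot(inherits(table, "cleavage_time_table"))
  if (missing(seed)) stop("an explicit integer seed is required")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 100L) stop("n_draws must be >= 100")
  point <- experimental_entropy(table)
  t50 <- table$t50
  sdv <- table$sd
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_draws), function(i) {
      t <- stats::rnorm(length(t50), t50, sdv)
      while (any(t <= 0)) {
        bad <- t <= 0
        t[bad] <- stats::rnorm(sum(bad), t50[bad], sdv[bad])
      }
      p <- (1 / t) / sum(1 / t)
      cleavage_entropy(p)
    }, numeric(1))
  })
  structure(list(point = point, mean_mc = mean(draws), sd_mc = stats::sd(draws),
                 n_draws = n_draws, seed = as.integer(seed)),
            class = "experimental_entropy")
}

#' @export
print.experimental_entropy <- function(x, ...) {
  cat(sprintf("experimental cleavage entropy: %.4f (MC %.4f +/- %.4f, %d draws)\n",
              x$point, x$mean_mc, x$sd_mc, x$n_draws))
  invisible(x)
}
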