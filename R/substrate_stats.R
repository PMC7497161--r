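#' Substrate table
#'
#' A set of substrate cleavage windows, one row per substrate, one column per
#' subsite (any contiguous subset of P4...P4', ordered N to C). Each cell is a
#' one-letter amino-acid code.
#'
#' @param records Data frame with an `id` column and one column per subsite
#'   label (e.g. `P1'`).
#' @param subsites Character vector of subsite labels in N-to-C order.
#'   Defaults to all non-`id` columns of `records` in their given order.
#' @return An object of class `substrate_table`.
#' @export
substrate_table <- function(records, subsites = setdiff(names(records), "id")) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("substrate table must contain at least one substrate")
  if (anyDuplicated(subsites)) stop("subsite labels must be unique")
  missing_cols <- setdiff(subsites, names(records))
  if (length(missing_cols)) {
    stop("missing subsite columns: ", paste(missing_cols, collapse = ", "))
  }
  for (s in subsites) {
    records[[s]] <- aa_one_letter(records[[s]])
  }
  structure(list(records = records, subsites = subsites),
            class = "substrate_table")
}

#' @export
print.substrate_table <- function(x, ...) {
  cat("substrate_table:", nrow(x$records), "substrates,",
      length(x$subsites), "subsites (", paste(x$subsites, collapse = " "), ")\n")
  invisible(x)
}

#' Read a substrate table from TSV
#'
#' Expects columns `id`, then subsite columns (`P4` ... `P4'`), MEROPS-like
#' one substrate per row.
#'
#' @param path Path to a tab-separated file.
#' @return A [substrate_table()].
#' @export
read_substrate_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  substrate_table(df)
}

#' Per-subsite amino-acid counts
#'
#' @param table A [substrate_table()].
#' @return Integer matrix, 20 rows (amino acids, [aa_alphabet()] order) by
#'   one column per subsite.
#' @export
subsite_counts <- function(table) {
  stopifnot(inherits(table, "substrate_table"))
  sapply(table$subsites, function(s) {
    tab <- table(factor(table$records[[s]], levels = aa_alphabet()))
    as.integer(tab)
  }) |> matrix(nrow = 20L,
               dimnames = list(aa_alphabet(), table$subsites))
}

#' Background amino-acid frequencies
#'
#' Validates a background distribution used to normalise raw substrate counts
#' (the natural occurrence of amino acids in the organism's proteome). All 20
#' amino acids must have strictly positive probability summing to one.
#'
#' @param freq Named numeric vector over the 20 canonical amino acids. If
#'   omitted, the bundled human proteome snapshot is used (see
#'   [human_aa_frequencies()]).
#' @return Named numeric vector of class `background_frequencies`.
#' @export
background_frequencies <- function(freq = human_aa_frequencies()) {
  if (is.null(names(freq))) stop("background frequencies must be named by amino acid")
  names(freq) <- aa_one_letter(names(freq))
  if (!setequal(names(freq), aa_alphabet()) || length(freq) != 20L) {
    stop("background must contain exactly the 20 canonical amino acids")
  }
  freq <- freq[aa_alphabet()]
  if (any(freq <= 0)) stop("background frequencies must all be > 0")
  if (abs(sum(freq) - 1) > 1e-9) stop("background frequencies must sum to 1")
  structure(freq, class = "background_frequencies")
}

#' Single-subsite probability profile
#'
#' @param subsite Subsite label (e.g. `"P1'"`).
#' @param p Named numeric vector of probabilities over (a subset of) the 20
#'   canonical amino acids; unnamed amino acids are taken as probability 0.
#' @return Object of class `subsite_profile` with fields `subsite`, `p`
#'   (full length-20 vector) and `support` (amino acids with p > 0).
#' @export
subsite_profile <- function(subsite, p) {
  if (is.null(names(p))) stop("profile probabilities must be named by amino acid")
  names(p) <- aa_one_letter(names(p))
  if (anyDuplicated(names(p))) stop("duplicated amino acids in profile")
  full <- stats::setNames(numeric(20L), aa_alphabet())
  full[names(p)] <- as.numeric(p)
  if (any(full < 0)) stop("probabilities must be non-negative")
  if (abs(sum(full) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(sum(full)), ")")
  }
  structure(list(subsite = subsite, p = full,
                 support = names(full)[full > 0]),
            class = "subsite_profile")
}

#' @export
print.subsite_profile <- function(x, ...) {
  cat("subsite_profile [", x$subsite, "]: ", length(x$support),
      " amino acids in support, S = ", round(cleavage_entropy(x), 3), "\n", sep = "")
  invisible(x)
}

#' Ordered set of subsite profiles
#'
#' @param profiles List of [subsite_profile()] objects with unique subsite
#'   labels, in N-to-C order.
#' @return Object of class `subsite_profile_set` (a named list).
#' @export
subsite_profile_set <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "subsite_profile")))
  labels <- vapply(profiles, `[[`, character(1), "subsite")
  if (anyDuplicated(labels)) stop("subsite labels must be unique")
  structure(stats::setNames(profiles, labels), class = "subsite_profile_set")
}

#' Normalise substrate counts by background frequencies
#'
#' Converts per-subsite amino-acid counts into probability profiles, dividing
#' each count by the background occurrence of that amino acid and
#' renormalising each subsite to sum to one. Amino acids never observed at a
#' subsite keep probability zero (no smoothing).
#'
#' @param table A [substrate_table()] or a count matrix as returned by
#'   [subsite_counts()] (20 rows, one column per subsite).
#' @param background A [background_frequencies()] vector.
#' @return A [subsite_profile_set()].
#' @export
normalize_counts <- function(table, background = background_frequencies()) {
  background <- background_frequencies(unclass(background))
  counts <- if (inherits(table, "substrate_table")) subsite_counts(table) else table
  if (!is.matrix(counts) || nrow(counts) != 20L) {
    stop("counts must be a 20-row matrix (amino acids x subsites)")
  }
  if (is.null(rownames(counts))) stop("count matrix must have amino-acid rownames")
  counts <- counts[aa_alphabet(), , drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  profiles <- lapply(colnames(counts), function(s) {
    w <- counts[, s] / unclass(background)
    if (sum(w) == 0) stop("subsite ", s, " has no observations")
    subsite_profile(s, w / sum(w))
  })
  subsite_profile_set(profiles)
}

#' Cleavage entropy of a subsite profile
#'
#' Shannon entropy in base 20 of the amino-acid probability distribution at
#' one subsite: S = -sum p * log20(p), with the 0 * log(0) terms defined as 0.
#' S = 0 for a perfectly specific pocket (a single amino acid binds) and
#' S = 1 for a uniform distribution over all 20 amino acids.
#'
#' @param profile A [subsite_profile()], or a bare probability vector (named
#'   by amino acid or not; must sum to 1).
#' @return Dimensionless entropy in \[0, 1\].
#' @export
cleavage_entropy <- function(profile) {
  p <- if (inherits(profile, "subsite_profile")) profile$p else as.numeric(profile)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  }
  p <- p[p > 0]
  -sum(p * log(p)) / log(20)
}

#' Entropy profile across subsites
#'
#' Applies [cleavage_entropy()] to every profile in a set, preserving subsite
#' order, e.g. to draw the S4 to S4' promiscuity pattern of a protease.
#'
#' @param profiles A [subsite_profile_set()].
#' @return Named numeric vector of entropies (names are subsite labels).
#' @export
entropy_profile <- function(profiles) {
  stopifnot(inherits(profiles, "subsite_profile_set"), length(profiles) >= 1L)
  vapply(profiles, cleavage_entropy, numeric(1))
}
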