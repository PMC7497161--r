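#' @keywords internal
.extdata <- function(file) {
  path <- system.file("extdata", file, package = "caspkit", mustWork = TRUE)
  path
}

#' Bundled human amino-acid background frequencies
#'
#' Pinned snapshot of the natural occurrence of the 20 amino acids in the
#' human proteome (UniProtKB proteome-wide composition, normalised to sum to
#' one). Used as the default background when normalising substrate counts;
#' callers may supply their own via [background_frequencies()].
#'
#' @return Named numeric vector of length 20.
#' @export
human_aa_frequencies <- function() {
  df <- utils::read.delim(.extdata("human_aa_frequencies.tsv"))
  f <- stats::setNames(df$freq, aa_one_letter(df$aa))
  f / sum(f)
}

#' Reference S1' substrate distributions for caspase-2 and caspase-3
#'
#' Background-normalised probabilities of each amino acid occurring at the
#' substrate P1' position, tabulated from the published substrate statistics
#' of the two proteases. Amino acids without any observation are absent from
#' the profile support (probability zero, not smoothed).
#'
#' @return A [subsite_profile_set()] with profiles named `casp2` and `casp3`
#'   (both describe the P1' subsite; the set is keyed by protease here).
#' @export
casp_p1prime_profiles <- function() {
  df <- utils::read.delim(.extdata("p1prime_substrate_profiles.tsv"))
  aa <- aa_one_letter(df$aa)
  mk <- function(col, label) {
    p <- df[[col]]
    keep <- !is.na(p)
    prof <- stats::setNames(p[keep], aa[keep])
    subsite_profile(label, prof / sum(prof))
  }
  structure(list(casp2 = mk("casp2", "casp2"), casp3 = mk("casp3", "casp3")),
            class = "subsite_profile_set")
}

#' Reference relative cleavage times (P1' scan)
#'
#' Times to cleave 50% of the substrate, relative to Gly, for each P1' amino
#' acid, with replicate standard deviations, for the unmutated caspase-2 and
#' the D323T and D323T/H226A mutants. Pro is excluded (cleavage too slow to
#' quantify).
#'
#' @param variant One of `"unmutated"`, `"D323T"`, `"D323T_H226A"`.
#' @return A [cleavage_time_table()].
#' @export
casp2_cleavage_times <- function(variant = c("unmutated", "D323T", "D323T_H226A")) {
  variant <- match.arg(variant)
  df <- utils::read.delim(.extdata("relative_cleavage_times.tsv"))
  aa <- aa_one_letter(df$p1prime)
  cleavage_time_table(
    variant = variant,
    t50 = stats::setNames(df[[variant]], aa),
    sd = stats::setNames(df[[paste0(variant, "_sd")]], aa),
    missing = "P"
  )
}

#' Reference dual-path free-energy ledgers (tetrahedral-intermediate state)
#'
#' Per-step mutation free-energy differences for the two alternative paths
#' from the unmutated protease to the quadruple mutant, with replicate
#' standard deviations and, for net-charge-changing steps, the uncorrected
#' raw values.
#'
#' @return List of two [cycle_ledger()] objects (`path1`, `path2`).
#' @export
ti_reference_ledgers <- function() {
  df <- utils::read.delim(.extdata("ti_cycle_ledger.tsv"))
  mk <- function(p) {
    d <- df[df$path == p, ]
    cycle_ledger(steps = data.frame(mutation = d$mutation, ddg = d$ddg_ti,
                                    sd = d$sd),
                 path_id = p, raw = d$ddg_raw)
  }
  list(path1 = mk(1L), path2 = mk(2L))
}

#' Reference free-energy table for the noncovalently bound state
#'
#' Binding free-energy differences for the two favourable mutations in both
#' paths, their raw (uncorrected) values where the perturbation changes net
#' charge, and the catalytic-step differences derived from the
#' tetrahedral-intermediate ledger.
#'
#' @return Data frame with columns `path`, `step`, `mutation`, `ddg_bind`,
#'   `sd`, `ddg_raw`, `ddg_cat`, `ddg_cat_sd`.
#' @export
noncovalent_reference_table <- function() {
  utils::read.delim(.extdata("noncovalent_cycle_ledger.tsv"))
}

#' Reference Michaelis-Menten parameters (FRET assay)
#'
#' Fitted K_M and k_cat (with 95% CI half-widths) per P1' amino acid for the
#' unmutated protease and the double mutant, plus the published catalytic
#' efficiencies.
#'
#' @return Data frame with columns `p1prime`, `enzyme`, `KM_uM`, `KM_ci`,
#'   `kcat`, `kcat_ci`, `efficiency`.
#' @export
mm_reference_parameters <- function() {
  utils::read.delim(.extdata("mm_parameters.tsv"))
}

#' Bundled charging-correction table
#'
#' Correction totals for the net-charge-changing perturbations of the
#' reference redesign cycles, keyed by mutation and cycle context
#' (`TI-path1`, `bind-path2`, ...).
#'
#' @return List of [charging_correction()] objects, named
#'   `"<mutation>@<context>"`.
#' @export
bundled_charging_corrections <- function() {
  read_corrections_yaml(.extdata("charging_corrections.yaml"))
}
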