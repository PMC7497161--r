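#' Formal side-chain charge of an amino acid
#'
#' Standard-pH convention: Asp and Glu carry -1, Lys and Arg +1, histidine is
#' neutral by default (configurable), everything else 0.
#'
#' @param aa One-letter code(s).
#' @param his_charge Formal charge assigned to His (default 0).
#' @return Integer vector of formal charges.
#' @export
aa_formal_charge <- function(aa, his_charge = 0L) {
  aa <- aa_one_letter(aa)
  ch <- stats::setNames(integer(20L), aa_alphabet())
  ch[c("D", "E")] <- -1L
  ch[c("K", "R")] <- 1L
  ch["H"] <- as.integer(his_charge)
  unname(ch[aa])
}

#' Net charge change of a point mutation
#'
#' Formal side-chain charge of the target residue minus that of the original
#' residue. Perturbations with a nonzero result change the system's net
#' charge and require ex-post charging corrections.
#'
#' @param from_aa,to_aa One-letter codes.
#' @param his_charge Formal charge assigned to His (default 0,
#'   standard-pH convention).
#' @return Integer charge delta.
#' @export
net_charge_change <- function(from_aa, to_aa, his_charge = 0L) {
  aa_formal_charge(to_aa, his_charge) - aa_formal_charge(from_aa, his_charge)
}

#' Parse a mutation name
#'
#' Accepts `"Asp323Thr"` or `"D323T"` style names.
#'
#' @param mutation Character scalar.
#' @return List with `from_aa`, `position`, `to_aa` (one-letter codes).
#' @export
parse_mutation <- function(mutation) {
  m <- regmatches(mutation,
                  regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", mutation))[[1]]
  if (length(m) != 4L) stop("cannot parse mutation name: ", mutation)
  list(from_aa = aa_one_letter(m[2]), position = as.integer(m[3]),
       to_aa = aa_one_letter(m[4]))
}

#' Charging-correction record for one perturbation
#'
#' Bookkeeping of the ex-post correction applied to a raw charging free
#' energy: the solvent-polarization term (`dG_pol`), the periodic-summation
#' potential term (`dG_psum`), the direct solute-solute interaction term
#' (`dG_dir`) and a solvent-permittivity term (`dG_eps`). Each term defaults
#' to 0; the total correction is their sum.
#'
#' @param mutation Mutation name (e.g. `"Val279Glu"`).
#' @param dG_pol,dG_psum,dG_dir,dG_eps Correction terms in kJ/mol.
#' @param source `"supplied"` (from external continuum-electrostatics runs)
#'   or `"estimated"` (from the crude analytical estimator,
#'   [estimate_born_correction()]).
#' @param context Optional context tag (e.g. `"TI-path1"`).
#' @return Object of class `charging_correction` with a `total` field.
#' @export
charging_correction <- function(mutation, dG_pol = 0, dG_psum = 0, dG_dir = 0,
                                dG_eps = 0, source = c("supplied", "estimated"),
                                context = NA_character_) {
  source <- match.arg(source)
  terms <- c(dG_pol = dG_pol, dG_psum = dG_psum, dG_dir = dG_dir, dG_eps = dG_eps)
  if (any(!is.finite(terms))) stop("correction terms must be finite")
  structure(list(mutation = mutation, terms = terms, total = sum(terms),
                 source = source, context = context),
            class = "charging_correction")
}

#' @export
print.charging_correction <- function(x, ...) {
  cat(sprintf("charging_correction [%s%s]: total %.3f kJ/mol (%s)\n",
              x$mutation, if (is.na(x$context)) "" else paste0("@", x$context),
              x$total, x$source))
  invisible(x)
}

#' Apply a charging correction to a raw free-energy difference
#'
#' corrected = raw + total correction. A mutation whose net charge change is
#' zero must carry a zero correction (the methodology-dependent electrostatic
#' artifacts cancel); this is enforced when the mutation name is parseable.
#'
#' @param raw Uncorrected DDG_raw in kJ/mol.
#' @param correction A [charging_correction()].
#' @param his_charge His convention for the net-charge validation.
#' @return Object of class `corrected_leg` with fields `raw`, `corrected`,
#'   `correction`.
#' @export
apply_corrections <- function(raw, correction, his_charge = 0L) {
  stopifnot(inherits(correction, "charging_correction"))
  if (!is.finite(raw)) stop("raw value must be finite")
  parsed <- tryCatch(parse_mutation(correction$mutation), error = function(e) NULL)
  if (!is.null(parsed)) {
    dq <- net_charge_change(parsed$from_aa, parsed$to_aa, his_charge)
    if (dq == 0L && abs(correction$total) > 1e-9) {
      stop("mutation ", correction$mutation,
           " conserves net charge but carries a nonzero correction")
    }
  }
  structure(list(raw = raw, corrected = raw + correction$total,
                 correction = correction),
            class = "corrected_leg")
}

#' @export
print.corrected_leg <- function(x, ...) {
  cat(sprintf("corrected_leg [%s]: raw %.2f -> corrected %.2f kJ/mol\n",
              x$correction$mutation, x$raw, x$corrected))
  invisible(x)
}

#' Read charging corrections from YAML
#'
#' Expects a sequence of mappings with keys `mutation`, optional `context`,
#' and any of `dG_pol`, `dG_psum`, `dG_dir`, `dG_eps`.
#'
#' @param path YAML file.
#' @return Named list of [charging_correction()] objects
#'   (`"<mutation>@<context>"` or `"<mutation>"`).
#' @export
read_corrections_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(y, function(e) {
    charging_correction(
      mutation = e$mutation,
      dG_pol = e$dG_pol %||% 0, dG_psum = e$dG_psum %||% 0,
      dG_dir = e$dG_dir %||% 0, dG_eps = e$dG_eps %||% 0,
      source = e$source %||% "supplied",
      context = e$context %||% NA_character_)
  })
  stats::setNames(out, vapply(out, function(x) {
    if (is.na(x$context)) x$mutation else paste0(x$mutation, "@", x$context)
  }, character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crude Born-style charging-correction estimate
#'
#' Analytical placeholder for the dominant solvent-polarization term when no
#' continuum-electrostatics result is available: the difference of Born
#' self-energies of the end-state formal charges in a dielectric of relative
#' permittivity `eps`, for an ion of effective radius `radius_nm`:
#' dG = -(1 - 1/eps) * (z_to^2 - z_from^2) * 138.935 / (2 * radius_nm) kJ/mol.
#' The result is flagged `estimated` and is no substitute for a solver-based
#' correction.
#'
#' @param mutation Mutation name (parseable, see [parse_mutation()]).
#' @param radius_nm Effective Born radius in nm (default 0.2).
#' @param eps Relative permittivity of the solvent model (default 61).
#' @param his_charge His convention.
#' @param context Optional context tag.
#' @return A [charging_correction()] with `source = "estimated"`.
#' @export
estimate_born_correction <- function(mutation, radius_nm = 0.2, eps = 61,
                                     his_charge = 0L, context = NA_character_) {
  p <- parse_mutation(mutation)
  z_from <- aa_formal_charge(p$from_aa, his_charge)
  z_to <- aa_formal_charge(p$to_aa, his_charge)
  ke <- 138.935  # e^2 / (4 pi eps0), kJ nm / mol
  dg <- -(1 - 1 / eps) * (z_to^2 - z_from^2) * ke / (2 * radius_nm)
  charging_correction(mutation, dG_pol = dg, source = "estimated",
                      context = context)
}
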