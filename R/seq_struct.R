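#' Protein sequence with accession numbering
#'
#' @param id Accession or label.
#' @param residues One-letter amino-acid string (canonical letters only).
#' @param numbering_offset Residue number of the first residue (per the
#'   accession's numbering). Default 1.
#' @return Object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, numbering_offset = 1L) {
  residues <- toupper(gsub("\\s", "", residues))
  if (nchar(residues) == 0L) stop("sequence must be nonempty")
  .check_aa(strsplit(residues, "")[[1]], "residue letter")
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "protein_sequence")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @param numbering_offset First residue number (applied to all records).
#' @return Named list of [protein_sequence()] objects.
#' @export
read_protein_fasta <- function(path, numbering_offset = 1L) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  stats::setNames(lapply(seq_along(aas), function(i) {
    protein_sequence(ids[i], as.character(aas[[i]]), numbering_offset)
  }), ids)
}

#' Global (Needleman-Wunsch) alignment of two protein sequences
#'
#' Optimal global alignment under an affine gap model (a gap of length L
#' costs `gap_open + L * gap_extend`). The dynamic programming is delegated
#' to [Biostrings::pairwiseAlignment()]; percent identity is computed over
#' all alignment columns, gap columns counting in the denominator (see
#' [percent_identity()]).
#'
#' @param a,b [protein_sequence()] objects (or bare strings).
#' @param substitution Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Object of class `alignment_result` with fields `aligned_a`,
#'   `aligned_b`, `score`, `identity_pct`, plus the input ids and numbering
#'   offsets.
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!inherits(a, "protein_sequence")) a <- protein_sequence("a", a)
  if (!inherits(b, "protein_sequence")) b <- protein_sequence("b", b)
  ali <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(ali))
  gb <- as.character(Biostrings::alignedSubject(ali))
  res <- structure(list(aligned_a = ga, aligned_b = gb,
                        score = Biostrings::score(ali),
                        id_a = a$id, id_b = b$id,
                        offset_a = a$numbering_offset,
                        offset_b = b$numbering_offset),
                   class = "alignment_result")
  res$identity_pct <- percent_identity(res)
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment %s vs %s: score %.1f, identity %.1f%% over %d columns\n",
              x$id_a, x$id_b, x$score, x$identity_pct, nchar(x$aligned_a)))
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' 100 x (identical columns) / (denominator). By convention the denominator
#' counts all alignment columns including gapped ones; set
#' `denominator = "ungapped"` for the alternative convention that drops gap
#' columns.
#'
#' @param r An `alignment_result`.
#' @param denominator `"all"` (default) or `"ungapped"`.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(r, denominator = c("all", "ungapped")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(r$aligned_a, "")[[1]]
  cb <- strsplit(r$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  ident <- sum(ca == cb & ca != "-")
  denom <- if (denominator == "all") length(ca) else sum(ca != "-" & cb != "-")
  100 * ident / denom
}

#' Structure-based active-site residue selection
#'
#' Selects the residues whose minimum heavy-atom distance to a reference
#' residue (the modelled P1' residue) is at most `cutoff_nm`, then extends
#' every such seed to a contiguous stretch of `stretch_len` residues
#' (centred on the seed, clamped to the chain bounds) and merges overlapping
#' stretches.
#'
#' @param structure A `pdb` object from [bio3d::read.pdb()].
#' @param ref_residue List with elements `chain` and `resno` identifying the
#'   reference residue.
#' @param cutoff_nm Distance cutoff in nm (default 1.0).
#' @param stretch_len Target stretch length in residues (default 35).
#' @param chain Chain whose residues are candidates for selection; defaults
#'   to the reference residue's chain.
#' @return Object of class `active_site_selection`: data frame `stretches`
#'   (columns `start`, `end`), the seed residues, and the selection rule.
#' @export
select_active_site <- function(structure, ref_residue, cutoff_nm = 1.0,
                               stretch_len = 35L, chain = ref_residue$chain) {
  stopifnot(inherits(structure, "pdb"))
  at <- structure$atom
  heavy <- is.na(at$elesy) | !(toupper(trimws(at$elesy)) %in% "H")
  # fall back to atom-name heuristics when the element column is absent
  heavy <- heavy & !grepl("^[0-9]*H", trimws(at$elety))
  at <- at[heavy & at$type %in% c("ATOM", "HETATM"), ]
  ref <- at[at$chain %in% ref_residue$chain & at$resno == ref_residue$resno, ]
  if (nrow(ref) == 0L) {
    stop("reference residue ", ref_residue$chain, ":", ref_residue$resno,
         " not found in structure")
  }
  cand <- at[at$chain %in% chain, ]
  xyz_ref <- as.matrix(ref[, c("x", "y", "z")])
  resnos <- sort(unique(cand$resno))
  mind <- vapply(resnos, function(rn) {
    xyz <- as.matrix(cand[cand$resno == rn, c("x", "y", "z")])
    d2 <- outer(rowSums(xyz^2), rowSums(xyz_ref^2), "+") - 2 * xyz %*% t(xyz_ref)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  cutoff_A <- cutoff_nm * 10
  seeds <- resnos[mind <= cutoff_A]
  if (length(seeds) == 0L) {
    stop("no residues within ", cutoff_nm, " nm of the reference residue")
  }
  lo <- min(resnos); hi <- max(resnos)
  half_before <- (stretch_len - 1L) %/% 2L
  stretches <- t(vapply(seeds, function(s) {
    start <- s - half_before
    end <- start + stretch_len - 1L
    if (start < lo) { start <- lo; end <- min(hi, lo + stretch_len - 1L) }
    if (end > hi)  { end <- hi;  start <- max(lo, hi - stretch_len + 1L) }
    c(start, end)
  }, numeric(2)))
  stretches <- .merge_stretches(stretches)
  structure(list(
    stretches = data.frame(start = stretches[, 1], end = stretches[, 2]),
    seeds = seeds,
    rule = list(ref_residue = ref_residue, cutoff_nm = cutoff_nm,
                stretch_len = as.integer(stretch_len))),
    class = "active_site_selection")
}

.merge_stretches <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2] + 1) {
      out[k, 2] <- max(out[k, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

#' @export
print.active_site_selection <- function(x, ...) {
  cat("active_site_selection:", nrow(x$stretches), "stretch(es)",
      paste(sprintf("%d-%d", x$stretches$start, x$stretches$end), collapse = ", "),
      "\n")
  invisible(x)
}

#' Nominate candidate mutations from an alignment and an active-site selection
#'
#' Walks the alignment columns, restricted to the selected stretches that are
#' classified as prime-side contacts (interacting with the substrate P1'-P4'
#' positions), and reports every position where the two sequences differ. The
#' proposed replacement is the template (second) sequence's residue.
#'
#' @param alignment An `alignment_result` from [global_align()] whose first
#'   sequence is the protease being redesigned.
#' @param selection An `active_site_selection` (stretch bounds in the first
#'   sequence's accession numbering).
#' @param contact_classes Character vector classifying every stretch as
#'   `"prime"` or `"nonprime"`, named `"start-end"` matching
#'   `selection$stretches` (the classification comes from visual inspection
#'   of the complex and is supplied by the user; see
#'   [read_stretch_classes_yaml()]).
#' @return Data frame with columns `position`, `from_aa`, `to_aa`,
#'   `rationale`.
#' @export
candidate_mutations <- function(alignment, selection, contact_classes) {
  stopifnot(inherits(alignment, "alignment_result"),
            inherits(selection, "active_site_selection"))
  st <- selection$stretches
  keys <- sprintf("%d-%d", st$start, st$end)
  if (!all(keys %in% names(contact_classes))) {
    stop("unclassified stretch(es): ",
         paste(setdiff(keys, names(contact_classes)), collapse = ", "))
  }
  cls <- contact_classes[keys]
  if (!all(cls %in% c("prime", "nonprime"))) {
    stop("contact classes must be 'prime' or 'nonprime'")
  }
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  pos_a <- cumsum(ca != "-") + alignment$offset_a - 1L
  out <- data.frame(position = integer(), from_aa = character(),
                    to_aa = character(), rationale = character())
  for (i in which(cls == "prime")) {
    sel <- ca != "-" & cb != "-" & ca != cb &
      pos_a >= st$start[i] & pos_a <= st$end[i]
    if (any(sel)) {
      out <- rbind(out, data.frame(
        position = pos_a[sel], from_aa = ca[sel], to_aa = cb[sel],
        rationale = sprintf("prime-side stretch %s", keys[i])))
    }
  }
  out[order(out$position), , drop = FALSE]
}

#' Read stretch contact classes from YAML
#'
#' Expects a mapping from `"start-end"` stretch keys to `"prime"` or
#' `"nonprime"`.
#'
#' @param path YAML file.
#' @return Named character vector.
#' @export
read_stretch_classes_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  unlist(y)
}
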