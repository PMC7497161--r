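# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# direct base-20 Shannon entropy
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p, base = 20))
}

# Score a complete gapped alignment under an affine gap model in which a gap
# of length L costs open + L * ext (matching the pairwiseAlignment
# convention). Terminal gaps are penalised like any other.
oracle_score_alignment <- function(ga, gb, mat, open, ext) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  score <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      score <- score - ext - if (in_gap_a) 0 else open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      score <- score - ext - if (in_gap_b) 0 else open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      score <- score + mat[ca[k], cb[k]]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  score
}

# Enumerate every global alignment of a and b (no gap-gap columns) and return
# the maximum achievable score. Exponential; only for short sequences.
oracle_best_alignment_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, ga, gb) {
    if (i > length(ca) && j > length(cb)) {
      s <- oracle_score_alignment(paste(ga, collapse = ""),
                                  paste(gb, collapse = ""), mat, open, ext)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      recurse(i + 1L, j + 1L, c(ga, ca[i]), c(gb, cb[j]))
    }
    if (i <= length(ca)) recurse(i + 1L, j, c(ga, ca[i]), c(gb, "-"))
    if (j <= length(cb)) recurse(i, j + 1L, c(ga, "-"), c(gb, cb[j]))
    invisible()
  }
  recurse(1L, 1L, character(), character())
  best
}

blosum62 <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

# tiny synthetic structure written as PDB text; residues at controlled
# distances (in Angstrom) from a reference CA placed at the origin
write_synthetic_pdb <- function(path, resnos, distances_A, chain = "A") {
  fmt <- "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C"
  lines <- vapply(seq_along(resnos), function(i) {
    sprintf(fmt, i, chain, resnos[i], distances_A[i], 0, 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
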