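#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter codes, in alphabetical order. All probability
#' vectors handled by the package are indexed by this alphabet.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter lookup (Title case as printed in most tables)
.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)

#' Convert amino-acid codes to one-letter form
#'
#' Accepts one-letter codes (returned unchanged) or three-letter codes in any
#' capitalisation ("Asp", "ASP", "asp").
#'
#' @param x Character vector of amino-acid codes.
#' @return Character vector of one-letter codes.
#' @export
aa_one_letter <- function(x) {
  x <- as.character(x)
  out <- ifelse(nchar(x) == 1L, toupper(x),
                unname(.aa3to1[paste0(
                  toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))]))
  bad <- is.na(out) | !(out %in% aa_alphabet())
  if (any(bad)) {
    stop("unrecognised amino-acid code(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

.check_aa <- function(x, what = "amino-acid code") {
  bad <- !(x %in% aa_alphabet())
  if (any(bad)) {
    stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "))
  }
  invisible(x)
}
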