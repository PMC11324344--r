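#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, alphabetically ordered.
#' All sequence handling in the package is restricted to this alphabet;
#' non-canonical residues are rejected at I/O time.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter <-> one-letter lookup (canonical residues only)
AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")
AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

# integer-ish residue charges used by the screened-electrostatic scorer;
# histidine gets +0.5 for its partial protonation at neutral pH
AA_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 0.5)

#' Default amino-acid groups
#'
#' Physico-chemical grouping used by the grouped replacement scheme of the
#' mutation chooser: negative, positive, polar, aliphatic and aromatic
#' residues.  Users may supply their own partition in a [chooser_policy()].
#'
#' @return Named list of character vectors of one-letter codes.
#' @export
default_aa_groups <- function() {
  list(negative  = c("D", "E"),
       positive  = c("K", "R", "H"),
       polar     = c("S", "T", "N", "Q", "C", "Y"),
       aliphatic = c("A", "V", "L", "I", "M", "G", "P"),
       aromatic  = c("F", "W"))
}

aa_charge <- function(aa) {
  q <- AA_CHARGE[aa]
  q[is.na(q)] <- 0
  unname(q)
}

check_aa <- function(aa, what = "amino acid") {
  bad <- setdiff(unique(aa), AA20)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s code(s): %s (must be one of the 20 canonical one-letter codes)",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}
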