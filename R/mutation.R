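#' Point mutation on a binder chain
#'
#' @param chain Single-character chain label.
#' @param pos 1-based residue position within the chain.
#' @param wt Wild-type one-letter code (the identity being replaced).
#' @param mut Mutant one-letter code; must differ from `wt`.
#' @return An object of class `mutation`.
#' @export
mutation <- function(chain, pos, wt, mut) {
  check_aa(c(wt, mut))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("position must be a positive integer", call. = FALSE)
  if (wt == mut) stop("wild-type and mutant residue must differ", call. = FALSE)
  structure(list(chain = as.character(chain), pos = pos, wt = wt, mut = mut),
            class = "mutation")
}

#' Format a mutation as `chain:wt pos mut`
#'
#' The canonical string form, e.g. `"A:I45W"`; inverse of
#' [parse_mutation_string()].
#'
#' @param m A `mutation`.
#' @return Character scalar.
#' @export
format_mutation <- function(m) {
  stopifnot(inherits(m, "mutation"))
  sprintf("%s:%s%d%s", m$chain, m$wt, m$pos, m$mut)
}

#' Parse a mutation string
#'
#' Accepts the `"<chain>:<wt><pos><mut>"` form, e.g. `"A:I45W"`.
#'
#' @param s Character scalar.
#' @return A `mutation`.
#' @export
parse_mutation_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  mm <- regmatches(s, regexec("^(.):([A-Za-z])([0-9]+)([A-Za-z])$", s))[[1]]
  if (length(mm) != 5) {
    stop(sprintf("malformed mutation string: '%s' (expected e.g. 'A:I45W')", s),
         call. = FALSE)
  }
  wt <- toupper(mm[3]); mut <- toupper(mm[5])
  bad <- setdiff(c(wt, mut), AA20)
  if (length(bad) > 0) {
    stop(sprintf("malformed mutation string '%s': '%s' is not a canonical amino acid",
                 s, paste(bad, collapse = "','")), call. = FALSE)
  }
  mutation(mm[2], as.integer(mm[4]), wt, mut)
}

#' @export
print.mutation <- function(x, ...) {
  cat("<mutation>", format_mutation(x), "\n")
  invisible(x)
}

# canonical key for a set of mutations, used for distinctness checks
mutation_set_key <- function(ms) {
  paste(sort(vapply(ms, format_mutation, character(1))), collapse = "+")
}
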