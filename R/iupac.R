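#' IUPAC nucleotide codes
#'
#' The 15 IUPAC nucleotide ambiguity codes and the concrete bases each one
#' denotes, taken from [Biostrings::IUPAC_CODE_MAP].
#'
#' @return A tibble with columns `code` and `bases` (a list-column of
#'   character vectors of concrete bases).
#' @examples
#' iupac_codes()
#' @export
iupac_codes <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  tibble::tibble(
    code = names(map),
    bases = purrr::map(unname(map), ~ strsplit(.x, "", fixed = TRUE)[[1]])
  )
}

# internal: named list code -> character vector of concrete bases
.iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(lapply(unname(map), function(x) strsplit(x, "")[[1]]), names(map))
}

# internal: 15x15 logical matrix, TRUE iff base sets intersect.
# Built once at load; '-' rows/cols absent by design (gaps never match).
.iupac_match_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sets <- .iupac_sets()
      n <- names(sets)
      m <- outer(n, n, Vectorize(function(a, b) length(intersect(sets[[a]], sets[[b]])) > 0L))
      dimnames(m) <- list(n, n)
      cache <<- m
    }
    cache
  }
})

.assert_iupac <- function(x, arg = "code") {
  bad <- !(x %in% names(Biostrings::IUPAC_CODE_MAP))
  if (any(bad)) {
    stop(sprintf("invalid IUPAC %s: %s", arg,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Do two IUPAC codes share a concrete base?
#'
#' Set-wise comparison: `TRUE` iff the concrete-base sets of the two codes
#' intersect, e.g. `Y = {C,T}` matches `C` but not `R = {A,G}`. Vectorized
#' over both arguments.
#'
#' @param code_a,code_b Character vectors of single IUPAC codes.
#' @return Logical vector.
#' @examples
#' iupac_match("Y", "C")
#' iupac_match("R", "C")
#' @export
iupac_match <- function(code_a, code_b) {
  code_a <- toupper(code_a)
  code_b <- toupper(code_b)
  .assert_iupac(code_a, "code_a")
  .assert_iupac(code_b, "code_b")
  m <- .iupac_match_matrix()
  m[cbind(code_a, code_b)]
}

# per-position degeneracy of an IUPAC string (vector of set sizes)
.position_degeneracy <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  .assert_iupac(chars, "residue")
  nchar(Biostrings::IUPAC_CODE_MAP[chars])
}

#' Reverse complement of an IUPAC string
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements (ambiguity codes are
#'   complemented set-wise, e.g. `Y` -> `R`).
#' @examples
#' revcomp("ACGT")
#' revcomp("YRK")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# smallest IUPAC code containing a set of concrete bases
.bases_to_code <- function(bases) {
  sets <- .iupac_sets()
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(sets)[vapply(sets, function(s) paste(sort(s), collapse = "") == key, logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for base set: ", key, call. = FALSE)
  hit
}
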