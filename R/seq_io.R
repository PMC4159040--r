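#' Construct a sequence set
#'
#' A sequence set is a tibble (one row per sequence, columns `id`,
#' `residues`, `description`) carrying a `role` -- `"block"` for sequences
#' whose amplification a clamp must suppress (organelle SSU rRNA genes),
#' `"pass"` for sequences to preserve (bacterial genes), or `"template"` for
#' in-silico PCR templates -- and an alignment flag. Residues are stored
#' uppercase; `U` is normalized to `T` (noted in `description`), `.` gap
#' characters become `-`.
#'
#' @param id Character vector of identifiers.
#' @param residues Character vector of nucleotide strings (IUPAC codes and
#'   `-` gaps allowed).
#' @param description Character vector of free-text descriptions.
#' @param role One of `"block"`, `"pass"`, `"template"`.
#' @param aligned Logical; if `TRUE` all members must have identical length
#'   (gaps included) and the common length is recorded as the alignment
#'   length.
#' @return A `seq_set` tibble.
#' @examples
#' seq_set(c("a", "b"), c("ACGT", "ACGA"), role = "pass")
#' @export
seq_set <- function(id, residues, description = "", role = c("pass", "block", "template"),
                    aligned = FALSE) {
  role <- match.arg(role)
  if (length(residues) == 0L) stop("no records", call. = FALSE)
  id <- unname(as.character(id))
  description <- rep_len(unname(as.character(description)), length(residues))
  norm <- .normalize_residues(unname(as.character(residues)), id)
  out <- tibble::tibble(
    id = id,
    residues = norm$residues,
    description = ifelse(norm$had_u, paste0(description, " [U normalized to T]"), description)
  )
  if (role == "template" && any(grepl("-", out$residues, fixed = TRUE))) {
    stop("template sequences must be gap-free; degap first", call. = FALSE)
  }
  alen <- NA_integer_
  if (aligned) {
    lens <- nchar(out$residues)
    if (length(unique(lens)) != 1L) {
      off <- out$id[lens != lens[1]][1]
      stop(sprintf("alignment rows have unequal lengths (record '%s')", off), call. = FALSE)
    }
    alen <- lens[1]
  }
  structure(out,
            class = c("seq_set", class(out)),
            role = role, aligned = aligned, alignment_length = alen)
}

# uppercase, U->T, '.'->'-', validate characters with record/position in errors
.normalize_residues <- function(residues, id) {
  residues <- toupper(residues)
  residues <- gsub(".", "-", residues, fixed = TRUE)
  had_u <- grepl("U", residues, fixed = TRUE)
  residues <- gsub("U", "T", residues, fixed = TRUE)
  valid <- c(names(Biostrings::IUPAC_CODE_MAP), "-")
  for (i in seq_along(residues)) {
    if (!nzchar(residues[i])) stop(sprintf("record '%s' is empty", id[i]), call. = FALSE)
    chars <- strsplit(residues[i], "")[[1]]
    bad <- which(!(chars %in% valid))
    if (length(bad)) {
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   chars[bad[1]], id[i], bad[1]), call. = FALSE)
    }
  }
  list(residues = residues, had_u = had_u)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> role=%s, %d sequence(s)%s\n",
              set_role(x), nrow(x),
              if (isTRUE(attr(x, "aligned")))
                sprintf(", aligned (%d columns)", attr(x, "alignment_length")) else ""))
  NextMethod()
}

#' Accessors for sequence-set metadata
#'
#' @param x A `seq_set`.
#' @return `set_role()` returns the role string; `is_aligned()` the
#'   alignment flag; `alignment_length()` the number of alignment columns
#'   (`NA` if unaligned).
#' @export
set_role <- function(x) attr(x, "role")

#' @rdname set_role
#' @export
is_aligned <- function(x) isTRUE(attr(x, "aligned"))

#' @rdname set_role
#' @export
alignment_length <- function(x) attr(x, "alignment_length")

#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param role Role to assign to the set (see [seq_set()]).
#' @return An unaligned `seq_set`, record order preserved.
#' @export
read_fasta <- function(path, role = "pass") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path, call. = FALSE)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seq_set(id, as.character(ss), desc, role = role, aligned = FALSE)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA (all rows the same length, `-` gaps) or Clustal
#' `.aln` files; the Clustal conservation line is ignored. Alignments are
#' consumed, not computed -- producing them (e.g. with CLUSTAL W or MAFFT)
#' is up to the caller.
#'
#' @param path File path.
#' @param format `"aligned-fasta"` or `"clustal"`.
#' @inheritParams read_fasta
#' @return An aligned `seq_set`.
#' @export
read_alignment <- function(path, format = c("aligned-fasta", "clustal"), role = "pass") {
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    x <- read_fasta(path, role = role)
    return(seq_set(x$id, x$residues, x$description, role = role, aligned = TRUE))
  }
  aln <- tryCatch(
    Biostrings::readDNAMultipleAlignment(path, format = "clustal"),
    error = function(e) Biostrings::readRNAMultipleAlignment(path, format = "clustal")
  )
  ss <- as.character(aln)
  seq_set(names(ss), unname(ss), role = role, aligned = TRUE)
}

#' Write a sequence set to FASTA
#'
#' @param x A `seq_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  nm <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  out <- Biostrings::BStringSet(x$residues)
  names(out) <- nm
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Remove gap characters from a sequence set
#'
#' @param x A `seq_set`.
#' @return An unaligned `seq_set` with all `-` removed.
#' @export
degap <- function(x) {
  seq_set(x$id, gsub("-", "", x$residues, fixed = TRUE), x$description,
          role = set_role(x), aligned = FALSE)
}

# character matrix (rows = members, cols = alignment columns / positions).
# Requires equal-length residues.
.seq_matrix <- function(x) {
  lens <- nchar(x$residues)
  if (length(unique(lens)) != 1L) {
    stop("sequences must have equal length for column-wise analysis", call. = FALSE)
  }
  matrix(unlist(strsplit(x$residues, "")), nrow = nrow(x), byrow = TRUE,
         dimnames = list(x$id, NULL))
}
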