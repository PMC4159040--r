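#' Construct a degenerate primer
#'
#' @param name Primer name, e.g. `"modified_63f"`.
#' @param residues IUPAC string, length >= 10.
#' @param orientation `"forward"` or `"reverse"`. A reverse primer anneals to
#'   the plus strand, so its footprint on the plus strand is the reverse
#'   complement of `residues`.
#' @return A `degenerate_primer` object.
#' @examples
#' degenerate_primer("modified_63f", "YRKGCYTWAYACATGCAAGTC", "forward")
#' @export
degenerate_primer <- function(name, residues, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  .assert_iupac(chars, "primer residue")
  if (nchar(residues) < 10L) stop("primer must be at least 10 nt", call. = FALSE)
  structure(list(name = name, residues = residues, orientation = orientation),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s): 5'-%s-3' [degeneracy %d]\n",
              x$name, x$orientation, x$residues, primer_degeneracy(x)))
  invisible(x)
}

#' Degeneracy and degenerate-position count of a primer
#'
#' `primer_degeneracy()` is the product over positions of the per-position
#' IUPAC set sizes; `count_degenerate_positions()` is the number of
#' positions whose set size exceeds 1 (e.g. 6 for the modified 63f primer).
#'
#' @param primer A `degenerate_primer`.
#' @return An integer.
#' @export
primer_degeneracy <- function(primer) {
  prod(.position_degeneracy(primer$residues))
}

#' @rdname primer_degeneracy
#' @export
count_degenerate_positions <- function(primer) {
  sum(.position_degeneracy(primer$residues) > 1L)
}

#' Expand a degenerate primer into its concrete variants
#'
#' @param primer A `degenerate_primer`.
#' @param cap Maximum degeneracy to expand (default 4096); beyond it, use
#'   set-wise matching ([locate_binding_sites()], [coverage()]) instead.
#' @return Character vector of all concrete DNA variants.
#' @examples
#' p <- degenerate_primer("ex", "ACGTACGTAY")
#' expand_degenerate(p)
#' @export
expand_degenerate <- function(primer, cap = 4096L) {
  d <- primer_degeneracy(primer)
  if (d > cap) {
    stop(sprintf("degeneracy %d exceeds cap %d; use set-wise coverage/matching instead",
                 d, cap), call. = FALSE)
  }
  sets <- .iupac_sets()
  chars <- strsplit(primer$residues, "")[[1]]
  grid <- expand.grid(rev(lapply(chars, function(ch) sets[[ch]])),
                      stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(chars)), drop = FALSE], 1L, paste0, collapse = ""))
}

# core scanner: IUPAC pattern vs one concrete/ambiguous template string.
# Returns 0-based starts and mismatch counts for all windows with <= max_mm.
.scan_pattern <- function(pattern, template, max_mm) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(template, "")[[1]]
  m <- length(p); n <- length(t)
  if (n < m) return(list(start0 = integer(0), mm = integer(0), mmpos = list()))
  M <- .iupac_match_matrix()
  valid <- rownames(M)
  nw <- n - m + 1L
  mism <- matrix(FALSE, nrow = nw, ncol = m)
  for (i in seq_len(m)) {
    tc <- t[i:(i + nw - 1L)]
    ok <- tc %in% valid
    hit <- logical(nw)
    hit[ok] <- M[p[i], tc[ok]]
    mism[, i] <- !hit
  }
  mm <- rowSums(mism)
  keep <- which(mm <= max_mm)
  list(start0 = keep - 1L, mm = as.integer(mm[keep]),
       mmpos = lapply(keep, function(k) which(mism[k, ])))
}

#' Locate primer binding sites on a template
#'
#' Scans both strands of a degapped template for windows matching the
#' primer within a mismatch budget. Matching is set-wise: an ambiguity code
#' in the template matches a primer position iff their base sets intersect.
#' A forward primer's plus-strand site carries strand `"+"`; reverse
#' primers are matched as their reverse complement on the plus strand
#' (strand `"+"` means the primer anneals in amplifiable orientation on
#' that template strand).
#'
#' @param primer A `degenerate_primer`.
#' @param template A single-row `seq_set` slice, or any list/row with `id`
#'   and `residues`.
#' @param max_mismatches Mismatch budget (default 0).
#' @return A tibble with columns `template_id`, `start`, `end` (1-based,
#'   inclusive, on the plus strand), `strand`, `mismatches`,
#'   `mismatch_positions` (list-column of 1-based primer positions), sorted
#'   by mismatches then start. Zero rows (with a warning) if the template
#'   is shorter than the primer.
#' @export
locate_binding_sites <- function(primer, template, max_mismatches = 0L) {
  tid <- template$id[1]
  seq <- toupper(template$residues[1])
  if (grepl("-", seq, fixed = TRUE)) stop("template must be degapped", call. = FALSE)
  m <- nchar(primer$residues)
  empty <- tibble::tibble(template_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          mismatches = integer(0), mismatch_positions = list())
  if (nchar(seq) < m) {
    warning("template shorter than primer; no sites")
    return(empty)
  }
  # footprint of the annealed primer on the plus strand
  pat_plus <- if (primer$orientation == "forward") primer$residues else revcomp(primer$residues)
  # the same primer annealing to the minus strand (site reported in plus coords)
  pat_minus <- revcomp(pat_plus)
  res <- list()
  for (str in c("+", "-")) {
    pat <- if (str == "+") pat_plus else pat_minus
    hit <- .scan_pattern(pat, seq, max_mismatches)
    if (length(hit$start0)) {
      res[[str]] <- tibble::tibble(
        template_id = tid,
        start = hit$start0 + 1L, end = hit$start0 + m,
        strand = str, mismatches = hit$mm,
        mismatch_positions = hit$mmpos
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$mismatches, .data$start)
}

#' Primer coverage of a sequence set
#'
#' Fraction of set members containing at least one binding site within the
#' mismatch budget. The default budget of 0 mirrors "fully matched"
#' probe-match semantics.
#'
#' @param primer A `degenerate_primer`.
#' @param seqs A `seq_set`.
#' @param max_mismatches Mismatch budget.
#' @param window Optional alignment-column range `c(first, last)` (1-based,
#'   inclusive); matching is then restricted to the degapped content of
#'   those columns. Requires an aligned set.
#' @return A one-row tibble: `primer_name`, `set_size`, `matched`,
#'   `fraction`, `mismatch_budget`.
#' @export
coverage <- function(primer, seqs, max_mismatches = 0L, window = NULL) {
  if (nrow(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  res <- seqs$residues
  if (!is.null(window)) {
    if (!is_aligned(seqs)) stop("window requires an aligned set", call. = FALSE)
    res <- substr(res, window[1], window[2])
  }
  res <- gsub("-", "", toupper(res), fixed = TRUE)
  hit <- vapply(seq_along(res), function(i) {
    s <- list(id = seqs$id[i], residues = res[i])
    if (nchar(res[i]) < nchar(primer$residues)) return(FALSE)
    nrow(locate_binding_sites(primer, s, max_mismatches)) > 0L
  }, logical(1))
  tibble::tibble(primer_name = primer$name, set_size = nrow(seqs),
                 matched = sum(hit), fraction = sum(hit) / nrow(seqs),
                 mismatch_budget = as.integer(max_mismatches))
}

#' Raise primer coverage by degenerating positions
#'
#' Greedy coverage-raising degeneration, mirroring the manual workflow that
#' turned 63f into the six-fold-degenerate modified 63f: at each step the
#' single position/base broadening that maximally raises exact-match
#' coverage is added (ties broken toward the lowest position index, then
#' alphabetical base), stopping after `max_new_positions` newly degenerated
#' positions or when no broadening gains coverage.
#'
#' @param primer A `degenerate_primer`.
#' @param seqs A `seq_set` to cover.
#' @param max_new_positions Maximum number of positions to degenerate.
#' @param window Optional alignment-column range passed to [coverage()].
#' @return A `degenerate_primer` whose coverage is >= the input primer's.
#' @export
degenerate_for_coverage <- function(primer, seqs, max_new_positions = 1L, window = NULL) {
  stopifnot(max_new_positions >= 1L)
  sets <- .iupac_sets()
  cur <- primer
  cur_cov <- coverage(cur, seqs, 0L, window)$fraction
  degenerated <- integer(0)
  for (step in seq_len(max_new_positions)) {
    chars <- strsplit(cur$residues, "")[[1]]
    best <- NULL
    for (p in seq_along(chars)) {
      have <- sets[[chars[p]]]
      for (b in setdiff(c("A", "C", "G", "T"), have)) {
        cand_chars <- chars
        cand_chars[p] <- .bases_to_code(c(have, b))
        cand <- degenerate_primer(cur$name, paste0(cand_chars, collapse = ""),
                                  cur$orientation)
        cov <- coverage(cand, seqs, 0L, window)$fraction
        if (cov > cur_cov + 1e-12 &&
            (is.null(best) || cov > best$cov + 1e-12)) {
          best <- list(primer = cand, cov = cov, pos = p)
        }
      }
    }
    if (is.null(best)) break
    newly <- !(best$pos %in% degenerated) &&
      length(sets[[strsplit(primer$residues, "")[[1]][best$pos]]]) == 1L
    cur <- best$primer
    cur_cov <- best$cov
    if (newly) degenerated <- c(degenerated, best$pos)
    if (length(degenerated) >= max_new_positions) break
  }
  cur$name <- if (identical(cur$residues, primer$residues)) primer$name else
    paste0(primer$name, "_degenerate")
  cur
}

#' Primers used in organelle-blocking 16S amplification
#'
#' The full-length bacterial 16S primer pair around which the bundled
#' organelle clamps were designed: the original 63f, its six-fold
#' degenerate modification (higher bacterial coverage), and the universal
#' reverse primer 1492r.
#'
#' @return A tibble with columns `name`, `residues`, `orientation`.
#' @examples
#' published_primers()
#' @export
published_primers <- function() {
  tibble::tibble(
    name = c("63f", "modified_63f", "1492r"),
    residues = c("CAGGCCTAACACATGCAAGTC", "YRKGCYTWAYACATGCAAGTC",
                 "GGTTACCTTGTTACGACTT"),
    orientation = c("forward", "forward", "reverse")
  )
}

#' Fetch a bundled primer as a `degenerate_primer`
#'
#' @param name One of the names in [published_primers()].
#' @return A `degenerate_primer`.
#' @export
get_primer <- function(name) {
  tbl <- published_primers()
  i <- match(name, tbl$name)
  if (is.na(i)) stop("unknown primer: ", name, call. = FALSE)
  degenerate_primer(tbl$name[i], tbl$residues[i], tbl$orientation[i])
}
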