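#' Construct an LNA clamp oligonucleotide
#'
#' A clamp is a short oligo, written 5'->3', that competes with a PCR
#' primer for overlapping template positions but cannot itself be extended
#' (its 3' end is phosphorylated). Selected residues are LNA-substituted to
#' raise duplex Tm and mismatch discrimination. By convention the bases
#' shared with the primer footprint occupy positions `1..overlap_len` at
#' the clamp's 5' end and are plain DNA.
#'
#' @param name Clamp name.
#' @param residues DNA string, 5'->3'.
#' @param lna_positions Integer vector of 1-based LNA-substituted positions.
#' @param phosphorylated_3prime Logical; designed clamps are always
#'   phosphorylated so they cannot prime extension.
#' @param overlap_len Number of 5' bases shared with the primer's annealing
#'   footprint.
#' @param target_tm Design target melting temperature, degC.
#' @param predicted_tm Optional model-predicted Tm, degC.
#' @param recommended_conc_uM Optional working concentration note, uM.
#' @return A `clamp_oligo` object.
#' @examples
#' clamp_oligo("ex", "GTCGAACGTTGTTTTCGG", c(6, 9, 13, 14, 16, 18), overlap_len = 3)
#' @export
clamp_oligo <- function(name, residues, lna_positions = integer(0),
                        phosphorylated_3prime = TRUE, overlap_len = 0L,
                        target_tm = 70, predicted_tm = NA_real_,
                        recommended_conc_uM = NA_real_) {
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("clamp residues must be concrete DNA bases", call. = FALSE)
  }
  lna_positions <- sort(unique(as.integer(lna_positions)))
  if (length(lna_positions) &&
      (min(lna_positions) < 1L || max(lna_positions) > length(chars))) {
    stop("lna_positions out of range 1..", length(chars), call. = FALSE)
  }
  structure(list(name = name, residues = residues,
                 lna_positions = lna_positions,
                 phosphorylated_3prime = isTRUE(phosphorylated_3prime),
                 overlap_len = as.integer(overlap_len),
                 target_tm = target_tm, predicted_tm = predicted_tm,
                 recommended_conc_uM = recommended_conc_uM),
            class = "clamp_oligo")
}

#' @export
print.clamp_oligo <- function(x, ...) {
  cat(sprintf("<clamp_oligo> %s: %s (%d nt, %d LNA, overlap %d%s)\n",
              x$name, order_string(x), nchar(x$residues),
              length(x$lna_positions), x$overlap_len,
              if (is.na(x$predicted_tm)) "" else sprintf(", Tm %.1f degC", x$predicted_tm)))
  invisible(x)
}

# longest run of consecutive integer positions
.max_run <- function(pos) {
  if (length(pos) == 0L) return(0L)
  pos <- sort(pos)
  r <- rle(c(1L, diff(pos)) == 1L)
  # runs of consecutive positions: diff==1 chains; length = chain + 1
  best <- 1L
  run <- 1L
  for (d in diff(pos)) {
    run <- if (d == 1L) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Vendor-style order string for a clamp
#'
#' LNA residues appear in square brackets (consecutive LNA bases share a
#' bracket) and a 3'-phosphate is written as a trailing `/3Phos/` tag,
#' e.g. `GTCGA[A]CG[T]TGT[TT]T[C]G[G]/3Phos/`.
#'
#' @param clamp A `clamp_oligo`.
#' @return A character string.
#' @export
order_string <- function(clamp) {
  chars <- strsplit(clamp$residues, "")[[1]]
  is_lna <- seq_along(chars) %in% clamp$lna_positions
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (is_lna[i]) {
      j <- i
      while (j < length(chars) && is_lna[j + 1L]) j <- j + 1L
      out <- c(out, paste0("[", paste0(chars[i:j], collapse = ""), "]"))
      i <- j + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste0(paste0(out, collapse = ""), if (clamp$phosphorylated_3prime) "/3Phos/" else "")
}

#' Structural design rules for clamp oligos
#'
#' Defaults: length 15-25 nt, 4-6 LNA substitutions, no run of more than 3
#' consecutive LNA bases (stretches of 4 or more are avoided), mandatory
#' 3'-phosphorylation, no LNA within the primer-overlap bases, and a
#' soft Tm tolerance around the 70 degC target.
#'
#' @param length_range,lna_count_range Integer `c(min, max)` ranges.
#' @param max_lna_run Longest allowed run of consecutive LNA positions.
#' @param require_phosphorylation Logical.
#' @param target_tm,tm_tol Target Tm and soft tolerance, degC.
#' @return A named list of rule settings.
#' @export
clamp_rules <- function(length_range = c(15L, 25L), lna_count_range = c(4L, 6L),
                        max_lna_run = 3L, require_phosphorylation = TRUE,
                        target_tm = 70, tm_tol = 5) {
  list(length_range = length_range, lna_count_range = lna_count_range,
       max_lna_run = max_lna_run,
       require_phosphorylation = require_phosphorylation,
       target_tm = target_tm, tm_tol = tm_tol)
}

#' Validate a clamp against the design rules
#'
#' Checks each structural rule (length, LNA count, maximum LNA run,
#' 3'-phosphorylation, LNA kept out of the primer-overlap bases) plus the
#' soft Tm-tolerance rule, and reports one row per rule. Validation never
#' throws on rule violations, only on malformed input.
#'
#' @param clamp A `clamp_oligo`.
#' @param rules A [clamp_rules()] list.
#' @param model A [thermo_model()] used for the Tm rule.
#' @return A tibble with columns `rule`, `observed`, `requirement`,
#'   `hard` (structural vs soft) and `pass`.
#' @examples
#' validate_clamp(get_clamp("LNA-Mit63"))
#' @export
validate_clamp <- function(clamp, rules = clamp_rules(), model = thermo_model()) {
  len <- nchar(clamp$residues)
  n_lna <- length(clamp$lna_positions)
  run <- .max_run(clamp$lna_positions)
  in_overlap <- sum(clamp$lna_positions <= clamp$overlap_len)
  tm <- tm_clamp(clamp, model)
  tibble::tibble(
    rule = c("length", "lna_count", "max_lna_run", "phosphorylated_3prime",
             "no_lna_in_overlap", "tm_within_tolerance"),
    observed = c(len, n_lna, run, as.integer(clamp$phosphorylated_3prime),
                 in_overlap, round(tm, 2)),
    requirement = c(
      sprintf("[%d, %d] nt", rules$length_range[1], rules$length_range[2]),
      sprintf("[%d, %d] LNA", rules$lna_count_range[1], rules$lna_count_range[2]),
      sprintf("<= %d consecutive", rules$max_lna_run),
      if (rules$require_phosphorylation) "required" else "optional",
      "0 LNA in overlap bases",
      sprintf("%.0f +/- %.0f degC", rules$target_tm, rules$tm_tol)
    ),
    hard = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    pass = c(
      len >= rules$length_range[1] && len <= rules$length_range[2],
      n_lna >= rules$lna_count_range[1] && n_lna <= rules$lna_count_range[2],
      run <= rules$max_lna_run,
      !rules$require_phosphorylation || clamp$phosphorylated_3prime,
      in_overlap == 0L,
      abs(tm - rules$target_tm) <= rules$tm_tol
    )
  )
}

#' Published organelle-blocking clamp oligos
#'
#' The four LNA clamps targeting plant mitochondrial and plastid (Poaceae
#' group) SSU rRNA genes at the modified 63f and 1492r primer-binding
#' regions. LNA positions are 1-based indices into the 5'->3' sequence;
#' all four clamps are 3'-phosphorylated, share 3 plain-DNA bases with
#' their primer's footprint at the 5' end, and were designed to a 70 degC
#' melting temperature.
#'
#' @return A tibble with columns `name`, `residues`, `lna_positions`
#'   (list-column), `overlap_len`, `phosphorylated_3prime`, `target_tm`,
#'   `competes_with`.
#' @examples
#' published_clamps()
#' @export
published_clamps <- function() {
  tibble::tibble(
    name = c("LNA-Mit63", "LNA-Mit1492", "LNA-Pla63", "LNA-Pla1492"),
    residues = c("GTCGAACGTTGTTTTCGG", "CTTCACCCCAGTCGAAGA",
                 "GTCGAACGGGAAGTGGT", "CTTCACTCCAGTCGCAAGC"),
    lna_positions = list(c(6L, 9L, 13L, 14L, 16L, 18L),
                         c(5L, 11L, 15L, 16L, 18L),
                         c(5L, 10L, 14L, 17L),
                         c(7L, 11L, 16L, 19L)),
    overlap_len = 3L,
    phosphorylated_3prime = TRUE,
    target_tm = 70,
    competes_with = c("modified_63f", "1492r", "modified_63f", "1492r")
  )
}

#' Fetch a bundled clamp as a `clamp_oligo`
#'
#' @param name One of the names in [published_clamps()].
#' @return A `clamp_oligo`.
#' @export
get_clamp <- function(name) {
  tbl <- published_clamps()
  i <- match(name, tbl$name)
  if (is.na(i)) stop("unknown clamp: ", name, call. = FALSE)
  clamp_oligo(tbl$name[i], tbl$residues[i], tbl$lna_positions[[i]],
              phosphorylated_3prime = tbl$phosphorylated_3prime[i],
              overlap_len = tbl$overlap_len[i], target_tm = tbl$target_tm[i])
}
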