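#' Thermodynamic model for oligo melting temperatures
#'
#' Nearest-neighbor DNA duplex parameters plus an LNA stabilization term.
#' The DNA parameters are the unified oligonucleotide set of SantaLucia
#' (1998, PNAS 95:1460), with the entropic salt correction
#' `dS + 0.368 (N-1) ln[Na+]` and the two-state Tm formula
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15`. LNA substitution is modeled
#' as a constant Tm increment per substituted residue; published duplex
#' measurements put each internal LNA at roughly +2 to +8 degC, and the
#' default of +3.5 degC per residue sits in the mid-low part of that range,
#' typical of evenly spread substitutions in 17-19-mers (Braasch & Corey
#' 2001, Chem Biol 8:1). The model identity is carried in every Tm report.
#'
#' @param monovalent_salt Monovalent cation concentration, mol/L (default
#'   0.05, i.e. 50 mM).
#' @param oligo_conc Total oligonucleotide strand concentration, mol/L
#'   (default 2.5e-7, i.e. 0.25 uM).
#' @param lna_dtm Tm increment per LNA substitution, degC.
#' @return A `thermo_model` object.
#' @examples
#' thermo_model()
#' @export
thermo_model <- function(monovalent_salt = 0.05, oligo_conc = 2.5e-7, lna_dtm = 3.5) {
  stopifnot(monovalent_salt > 0, oligo_conc > 0, is.finite(lna_dtm))
  structure(list(
    nn_table = "SantaLucia 1998 unified DNA/DNA",
    lna_increments = sprintf("uniform +%.1f degC per LNA substitution (within published 2-8 degC per-residue range)", lna_dtm),
    lna_dtm = lna_dtm,
    monovalent_salt = monovalent_salt,
    oligo_conc = oligo_conc
  ), class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat(sprintf("<thermo_model> %s; LNA: %s; [Na+]=%g M, CT=%g M\n",
              x$nn_table, x$lna_increments, x$monovalent_salt, x$oligo_conc))
  invisible(x)
}

# SantaLucia 1998 unified NN parameters: dH kcal/mol, dS cal/(mol K).
# Keys are the plus-strand dinucleotide 5'->3'.
.nn_unified <- function() {
  dH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
          "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
          "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
          "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
  dS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
          "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
          "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
          "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
  list(dH = dH, dS = dS,
       init_AT = c(dH = 2.3, dS = 4.1), init_GC = c(dH = 0.1, dS = -2.8),
       sym = c(dH = 0, dS = -1.4))
}

.tm_dna_one <- function(oligo, model) {
  oligo <- toupper(oligo)
  n <- nchar(oligo)
  if (n < 8L || n > 40L) stop("oligo length must be in [8, 40]", call. = FALSE)
  chars <- strsplit(oligo, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("ambiguity codes not allowed here; expand the primer first", call. = FALSE)
  }
  nn <- .nn_unified()
  dinucs <- paste0(chars[-n], chars[-1])
  dH <- sum(nn$dH[dinucs])
  dS <- sum(nn$dS[dinucs])
  for (term in chars[c(1L, n)]) {
    init <- if (term %in% c("A", "T")) nn$init_AT else nn$init_GC
    dH <- dH + init["dH"]; dS <- dS + init["dS"]
  }
  selfcomp <- identical(oligo, revcomp(oligo))
  x <- 1
  if (selfcomp) { dH <- dH + nn$sym["dH"]; dS <- dS + nn$sym["dS"]; x <- 4 }
  dS <- dS + 0.368 * (n - 1) * log(model$monovalent_salt)
  ct <- model$oligo_conc * x / 4
  unname(1000 * dH / (dS + 1.9872 * log(ct)) - 273.15)
}

#' Predict the melting temperature of a DNA oligo
#'
#' Nearest-neighbor two-state Tm under the given [thermo_model()]
#' conditions. Degenerate (IUPAC-ambiguous) oligos are scored as the mean
#' Tm over their expanded concrete variants (at most 64; the min and max
#' are attached as attributes `tm_min` / `tm_max`).
#'
#' @param oligo A DNA string, length 8-40.
#' @param model A [thermo_model()].
#' @return Predicted Tm in degC.
#' @examples
#' tm_dna("ACGTTGCAGT")
#' @export
tm_dna <- function(oligo, model = thermo_model()) {
  oligo <- toupper(oligo)
  chars <- strsplit(oligo, "")[[1]]
  if (all(chars %in% c("A", "C", "G", "T"))) return(.tm_dna_one(oligo, model))
  p <- degenerate_primer("tmp", oligo, "forward")
  variants <- expand_degenerate(p, cap = 64L)
  tms <- vapply(variants, .tm_dna_one, numeric(1), model = model)
  structure(mean(tms), tm_min = min(tms), tm_max = max(tms))
}

#' Predict the melting temperature of an LNA clamp oligo
#'
#' The DNA nearest-neighbor Tm of the base sequence plus the model's
#' per-substitution LNA increment times the number of LNA positions; by
#' construction adding an LNA substitution never lowers the prediction.
#'
#' @param clamp A [clamp_oligo()].
#' @param model A [thermo_model()].
#' @return Predicted Tm in degC.
#' @examples
#' tm_clamp(get_clamp("LNA-Mit63"))
#' @export
tm_clamp <- function(clamp, model = thermo_model()) {
  n <- nchar(clamp$residues)
  if (length(clamp$lna_positions) &&
      (min(clamp$lna_positions) < 1L || max(clamp$lna_positions) > n)) {
    stop("LNA mask index out of range", call. = FALSE)
  }
  as.numeric(tm_dna(clamp$residues, model)) + model$lna_dtm * length(clamp$lna_positions)
}
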