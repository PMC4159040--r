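# Brute-force binding-site oracle: expand the primer into concrete variants
# and scan every window by exact character comparison, independently of the
# package's set-wise scanner. Concrete templates only.
oracle_sites <- function(primer, template_str, max_mm) {
  variants <- expand_degenerate(primer)
  pat_plus <- if (primer$orientation == "forward") variants else revcomp(variants)
  scan_one <- function(pats, strand) {
    t <- strsplit(template_str, "")[[1]]
    m <- nchar(pats[1]); n <- length(t)
    if (n < m) return(NULL)
    out <- NULL
    for (s in 1:(n - m + 1)) {
      win <- t[s:(s + m - 1)]
      mm <- min(vapply(pats, function(p) {
        sum(strsplit(p, "")[[1]] != win)
      }, numeric(1)))
      if (mm <= max_mm) {
        out <- rbind(out, data.frame(start = s, end = s + m - 1,
                                     strand = strand, mismatches = mm))
      }
    }
    out
  }
  res <- rbind(scan_one(pat_plus, "+"), scan_one(revcomp(pat_plus), "-"))
  if (is.null(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res[order(res$mismatches, res$start), , drop = FALSE]
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

random_iupac <- function(n, codes = c("A", "C", "G", "T", "R", "Y", "K", "W")) {
  paste0(sample(codes, n, replace = TRUE, prob = c(rep(5, 4), rep(1, length(codes) - 4))),
         collapse = "")
}

# study conditions for planted-truth design runs: the generator plants
# per-base pass-window divergence 0.6, so the discriminating-column
# threshold is set below that rate
planted_design_config <- function() design_config(pass_div_threshold = 0.5)
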