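#' Specification for a synthetic block/pass fixture
#'
#' Describes the planted structure the generator emulates: a shared
#' backbone carrying a primer-compatible site, a downstream clamp window
#' that is conserved within the block (organelle-like) set and divergent in
#' the pass (bacterial-like) set, and independent per-position background
#' substitutions elsewhere. Defaults describe the standard study
#' conditions used throughout the test-suite: 20 block and 200 pass
#' members of 120 nt, a fully conserved 18-column window overlapping the
#' modified 63f footprint by 3 bases, per-base pass-window divergence 0.6,
#' and background divergence 0.05.
#'
#' @param seed Integer RNG seed; identical specs produce byte-identical
#'   sets (Mersenne-Twister, via [withr::with_seed()]).
#' @param n_block,n_pass Set sizes.
#' @param seq_len Sequence length, nt.
#' @param primer A `degenerate_primer` planted in every member (one
#'   concrete variant, drawn once per fixture).
#' @param primer_site_start 1-based position of the primer footprint.
#' @param window_offset Columns between the maximal-overlap window anchor
#'   and the planted window start (0 = window abuts the footprint with
#'   `overlap_len` shared bases).
#' @param window_len Planted window length, columns.
#' @param overlap_len Planted primer-footprint overlap, bases.
#' @param block_window_conservation Per-base probability that a block
#'   member retains the window consensus base.
#' @param pass_window_divergence Per-base probability that a pass member's
#'   window base is substituted away from the window consensus.
#' @param background_divergence Per-base substitution probability outside
#'   the primer site and window, both sets.
#' @param primer_site_retention Per-member probability that the planted
#'   primer site is retained intact (both sets); a non-retained member gets
#'   one substitution, at a random footprint position, to a base outside
#'   the primer's IUPAC set there. Lower values emulate imperfect primer
#'   conservation for coverage experiments.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_block = 20L, n_pass = 200L, seq_len = 120L,
                         primer = get_primer("modified_63f"),
                         primer_site_start = 31L, window_offset = 0L,
                         window_len = 18L, overlap_len = 3L,
                         block_window_conservation = 1.0,
                         pass_window_divergence = 0.6,
                         background_divergence = 0.05,
                         primer_site_retention = 1.0) {
  probs <- c(block_window_conservation, pass_window_divergence,
             background_divergence, primer_site_retention)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  m <- nchar(primer$residues)
  p_end <- primer_site_start + m - 1L
  w_start <- p_end - overlap_len + 1L + window_offset
  w_end <- w_start + window_len - 1L
  if (primer_site_start < 1L || w_end > seq_len || w_start < 1L) {
    stop("infeasible geometry: primer site plus window must fit within seq_len",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_block = n_block, n_pass = n_pass,
                 seq_len = seq_len, primer = primer,
                 primer_site_start = primer_site_start, primer_site_end = p_end,
                 window_offset = window_offset, window_len = window_len,
                 overlap_len = overlap_len, window_start = w_start, window_end = w_end,
                 block_window_conservation = block_window_conservation,
                 pass_window_divergence = pass_window_divergence,
                 background_divergence = background_divergence,
                 primer_site_retention = primer_site_retention),
            class = "fixture_spec")
}

# substitute positions of a char matrix at per-cell probability p,
# uniformly over the 3 alternative bases
.mutate_cells <- function(mat, cols, p) {
  if (p <= 0 || length(cols) == 0L) return(mat)
  sub <- mat[, cols, drop = FALSE]
  hit <- matrix(stats::runif(length(sub)) < p, nrow = nrow(sub))
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- sub[hit]
    sub[hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
    mat[, cols] <- sub
  }
  mat
}

#' Generate a block/pass fixture with planted ground truth
#'
#' @param spec A [fixture_spec()].
#' @return A list: `block` and `pass` (aligned `seq_set`s of equal-length,
#'   gap-free sequences), and `truth` recording the planted window
#'   coordinates, window consensus, primer site and concrete primer
#'   variant.
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 42, n_block = 5, n_pass = 10))
#' fx$truth$window_start
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    backbone <- sample(bases, spec$seq_len, replace = TRUE)
    variant <- sample(expand_degenerate(spec$primer), 1L)
    p_cols <- spec$primer_site_start:spec$primer_site_end
    backbone[p_cols] <- strsplit(variant, "")[[1]]
    w_cols <- spec$window_start:spec$window_end
    w_only <- setdiff(w_cols, p_cols)
    bg_cols <- setdiff(seq_len(spec$seq_len), union(p_cols, w_cols))

    primer_sets <- .iupac_sets()[strsplit(spec$primer$residues, "")[[1]]]
    make_set <- function(n, window_sub_rate, prefix, role) {
      mat <- matrix(rep(backbone, each = n), nrow = n)
      mat <- .mutate_cells(mat, bg_cols, spec$background_divergence)
      mat <- .mutate_cells(mat, w_only, window_sub_rate)
      if (spec$primer_site_retention < 1) {
        eligible <- which(lengths(primer_sets) < 4L)  # an N position cannot mismatch
        lost <- which(stats::runif(n) >= spec$primer_site_retention)
        for (i in lost) {
          j <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
          mat[i, p_cols[j]] <- sample(setdiff(c("A", "C", "G", "T"), primer_sets[[j]]), 1L)
        }
      }
      seq_set(sprintf("%s_%03d", prefix, seq_len(n)),
              apply(mat, 1L, paste0, collapse = ""),
              role = role, aligned = TRUE)
    }
    block <- make_set(spec$n_block, 1 - spec$block_window_conservation, "block", "block")
    pass_ <- make_set(spec$n_pass, spec$pass_window_divergence, "pass", "pass")
    truth <- list(window_start = spec$window_start, window_end = spec$window_end,
                  window_consensus = paste0(backbone[w_cols], collapse = ""),
                  overlap_len = spec$overlap_len,
                  primer_start = spec$primer_site_start,
                  primer_end = spec$primer_site_end,
                  primer_variant = variant, spec = spec)
    list(block = block, pass = pass_, truth = truth)
  })
}

#' Generate in-silico PCR templates with planted primer sites
#'
#' Builds random templates carrying exact forward and reverse primer
#' footprints at planned coordinates so that predicted product lengths are
#' known a priori: `product = rev_start + reverse_length - fwd_start`
#' (footprint-inclusive, 1-based).
#'
#' @param plan A data frame with columns `name`, `length`, `fwd_start`,
#'   `rev_start` (1-based plus-strand starts of the forward footprint and
#'   of the reverse primer's footprint).
#' @param forward,reverse `degenerate_primer`s.
#' @param seed Integer RNG seed.
#' @return A `seq_set` of role `"template"`.
#' @export
generate_templates <- function(plan, forward = get_primer("modified_63f"),
                               reverse = get_primer("1492r"), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    fl <- nchar(forward$residues)
    rl <- nchar(reverse$residues)
    fwd_var <- sample(expand_degenerate(forward), 1L)
    rev_var <- sample(expand_degenerate(reverse), 1L)
    res <- character(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      len <- plan$length[i]
      f0 <- plan$fwd_start[i]; r0 <- plan$rev_start[i]
      if (f0 < 1L || r0 < 1L || f0 + fl - 1L > len || r0 + rl - 1L > len) {
        stop("planned site does not fit within the template", call. = FALSE)
      }
      f_cols <- f0:(f0 + fl - 1L)
      r_cols <- r0:(r0 + rl - 1L)
      if (length(intersect(f_cols, r_cols))) {
        stop("planned forward and reverse sites overlap", call. = FALSE)
      }
      tmpl <- sample(bases, len, replace = TRUE)
      tmpl[f_cols] <- strsplit(fwd_var, "")[[1]]
      # reverse primer footprint on the plus strand is its reverse complement
      tmpl[r_cols] <- strsplit(revcomp(rev_var), "")[[1]]
      res[i] <- paste0(tmpl, collapse = "")
    }
    seq_set(plan$name, res, role = "template", aligned = FALSE)
  })
}
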