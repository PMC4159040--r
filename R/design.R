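#' Design configuration
#'
#' Tunable parameters of the clamp design search. Defaults envelope the
#' geometry of the bundled organelle clamps: windows of 16-20 alignment
#' columns sharing 2-4 plain-DNA bases with the primer footprint, starting
#' at most 5 columns past the primer 3' end; 4-6 LNA substitutions with no
#' run longer than 3; a 70 degC melting-temperature target with a 5 degC
#' soft tolerance.
#'
#' @param window_len_range Window length range, alignment columns.
#' @param overlap_range Allowed primer-footprint overlap, bases.
#' @param max_offset Maximum gap (columns) between the primer 3' end and a
#'   non-overlapping window.
#' @param min_block_conservation Minimum mean within-block conservation of
#'   a candidate window (block members matching the block consensus).
#' @param pass_div_threshold A column is discriminating when at least this
#'   fraction of pass-set members differ from the block consensus there.
#' @param lna_count_range Allowed number of LNA substitutions.
#' @param max_lna_run Longest allowed run of consecutive LNA positions.
#' @param target_tm,tm_tol Melting-temperature target and soft tolerance,
#'   degC.
#' @param max_primer_mm Mismatch budget when locating the primer footprint
#'   on the block consensus.
#' @param max_windows_tried Number of ranked windows attempted before
#'   giving up.
#' @return A named list.
#' @export
design_config <- function(window_len_range = c(16L, 20L), overlap_range = c(2L, 4L),
                          max_offset = 5L, min_block_conservation = 0.9,
                          pass_div_threshold = 0.7, lna_count_range = c(4L, 6L),
                          max_lna_run = 3L, target_tm = 70, tm_tol = 5,
                          max_primer_mm = 2L, max_windows_tried = 10L) {
  as.list(environment())
}

# per-column statistics of a block/pass alignment pair.
# Consensus is block-majority; ties break toward the base mismatching more
# pass members. Divergence counts pass members whose base set does not
# intersect the consensus base (gaps always diverge).
.column_stats <- function(block, pass_) {
  B <- .seq_matrix(block)
  P <- .seq_matrix(pass_)
  if (ncol(B) != ncol(P)) stop("block and pass sets must share alignment columns", call. = FALSE)
  C <- ncol(B)
  M <- .iupac_match_matrix()
  valid <- rownames(M)
  consensus <- character(C)
  block_cons <- numeric(C)
  pass_div <- numeric(C)
  for (j in seq_len(C)) {
    bj <- B[, j]
    tab <- sort(table(bj), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      pj <- P[, j]
      div <- vapply(top, function(b) {
        if (!(b %in% valid)) return(Inf)
        ok <- pj %in% valid
        mean(c(!M[b, pj[ok]], rep(TRUE, sum(!ok))))
      }, numeric(1))
      top <- top[order(-div, top)][1]
    }
    cons <- top[1]
    consensus[j] <- cons
    block_cons[j] <- mean(bj == cons)
    pj <- P[, j]
    if (cons %in% valid) {
      ok <- pj %in% valid
      mism <- rep(TRUE, length(pj))
      mism[ok] <- !M[cons, pj[ok]]
      pass_div[j] <- mean(mism)
    } else {
      pass_div[j] <- 1
    }
  }
  tibble::tibble(column = seq_len(C), block_consensus = consensus,
                 block_conservation = block_cons, pass_divergence = pass_div)
}

#' Find candidate clamp windows near a primer footprint
#'
#' Enumerates alignment windows that extend from the primer's 3' flank --
#' either overlapping the footprint by `overlap_range` bases or shifted up
#' to `max_offset` columns past it -- and are conserved within the block
#' set while divergent in the pass set. Windows whose block consensus
#' contains a gap, falls below `min_block_conservation`, or has no
#' discriminating column are discarded. Candidates are ranked by block
#' conservation (over the full window), then pass divergence (over the
#' clamp-specific, non-footprint columns: the overlap bases are shared with
#' the primer by design and carry no discriminating signal), then proximity
#' to the primer 3' end (offset, then smaller overlap, then shorter
#' window).
#'
#' @param block,pass_ Aligned `seq_set`s sharing coordinates (equal-length
#'   unaligned sets are treated as trivially aligned).
#' @param primer_site List with `start`, `end` (1-based inclusive columns
#'   of the primer footprint on the plus strand) and `orientation`
#'   (`"forward"` or `"reverse"`).
#' @param config A [design_config()].
#' @return A tibble of ranked window candidates: `start`, `end`, `length`,
#'   `overlap_len`, `offset`, `block_conservation`, `pass_divergence`,
#'   `n_discriminating`, `discriminating_cols` (list-column of absolute
#'   columns), `consensus` (plus-strand window consensus).
#' @export
find_clamp_windows <- function(block, pass_, primer_site, config = design_config()) {
  stats <- .column_stats(block, pass_)
  C <- nrow(stats)
  ori <- match.arg(primer_site$orientation, c("forward", "reverse"))
  p_start <- primer_site$start
  p_end <- primer_site$end
  fp_cols <- p_start:p_end
  ov_rng <- config$overlap_range
  disc <- stats$pass_divergence >= config$pass_div_threshold

  cand <- list()
  anchors <- if (ori == "forward") {
    (p_end - ov_rng[2] + 1L):(p_end + config$max_offset + 1L)
  } else {
    (p_start + ov_rng[2] - 1L):(p_start - config$max_offset - 1L)
  }
  for (a in anchors) {
    if (ori == "forward") {
      ov <- max(0L, p_end - a + 1L)
      off <- max(0L, a - p_end - 1L)
    } else {
      ov <- max(0L, a - p_start + 1L)
      off <- max(0L, p_start - a - 1L)
    }
    if (!(ov == 0L || (ov >= ov_rng[1] && ov <= ov_rng[2]))) next
    for (L in config$window_len_range[1]:config$window_len_range[2]) {
      s <- if (ori == "forward") a else a - L + 1L
      e <- s + L - 1L
      if (s < 1L || e > C) next
      cols <- s:e
      cons <- stats$block_consensus[cols]
      if (any(cons == "-")) next
      bc <- mean(stats$block_conservation[cols])
      if (bc < config$min_block_conservation) next
      spec_cols <- setdiff(cols, fp_cols)  # the clamp-specific (non-footprint) region
      dc <- spec_cols[disc[spec_cols]]
      if (length(dc) == 0L) next
      cand[[length(cand) + 1L]] <- tibble::tibble(
        start = s, end = e, length = L, overlap_len = ov, offset = off,
        block_conservation = bc,
        pass_divergence = mean(stats$pass_divergence[spec_cols]),
        n_discriminating = length(dc),
        discriminating_cols = list(dc),
        consensus = paste0(cons, collapse = "")
      )
    }
  }
  if (length(cand) == 0L) {
    message("no candidate window meets the block-conservation/divergence requirements")
    return(tibble::tibble(start = integer(0), end = integer(0), length = integer(0),
                          overlap_len = integer(0), offset = integer(0),
                          block_conservation = numeric(0), pass_divergence = numeric(0),
                          n_discriminating = integer(0), discriminating_cols = list(),
                          consensus = character(0)))
  }
  out <- dplyr::bind_rows(cand)
  dplyr::arrange(out, dplyr::desc(.data$block_conservation),
                 dplyr::desc(.data$pass_divergence),
                 .data$offset, .data$overlap_len, .data$length, .data$start)
}

#' Choose LNA substitution positions within a clamp window
#'
#' Picks `count` positions from the discriminating, non-overlap positions
#' of the window such that no run of consecutive LNA positions exceeds
#' `max_run`, preferring the most even spread: greatest minimum gap between
#' chosen positions, then greatest span of the window, then the
#' lexicographically smallest position set. The search is exhaustive over
#' valid subsets, so the result is deterministic.
#'
#' @param consensus Window consensus DNA string (clamp orientation).
#' @param discriminating Integer vector of 1-based candidate positions in
#'   clamp coordinates.
#' @param overlap_len Number of 5' primer-overlap bases; these are never
#'   LNA-substituted.
#' @param count Number of LNA positions to choose; if `NULL`, the largest
#'   feasible count in `count_range`.
#' @param count_range Allowed range of LNA counts.
#' @param max_run Longest allowed run of consecutive chosen positions.
#' @return Sorted integer vector of chosen positions.
#' @export
select_lna_positions <- function(consensus, discriminating, overlap_len = 0L,
                                 count = NULL, count_range = c(4L, 6L),
                                 max_run = 3L) {
  n <- nchar(consensus)
  pool <- sort(unique(as.integer(discriminating)))
  pool <- pool[pool > overlap_len & pool <= n]
  if (length(pool) < count_range[1]) {
    stop(sprintf("insufficient discriminating positions: %d available, %d required",
                 length(pool), count_range[1]), call. = FALSE)
  }
  counts <- if (is.null(count)) rev(count_range[1]:count_range[2]) else as.integer(count)
  for (k in counts) {
    if (k > length(pool)) next
    sel <- .best_subset(pool, k, max_run)
    if (!is.null(sel)) return(sel)
  }
  stop("LNA placement constraint unsatisfiable: every candidate selection exceeds the maximum run",
       call. = FALSE)
}

# exhaustive scored search over k-subsets of pool obeying the run limit
.best_subset <- function(pool, k, max_run) {
  if (k == 0L) return(integer(0))
  if (choose(length(pool), k) > 2e5) {
    stop("candidate position pool too large for exhaustive placement", call. = FALSE)
  }
  combos <- utils::combn(pool, k)
  ok <- apply(combos, 2L, function(s) .max_run(s) <= max_run)
  if (!any(ok)) return(NULL)
  combos <- combos[, ok, drop = FALSE]
  min_gap <- apply(combos, 2L, function(s) if (k == 1L) Inf else min(diff(s)))
  span <- combos[k, ] - combos[1, ]
  ord <- order(-min_gap, -span)
  best_score <- c(min_gap[ord[1]], span[ord[1]])
  tied <- which(min_gap == best_score[1] & span == best_score[2])
  # lexicographically smallest among ties
  tie_mat <- combos[, tied, drop = FALSE]
  pick <- tied[do.call(order, split(tie_mat, row(tie_mat)))[1]]
  as.integer(combos[, pick])
}

#' Tune a clamp toward the target melting temperature
#'
#' Adjusts the number of LNA substitutions within `count_range` until the
#' predicted Tm is within `tol` of `target`, or options are exhausted, in
#' which case the best-|deviation| candidate is returned with attribute
#' `tm_out_of_tolerance = TRUE`. When `context` (the window's
#' discriminating positions) is supplied, positions are re-selected with
#' [select_lna_positions()] for each count; otherwise only subsets of the
#' current positions are considered.
#'
#' @param candidate A `clamp_oligo`.
#' @param model A [thermo_model()].
#' @param target Target Tm, degC (default 70).
#' @param tol Tolerance, degC.
#' @param context Optional list with `discriminating` (clamp-coordinate
#'   positions), `count_range`, `max_run`.
#' @return A `clamp_oligo` with `predicted_tm` filled in.
#' @export
tune_to_tm <- function(candidate, model = thermo_model(), target = 70, tol = 5,
                       context = NULL) {
  base_tm <- as.numeric(tm_dna(candidate$residues, model))
  cur_n <- length(candidate$lna_positions)
  cur_tm <- base_tm + model$lna_dtm * cur_n
  if (abs(cur_tm - target) <= tol) {
    candidate$predicted_tm <- cur_tm
    return(candidate)
  }
  rng <- if (!is.null(context)) context$count_range else c(0L, cur_n)
  max_run <- if (!is.null(context)) context$max_run else 3L
  pool <- if (!is.null(context)) context$discriminating else candidate$lna_positions
  counts <- rng[1]:rng[2]
  counts <- counts[order(abs(base_tm + model$lna_dtm * counts - target))]
  best <- candidate
  best$predicted_tm <- cur_tm
  for (k in counts) {
    sel <- tryCatch(
      select_lna_positions(candidate$residues, pool,
                           overlap_len = candidate$overlap_len,
                           count = k, count_range = c(k, k), max_run = max_run),
      error = function(e) NULL
    )
    if (is.null(sel)) next
    tm_k <- base_tm + model$lna_dtm * k
    if (abs(tm_k - target) < abs(best$predicted_tm - target)) {
      best$lna_positions <- sel
      best$predicted_tm <- tm_k
    }
    if (abs(tm_k - target) <= tol) break
  }
  if (abs(best$predicted_tm - target) > tol) {
    attr(best, "tm_out_of_tolerance") <- TRUE
    warning(sprintf("clamp '%s': best achievable Tm %.1f degC is outside %g +/- %g degC",
                    best$name, best$predicted_tm, target, tol))
  }
  best
}

#' Design an organelle-blocking clamp oligo
#'
#' End-to-end design: locate the primer footprint on the block consensus,
#' enumerate and rank block-conserved / pass-divergent windows at the
#' primer 3' flank ([find_clamp_windows()]), place LNA substitutions on
#' discriminating positions ([select_lna_positions()]), tune the LNA count
#' to the target Tm ([tune_to_tm()]), and validate ([validate_clamp()]).
#' Deterministic given inputs and configuration.
#'
#' @param block Aligned `seq_set` of sequences to suppress (role block).
#' @param pass_ Aligned `seq_set` of sequences to preserve.
#' @param primer A `degenerate_primer` whose footprint anchors the window.
#' @param config A [design_config()].
#' @param model A [thermo_model()].
#' @param name Name for the designed clamp.
#' @return A `clamp_design` object: the chosen `clamp_oligo`, the ranked
#'   window table, the validation table, per-block-member mismatch
#'   exceptions, per-column statistics, and the located primer site.
#'   Methods: [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot], `print`.
#' @export
design_clamp <- function(block, pass_, primer, config = design_config(),
                         model = thermo_model(), name = "clamp") {
  if (is.null(pass_) || nrow(pass_) == 0L) stop("pass set required", call. = FALSE)
  if (nrow(block) == 1L) {
    warning("block set has a single member; conservation evidence is trivial")
  }
  stats <- .column_stats(block, pass_)
  site <- .locate_primer_site(primer, stats, config$max_primer_mm)
  windows <- find_clamp_windows(block, pass_, site, config)
  if (nrow(windows) == 0L) {
    stop("find_clamp_windows: no candidate window found", call. = FALSE)
  }
  chosen <- NULL
  validation <- NULL
  for (w in seq_len(min(nrow(windows), config$max_windows_tried))) {
    win <- windows[w, ]
    res <- tryCatch(
      .build_clamp(win, site, config, model, name),
      error = function(e) NULL
    )
    if (is.null(res)) next
    validation <- validate_clamp(res, clamp_rules(
      lna_count_range = config$lna_count_range, max_lna_run = config$max_lna_run,
      target_tm = config$target_tm, tm_tol = config$tm_tol
    ), model)
    if (all(validation$pass[validation$hard])) {
      chosen <- res
      windows <- dplyr::bind_rows(windows[w, ], windows[-w, ])
      break
    }
  }
  if (is.null(chosen)) {
    stop("select_lna_positions/validate_clamp: no window yielded a clamp passing all structural rules",
         call. = FALSE)
  }
  exceptions <- .block_exceptions(block, chosen, windows$start[1], windows$end[1], site)
  structure(list(clamp = chosen, windows = windows, validation = validation,
                 exceptions = exceptions, column_stats = stats,
                 primer_site = site, config = config, model = model),
            class = "clamp_design")
}

# footprint of the primer on the (degapped) block consensus, in columns
.locate_primer_site <- function(primer, stats, max_mm) {
  cons <- stats$block_consensus
  keep <- cons != "-"
  cols <- stats$column[keep]
  tmpl <- list(id = "block_consensus", residues = paste0(cons[keep], collapse = ""))
  for (mm in 0:max_mm) {
    sites <- suppressWarnings(locate_binding_sites(primer, tmpl, mm))
    sites <- sites[sites$strand == "+", ]
    if (nrow(sites) > 0L) {
      s <- sites[1, ]
      return(list(start = cols[s$start], end = cols[s$end],
                  orientation = primer$orientation, mismatches = s$mismatches,
                  primer = primer))
    }
  }
  stop("locate_primer_site: primer footprint not found on block consensus", call. = FALSE)
}

# assemble a clamp from a ranked window row
.build_clamp <- function(win, site, config, model, name) {
  ori <- site$orientation
  cols <- win$start:win$end
  cons <- win$consensus
  if (ori == "forward") {
    residues <- cons
    to_clamp <- function(col) col - win$start + 1L
  } else {
    residues <- revcomp(cons)
    to_clamp <- function(col) win$end - col + 1L
  }
  disc <- sort(to_clamp(win$discriminating_cols[[1]]))
  base_tm <- as.numeric(tm_dna(residues, model))
  k0 <- max(config$lna_count_range[1],
            min(config$lna_count_range[2],
                round((config$target_tm - base_tm) / model$lna_dtm)))
  sel <- select_lna_positions(residues, disc, overlap_len = win$overlap_len,
                              count = k0, count_range = config$lna_count_range,
                              max_run = config$max_lna_run)
  cand <- clamp_oligo(name, residues, sel, phosphorylated_3prime = TRUE,
                      overlap_len = win$overlap_len, target_tm = config$target_tm)
  tune_to_tm(cand, model, target = config$target_tm, tol = config$tm_tol,
             context = list(discriminating = disc,
                            count_range = config$lna_count_range,
                            max_run = config$max_lna_run))
}

# per-block-member mismatch table over the chosen window
.block_exceptions <- function(block, clamp, w_start, w_end, site) {
  win <- substr(block$residues, w_start, w_end)
  ref <- if (site$orientation == "forward") clamp$residues else revcomp(clamp$residues)
  mm <- vapply(win, function(s) {
    a <- strsplit(s, "")[[1]]
    b <- strsplit(ref, "")[[1]]
    sum(a != b)
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(id = block$id, mismatches = mm,
                 exception = mm > 0L, beyond_tolerated = mm > 2L) |>
    dplyr::filter(.data$exception)
}

#' @export
print.clamp_design <- function(x, ...) {
  cat("<clamp_design>\n")
  cat(sprintf("  primer footprint: columns %d-%d (%s, %d mismatch(es) vs block consensus)\n",
              x$primer_site$start, x$primer_site$end, x$primer_site$orientation,
              x$primer_site$mismatches))
  w <- x$windows[1, ]
  cat(sprintf("  window: columns %d-%d (len %d, overlap %d, offset %d); block conservation %.3f, pass divergence %.3f\n",
              w$start, w$end, w$length, w$overlap_len, w$offset,
              w$block_conservation, w$pass_divergence))
  print(x$clamp)
  nh <- sum(!x$validation$pass & x$validation$hard)
  cat(sprintf("  validation: %d structural failure(s); %d block member(s) with in-window mismatches\n",
              nh, nrow(x$exceptions)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname design_clamp
#' @param x A `clamp_design` object.
#' @param ... Unused.
#' @export
tidy.clamp_design <- function(x, ...) x$windows

#' @rdname design_clamp
#' @export
glance.clamp_design <- function(x, ...) {
  w <- x$windows[1, ]
  tibble::tibble(
    clamp_name = x$clamp$name,
    window_start = w$start, window_end = w$end,
    window_length = w$length, overlap_len = w$overlap_len, offset = w$offset,
    block_conservation = w$block_conservation,
    pass_divergence = w$pass_divergence,
    n_lna = length(x$clamp$lna_positions),
    predicted_tm = x$clamp$predicted_tm,
    n_exceptions = nrow(x$exceptions),
    structural_pass = all(x$validation$pass[x$validation$hard])
  )
}

#' Write a clamp to annotated FASTA
#'
#' LNA-substituted positions are written lowercase and a `/3Phos/` tag is
#' appended to phosphorylated clamps.
#'
#' @param clamp A `clamp_oligo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clamp_fasta <- function(clamp, path) {
  chars <- strsplit(clamp$residues, "")[[1]]
  lna <- seq_along(chars) %in% clamp$lna_positions
  chars[lna] <- tolower(chars[lna])
  seqtxt <- paste0(paste0(chars, collapse = ""),
                   if (clamp$phosphorylated_3prime) "/3Phos/" else "")
  writeLines(c(paste0(">", clamp$name), seqtxt), path)
  invisible(path)
}
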