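#' Predict PCR amplicons on a template
#'
#' Locates forward and reverse primer binding sites (set-wise IUPAC
#' matching within a mismatch budget) and pairs every amplifiable
#' orientation -- forward site upstream of the reverse footprint, both
#' supporting exponential amplification -- into predicted products. The
#' product length includes both primer footprints
#' (`reverse end - forward start + 1`). The pair with the fewest total
#' mismatches (then the shortest product) is flagged `primary`.
#'
#' @param forward,reverse `degenerate_primer`s.
#' @param template A single-row `seq_set` slice (or list with `id`,
#'   `residues`), degapped.
#' @param max_mm Mismatch budget per primer site.
#' @param max_len Maximum product length considered (default 5000 bp).
#' @return A tibble: `template_id`, `fwd_start`, `fwd_end`, `fwd_mismatches`,
#'   `rev_start`, `rev_end`, `rev_mismatches`, `product_length`, `primary`.
#' @export
predict_amplicon <- function(forward, reverse, template, max_mm = 0L, max_len = 5000L) {
  fwd <- locate_binding_sites(forward, template, max_mm)
  rev <- locate_binding_sites(reverse, template, max_mm)
  empty <- tibble::tibble(template_id = character(0), fwd_start = integer(0),
                          fwd_end = integer(0), fwd_mismatches = integer(0),
                          rev_start = integer(0), rev_end = integer(0),
                          rev_mismatches = integer(0), product_length = integer(0),
                          primary = logical(0))
  fwd <- fwd[fwd$strand == "+", ]
  rev <- rev[rev$strand == "+", ]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  pairs <- tidyr::crossing(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  out <- purrr::pmap_dfr(pairs, function(f, r) {
    fs <- fwd[f, ]; rs <- rev[r, ]
    len <- rs$end - fs$start + 1L
    if (fs$start >= rs$start || len > max_len || fs$end >= rs$start) return(NULL)
    tibble::tibble(template_id = fs$template_id,
                   fwd_start = fs$start, fwd_end = fs$end,
                   fwd_mismatches = fs$mismatches,
                   rev_start = rs$start, rev_end = rs$end,
                   rev_mismatches = rs$mismatches,
                   product_length = len)
  })
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- dplyr::mutate(out, total_mm = .data$fwd_mismatches + .data$rev_mismatches)
  out <- dplyr::arrange(out, .data$total_mm, .data$product_length, .data$fwd_start)
  out$primary <- seq_len(nrow(out)) == 1L
  dplyr::select(out, -"total_mm")
}

#' Classify templates as clamp-blocked or amplifiable
#'
#' A template is `blocked` when at least one clamp matches it (either
#' strand) within `max_clamp_mm` mismatches at a site overlapping a primer
#' binding footprint, so that clamp binding physically excludes primer
#' extension; otherwise it is `amplifiable`. If `primers` is `NULL` any
#' clamp match blocks (useful when footprint positions are unknown).
#'
#' @param clamps A list of `clamp_oligo`s (or a single one).
#' @param templates A `seq_set`.
#' @param max_clamp_mm Clamp mismatch budget (default 0: perfect-match
#'   clamping).
#' @param primers Optional list of `degenerate_primer`s whose footprints
#'   the clamp site must overlap.
#' @param max_primer_mm Mismatch budget when locating primer footprints.
#' @return A tibble: `id`, `label` (`"blocked"`/`"amplifiable"`),
#'   `blocked_by` (list-column of clamp names).
#' @export
classify_blocking <- function(clamps, templates, max_clamp_mm = 0L,
                              primers = NULL, max_primer_mm = 1L) {
  if (inherits(clamps, "clamp_oligo")) clamps <- list(clamps)
  res <- gsub("-", "", toupper(templates$residues), fixed = TRUE)
  labels <- character(nrow(templates))
  by <- vector("list", nrow(templates))
  for (i in seq_len(nrow(templates))) {
    tmpl <- list(id = templates$id[i], residues = res[i])
    fp <- NULL
    fp_done <- FALSE
    hits <- character(0)
    for (cl in clamps) {
      cp <- degenerate_primer(cl$name, cl$residues, "forward")
      sites <- suppressWarnings(locate_binding_sites(cp, tmpl, max_clamp_mm))
      if (nrow(sites) == 0L) next
      if (!is.null(primers)) {
        if (!fp_done) {  # footprints are only needed once a clamp site exists
          fp <- dplyr::bind_rows(lapply(primers, function(p) {
            suppressWarnings(locate_binding_sites(p, tmpl, max_primer_mm))
          }))
          fp_done <- TRUE
        }
        if (nrow(fp) > 0L) {
          ok <- vapply(seq_len(nrow(sites)), function(s) {
            any(sites$start[s] <= fp$end & sites$end[s] >= fp$start)
          }, logical(1))
          sites <- sites[ok, ]
        }
      }
      if (nrow(sites) > 0L) hits <- c(hits, cl$name)
    }
    labels[i] <- if (length(hits)) "blocked" else "amplifiable"
    by[[i]] <- hits
  }
  tibble::tibble(id = templates$id, label = labels, blocked_by = by)
}

#' Count database sequences matching a probe
#'
#' Strand-agnostic probe-match screening: counts database members that
#' contain the query (set-wise IUPAC matching) within the mismatch budget
#' on either strand. Used to check that a designed clamp matches as few
#' bacterial SSU rRNA genes as possible.
#'
#' @param query A DNA string, length >= 10.
#' @param database A `seq_set`.
#' @param max_mm Mismatch budget (default 0: "fully matched").
#' @return A one-row tibble: `query`, `database_size`, `exact_matches`,
#'   `hits` (list-column tibble of `id`, `start`, `strand` -- the first
#'   site per matching member).
#' @export
probe_match <- function(query, database, max_mm = 0L) {
  if (nchar(query) < 10L) stop("query must be at least 10 nt", call. = FALSE)
  qp <- degenerate_primer("probe", query, "forward")
  hits <- list()
  for (i in seq_len(nrow(database))) {
    tmpl <- list(id = database$id[i],
                 residues = gsub("-", "", toupper(database$residues[i]), fixed = TRUE))
    s <- suppressWarnings(locate_binding_sites(qp, tmpl, max_mm))
    if (nrow(s) > 0L) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        id = database$id[i], start = s$start[1], strand = s$strand[1])
    }
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(id = character(0), start = integer(0), strand = character(0))
  tibble::tibble(query = query, database_size = nrow(database),
                 exact_matches = nrow(hits), hits = list(hits))
}

#' Percent identity, rounded half-up
#'
#' Sequence-similarity arithmetic for identity reports:
#' `round_half_up(100 * matches / aligned_length)`. Vectorized.
#'
#' @param matches Number of identical positions.
#' @param aligned_length Alignment length (> 0).
#' @return Integer percent.
#' @examples
#' percent_identity(480, 483)
#' @export
percent_identity <- function(matches, aligned_length) {
  if (any(aligned_length <= 0)) stop("aligned_length must be positive", call. = FALSE)
  if (any(matches < 0 | matches > aligned_length)) {
    stop("matches must be in [0, aligned_length]", call. = FALSE)
  }
  as.integer(floor(100 * matches / aligned_length + 0.5))
}
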