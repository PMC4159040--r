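test_that("a planted conserved/divergent window is top-ranked", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  site <- list(start = fx$truth$primer_start, end = fx$truth$primer_end,
               orientation = "forward")
  w <- find_clamp_windows(fx$block, fx$pass, site, planted_design_config())
  expect_gt(nrow(w), 0)
  # neighbouring windows differ only by sampling noise in realized pass
  # divergence, so recovery is to within one column
  expect_lte(abs(w$start[1] - fx$truth$window_start), 1)
  expect_equal(w$block_conservation[1], 1.0)
  # consensus over the top window matches every block member there
  expect_true(all(substr(fx$block$residues, w$start[1], w$end[1]) == w$consensus[1]))
})

test_that("an undiscriminating pass set yields no windows", {
  fx <- generate_fixture(fixture_spec(seed = 4, n_pass = 20,
                                      pass_window_divergence = 0))
  # pass identical to block in the window: no discriminating columns
  site <- list(start = fx$truth$primer_start, end = fx$truth$primer_end,
               orientation = "forward")
  expect_message(
    w <- find_clamp_windows(fx$block, fx$pass, site, planted_design_config()),
    "no candidate window"
  )
  expect_equal(nrow(w), 0L)
})

test_that("equally scored windows break ties toward the primer 3' end", {
  # two disjoint-length candidates at the same start score identically on a
  # perfectly clean fixture; the shorter/closer configuration must rank first
  fx <- generate_fixture(fixture_spec(seed = 9, background_divergence = 0))
  site <- list(start = fx$truth$primer_start, end = fx$truth$primer_end,
               orientation = "forward")
  w <- find_clamp_windows(fx$block, fx$pass, site, planted_design_config())
  ties <- w[abs(w$block_conservation - w$block_conservation[1]) < 1e-12 &
              abs(w$pass_divergence - w$pass_divergence[1]) < 1e-12, ]
  if (nrow(ties) > 1) {
    expect_true(all(ties$offset >= ties$offset[1]))
    expect_true(all(ties$overlap_len[ties$offset == ties$offset[1]] >=
                      ties$overlap_len[1]))
  }
  expect_equal(w$start[1], fx$truth$window_start)
})

test_that("LNA placement selects discriminating positions with maximal spread", {
  # forced selection: exactly six candidates for six substitutions
  sel <- select_lna_positions("GTCGAACGTTGTTTTCGG", c(6, 9, 13, 14, 16, 18),
                              overlap_len = 3, count = 6)
  expect_equal(sel, c(6L, 9L, 13L, 14L, 16L, 18L))
  expect_lte(lnaclamp:::.max_run(sel), 3L)

  # dense candidate run: exhaustive oracle over valid 4-subsets of {1..5}
  oracle <- combn(1:5, 4)
  valid <- oracle[, apply(oracle, 2, function(s) lnaclamp:::.max_run(s) <= 3)]
  scores <- apply(valid, 2, function(s) c(min(diff(s)), s[4] - s[1]))
  best <- valid[, order(-scores[1, ], -scores[2, ],
                        valid[1, ], valid[2, ], valid[3, ], valid[4, ])[1]]
  sel2 <- select_lna_positions("ACGTACGTACGTACGTAC", 1:5, overlap_len = 0,
                               count = 4)
  expect_equal(sel2, as.integer(best))
  expect_equal(sel2, c(1L, 2L, 3L, 5L))

  # unsatisfiable: four candidates forming a run of four
  expect_error(
    select_lna_positions("ACGTACGTACGTACGTAC", 7:10, overlap_len = 0,
                         count = 4, count_range = c(4, 4)),
    "unsatisfiable"
  )
  # too few candidates
  expect_error(
    select_lna_positions("ACGTACGTACGTACGTAC", c(5, 9), overlap_len = 0,
                         count_range = c(4, 6)),
    "insufficient discriminating positions: 2 available, 4 required"
  )
  # overlap positions are excluded from the pool
  sel3 <- select_lna_positions("ACGTACGTACGTACGTAC", c(2, 3, 6, 9, 12, 15),
                               overlap_len = 3, count = 4)
  expect_true(all(sel3 > 3))
})

test_that("Tm tuning adjusts the LNA count toward the target", {
  s <- "GTCGAACGTTGTTTTCGG"
  ctx <- list(discriminating = c(6, 9, 13, 14, 16, 18),
              count_range = c(4L, 6L), max_run = 3L)
  # within tolerance: unchanged
  c_ok <- clamp_oligo("ok", s, c(6, 9, 13, 14, 16, 18), overlap_len = 3)
  tuned <- tune_to_tm(c_ok, context = ctx)
  expect_equal(tuned$lna_positions, c_ok$lna_positions)
  expect_equal(tuned$predicted_tm, tm_clamp(c_ok))

  # too few substitutions: Tm low, count raised, Tm increases
  c_low <- clamp_oligo("low", s, c(6, 13, 18), overlap_len = 3)
  low_tm <- tm_clamp(c_low)
  expect_lt(low_tm, 65)
  tuned2 <- tune_to_tm(c_low, context = ctx)
  expect_gt(length(tuned2$lna_positions), length(c_low$lna_positions))
  expect_gt(tuned2$predicted_tm, low_tm)
  expect_lte(abs(tuned2$predicted_tm - 70), 5)

  # options exhausted: best-effort result flagged
  c_far <- clamp_oligo("far", "ATATATATTATATATA", c(3, 6, 9, 12), overlap_len = 0)
  expect_warning(tuned3 <- tune_to_tm(c_far, target = 70, tol = 3,
                                      context = list(discriminating = c(3, 6, 9, 12, 15),
                                                     count_range = c(4L, 5L),
                                                     max_run = 3L)),
                 "outside")
  expect_true(isTRUE(attr(tuned3, "tm_out_of_tolerance")))
})

test_that("end-to-end design recovers planted truth and respects all constraints", {
  fx <- generate_fixture(fixture_spec(seed = 12))
  d <- design_clamp(fx$block, fx$pass, get_primer("modified_63f"),
                    planted_design_config())
  g <- glance(d)
  expect_lte(abs(g$window_start - fx$truth$window_start), 1)
  expect_true(g$structural_pass)
  expect_gte(g$n_lna, 4)
  expect_lte(g$n_lna, 6)
  # clamp sequence equals the block consensus over the window: zero
  # mismatches against every block member on this fully conserved fixture
  expect_equal(nrow(d$exceptions), 0L)
  # each LNA position sits on a column where the pass majority differs
  cols <- g$window_start + d$clamp$lna_positions - 1L
  stats <- d$column_stats
  expect_true(all(stats$pass_divergence[cols] > 0.5))
  # determinism
  d2 <- design_clamp(fx$block, fx$pass, get_primer("modified_63f"),
                     planted_design_config())
  expect_identical(glance(d2), g)
  expect_identical(d2$clamp$lna_positions, d$clamp$lna_positions)
})

test_that("designed clamps block every block member and spare divergent pass members", {
  fx <- generate_fixture(fixture_spec(seed = 13))
  d <- design_clamp(fx$block, fx$pass, get_primer("modified_63f"),
                    planted_design_config())
  cb <- classify_blocking(d$clamp, fx$block,
                          primers = list(get_primer("modified_63f")))
  expect_true(all(cb$label == "blocked"))
  cp <- classify_blocking(d$clamp, fx$pass,
                          primers = list(get_primer("modified_63f")))
  # with per-base window divergence 0.6 a perfect clamp match in a pass
  # member is vanishingly rare
  expect_gt(mean(cp$label == "amplifiable"), 0.9)
})

test_that("degenerate inputs are rejected with stage identity", {
  fx <- generate_fixture(fixture_spec(seed = 14, n_block = 2, n_pass = 5))
  expect_error(design_clamp(fx$block, fx$pass[0, ], get_primer("modified_63f")),
               "pass set required")
  expect_warning(
    try(design_clamp(fx$block[1, ], fx$pass, get_primer("modified_63f"),
                     planted_design_config()), silent = TRUE),
    "single member"
  )
  # identical block and pass sets: the failure names the stage
  expect_error(
    suppressMessages(design_clamp(fx$pass, fx$pass, get_primer("modified_63f"),
                                  planted_design_config())),
    "find_clamp_windows"
  )
})

test_that("design results expose tidy/glance/autoplot interfaces", {
  fx <- generate_fixture(fixture_spec(seed = 15, n_pass = 60))
  d <- design_clamp(fx$block, fx$pass, get_primer("modified_63f"),
                    planted_design_config())
  expect_s3_class(tidy(d), "tbl_df")
  expect_gt(nrow(tidy(d)), 0)
  expect_equal(nrow(glance(d)), 1L)
  p <- ggplot2::autoplot(d)
  expect_s3_class(p, "ggplot")
})

test_that("designed clamps obey structural constraints across random fixtures", {
  withr::with_seed(61, seeds <- sample(1e6, 25))
  for (s in seeds) {
    fx <- generate_fixture(fixture_spec(seed = s, n_block = 10, n_pass = 40))
    d <- design_clamp(fx$block, fx$pass, get_primer("modified_63f"),
                      planted_design_config())
    cl <- d$clamp
    expect_true(cl$phosphorylated_3prime)
    expect_gte(length(cl$lna_positions), 4)
    expect_lte(length(cl$lna_positions), 6)
    expect_lte(lnaclamp:::.max_run(cl$lna_positions), 3)
    expect_true(all(cl$lna_positions > cl$overlap_len))
    expect_gte(nchar(cl$residues), 15)
    expect_lte(nchar(cl$residues), 25)
  }
})
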