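test_that("degenerate expansion obeys the product law", {
  expect_equal(expand_degenerate(degenerate_primer("p", "ACGTACGTAC")), "ACGTACGTAC")
  p2 <- degenerate_primer("p", "AYACGTACGT")
  expect_setequal(expand_degenerate(p2), c("ACACGTACGT", "ATACGTACGT"))
  # property: |expansion| equals the product of per-position set sizes
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- degenerate_primer("r", random_iupac(10))
      expect_length(expand_degenerate(p), primer_degeneracy(p))
    }
  })
  big <- degenerate_primer("big", strrep("N", 10))
  expect_error(expand_degenerate(big), "cap")
})

test_that("the modified 63f primer has 6 degenerate positions and 64 variants", {
  p <- get_primer("modified_63f")
  expect_equal(count_degenerate_positions(p), 6L)
  expect_length(expand_degenerate(p), 64L)
  # the original 63f is one of its variants
  expect_true(get_primer("63f")$residues %in% expand_degenerate(p))
  expect_equal(count_degenerate_positions(degenerate_primer("p", "ACGTACGTAC")), 0L)
  expect_equal(count_degenerate_positions(degenerate_primer("p", "NNACGTACGT")), 2L)
})

test_that("binding-site search finds exact and near-exact sites", {
  p <- degenerate_primer("p", "ACGTACGTAC")
  tpl <- list(id = "t", residues = paste0("TT", "ACGTACGTAC", "TTT"))
  s <- locate_binding_sites(p, tpl, 0)
  expect_equal(s$start[s$strand == "+"], 3L)
  expect_equal(s$mismatches[s$strand == "+"], 0L)
  tpl2 <- list(id = "t", residues = paste0("TT", "ACGAACGTAC", "TTT"))
  expect_equal(nrow(locate_binding_sites(p, tpl2, 0)), 0L)
  s2 <- locate_binding_sites(p, tpl2, 1)
  expect_equal(s2$mismatches[s2$strand == "+"], 1L)
  expect_equal(s2$mismatch_positions[s2$strand == "+"][[1]], 4L)
  expect_warning(locate_binding_sites(p, list(id = "short", residues = "ACGT"), 0),
                 "shorter")
})

test_that("binding-site search agrees with the expanded-variant brute-force oracle", {
  withr::with_seed(101, {
    for (i in 1:40) {
      m <- sample(10:12, 1)
      p <- degenerate_primer("r", random_iupac(m),
                             orientation = sample(c("forward", "reverse"), 1))
      tpl_str <- random_dna(sample(40:60, 1))
      # sometimes plant a variant so non-trivial hits occur
      if (i %% 2 == 0) {
        v <- sample(expand_degenerate(p), 1)
        pos <- sample(nchar(tpl_str) - m + 1, 1)
        fp <- if (p$orientation == "forward") v else revcomp(v)
        substr(tpl_str, pos, pos + m - 1) <- fp
      }
      mm <- sample(0:2, 1)
      got <- locate_binding_sites(p, list(id = "t", residues = tpl_str), mm)
      want <- oracle_sites(p, tpl_str, mm)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        got_o <- got[order(got$strand, got$start), ]
        want_o <- want[order(want$strand, want$start), ]
        expect_equal(got_o$start, want_o$start)
        expect_equal(got_o$mismatches, as.integer(want_o$mismatches))
      }
    }
  })
})

test_that("coverage counts matched members and is monotone in the budget", {
  p <- degenerate_primer("p", "ACGTACGTAC")
  seqs <- seq_set(paste0("s", 1:4),
                  c(paste0("TT", "ACGTACGTAC", "TT"),
                    paste0("GG", "ACGTACGTAC", "AA"),
                    paste0("ACGTACGTAC", "GGGG"),
                    paste0("TT", "ACGAACGAAC", "TT")))
  cov0 <- coverage(p, seqs, 0)
  expect_equal(cov0$fraction, 0.75)
  expect_equal(cov0$matched, 3L)
  cov2 <- coverage(p, seqs, 2)
  expect_gte(cov2$fraction, cov0$fraction)
  expect_error(coverage(p, seqs[0, ], 0), "empty")
})

test_that("coverage recovers a planted primer-site conservation rate", {
  for (seed in c(5, 6, 7)) {
    spec <- fixture_spec(seed = seed, n_block = 5, n_pass = 500,
                         primer_site_retention = 0.8)
    fx <- generate_fixture(spec)
    cov <- coverage(get_primer("modified_63f"), fx$pass, 0)
    expect_lt(abs(cov$fraction - 0.8), 0.05)
  }
})

test_that("greedy degeneration raises coverage and recovers a two-variant site", {
  # 10 + 10 sequences built from two site variants differing at one position
  site_a <- "ACGTACGTAC"
  site_b <- "ACGTACGTGC"  # position 9 A->G
  withr::with_seed(21, {
    flank <- replicate(20, random_dna(8))
    seqs <- seq_set(paste0("s", 1:20),
                    paste0(flank, c(rep(site_a, 10), rep(site_b, 10))))
  })
  p <- degenerate_primer("site", site_a)
  expect_equal(coverage(p, seqs, 0)$fraction, 0.5)
  p2 <- degenerate_for_coverage(p, seqs, max_new_positions = 1)
  expect_equal(coverage(p2, seqs, 0)$fraction, 1.0)
  expect_equal(substr(p2$residues, 9, 9), "R")
  expect_equal(count_degenerate_positions(p2), 1L)

  # already-full coverage: unchanged
  pN <- degenerate_primer("full", "ACGTACGTRC")
  expect_equal(degenerate_for_coverage(pN, seqs, 1)$residues, pN$residues)

  # coverage(output) >= coverage(input) on arbitrary inputs
  withr::with_seed(31, {
    for (i in 1:5) {
      seqs_r <- seq_set(paste0("r", 1:15), replicate(15, random_dna(30)))
      pr <- degenerate_primer("r", random_dna(10))
      out <- degenerate_for_coverage(pr, seqs_r, 2)
      expect_gte(coverage(out, seqs_r, 0)$fraction,
                 coverage(pr, seqs_r, 0)$fraction)
    }
  })
})

test_that("coverage is non-decreasing under single-position IUPAC broadening", {
  withr::with_seed(41, {
    seqs <- seq_set(paste0("s", 1:30), replicate(30, random_dna(40)))
    p <- degenerate_primer("p", random_dna(10))
    base_cov <- coverage(p, seqs, 0)$fraction
    chars <- strsplit(p$residues, "")[[1]]
    for (pos in c(1, 5, 10)) {
      for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
        broad <- chars
        broad[pos] <- lnaclamp:::.bases_to_code(c(chars[pos], b))
        pb <- degenerate_primer("b", paste0(broad, collapse = ""))
        expect_gte(coverage(pb, seqs, 0)$fraction, base_cov)
      }
    }
  })
})
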