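test_that("dna_sequence normalizes case and rejects non-ACGT residues", {
  s <- dna_sequence("acgtACGT")
  expect_equal(s$residues, "ACGTACGT")
  expect_error(dna_sequence("ACGTN"), "non-ACGT character 'N' at position 4")
  expect_error(dna_sequence("ACG-T"), "position 3")
})

test_that("reverse complement is correct and an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")   # palindrome
  expect_equal(reverse_complement("AAAA"), "TTTT")
  withr::with_seed(11, {
    for (i in 1:20) {
      r <- rand_dna(200)
      expect_equal(reverse_complement(reverse_complement(r)), r)
    }
  })
  expect_error(reverse_complement("ACGZ"), "non-IUPAC")
})

test_that("find_sites locates I-SceI and degenerate sites on both strands", {
  isce <- get_enzyme("I-SceI")
  hits <- find_sites(dna_sequence("TTTAGGGATAACAGGGTAATTT"), isce)
  expect_equal(hits$position, 2L)       # 0-based footprint start
  expect_equal(hits$strand, "+")
  # minus strand: embed the reverse complement of the site
  s_rc <- paste0("CCC", reverse_complement(isce$site), "CCC")
  hits2 <- find_sites(dna_sequence(s_rc), isce)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$position, 3L)
  # absent motif
  expect_equal(nrow(find_sites(dna_sequence(strrep("AC", 40)), isce)), 0L)
  # degenerate site matches its expansion
  enz <- restriction_enzyme("toy", "GANTC", 1L, 4L)
  expect_equal(find_sites(dna_sequence("AAGACTCAA"), enz)$position, 2L)
})

test_that("circular site search wraps across the origin", {
  isce <- get_enzyme("I-SceI")
  # split the 18-bp site 10/8 across the origin
  site <- isce$site
  s <- paste0(substr(site, 11, 18), strrep("C", 30), substr(site, 1, 10))
  hits <- find_sites(dna_sequence(s, "circular"), isce)
  expect_equal(hits$position, 38L)
  # same sequence treated as linear has no site
  expect_equal(nrow(find_sites(dna_sequence(s, "linear"), isce)), 0L)
})

test_that("find_sites agrees with a brute-force IUPAC scanner", {
  enzymes <- lapply(c("I-SceI", "XbaI", "FseI", "EcoRI"), get_enzyme)
  withr::with_seed(42, {
    for (rep in 1:100) {
      enz <- enzymes[[sample.int(length(enzymes), 1)]]
      s <- rand_dna(300)
      for (k in seq_len(sample.int(4, 1) - 1L)) {
        at <- sample.int(300 - 18, 1)
        ins <- if (runif(1) < 0.5) enz$site else rc_chr(enz$site)
        substr(s, at, at + nchar(ins) - 1L) <- ins
      }
      circ <- runif(1) < 0.5
      got <- find_sites(dna_sequence(s, if (circ) "circular" else "linear"), enz)
      want <- bf_find_sites(s, enz$site, circular = circ)
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
    }
  })
})

test_that("digestion produces the expected fragment counts and ends", {
  isce <- get_enzyme("I-SceI")
  # linear 30-mer with one site -> 2 fragments summing to 30
  s <- paste0("ACCCAA", isce$site, "CCGGTA")
  expect_equal(nchar(s), 30L)
  frs <- digest(dna_sequence(s), isce)
  expect_length(frs, 2L)
  expect_equal(sum(fragment_lengths(frs)), 30L)
  cut_at <- bf_find_sites(s, isce$site)$position + isce$cut_top
  expect_equal(fragment_lengths(frs)[1], cut_at)
  expect_equal(frs[[1]]$right_end$enzyme, "I-SceI")
  expect_equal(frs[[1]]$right_end$overhang, isce$cut_bottom - isce$cut_top)
  # circular with two sites -> 2 fragments
  circ <- dna_sequence(paste0(isce$site, strrep("AC", 50), isce$site,
                              strrep("GT", 60)), "circular")
  frs2 <- digest(circ, isce)
  expect_length(frs2, 2L)
  expect_equal(sum(fragment_lengths(frs2)), nchar(circ$residues))
  # uncut circular returned intact and flagged
  un <- digest(dna_sequence(strrep("ACGG", 30), "circular"), isce)
  expect_length(un, 1L)
  expect_true(un[[1]]$uncut)
  expect_equal(un[[1]]$sequence$topology, "circular")
})

test_that("digestion conserves length on random multi-enzyme digests", {
  panel <- lapply(c("EcoRI", "BamHI", "I-SceI"), get_enzyme)
  withr::with_seed(7, {
    for (rep in 1:40) {
      s <- rand_dna(600)
      for (enz in panel) {
        for (k in seq_len(sample.int(3, 1))) {
          at <- sample.int(550, 1)
          substr(s, at, at + nchar(enz$site) - 1L) <- enz$site
        }
      }
      circ <- runif(1) < 0.5
      seq <- dna_sequence(s, if (circ) "circular" else "linear")
      frs <- digest(seq, panel)
      expect_equal(sum(fragment_lengths(frs)), 600L)
      ncuts <- sum(!vapply(frs, function(f) isTRUE(f$uncut), logical(1)))
      if (ncuts > 0) {
        expect_length(frs, if (circ) length(frs) else length(frs))
      }
    }
  })
})

test_that("digesting a rotated circle yields the same fragment multiset", {
  isce <- get_enzyme("I-SceI")
  withr::with_seed(5, {
    s <- paste0(isce$site, rand_dna(200), isce$site, rand_dna(120),
                get_enzyme("EcoRI")$site, rand_dna(60))
    seq <- dna_sequence(s, "circular")
    base <- sort(fragment_lengths(digest(seq, list(isce, get_enzyme("EcoRI")))))
    for (off in c(1, 17, 100, 311)) {
      rot <- rotate(seq, off)
      expect_equal(sort(fragment_lengths(
        digest(rot, list(isce, get_enzyme("EcoRI"))))), base)
    }
  })
})

test_that("cuts closer than the overhang are rejected", {
  enz <- restriction_enzyme("toy4", "AAAA", 0L, 4L)
  expect_error(digest(dna_sequence("GGAAAAAGG"), enz), "overlapping cuts")
})

test_that("the bundled enzyme table carries the framework enzymes", {
  tab <- enzyme_table()
  expect_true(all(c("I-SceI", "XbaI", "XhoI", "FseI", "PacI") %in% tab$name))
  isce <- get_enzyme("I-SceI")
  expect_equal(nchar(isce$site), 18L)
  # XbaI leaves a 4-nt 5' overhang, FseI a 4-nt 3' overhang
  xba <- get_enzyme("XbaI")
  expect_equal(xba$cut_bottom - xba$cut_top, 4L)
  fse <- get_enzyme("FseI")
  expect_equal(fse$cut_bottom - fse$cut_top, -4L)
  expect_error(get_enzyme("NoSuchEnzyme"), "unknown enzyme")
})

test_that("canonical circular form is rotation- and strand-invariant", {
  withr::with_seed(13, {
    for (rep in 1:15) {
      s <- rand_dna(80)
      seq <- dna_sequence(s, "circular")
      base <- canonical_circular(seq)
      expect_equal(canonical_circular(rotate(seq, sample.int(79, 1))), base)
      expect_equal(canonical_circular(reverse_complement(seq)), base)
      # Booth's algorithm against brute-force minimal rotation
      rots <- vapply(0:(nchar(s) - 1), function(k) {
        paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
      }, character(1))
      k <- unskit:::.least_rotation_index(s)
      expect_equal(paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k)),
                   min(rots))
    }
  })
})
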