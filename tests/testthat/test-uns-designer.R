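test_that("nearest-neighbor Tm is GC-monotone and strand-symmetric", {
  expect_lt(melting_temperature(strrep("A", 40)),
            melting_temperature(strrep("ACGC", 10)))
  withr::with_seed(3, {
    for (i in 1:10) {
      s <- rand_dna(40)
      expect_equal(melting_temperature(s),
                   melting_temperature(reverse_complement(s)))
    }
  })
  expect_error(melting_temperature("ACGT"), "too short")
})

test_that("Tm matches an independent term-by-term parameter summation", {
  # hand summation over the published unified nearest-neighbor table,
  # written as an explicit loop with its own copy of the constants
  dh_tab <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
              CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
              GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
              TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  ds_tab <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
              CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
              GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
              TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  oracle_tm <- function(s, ct = 2.5e-7, na = 0.05) {
    ch <- strsplit(s, "")[[1]]
    dh <- 0; ds <- 0
    for (i in seq_len(length(ch) - 1)) {
      key <- paste0(ch[i], ch[i + 1])
      dh <- dh + dh_tab[[key]]
      ds <- ds + ds_tab[[key]]
    }
    for (e in ch[c(1, length(ch))]) {
      if (e == "G" || e == "C") { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (length(ch) - 1) * log(na)
    1000 * dh / (ds + 1.987 * log(ct / 4)) - 273.15
  }
  fixed <- "TACGGACTTGCACGTATGCCAGTTAACGGTCATCGGATCA"
  expect_equal(nchar(fixed), 40L)
  expect_equal(melting_temperature(fixed), oracle_tm(fixed), tolerance = 1e-10)
  withr::with_seed(9, {
    for (i in 1:10) {
      s <- rand_dna(30)
      if (identical(s, rc_chr(s))) next  # oracle skips the symmetry term
      expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-10)
    }
  })
})

test_that("hairpin stem scoring matches exhaustive enumeration", {
  expect_equal(hairpin_stem("AAAAAAAAAA"), 0L)          # homopolymer
  # GGGGC:GCCCC is a 5-bp stem around the AAAT loop
  expect_equal(hairpin_stem("GGGGCAAATGCCCC"), 5L)
  expect_equal(bf_hairpin("GGGGCAAATGCCCC"), 5L)
  withr::with_seed(21, {
    # appending a 6-bp inverted repeat yields a stem >= 6
    for (i in 1:5) {
      clean <- rand_dna(20)
      arm <- rand_dna(6)
      s <- paste0(clean, arm, rand_dna(5), rc_chr(arm))
      expect_gte(hairpin_stem(s), 6L)
    }
    for (i in 1:40) {
      s <- rand_dna(30)
      expect_equal(hairpin_stem(s), bf_hairpin(s))
    }
  })
})

test_that("cross-annealing equals the longest-common-substring oracle", {
  u <- "ATCGGACTTACGGATCCATG"
  expect_equal(cross_anneal_score(u, reverse_complement(u)), nchar(u))
  expect_equal(cross_anneal_score(strrep("A", 30), strrep("C", 30)), 0L)
  withr::with_seed(33, {
    for (i in 1:40) {
      a <- rand_dna(40); b <- rand_dna(40)
      expect_equal(cross_anneal_score(a, b), bf_lcs(a, rc_chr(b)))
      expect_equal(cross_anneal_score(a, b), cross_anneal_score(b, a))
    }
  })
})

test_that("candidate generation is deterministic and filter-tight", {
  cfg <- design_config(rng_seed = 17, n_candidates = 25)
  c1 <- generate_candidates(cfg)
  c2 <- generate_candidates(cfg)
  expect_identical(vapply(c1, `[[`, "", "sequence"),
                   vapply(c2, `[[`, "", "sequence"))
  for (cand in c1) {
    expect_equal(nchar(cand$sequence), 40L)
    expect_gte(cand$gc_fraction, cfg$gc_min)
    expect_lte(cand$gc_fraction, cfg$gc_max)
    expect_lte(cand$hairpin_stem, cfg$threshold_hairpin)
    expect_lte(cand$self_dimer, cfg$threshold_cross)
    expect_gte(cand$tm_celsius, cfg$tm_min)
    expect_lte(cand$tm_celsius, cfg$tm_max)
    expect_false(grepl("TAGGGATAACAGGGTAAT", cand$sequence, fixed = TRUE))
    expect_false(grepl(rc_chr("TAGGGATAACAGGGTAAT"), cand$sequence,
                       fixed = TRUE))
  }
})

test_that("infeasible design constraints fail loudly with diagnostics", {
  cfg <- design_config(gc_min = 0.999, gc_max = 1.0, homopolymer_max = 4,
                       rng_seed = 1, n_candidates = 5)
  expect_error(generate_candidates(cfg, max_attempts = 2000),
               "budget.*tightest filter", ignore.case = TRUE)
})

test_that("greedy selection yields a named orthogonal set", {
  cfg <- design_config(rng_seed = 23, n_candidates = 40)
  cands <- generate_candidates(cfg)
  set <- select_orthogonal_set(cands, 5, cfg)
  expect_named(set$members, c("UNS1", "UNS2", "UNS3", "UNS4", "UNS5", "UNSX"))
  # all pairwise scores within threshold; intended pairings score 40
  mem <- set$members
  for (i in seq_along(mem)) {
    expect_equal(cross_anneal_score(mem[i], reverse_complement(mem[i])), 40L)
    for (j in seq_along(mem)) {
      if (i == j) next
      expect_lte(max(cross_anneal_score(mem[i], mem[j]),
                     cross_anneal_score(mem[i], reverse_complement(mem[j]))),
                 cfg$threshold_cross)
    }
  }
  expect_true(validate_set(set)$pass)
  # a sequence plus its reverse complement can never coexist
  u <- cands[[1]]$sequence
  clash <- list(structure(list(sequence = u, self_dimer = self_dimer(u)),
                          class = "uns_candidate"),
                structure(list(sequence = rc_chr(u),
                               self_dimer = self_dimer(u)),
                          class = "uns_candidate"))
  expect_error(select_orthogonal_set(clash, 2, cfg), "pool exhausted")
})

test_that("validate_set flags duplicates and forbidden motifs", {
  cfg <- design_config(rng_seed = 29, n_candidates = 30)
  set <- select_orthogonal_set(generate_candidates(cfg), 3, cfg)
  # duplicated member under a distinct name
  dup <- set
  dup$members[["UNS2"]] <- dup$members[["UNS1"]]
  rep <- validate_set(dup, cfg)
  expect_false(rep$pass)
  expect_false(rep$checks$pass[rep$checks$check == "distinct"])
  expect_false(rep$checks$pass[rep$checks$check == "cross_annealing"])
  # member mutated to carry an XbaI site
  bad <- set
  m <- bad$members[["UNS3"]]
  substr(m, 10, 15) <- "TCTAGA"
  bad$members[["UNS3"]] <- m
  rep2 <- validate_set(bad, cfg)
  expect_false(rep2$checks$pass[rep2$checks$check == "forbidden_motifs"])
})

test_that("whole-set design is deterministic in the seed", {
  cfg <- design_config(rng_seed = 31, n_candidates = 30)
  s1 <- design_uns_set(3, cfg)
  s2 <- design_uns_set(3, cfg)
  expect_identical(s1$members, s2$members)
  s3 <- design_uns_set(3, design_config(rng_seed = 32, n_candidates = 30))
  expect_false(identical(s1$members, s3$members))
})
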