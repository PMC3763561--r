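test_that("position assignment yields consecutive pairs and the X bridge", {
  set <- toy_uns_set(8)
  d5 <- circuit_design(paste0("pv", 1:5), "carrier")
  a5 <- assign_positions(d5, set)
  expect_equal(a5$entries$uns_left, paste0("UNS", 1:5))
  expect_equal(a5$entries$uns_right, paste0("UNS", 2:6))
  expect_equal(unname(a5$adaptor), c("UNS6", "UNSX"))
  d1 <- circuit_design("pv1", "carrier")
  a1 <- assign_positions(d1, set)
  expect_equal(unname(a1$adaptor), c("UNS2", "UNSX"))
  d11 <- circuit_design(paste0("pv", 1:11), "carrier")
  expect_error(assign_positions(d11, toy_uns_set(7)),
               "needs UNS1-12 \\+ X")
})

test_that("adaptor selection alternates Kan and Tet between rounds", {
  fx <- cached_fixture(2)
  expect_equal(select_adaptor(2, "none", fx$adaptors)$marker, "Kan")
  expect_equal(select_adaptor(2, "Kan", fx$adaptors)$marker, "Tet")
  expect_equal(select_adaptor(2, "Tet", fx$adaptors)$marker, "Kan")
  no_kan <- Filter(function(a) a$marker != "Kan", fx$adaptors)
  expect_error(select_adaptor(2, "Tet", no_kan), "no Kan adaptor")
})

test_that("a 5-TU plan rosters 7 inputs with the protocol quantities", {
  plan <- cached_plan(5)
  expect_equal(nrow(plan$roster), 7L)
  expect_equal(sum(plan$roster$kind == "position"), 5L)
  expect_equal(plan$roster$fmol_digest[plan$roster$kind == "position"],
               rep(70, 5))
  expect_equal(plan$roster$fmol_digest[plan$roster$kind == "adaptor"], 280)
  expect_equal(plan$roster$fmol_digest[plan$roster$kind == "carrier"], 140)
  expect_equal(plan$roster$fmol_pool, rep(7, 7))
  expect_equal(plan$adaptor$uns_pair, c("UNS6", "UNSX"))
  expect_equal(plan$junction_order, c(paste0("UNS", 1:6), "UNSX"))
})

test_that("duplicate addresses are a positional conflict", {
  fx <- cached_fixture(3)
  dup <- fx$design
  dup$entries[2] <- dup$entries[3]   # two entries with the 3-4 pair
  expect_error(plan_assembly(dup, fx$uns_set, fx$registry),
               "positional conflict|requires")
  same_twice <- circuit_design(rep(fx$design$entries[1], 2),
                               fx$design$carrier)
  expect_error(plan_assembly(same_twice, fx$uns_set, fx$registry),
               "positional conflict")
})

test_that("predicted length follows from insert arithmetic; UNS census is 1", {
  fx <- cached_fixture(4)
  plan <- cached_plan(4)
  # independent arithmetic: sum of UNS-trimmed body lengths, each shared
  # address counted once
  isce <- get_enzyme("I-SceI")
  body_len <- function(circ, enzymes, uL, uR) {
    for (f in digest(circ, enzymes)) {
      s <- f$sequence$residues
      pl <- regexpr(uL, s, fixed = TRUE)
      pr <- regexpr(uR, s, fixed = TRUE)
      if (pl > 0 && pr > 0 && pl < pr) return(pr + 40 - pl)
    }
    stop("insert not found")
  }
  lens <- vapply(seq_len(4), function(i) {
    pv <- fx$position_vectors[[i]]
    body_len(pv$sequence, isce,
             uns_member(fx$uns_set, pv$uns_pair[1]),
             uns_member(fx$uns_set, pv$uns_pair[2]))
  }, numeric(1))
  ad <- fx$adaptors[[plan$adaptor$name]]
  lens <- c(lens, body_len(ad$sequence,
                           list(get_enzyme("XbaI"), get_enzyme("XhoI")),
                           uns_member(fx$uns_set, "UNS5"),
                           uns_member(fx$uns_set, "UNSX")))
  lens <- c(lens, body_len(fx$carrier$sequence, get_enzyme("FseI"),
                           uns_member(fx$uns_set, "UNSX"),
                           uns_member(fx$uns_set, "UNS1")))
  # 6 shared junction UNSs counted twice in the bodies
  expect_equal(nchar(plan$predicted_sequence$residues), sum(lens) - 6 * 40)
  # every address appears exactly once in the predicted circle
  census <- unskit:::.uns_census(plan$predicted_sequence$residues, fx$uns_set)
  expect_equal(unname(census[c(paste0("UNS", 1:5), "UNSX")]), rep(1L, 6))
})

test_that("a 1-TU circuit contains UNS1, UNS2 and UNSX exactly once", {
  fx <- cached_fixture(1)
  plan <- cached_plan(1)
  census <- unskit:::.uns_census(plan$predicted_sequence$residues, fx$uns_set)
  expect_equal(unname(census[c("UNS1", "UNS2", "UNSX")]), rep(1L, 3))
})

test_that("protocol sheet arithmetic follows the 650 g/mol/bp rule", {
  expect_equal(fmol_to_ng(7, 10000), 45.5)
  expect_equal(fmol_to_ng(0, 12345), 0)
  plan <- cached_plan(2)
  sheet <- protocol_sheet(plan, concentrations = 50)
  expect_equal(sheet$mass_digest_ng,
               sheet$fmol_digest * sheet$length_bp * 650e-6)
  expect_equal(sum(sheet$mass_pool_ng),
               sum(sheet$fmol_pool * sheet$length_bp * 650e-6))
  expect_equal(sheet$volume_digest_ul, sheet$mass_digest_ng / 50)
  expect_error(protocol_sheet(plan, concentrations = 0), "positive")
})

test_that("hierarchical planning re-enters at position 1-2 and checks collisions", {
  hx <- .fixture_cache$hier
  if (is.null(hx)) {
    hx <- make_hierarchical_fixture(7, n_module_tus = 2, n_tail_tus = 2)
    .fixture_cache$hier <- hx
  }
  plan2 <- plan_hierarchical(hx$module, hx$design_tail, hx$uns_set_round2,
                             hx$round2$registry)
  expect_equal(plan2$roster$kind[1], "module")
  expect_equal(c(plan2$roster$uns_left[1], plan2$roster$uns_right[1]),
               c("UNS1", "UNS2"))
  expect_equal(plan2$roster$fmol_digest[1], 140)
  expect_equal(plan2$adaptor$marker, "Tet")   # module round used Kan

  # module alone + adaptor + carrier: a valid 1-entry plan
  empty_tail <- circuit_design(character(0), hx$design_tail$carrier,
                               hx$design_tail$previous_round_marker)
  plan_solo <- plan_hierarchical(hx$module, empty_tail, hx$uns_set_round2,
                                 hx$round2$registry)
  expect_equal(nrow(plan_solo$roster), 3L)
  expect_equal(plan_solo$adaptor$uns_pair[1], "UNS2")

  # a module whose interior reuses a tail address collides
  set <- hx$uns_set_round2
  isce_site <- "TAGGGATAACAGGGTAAT"
  fake <- withr::with_seed(55, dna_sequence(paste0(
    isce_site, uns_member(set, "UNS1"), rand_dna(150),
    uns_member(set, "UNS3"), rand_dna(150),
    uns_member(set, "UNS2"), isce_site, rand_dna(300)), "circular"))
  expect_error(plan_hierarchical(fake, hx$design_tail, set,
                                 hx$round2$registry),
               "collision.*UNS3")
})
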