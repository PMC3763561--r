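test_that("terminal homology finds shared addresses and respects flaps", {
  set <- toy_uns_set(3, seed = 61)
  frs <- toy_ring_fragments(unname(set$members[c("UNS1", "UNS2", "UNS3")]),
                            seed = 62)
  j <- terminal_homology(frs[[1]], frs[[2]])
  expect_equal(j$overlap, 40L)
  expect_equal(j$sequence, uns_member(set, "UNS2"))
  expect_equal(j$orientation, "+")
  expect_equal(c(j$flap_a, j$flap_b), c(0L, 0L))
  # reverse-complemented partner is found in the "-" orientation
  j2 <- terminal_homology(frs[[1]], reverse_complement(frs[[2]]))
  expect_equal(j2$overlap, 40L)
  expect_equal(j2$orientation, "-")
  # unrelated ends share no 20-mer
  withr::with_seed(63, {
    expect_null(terminal_homology(rand_dna(100), rand_dna(100)))
  })
  # a flap beyond tolerance suppresses the junction
  long_flap <- dna_sequence(paste0(frs[[1]]$residues,
                                   withr::with_seed(64, rand_dna(16))),
                            "linear", "flapped")
  expect_null(terminal_homology(long_flap, frs[[2]],
                                gibson_params(flap_tolerance = 15)))
  expect_equal(terminal_homology(long_flap, frs[[2]],
                                 gibson_params(flap_tolerance = 16))$overlap,
               40L)
})

test_that("terminal homology matches a brute-force window scan", {
  params <- gibson_params(min_overlap = 8, chew_window = 40,
                          flap_tolerance = 10)
  bf_best <- function(a, b) {
    # all-pairs extension over the two windows, both orientations of b
    best <- 0L
    for (sb in c(b, rc_chr(b))) {
      wa <- substr(a, max(1, nchar(a) - 39), nchar(a))
      wb <- substr(sb, 1, min(40, nchar(sb)))
      xa <- strsplit(wa, "")[[1]]; yb <- strsplit(wb, "")[[1]]
      for (i in seq_along(xa)) for (j in seq_along(yb)) {
        k <- 0L
        while (i + k <= length(xa) && j + k <= length(yb) &&
               xa[i + k] == yb[j + k]) k <- k + 1L
        if (k >= params$min_overlap &&
            length(xa) - (i + k - 1L) <= params$flap_tolerance &&
            j - 1L <= params$flap_tolerance &&
            (i + k - 1L == length(xa) || j + k - 1L == length(yb) ||
               xa[i + k] != yb[j + k]) && k > best) best <- k
      }
    }
    best
  }
  withr::with_seed(71, {
    for (rep in 1:40) {
      core <- rand_dna(sample(8:25, 1))
      a <- paste0(rand_dna(60), core, rand_dna(sample(0:10, 1)))
      b <- paste0(rand_dna(sample(0:10, 1)), core, rand_dna(60))
      if (sample(c(TRUE, FALSE), 1)) b <- rc_chr(b)
      got <- terminal_homology(a, b, params)
      want <- bf_best(a, b)
      expect_equal(if (is.null(got)) 0L else got$overlap, want)
    }
  })
})

test_that("a clean address ring assembles into one canonical circle", {
  set <- toy_uns_set(4, seed = 81)
  addrs <- unname(set$members[c("UNS1", "UNS2", "UNS3", "UNS4", "UNSX")])
  frs <- toy_ring_fragments(addrs, seed = 82)
  res <- simulate_one_pot(frs)
  expect_equal(res$status, "unique_circular")
  expect_length(res$products, 1L)
  p <- res$products[[1]]
  expect_equal(nrow(p$junctions), 5L)
  expect_true(all(p$junctions$overlap == 40L))
  # product length conservation: sum of fragments minus overlaps and flaps
  expect_equal(nchar(p$sequence$residues),
               sum(vapply(frs, function(f) nchar(f$residues), numeric(1))) -
                 sum(p$junctions$overlap) -
                 sum(p$junctions$flap_left + p$junctions$flap_right))
  # input order and fragment orientation do not change the product
  withr::with_seed(83, {
    for (rep in 1:3) {
      shuffled <- sample(frs)
      flip <- sample.int(5, 2)
      for (i in flip) shuffled[[i]] <- reverse_complement(shuffled[[i]])
      res2 <- simulate_one_pot(shuffled)
      expect_equal(res2$status, "unique_circular")
      expect_identical(res2$products[[1]]$sequence$residues,
                       p$sequence$residues)
    }
  })
  vj <- verify_junctions(p, set)
  expect_true(vj$pass)
})

test_that("one-pot enumeration matches the exhaustive arrangement oracle", {
  withr::with_seed(91, {
    for (rep in 1:4) {
      m <- sample(3:5, 1)
      addrs <- vapply(seq_len(m), function(i) rand_dna(40), character(1))
      frs <- toy_ring_fragments(addrs, body_len = 60,
                                seed = sample.int(1e6, 1))
      got <- simulate_one_pot(frs)
      want <- bf_one_pot_products(frs)
      expect_equal(sort(vapply(got$products,
                               function(p) p$sequence$residues,
                               character(1))), want)
    }
  })
})

test_that("shared address pairs are flagged ambiguous, dropouts incomplete", {
  set <- toy_uns_set(3, seed = 101)
  addrs <- unname(set$members[c("UNS1", "UNS2", "UNS3", "UNSX")])
  frs <- toy_ring_fragments(addrs, seed = 102)
  # two competing fragments with the same (UNS2, UNS3) flanks
  twin <- withr::with_seed(103, dna_sequence(
    paste0(addrs[2], rand_dna(150), addrs[3]), "linear", "twin"))
  res <- simulate_one_pot(c(frs, list(twin)))
  expect_equal(res$status, "ambiguous")
  expect_gte(length(res$products), 2L)
  # removing one ring member leaves no full circle
  res2 <- simulate_one_pot(frs[-2])
  expect_equal(res2$status, "incomplete")
  expect_length(res2$products, 0L)
})

test_that("repeated internal cargo cannot divert junctions", {
  set <- toy_uns_set(3, seed = 111)
  addrs <- unname(set$members[c("UNS1", "UNS2", "UNS3", "UNSX")])
  shared <- withr::with_seed(112, rand_dna(400))
  frs <- list(
    dna_sequence(paste0(addrs[1], shared, addrs[2]), "linear", "fA"),
    dna_sequence(paste0(addrs[2], shared, addrs[3]), "linear", "fB"),
    dna_sequence(paste0(addrs[3], withr::with_seed(113, rand_dna(200)),
                        addrs[4]), "linear", "fC"),
    dna_sequence(paste0(addrs[4], withr::with_seed(114, rand_dna(200)),
                        addrs[1]), "linear", "fD"))
  res <- simulate_one_pot(frs)
  expect_equal(res$status, "unique_circular")
  expect_equal(res$products[[1]]$n_fragments, 4L)
})

test_that("junction verification reports a missing bridge", {
  set <- toy_uns_set(2, seed = 121)
  addrs <- unname(set$members[c("UNS1", "UNS2")])
  # ring closed without UNSX: order check must fail against the full set
  frs <- toy_ring_fragments(addrs, seed = 122)
  res <- simulate_one_pot(frs)
  expect_equal(res$status, "unique_circular")
  vj <- verify_junctions(res$products[[1]], set)
  expect_false(vj$order_ok)
  expect_false(vj$pass)
})

test_that("simulator and planner agree on a fixture with junction census n+2", {
  fx <- cached_fixture(3)
  plan <- cached_plan(3)
  res <- simulate_one_pot(plan_fragments(plan))
  expect_equal(res$status, "unique_circular")
  p <- res$products[[1]]
  expect_equal(nrow(p$junctions), 3L + 2L)
  expect_identical(p$sequence$residues,
                   canonical_circular(plan$predicted_sequence))
  vj <- verify_junctions(p, fx$uns_set)
  expect_true(vj$pass)
  expect_true(all(vj$junctions$uns_count == 1L))
})
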