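#' @importFrom stats setNames
NULL

.BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' GC fraction of a DNA string
#' @param seq A `dna_sequence` or character scalar.
#' @return Fraction of G/C residues in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  s <- .residues(seq)
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[AT]", "", s))
  gc / n
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), for the 16 dimer stacks read 5'->3'
# on the top strand of a perfect duplex.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor duplex melting temperature
#'
#' Tm of the perfect duplex of `seq` with its complement, from the unified
#' nearest-neighbor parameter set (SantaLucia 1998) with duplex-initiation
#' and terminal A:T terms, the entropic salt correction
#' `dS + 0.368 (L-1) ln[Na+]`, and `Tm = 1000 dH / (dS + R ln(CT/x)) - 273.15`
#' with R = 1.987 cal/(mol K). `x` is 4 for non-self-complementary duplexes
#' and 1 for self-complementary ones (which also receive the symmetry
#' entropy term). Strand-symmetric: `Tm(s) == Tm(reverse_complement(s))`,
#' and monotone non-decreasing in GC content at fixed length.
#'
#' @param seq A `dna_sequence` or character scalar, length >= 8.
#' @param conc_molar Total strand concentration in mol/L (default 2.5e-7).
#' @param na_molar Monovalent cation concentration in mol/L (default 0.05).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, conc_molar = 2.5e-7, na_molar = 0.05) {
  s <- .residues(seq)
  n <- nchar(s)
  if (n < 8L) stop("sequence too short for a duplex Tm (need >= 8 nt)")
  if (grepl("[^ACGT]", s)) stop("Tm requires a concrete A/C/G/T sequence")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  stacks <- paste0(ch[-n], ch[-1L])
  dh <- sum(.NN_DH[stacks])
  ds <- sum(.NN_DS[stacks])
  # initiation with terminal G:C (0.1, -2.8) or terminal A:T (2.3, 4.1)
  for (term in ch[c(1L, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfcomp <- identical(s, .revcomp_chr(s))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  x <- if (selfcomp) 1 else 4
  1000 * dh / (ds + 1.987 * log(conc_molar / x)) - 273.15
}

#' Longest intramolecular hairpin stem
#'
#' Length in nucleotides of the longest contiguous Watson-Crick stem the
#' sequence can fold back on itself, requiring a loop of at least 3 nt
#' between the innermost pair. Returns 0 when no stem of length >= 2 exists.
#'
#' @param seq A `dna_sequence` or character scalar.
#' @param min_loop Minimum loop length in nt (default 3).
#' @return Integer stem length.
#' @export
hairpin_stem <- function(seq, min_loop = 3L) {
  s <- .residues(seq)
  n <- nchar(s)
  if (n < 2L * 2L + min_loop) return(0L)
  u <- utf8ToInt(s)
  comp <- integer(128)
  comp[utf8ToInt("A")] <- utf8ToInt("T"); comp[utf8ToInt("T")] <- utf8ToInt("A")
  comp[utf8ToInt("C")] <- utf8ToInt("G"); comp[utf8ToInt("G")] <- utf8ToInt("C")
  pc <- comp[u]                 # pc[i] == u[j]  <=>  i pairs j
  # S[i, j]: length of the contiguous stem whose innermost pair is (i, j),
  # built row by row: S[i, j] = P[i, j] * (S[i-1, j+1] + 1)
  best <- 0L
  prev <- integer(n)
  jv <- seq_len(n)
  for (i in seq_len(n)) {
    hit <- pc[i] == u
    cur <- integer(n)
    cur[hit] <- c(prev[-1L], 0L)[hit] + 1L
    # innermost pair needs i < j with loop j - i - 1 >= min_loop
    valid <- hit & (jv - i - 1L >= min_loop)
    if (any(valid)) best <- max(best, cur[valid])
    prev <- cur
  }
  if (best >= 2L) best else 0L
}

# Longest common substring of two strings; returns length (and optionally
# end coordinates) via the standard dynamic program, vectorized per row.
.lcs_len <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m)
  best <- 0L
  for (i in seq_len(n)) {
    shifted <- c(0L, prev[-m])
    cur <- integer(m)
    hit <- x[i] == y
    cur[hit] <- shifted[hit] + 1L
    mi <- max(cur)
    if (mi > best) best <- mi
    prev <- cur
  }
  best
}

#' Cross-annealing score between two sequences
#'
#' Length of the longest contiguous perfect duplex formable between `a` and
#' `b` in any relative alignment: the longest common substring between `a`
#' and the reverse complement of `b`. Symmetric in its arguments. The
#' intended pairing of a sequence with its own reverse complement scores the
#' full sequence length.
#'
#' @param a,b `dna_sequence` objects or character scalars.
#' @return Integer duplex length in nt.
#' @export
cross_anneal_score <- function(a, b) {
  .lcs_len(.residues(a), .revcomp_chr(.residues(b)))
}

#' Self-dimer score
#'
#' Longest contiguous duplex between a sequence and a second copy of itself,
#' i.e. `cross_anneal_score(seq, seq)`.
#' @param seq A `dna_sequence` or character scalar.
#' @return Integer duplex length in nt.
#' @export
self_dimer <- function(seq) cross_anneal_score(seq, seq)

#' Design configuration for UNS generation
#'
#' Free parameters of the address-sequence designer. Defaults reflect
#' common overlap-design practice: GC 0.40-0.60, Tm 62-72 C, hairpin stems
#' capped at 5 nt, cross-annealing capped at 12 nt, homopolymers capped at
#' 4 nt, and the recognition sites of the framework's enzymes (I-SceI, XbaI,
#' XhoI, FseI, PacI) forbidden on either strand.
#'
#' @param gc_min,gc_max GC-fraction bounds.
#' @param tm_min,tm_max Duplex Tm bounds in degrees Celsius.
#' @param threshold_hairpin Maximum allowed hairpin stem (nt).
#' @param threshold_cross Maximum allowed cross-annealing score between
#'   distinct set members (nt).
#' @param homopolymer_max Maximum run of a single base (nt).
#' @param forbidden_motifs Character vector of motifs that must not occur on
#'   either strand of a designed sequence.
#' @param rng_seed Integer seed; candidate generation is deterministic in it.
#' @param n_candidates Number of candidates to generate.
#' @param uns_length Address length in bp (40 throughout the framework).
#' @return An object of class `design_config`.
#' @export
design_config <- function(gc_min = 0.40, gc_max = 0.60,
                          tm_min = 62, tm_max = 72,
                          threshold_hairpin = 5L, threshold_cross = 12L,
                          homopolymer_max = 4L,
                          forbidden_motifs = NULL,
                          rng_seed = 1L, n_candidates = 5000L,
                          uns_length = 40L) {
  if (is.null(forbidden_motifs)) {
    tab <- enzyme_table()
    forbidden_motifs <- tab$site[tab$name %in%
                                   c("I-SceI", "XbaI", "XhoI", "FseI", "PacI")]
  }
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 1,
            threshold_hairpin < uns_length, threshold_cross < uns_length,
            homopolymer_max >= 1, n_candidates >= 1, uns_length >= 8)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max,
                 threshold_hairpin = as.integer(threshold_hairpin),
                 threshold_cross = as.integer(threshold_cross),
                 homopolymer_max = as.integer(homopolymer_max),
                 forbidden_motifs = toupper(forbidden_motifs),
                 rng_seed = as.integer(rng_seed),
                 n_candidates = as.integer(n_candidates),
                 uns_length = as.integer(uns_length)),
            class = "design_config")
}

.has_forbidden_motif <- function(s, motifs) {
  for (m in motifs) {
    if (grepl(m, s, fixed = TRUE) || grepl(.revcomp_chr(m), s, fixed = TRUE))
      return(m)
  }
  NULL
}

.homopolymer_run <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

# Run thunk with a private RNG stream; global .Random.seed is untouched.
.with_seed <- function(seed, thunk) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  thunk()
}

#' Generate filtered UNS candidates
#'
#' Rejection sampling of uniform random sequences of the configured length.
#' A candidate is kept only if it passes, in order: GC bounds, homopolymer
#' cap, forbidden-motif scan on both strands, hairpin-stem cap, self-dimer
#' cap, and Tm bounds. Deterministic given `config$rng_seed`. If the
#' attempt budget is exhausted first, the error reports the acceptance rate
#' and the filter that rejected most candidates.
#'
#' @param config A [design_config()].
#' @param max_attempts Attempt budget (default `200 * n_candidates`).
#' @return List of `uns_candidate` objects with fields `sequence`,
#'   `gc_fraction`, `tm_celsius`, `hairpin_stem`, `self_dimer`.
#' @export
generate_candidates <- function(config, max_attempts = 200L * config$n_candidates) {
  stopifnot(inherits(config, "design_config"))
  .with_seed(config$rng_seed, function() {
    out <- vector("list", config$n_candidates)
    got <- 0L
    attempts <- 0L
    fails <- c(gc = 0L, homopolymer = 0L, forbidden_motif = 0L,
               hairpin = 0L, self_dimer = 0L, tm = 0L)
    while (got < config$n_candidates && attempts < max_attempts) {
      attempts <- attempts + 1L
      s <- paste(sample(c("A", "C", "G", "T"), config$uns_length,
                        replace = TRUE), collapse = "")
      gc <- gc_fraction(s)
      if (gc < config$gc_min || gc > config$gc_max) {
        fails["gc"] <- fails["gc"] + 1L; next
      }
      if (.homopolymer_run(s) > config$homopolymer_max) {
        fails["homopolymer"] <- fails["homopolymer"] + 1L; next
      }
      if (!is.null(.has_forbidden_motif(s, config$forbidden_motifs))) {
        fails["forbidden_motif"] <- fails["forbidden_motif"] + 1L; next
      }
      hp <- hairpin_stem(s)
      if (hp > config$threshold_hairpin) {
        fails["hairpin"] <- fails["hairpin"] + 1L; next
      }
      sd <- self_dimer(s)
      if (sd > config$threshold_cross) {
        fails["self_dimer"] <- fails["self_dimer"] + 1L; next
      }
      tm <- melting_temperature(s)
      if (tm < config$tm_min || tm > config$tm_max) {
        fails["tm"] <- fails["tm"] + 1L; next
      }
      got <- got + 1L
      out[[got]] <- structure(list(sequence = s, gc_fraction = gc,
                                   tm_celsius = tm, hairpin_stem = hp,
                                   self_dimer = sd),
                              class = "uns_candidate")
    }
    if (got < config$n_candidates) {
      worst <- names(fails)[which.max(fails)]
      stop(sprintf(paste0("candidate generation exhausted its budget: ",
                          "%d/%d accepted in %d attempts (rate %.4f); ",
                          "tightest filter: %s (%d rejections)"),
                   got, config$n_candidates, attempts, got / attempts,
                   worst, fails[worst]))
    }
    out
  })
}

.uns_pair_score <- function(u, v) {
  # worst duplex between u and either strand of v
  max(cross_anneal_score(u, v), .lcs_len(u, v))
}

#' Greedy selection of an orthogonal UNS set
#'
#' Seeds the set with the candidate of lowest self-dimer score and then
#' repeatedly adds the candidate minimizing its worst cross-annealing score
#' against all chosen members and their reverse complements, rejecting
#' candidates whose worst score exceeds `threshold_cross`. Ties are broken
#' by the lexicographically smallest sequence, making selection
#' deterministic given the candidate order. The first `n` selected members
#' are named `UNS1`...`UNSn`; the final member is the linking address
#' `UNSX`, giving `n + 1` members in total.
#'
#' @param candidates List of `uns_candidate` (from [generate_candidates()]).
#' @param n Number of numbered members requested (>= 2); one extra member,
#'   `UNSX`, is always added.
#' @param config The [design_config()] whose `threshold_cross` binds.
#' @return An object of class `uns_set`.
#' @export
select_orthogonal_set <- function(candidates, n, config) {
  stopifnot(n >= 2, length(candidates) >= 1)
  seqs <- vapply(candidates, function(c) c$sequence, character(1))
  sdim <- vapply(candidates, function(c) c$self_dimer, numeric(1))
  dup <- duplicated(seqs)
  seqs <- seqs[!dup]; sdim <- sdim[!dup]
  need <- n + 1L
  ord <- order(sdim, seqs)
  chosen <- seqs[ord[1L]]
  pool <- seqs[-ord[1L]]
  worst <- vapply(pool, function(u) .uns_pair_score(u, chosen[1L]), numeric(1))
  while (length(chosen) < need) {
    ok <- worst <= config$threshold_cross
    if (!any(ok)) {
      stop(sprintf(paste0("candidate pool exhausted: selected %d of %d ",
                          "members at cross-annealing threshold %d nt"),
                   length(chosen), need, config$threshold_cross))
    }
    cand <- which(ok)
    pick <- cand[order(worst[cand], pool[cand])][1L]
    new <- pool[pick]
    chosen <- c(chosen, new)
    pool <- pool[-pick]
    worst <- worst[-pick]
    if (length(pool)) {
      upd <- vapply(pool, function(u) .uns_pair_score(u, new), numeric(1))
      worst <- pmax(worst, upd)
    }
  }
  members <- stats::setNames(chosen, c(paste0("UNS", seq_len(n)), "UNSX"))
  uns_set(members, config)
}

#' Construct a UNS set
#'
#' @param members Named character vector of sequences; names must be
#'   `UNS1`...`UNSn` plus `UNSX`.
#' @param config The [design_config()] the set was designed under.
#' @return An object of class `uns_set` carrying the members and the full
#'   cross-annealing matrix over members and their reverse complements.
#' @export
uns_set <- function(members, config = design_config()) {
  stopifnot(is.character(members), !is.null(names(members)))
  if (!"UNSX" %in% names(members)) stop("a UNS set must contain member 'UNSX'")
  all_seqs <- c(members,
                stats::setNames(vapply(members, .revcomp_chr, character(1)),
                                paste0(names(members), "_rc")))
  m <- length(all_seqs)
  cm <- matrix(0L, m, m, dimnames = list(names(all_seqs), names(all_seqs)))
  for (i in seq_len(m)) for (j in i:m) {
    cm[i, j] <- cm[j, i] <- cross_anneal_score(all_seqs[i], all_seqs[j])
  }
  structure(list(members = members, cross_matrix = cm, thresholds = config),
            class = "uns_set")
}

#' @export
print.uns_set <- function(x, ...) {
  cat(sprintf("<uns_set> %d members (%s), %d bp each\n",
              length(x$members), paste(names(x$members), collapse = ", "),
              unique(nchar(x$members))[1]))
  invisible(x)
}

#' Look up a UNS member sequence
#' @param set An `uns_set`.
#' @param name Member name, e.g. `"UNS3"` or `"UNSX"`.
#' @return Character scalar sequence.
#' @export
uns_member <- function(set, name) {
  s <- set$members[name]
  if (any(is.na(s))) stop(sprintf("UNS set has no member '%s'",
                                  paste(name[is.na(s)], collapse = ",")))
  unname(s)
}

#' Number of numbered members in a UNS set
#' @param set An `uns_set`.
#' @return Integer count of `UNS<k>` members (excluding `UNSX`).
#' @export
uns_numbered <- function(set) sum(grepl("^UNS[0-9]+$", names(set$members)))

#' Validate a UNS set against its design criteria
#'
#' Recomputes every per-sequence criterion (length, GC, homopolymer,
#' forbidden motifs, hairpin, self-dimer, Tm) and every pairwise
#' cross-annealing score, reporting each check with its worst offender.
#'
#' @param set An `uns_set`.
#' @param config A [design_config()]; defaults to the set's own.
#' @return List with `pass` (logical) and `checks` (data.frame of
#'   `check`, `pass`, `detail`).
#' @export
validate_set <- function(set, config = set$thresholds) {
  mem <- set$members
  nm <- names(mem)
  checks <- list()
  add <- function(check, pass, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  lens <- nchar(mem)
  add("length", all(lens == config$uns_length),
      sprintf("lengths %s", paste(unique(lens), collapse = ",")))
  add("distinct", !anyDuplicated(mem),
      if (anyDuplicated(mem)) sprintf("duplicate sequence at %s",
                                      nm[duplicated(mem)][1]) else "all distinct")
  add("contains_UNSX", "UNSX" %in% nm, "")
  gcs <- vapply(mem, gc_fraction, numeric(1))
  add("gc", all(gcs >= config$gc_min & gcs <= config$gc_max),
      sprintf("worst %s gc=%.2f", nm[which.max(abs(gcs - 0.5))],
              gcs[which.max(abs(gcs - 0.5))]))
  hp <- vapply(mem, hairpin_stem, integer(1))
  add("hairpin", all(hp <= config$threshold_hairpin),
      sprintf("worst %s stem=%d", nm[which.max(hp)], max(hp)))
  runs <- vapply(mem, .homopolymer_run, integer(1))
  add("homopolymer", all(runs <= config$homopolymer_max),
      sprintf("worst run %d", max(runs)))
  motif_hits <- vapply(mem, function(s) {
    h <- .has_forbidden_motif(s, config$forbidden_motifs)
    if (is.null(h)) "" else h
  }, character(1))
  add("forbidden_motifs", all(motif_hits == ""),
      if (any(motif_hits != "")) sprintf("%s contains %s",
                                         nm[motif_hits != ""][1],
                                         motif_hits[motif_hits != ""][1]) else "clean")
  tms <- vapply(mem, melting_temperature, numeric(1))
  add("tm", all(tms >= config$tm_min & tms <= config$tm_max),
      sprintf("range %.1f-%.1f C", min(tms), max(tms)))
  worst_pair <- c(NA_character_, NA_character_); worst_score <- -1L
  if (length(mem) > 1L) {
    for (i in seq_along(mem)) for (j in seq_along(mem)) {
      if (i >= j) next
      sc <- .uns_pair_score(mem[i], mem[j])
      if (sc > worst_score) { worst_score <- sc; worst_pair <- nm[c(i, j)] }
    }
  }
  add("cross_annealing", worst_score <= config$threshold_cross,
      sprintf("worst pair %s-%s: %d nt", worst_pair[1], worst_pair[2],
              worst_score))
  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}

#' Design an orthogonal UNS set in one call
#'
#' Convenience wrapper: [generate_candidates()] then
#' [select_orthogonal_set()].
#'
#' @param n Number of numbered members (`UNSX` is added on top).
#' @param config A [design_config()].
#' @return An `uns_set`.
#' @export
design_uns_set <- function(n, config = design_config()) {
  select_orthogonal_set(generate_candidates(config), n, config)
}
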