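# Independent oracles and shared fixtures for the test suite.

.IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "[AG]", Y = "[CT]", S = "[GC]", W = "[AT]",
                  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                  H = "[ACT]", V = "[ACG]", N = "[ACGT]")

rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                            toupper(s)), "")[[1]]), collapse = "")
}

# brute-force IUPAC site scanner via regex character classes + lookahead
bf_find_sites <- function(s, site, circular = FALSE) {
  L <- nchar(s)
  w <- nchar(site)
  subject <- if (circular && L >= w) paste0(s, substr(s, 1, w - 1)) else s
  to_rx <- function(p) paste(.IUPAC_CLASS[strsplit(p, "")[[1]]], collapse = "")
  scan <- function(p) {
    m <- gregexpr(sprintf("(?=%s)", to_rx(p)), subject, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m) - 1L
  }
  plus <- scan(site)
  rc <- rc_chr(site)
  minus <- if (identical(rc, site)) integer() else scan(rc)
  pos <- c(plus, minus)
  strand <- c(rep("+", length(plus)), rep("-", length(minus)))
  keep <- pos < L
  out <- unique(data.frame(position = pos[keep], strand = strand[keep],
                           stringsAsFactors = FALSE))
  out[order(out$position, out$strand), , drop = FALSE]
}

# longest common substring by exhaustive extension from every start pair
bf_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- 0L
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      k <- 0L
      while (i + k <= length(x) && j + k <= length(y) &&
             x[i + k] == y[j + k]) k <- k + 1L
      if (k > best) best <- k
    }
  }
  best
}

# exhaustive stem/loop enumeration, O(L^3)
bf_hairpin <- function(s, min_loop = 3L) {
  x <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(x)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      k <- 0L
      while (i + k < j - k &&
             comp[[x[i + k]]] == x[j - k]) {
        k <- k + 1L
        loop <- (j - k + 1L) - (i + k - 1L) - 1L
        if (loop >= min_loop && k > best) best <- k
      }
    }
  }
  if (best >= 2L) best else 0L
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# small synthetic UNS-style address set from random 40-mers (no design
# filters; spurious >= 20 nt homology between random 40-mers is vanishingly
# rare)
toy_uns_set <- function(n, seed = 1) {
  withr::with_seed(seed, {
    mem <- vapply(seq_len(n + 1L), function(i) rand_dna(40L), character(1))
  })
  names(mem) <- c(paste0("UNS", seq_len(n)), "UNSX")
  uns_set(mem, design_config())
}

# closed ring of m fragments: fragment i = addr_i + body_i + addr_{i+1}
toy_ring_fragments <- function(addrs, body_len = 120L, seed = 2) {
  m <- length(addrs)
  withr::with_seed(seed, {
    lapply(seq_len(m), function(i) {
      nxt <- if (i == m) 1L else i + 1L
      dna_sequence(paste0(addrs[i], rand_dna(body_len), addrs[nxt]),
                   "linear", name = sprintf("ring%d", i))
    })
  })
}

# exhaustive one-pot oracle: every arrangement (fragment 1 fixed, forward)
# and orientation pattern; junctions via terminal_homology; independent
# splice; products deduplicated by canonical circular form
bf_one_pot_products <- function(fragments, params = gibson_params()) {
  m <- length(fragments)
  seqs <- vapply(fragments, function(f) {
    if (inherits(f, "dna_sequence")) f$residues else toupper(f)
  }, character(1))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  splice <- function(ord_seqs, juncs) {
    pieces <- character(length(ord_seqs))
    for (t in seq_along(ord_seqs)) {
      jin <- juncs[[t]]
      jout <- juncs[[if (t == length(ord_seqs)) 1L else t + 1L]]
      s <- ord_seqs[t]
      pieces[t] <- substr(s, jin$flap_b + jin$overlap + 1L,
                          nchar(s) - jout$flap_a)
    }
    paste(pieces, collapse = "")
  }
  found <- character()
  for (ord in perms(seq.int(2L, m))) {
    order_all <- c(1L, ord)
    n_or <- m - 1L
    for (mask in 0:(2^n_or - 1L)) {
      ors <- c("+", ifelse(bitwAnd(mask, 2^(seq_len(n_or) - 1L)) > 0L,
                           "-", "+"))
      oseqs <- vapply(seq_len(m), function(t) {
        s <- seqs[order_all[t]]
        if (ors[t] == "-") rc_chr(s) else s
      }, character(1))
      juncs <- vector("list", m)   # junction entering fragment t
      ok <- TRUE
      for (t in seq_len(m)) {
        prev <- if (t == 1L) m else t - 1L
        j <- unskit:::.junction_fixed(oseqs[prev], oseqs[t], params)
        if (is.null(j)) { ok <- FALSE; break }
        juncs[[t]] <- j
      }
      if (ok) found <- c(found, canonical_circular(splice(oseqs, juncs)))
    }
  }
  sort(unique(found))
}

# memoized fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(n, repeat_fraction = 0, seed = n) {
  key <- sprintf("fx_%d_%s_%d", n, repeat_fraction, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture_library(seed, n,
                                                  repeat_fraction = repeat_fraction)
  }
  .fixture_cache[[key]]
}

cached_plan <- function(n, repeat_fraction = 0, seed = n) {
  key <- sprintf("plan_%d_%s_%d", n, repeat_fraction, seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(n, repeat_fraction, seed)
    .fixture_cache[[key]] <- plan_assembly(fx$design, fx$uns_set, fx$registry)
  }
  .fixture_cache[[key]]
}
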