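#' DNA sequence object
#'
#' Container for a concrete (non-degenerate) DNA sequence together with its
#' topology and optional feature annotations. Residues are normalized to
#' uppercase A/C/G/T; any other character is rejected with its position.
#' All coordinates in this package are 0-based, half-open, on the top strand.
#'
#' @param residues Character scalar over A/C/G/T (case-insensitive).
#' @param topology Either `"linear"` or `"circular"`.
#' @param name Identifier for the sequence.
#' @param features Optional data.frame with columns `label`, `start`, `end`,
#'   `strand` (0-based half-open, strand `"+"`/`"-"`).
#' @return An object of class `dna_sequence`.
#' @export
dna_sequence <- function(residues, topology = c("linear", "circular"),
                         name = "seq", features = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- regexpr("[^ACGT]", residues)
  if (bad > 0L) {
    stop(sprintf("non-ACGT character '%s' at position %d in '%s'",
                 substr(residues, bad, bad), as.integer(bad) - 1L, name))
  }
  if (is.null(features)) {
    features <- data.frame(label = character(), start = integer(),
                           end = integer(), strand = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(residues = residues, topology = topology, name = name,
                 features = features),
            class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat(sprintf("<dna_sequence> %s: %d bp, %s, %d feature(s)\n",
              x$name, nchar(x$residues), x$topology, nrow(x$features)))
  invisible(x)
}

#' @export
length.dna_sequence <- function(x) nchar(x$residues)

#' Coerce to a dna_sequence
#'
#' Accepts a `dna_sequence` (returned as is) or a character scalar.
#' @param x Input sequence.
#' @param ... Passed to [dna_sequence()] for character input.
#' @return A `dna_sequence`.
#' @export
as_dna <- function(x, ...) {
  if (inherits(x, "dna_sequence")) return(x)
  dna_sequence(x, ...)
}

.residues <- function(x) if (inherits(x, "dna_sequence")) x$residues else toupper(x)

#' Reverse complement
#'
#' Watson-Crick reverse complement. An involution: applying it twice returns
#' the input. Feature annotations are remapped to the opposite strand.
#'
#' @param seq A `dna_sequence` or character scalar.
#' @return Same type as the input.
#' @export
reverse_complement <- function(seq) {
  if (is.character(seq)) {
    return(.revcomp_chr(seq))
  }
  L <- nchar(seq$residues)
  feats <- seq$features
  if (nrow(feats)) {
    feats <- data.frame(label = feats$label,
                        start = L - feats$end,
                        end = L - feats$start,
                        strand = ifelse(feats$strand == "+", "-", "+"),
                        stringsAsFactors = FALSE)
  }
  dna_sequence(.revcomp_chr(seq$residues), seq$topology, seq$name, feats)
}

.revcomp_chr <- function(s) {
  s <- toupper(s)
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", s)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 substr(s, bad, bad), as.integer(bad) - 1L))
  }
  intToUtf8(rev(utf8ToInt(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s))))
}

#' Rotate a circular sequence
#'
#' Moves the origin of a circular sequence by `offset` residues. Site
#' searches and digestion are rotation-invariant, so rotation changes only
#' the coordinate frame.
#'
#' @param seq A circular `dna_sequence`.
#' @param offset Integer rotation (new index 0 = old index `offset`).
#' @return Rotated `dna_sequence` (features dropped).
#' @export
rotate <- function(seq, offset) {
  seq <- as_dna(seq, topology = "circular")
  if (seq$topology != "circular") stop("rotate() requires a circular sequence")
  L <- nchar(seq$residues)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0L) return(dna_sequence(seq$residues, "circular", seq$name))
  r <- paste0(substr(seq$residues, offset + 1L, L),
              substr(seq$residues, 1L, offset))
  dna_sequence(r, "circular", seq$name)
}

# Booth's algorithm: index (0-based) of the lexicographically least rotation.
.least_rotation_index <- function(s) {
  S <- utf8ToInt(paste0(s, s))
  n <- length(S)
  f <- rep.int(-1L, n)
  k <- 0L
  for (j in 1L:(n - 1L)) {         # j is 0-based index into S[ ]
    sj <- S[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != S[k + i + 2L]) {
      if (sj < S[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != S[k + i + 2L]) {     # i == -1 here
      if (sj < S[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k
}

#' Canonical form of a circular sequence
#'
#' Returns the lexicographically least rotation, taken over both strands,
#' as a plain string. Two circular molecules are identical as DNA exactly
#' when their canonical forms are byte-identical; the assembly simulator and
#' the planner both report predicted circles in this form.
#'
#' @param seq A `dna_sequence` (circular) or character scalar.
#' @return Character scalar: canonical top-strand representation.
#' @export
canonical_circular <- function(seq) {
  s <- .residues(seq)
  rc <- .revcomp_chr(s)
  canon <- function(x) {
    k <- .least_rotation_index(x)
    if (k == 0L) x else paste0(substr(x, k + 1L, nchar(x)), substr(x, 1L, k))
  }
  a <- canon(s); b <- canon(rc)
  if (a <= b) a else b
}

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param site Recognition site, IUPAC codes allowed, length >= 4.
#' @param cut_top Top-strand cut offset relative to site start.
#' @param cut_bottom Bottom-strand cut offset relative to site start.
#'   The overhang length is `cut_bottom - cut_top`: positive for a
#'   5' overhang, zero for blunt, negative for a 3' overhang.
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, cut_top, cut_bottom) {
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition site must be at least 4 bp")
  if (grepl("[^ACGTRYSWKMBDHVN]", site)) stop("site must use IUPAC DNA codes")
  structure(list(name = name, site = site,
                 cut_top = as.integer(cut_top),
                 cut_bottom = as.integer(cut_bottom)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (cut %d/%d, overhang %+d)\n",
              x$name, x$site, x$cut_top, x$cut_bottom,
              x$cut_bottom - x$cut_top))
  invisible(x)
}

.enzyme_cache <- new.env(parent = emptyenv())

#' Bundled restriction enzyme table
#'
#' Canonical REBASE recognition sites and cut offsets for the enzymes the
#' assembly framework uses (I-SceI with its 18-bp site, XbaI, XhoI, FseI,
#' PacI) plus common six- and eight-cutters useful in diagnostic panels.
#'
#' @return data.frame with columns `name`, `site`, `cut_top`, `cut_bottom`.
#' @export
enzyme_table <- function() {
  if (is.null(.enzyme_cache$tab)) {
    path <- system.file("extdata", "enzymes.csv", package = "unskit")
    .enzyme_cache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .enzyme_cache$tab
}

#' Look up a bundled enzyme by name
#'
#' @param name Enzyme name as in [enzyme_table()], e.g. `"I-SceI"`.
#' @return A `restriction_enzyme`.
#' @export
get_enzyme <- function(name) {
  tab <- enzyme_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop(sprintf("unknown enzyme '%s'; see enzyme_table()", name))
  restriction_enzyme(tab$name[i], tab$site[i], tab$cut_top[i], tab$cut_bottom[i])
}

# Match an IUPAC pattern against a concrete subject string; 0-based starts.
.match_starts <- function(pattern, subject) {
  if (nchar(pattern) > nchar(subject)) return(integer())
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = c(pattern = FALSE, subject = TRUE))
  BiocGenerics::start(m) - 1L
}

#' Find restriction sites
#'
#' Locates all occurrences of an enzyme's (possibly degenerate) recognition
#' site on both strands. Positions are 0-based starts of the site footprint
#' on the top strand. For circular sequences the search wraps across the
#' origin (the doubled-sequence scan keeps hits starting before the origin
#' repeat). Palindromic sites are reported once, on the plus strand.
#'
#' @param seq A `dna_sequence` or character scalar (assumed linear).
#' @param enzyme A `restriction_enzyme`.
#' @return data.frame with columns `position` (integer) and `strand`.
#' @export
find_sites <- function(seq, enzyme) {
  seq <- as_dna(seq)
  s <- seq$residues
  L <- nchar(s)
  w <- nchar(enzyme$site)
  subject <- if (seq$topology == "circular" && L >= w) {
    paste0(s, substr(s, 1L, w - 1L))
  } else s
  hits <- data.frame(position = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  if (L < w) return(hits)
  plus <- .match_starts(enzyme$site, subject)
  site_rc <- .revcomp_chr(enzyme$site)
  palindromic <- identical(site_rc, enzyme$site)
  minus <- if (palindromic) integer() else .match_starts(site_rc, subject)
  pos <- c(plus, minus)
  strand <- c(rep("+", length(plus)), rep("-", length(minus)))
  keep <- pos < L
  hits <- data.frame(position = pos[keep], strand = strand[keep],
                     stringsAsFactors = FALSE)
  hits <- unique(hits)
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

.fragment_end <- function(enzyme = NULL, overhang = 0L, overhang_seq = "") {
  if (is.null(enzyme)) list(enzyme = NA_character_, overhang = 0L,
                            overhang_seq = "", terminus = TRUE)
  else list(enzyme = enzyme, overhang = as.integer(overhang),
            overhang_seq = overhang_seq, terminus = FALSE)
}

#' Digest a sequence with one or more restriction enzymes
#'
#' Simulates a complete double digest. Fragments are delimited by the
#' top-strand cut coordinates, so fragment lengths always sum to the parent
#' length (overhang bases are counted once, on the fragment whose top strand
#' carries them). A circular substrate with k cut positions yields k
#' fragments; a linear one yields k + 1. An uncut circular substrate is
#' returned intact with `uncut = TRUE`.
#'
#' @param seq A `dna_sequence` or character scalar.
#' @param enzymes A `restriction_enzyme` or list of them.
#' @return List of `dna_fragment` objects, ordered by position. Each carries
#'   `sequence`, `left_end`, `right_end` (producing enzyme and overhang) and
#'   `source` (parent name plus 0-based start/end).
#' @export
digest <- function(seq, enzymes) {
  seq <- as_dna(seq)
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  if (!length(enzymes)) stop("at least one enzyme required")
  s <- seq$residues
  L <- nchar(s)
  if (L == 0L) stop("empty sequence")

  cuts <- data.frame(tc = integer(), enzyme = character(),
                     overhang = integer(), stringsAsFactors = FALSE)
  for (enz in enzymes) {
    sites <- find_sites(seq, enz)
    if (!nrow(sites)) next
    w <- nchar(enz$site)
    tc <- ifelse(sites$strand == "+",
                 sites$position + enz$cut_top,
                 sites$position + w - enz$cut_bottom)
    bc <- ifelse(sites$strand == "+",
                 sites$position + enz$cut_bottom,
                 sites$position + w - enz$cut_top)
    if (seq$topology == "circular") {
      tc <- ((tc %% L) + L) %% L
    } else {
      keep <- tc >= 0L & tc <= L & bc >= 0L & bc <= L
      tc <- tc[keep]
    }
    if (length(tc)) {
      cuts <- rbind(cuts, data.frame(tc = as.integer(tc), enzyme = enz$name,
                                     overhang = enz$cut_bottom - enz$cut_top,
                                     stringsAsFactors = FALSE))
    }
  }
  cuts <- unique(cuts)
  cuts <- cuts[order(cuts$tc), , drop = FALSE]

  if (!nrow(cuts)) {
    frag <- structure(list(sequence = seq,
                           left_end = .fragment_end(), right_end = .fragment_end(),
                           source = list(parent = seq$name, start = 0L, end = L),
                           uncut = TRUE),
                      class = "dna_fragment")
    return(list(frag))
  }

  # adjacent cuts closer than an overhang would shear the overhang itself
  tcs <- cuts$tc
  gaps <- if (length(tcs) > 1L) diff(tcs) else integer()
  if (seq$topology == "circular" && length(tcs) > 1L) {
    gaps <- c(gaps, L - tcs[length(tcs)] + tcs[1L])
  }
  maxov <- max(abs(cuts$overhang))
  if (length(gaps) && any(gaps < maxov)) stop("overlapping cuts")

  sub_circ <- function(from, to) { # 0-based half-open with wrap
    if (from < to) substr(s, from + 1L, to)
    else paste0(substr(s, from + 1L, L), substr(s, 1L, to))
  }
  end_of <- function(i) {
    ov <- cuts$overhang[i]
    tc <- cuts$tc[i]
    oseq <- if (ov == 0L) "" else {
      a <- min(tc, tc + ov); b <- max(tc, tc + ov)
      sub_circ(((a %% L) + L) %% L, if (b %% L == 0L) L else ((b %% L) + L) %% L)
    }
    .fragment_end(cuts$enzyme[i], ov, oseq)
  }

  frags <- list()
  k <- nrow(cuts)
  if (seq$topology == "circular") {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      from <- cuts$tc[i]; to <- cuts$tc[j]
      body <- if (k == 1L) {
        paste0(substr(s, from + 1L, L), substr(s, 1L, from))
      } else sub_circ(from, to)
      frags[[i]] <- structure(list(
        sequence = dna_sequence(body, "linear",
                                sprintf("%s_frag%d", seq$name, i)),
        left_end = end_of(i), right_end = end_of(j),
        source = list(parent = seq$name, start = from, end = to)),
        class = "dna_fragment")
    }
  } else {
    bounds <- c(0L, cuts$tc, L)
    for (i in seq_len(k + 1L)) {
      from <- bounds[i]; to <- bounds[i + 1L]
      left <- if (i == 1L) .fragment_end() else end_of(i - 1L)
      right <- if (i == k + 1L) .fragment_end() else end_of(i)
      frags[[i]] <- structure(list(
        sequence = dna_sequence(substr(s, from + 1L, to), "linear",
                                sprintf("%s_frag%d", seq$name, i)),
        left_end = left, right_end = right,
        source = list(parent = seq$name, start = from, end = to)),
        class = "dna_fragment")
    }
  }
  frags
}

#' @export
print.dna_fragment <- function(x, ...) {
  cat(sprintf("<dna_fragment> %s: %d bp [%s | %s]%s\n",
              x$sequence$name, nchar(x$sequence$residues),
              ifelse(is.na(x$left_end$enzyme), "end", x$left_end$enzyme),
              ifelse(is.na(x$right_end$enzyme), "end", x$right_end$enzyme),
              if (isTRUE(x$uncut)) " (uncut)" else ""))
  invisible(x)
}

#' Fragment lengths of a digest
#'
#' @param fragments List of `dna_fragment` as returned by [digest()].
#' @return Integer vector of fragment lengths.
#' @export
fragment_lengths <- function(fragments) {
  vapply(fragments, function(f) nchar(f$sequence$residues), integer(1))
}
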