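.PART_ROLES <- c("promoter", "gene", "polyA", "insulator", "selection_marker",
                 "replication_element", "backbone")

# advisory length bounds per role; violations warn, never error
.ROLE_BOUNDS <- list(promoter = c(100, 3000), gene = c(300, 10000),
                     polyA = c(50, 1000), insulator = c(100, 2000),
                     selection_marker = c(400, 2500),
                     replication_element = c(300, 4000),
                     backbone = c(800, 12000))

#' Basic genetic part
#'
#' A named linear sequence with a role. Gene parts must not contain the
#' I-SceI recognition site on either strand (hard error), since that site
#' is the excision signal of the addressing system; other role-typical
#' length bounds are advisory warnings only.
#'
#' @param name Part name.
#' @param role One of promoter, gene, polyA, insulator, selection_marker,
#'   replication_element, backbone.
#' @param sequence A `dna_sequence` (linear) or character scalar.
#' @return An object of class `part`.
#' @export
part <- function(name, role, sequence) {
  role <- match.arg(role, .PART_ROLES)
  seq <- as_dna(sequence, name = name)
  if (role == "gene") {
    hit <- find_sites(seq, get_enzyme("I-SceI"))
    if (nrow(hit)) {
      stop(sprintf("gene part '%s' contains the I-SceI site at position %d (%s strand)",
                   name, hit$position[1], hit$strand[1]))
    }
  }
  b <- .ROLE_BOUNDS[[role]]
  L <- nchar(seq$residues)
  if (L < b[1] || L > b[2]) {
    warning(sprintf("part '%s' (%s) length %d bp is outside the typical %d-%d bp range",
                    name, role, L, b[1], b[2]))
  }
  structure(list(name = name, role = role, sequence = seq), class = "part")
}

#' @export
print.part <- function(x, ...) {
  cat(sprintf("<part> %s (%s): %d bp\n", x$name, x$role,
              nchar(x$sequence$residues)))
  invisible(x)
}

#' Random DNA free of the framework's restriction sites
#'
#' Uniform random sequence with any occurrence of the given motifs (on
#' either strand) destroyed by point substitution, so fixture parts never
#' carry accidental I-SceI/XbaI/XhoI/FseI/PacI sites. Uses the current RNG
#' stream.
#'
#' @param n Length in bp.
#' @param forbidden Character vector of motifs to scrub (default: the five
#'   framework enzymes' sites).
#' @return Character scalar.
#' @export
random_dna <- function(n, forbidden = NULL) {
  if (is.null(forbidden)) {
    tab <- enzyme_table()
    forbidden <- tab$site[tab$name %in% c("I-SceI", "XbaI", "XhoI", "FseI", "PacI")]
  }
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  pats <- unique(c(forbidden, vapply(forbidden, .revcomp_chr, character(1))))
  repeat {
    hit <- NULL
    for (p in pats) {
      i <- regexpr(p, s, fixed = TRUE)
      if (i > 0L) { hit <- c(i, nchar(p)); break }
    }
    if (is.null(hit)) break
    j <- hit[1] + sample.int(hit[2], 1L) - 1L
    old <- substr(s, j, j)
    substr(s, j, j) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  s
}

# default Gateway att recombination scars (placeholder spacer strings;
# configurable through `scars`); kept short and site-free
.DEFAULT_SCARS <- list(attB4 = "CAACTTTGTATAGAAAAGTTGC",
                       attB1 = "CAAGTTTGTACAAAAAAGCAGG",
                       attB2 = "ACCCAGCTTTCTTGTACAAAGT")

#' Destination layout for position-vector composition
#'
#' The constant anatomy a Gateway destination vector contributes to every
#' position vector: backbone, tandem insulator, polyadenylation signal and
#' the att recombination scar spacers.
#'
#' @param backbone,insulator,polyA `part` objects of matching role.
#' @param scars Named list of scar strings (`attB4`, `attB1`, `attB2`).
#' @return List of class `destination_layout`.
#' @export
destination_layout <- function(backbone, insulator, polyA,
                               scars = .DEFAULT_SCARS) {
  stopifnot(inherits(backbone, "part"), inherits(insulator, "part"),
            inherits(polyA, "part"))
  structure(list(backbone = backbone, insulator = insulator, polyA = polyA,
                 scars = scars), class = "destination_layout")
}

.ISCEI_SITE <- "TAGGGATAACAGGGTAAT"

#' Compose a position vector (sequence-level Gateway LR model)
#'
#' Builds the circular position vector housing one transcription unit at
#' the given circuit position: backbone, I-SceI site, `UNS_n`, tandem
#' insulator, att-scarred promoter and gene, polyA, `UNS_{n+1}`, I-SceI
#' site. Gateway recombination is modeled as deterministic cassette
#' substitution with configurable scar spacers. Every element is annotated.
#'
#' @param promoter,gene `part` objects.
#' @param layout A [destination_layout()].
#' @param uns_set An `uns_set` with members `UNS<position>` and
#'   `UNS<position+1>`.
#' @param position Integer circuit position (>= 1).
#' @param tu_name Optional transcription-unit name.
#' @return Object of class `position_vector` with fields `sequence`
#'   (annotated circular `dna_sequence`), `position`, `tu_name`, `uns_pair`.
#' @export
gateway_lr_compose <- function(promoter, gene, layout, uns_set, position,
                               tu_name = NULL) {
  stopifnot(inherits(promoter, "part"), inherits(gene, "part"),
            inherits(layout, "destination_layout"), position >= 1)
  for (p in list(promoter, gene)) {
    hit <- find_sites(p$sequence, get_enzyme("I-SceI"))
    if (nrow(hit)) {
      stop(sprintf("part '%s' contains the I-SceI site at position %d; it cannot enter a position vector",
                   p$name, hit$position[1]))
    }
  }
  un <- paste0("UNS", position)
  un1 <- paste0("UNS", position + 1L)
  uL <- uns_member(uns_set, un)
  uR <- uns_member(uns_set, un1)
  if (is.null(tu_name)) tu_name <- sprintf("TU%d_%s_%s", position,
                                           promoter$name, gene$name)
  pieces <- list(
    backbone = layout$backbone$sequence$residues,
    `I-SceI_5` = .ISCEI_SITE,
    uns_left = uL,
    insulator_1 = layout$insulator$sequence$residues,
    insulator_2 = layout$insulator$sequence$residues,
    attB4 = layout$scars$attB4,
    promoter = promoter$sequence$residues,
    attB1 = layout$scars$attB1,
    gene = gene$sequence$residues,
    attB2 = layout$scars$attB2,
    polyA = layout$polyA$sequence$residues,
    uns_right = uR,
    `I-SceI_3` = .ISCEI_SITE)
  labels <- c("backbone", "I-SceI", un, "insulator", "insulator",
              "attB4_scar", promoter$name, "attB1_scar", gene$name,
              "attB2_scar", "polyA", un1, "I-SceI")
  lens <- vapply(pieces, nchar, integer(1))
  ends <- cumsum(lens)
  feats <- data.frame(label = labels, start = ends - lens, end = ends,
                      strand = "+", stringsAsFactors = FALSE)
  seq <- dna_sequence(paste(unlist(pieces), collapse = ""), "circular",
                      name = sprintf("pPos%d_%s", position, tu_name),
                      features = feats)
  structure(list(sequence = seq, position = as.integer(position),
                 tu_name = tu_name, uns_pair = c(un, un1)),
            class = "position_vector")
}

#' @export
print.position_vector <- function(x, ...) {
  cat(sprintf("<position_vector> %s: position %d (%s-%s), %d bp\n",
              x$sequence$name, x$position, x$uns_pair[1], x$uns_pair[2],
              nchar(x$sequence$residues)))
  invisible(x)
}

#' Compose a carrier vector
#'
#' Circular vector contributing the propagation backbone plus the linking
#' addresses `UNSX` (5' of the backbone in the assembled circle) and `UNS1`
#' (3'), with exactly one site for its linearization enzyme (FseI or PacI)
#' between `UNS1` and `UNSX`. The `hierarchical` flavor additionally embeds
#' relay addresses for the next assembly round (`relay$uns1`, `relay$uns2`)
#' flanking the backbone together with intact I-SceI sites, so the whole
#' assembled circuit can later be excised as a position 1-2 part.
#'
#' @param uns_set An `uns_set` (provides `UNS1`, `UNSX`).
#' @param backbone A backbone `part` (replication + selection elements).
#' @param linearization_enzyme `"FseI"` or `"PacI"`.
#' @param flavor One of `"standard"`, `"linear_pJazz_like"`, `"BAC_like"`,
#'   `"hierarchical"` (metadata except for `"hierarchical"`).
#' @param relay For the hierarchical flavor: list with `uns1`, `uns2`
#'   character sequences from the NEXT round's UNS set.
#' @param name Vector name.
#' @return Object of class `carrier_vector`.
#' @export
make_carrier_vector <- function(uns_set, backbone,
                                linearization_enzyme = c("FseI", "PacI"),
                                flavor = "standard", relay = NULL,
                                name = "pCarrier") {
  linearization_enzyme <- match.arg(linearization_enzyme)
  stopifnot(inherits(backbone, "part"))
  if (identical(flavor, "hierarchical") &&
      (is.null(relay) || is.null(relay$uns1) || is.null(relay$uns2))) {
    stop("hierarchical carrier requires relay = list(uns1=, uns2=)")
  }
  site <- get_enzyme(linearization_enzyme)$site
  core <- if (identical(flavor, "hierarchical")) {
    list(relay_uns2 = relay$uns2, `I-SceI_a` = .ISCEI_SITE,
         backbone = backbone$sequence$residues,
         `I-SceI_b` = .ISCEI_SITE, relay_uns1 = relay$uns1)
  } else {
    list(backbone = backbone$sequence$residues)
  }
  pieces <- c(list(unsx = uns_member(uns_set, "UNSX")), core,
              list(uns1 = uns_member(uns_set, "UNS1"),
                   spacer_a = "ACTG", lin_site = site, spacer_b = "GTCA"))
  labels <- c("UNSX",
              if (identical(flavor, "hierarchical"))
                c("relay_UNS2", "I-SceI", "backbone", "I-SceI", "relay_UNS1")
              else "backbone",
              "UNS1", "spacer", linearization_enzyme, "spacer")
  lens <- vapply(pieces, nchar, integer(1))
  ends <- cumsum(lens)
  feats <- data.frame(label = labels, start = ends - lens, end = ends,
                      strand = "+", stringsAsFactors = FALSE)
  seq <- dna_sequence(paste(unlist(pieces), collapse = ""), "circular",
                      name = name, features = feats)
  structure(list(sequence = seq, flavor = flavor,
                 linearization_enzyme = linearization_enzyme,
                 relay = relay),
            class = "carrier_vector")
}

#' @export
print.carrier_vector <- function(x, ...) {
  cat(sprintf("<carrier_vector> %s (%s, cut by %s): %d bp\n",
              x$sequence$name, x$flavor, x$linearization_enzyme,
              nchar(x$sequence$residues)))
  invisible(x)
}

#' Compose an adaptor vector
#'
#' Circular vector with the excisable bridging cassette
#' `[UNS_k][selection marker][UNSX]` flanked by single XbaI and XhoI sites.
#' The cassette links the last transcription unit (right flank `UNS_k`,
#' k = n + 1 for an n-TU circuit) to the carrier's `UNSX` and contributes
#' the round's selection marker (Kan or Tet).
#'
#' @param uns_set An `uns_set` with members `UNS<k>` and `UNSX`.
#' @param k Numbered address index of the cassette's 5' flank.
#' @param marker `"Kan"` or `"Tet"`.
#' @param marker_part A selection_marker `part`.
#' @param backbone A backbone `part`.
#' @param name Vector name.
#' @return Object of class `adaptor_vector`.
#' @export
make_adaptor_vector <- function(uns_set, k, marker = c("Kan", "Tet"),
                                marker_part, backbone, name = NULL) {
  marker <- match.arg(marker)
  stopifnot(inherits(marker_part, "part"), inherits(backbone, "part"))
  uk <- paste0("UNS", k)
  if (is.null(name)) name <- sprintf("pAdaptor_%s_X_%s", uk, marker)
  pieces <- list(backbone = backbone$sequence$residues,
                 xba = get_enzyme("XbaI")$site,
                 uns_k = uns_member(uns_set, uk),
                 marker = marker_part$sequence$residues,
                 unsx = uns_member(uns_set, "UNSX"),
                 xho = get_enzyme("XhoI")$site)
  labels <- c("backbone", "XbaI", uk, paste0(marker, "R"), "UNSX", "XhoI")
  lens <- vapply(pieces, nchar, integer(1))
  ends <- cumsum(lens)
  feats <- data.frame(label = labels, start = ends - lens, end = ends,
                      strand = "+", stringsAsFactors = FALSE)
  seq <- dna_sequence(paste(unlist(pieces), collapse = ""), "circular",
                      name = name, features = feats)
  structure(list(sequence = seq, marker = marker,
                 uns_pair = c(uk, "UNSX"), k = as.integer(k)),
            class = "adaptor_vector")
}

#' @export
print.adaptor_vector <- function(x, ...) {
  cat(sprintf("<adaptor_vector> %s: %s-UNSX, marker %s, %d bp\n",
              x$sequence$name, x$uns_pair[1], x$marker,
              nchar(x$sequence$residues)))
  invisible(x)
}

.count_fixed <- function(s, motif) {
  n <- 0L; from <- 1L
  repeat {
    i <- regexpr(motif, substr(s, from, nchar(s)), fixed = TRUE)
    if (i < 0L) break
    n <- n + 1L
    from <- from + i
  }
  n
}

.uns_census <- function(s, uset) {
  vapply(uset$members, function(u) {
    .count_fixed(s, u) + .count_fixed(s, .revcomp_chr(u))
  }, integer(1))
}

#' Validate a vector's layout invariants
#'
#' Re-derives each vector type's structural invariants by direct sequence
#' scanning: restriction-site censuses, address placement and order.
#'
#' @param v A `position_vector`, `carrier_vector` or `adaptor_vector`.
#' @param uns_set The `uns_set` the vector was built against.
#' @return List with `pass` and a `checks` data.frame.
#' @export
validate_layout <- function(v, uns_set) UseMethod("validate_layout")

.layout_report <- function(checks) {
  df <- do.call(rbind, checks)
  list(pass = all(df$pass), checks = df)
}

.chk <- function(check, pass, detail = "") {
  data.frame(check = check, pass = pass, detail = detail,
             stringsAsFactors = FALSE)
}

#' @export
validate_layout.position_vector <- function(v, uns_set) {
  s <- v$sequence$residues
  isce <- get_enzyme("I-SceI")
  sites <- find_sites(v$sequence, isce)
  checks <- list(.chk("I-SceI site count == 2", nrow(sites) == 2L,
                      sprintf("found %d", nrow(sites))))
  uL <- uns_member(uns_set, v$uns_pair[1])
  uR <- uns_member(uns_set, v$uns_pair[2])
  frs <- digest(v$sequence, isce)
  insert <- NULL
  if (nrow(sites) == 2L) {
    for (f in frs) {
      fs <- f$sequence$residues
      if (.count_fixed(fs, uL) == 1L && .count_fixed(fs, uR) == 1L) insert <- fs
    }
  }
  checks[[length(checks) + 1L]] <-
    .chk("insert carries both flank UNSs", !is.null(insert))
  if (!is.null(insert)) {
    Li <- nchar(insert)
    rem <- nchar(isce$site) - isce$cut_top   # top-strand remnant before UNS
    checks[[length(checks) + 1L]] <-
      .chk("UNS order", substr(insert, rem + 1L, rem + 40L) == uL &&
             substr(insert, Li - isce$cut_top - 39L, Li - isce$cut_top) == uR,
           "insert must read UNS_n ... UNS_{n+1}")
    ins <- v$sequence$features$label == "insulator"
    checks[[length(checks) + 1L]] <-
      .chk("tandem insulator", sum(ins) == 2L,
           sprintf("%d insulator features", sum(ins)))
  }
  census <- .uns_census(s, uns_set)
  expected <- stats::setNames(rep(0L, length(uns_set$members)),
                              names(uns_set$members))
  expected[v$uns_pair] <- 1L
  checks[[length(checks) + 1L]] <-
    .chk("UNS census", all(census == expected),
         paste(names(census)[census != expected], collapse = ","))
  .layout_report(checks)
}

#' @export
validate_layout.carrier_vector <- function(v, uns_set) {
  s <- v$sequence$residues
  lin <- get_enzyme(v$linearization_enzyme)
  sites <- find_sites(v$sequence, lin)
  checks <- list(.chk(sprintf("%s site count == 1", lin$name),
                      nrow(sites) == 1L, sprintf("found %d", nrow(sites))))
  c1 <- .count_fixed(s, uns_member(uns_set, "UNS1")) +
    .count_fixed(s, .revcomp_chr(uns_member(uns_set, "UNS1")))
  cx <- .count_fixed(s, uns_member(uns_set, "UNSX")) +
    .count_fixed(s, .revcomp_chr(uns_member(uns_set, "UNSX")))
  checks[[length(checks) + 1L]] <-
    .chk("carrier UNS census", c1 == 1L && cx == 1L,
         sprintf("UNS1 x%d, UNSX x%d", c1, cx))
  if (nrow(sites) == 1L) {
    lin_frag <- digest(v$sequence, lin)[[1]]$sequence$residues
    px <- regexpr(uns_member(uns_set, "UNSX"), lin_frag, fixed = TRUE)
    p1 <- regexpr(uns_member(uns_set, "UNS1"), lin_frag, fixed = TRUE)
    checks[[length(checks) + 1L]] <-
      .chk("UNSX precedes UNS1 on linearized carrier",
           px > 0L && p1 > 0L && px < p1)
  }
  .layout_report(checks)
}

#' @export
validate_layout.adaptor_vector <- function(v, uns_set) {
  s <- v$sequence$residues
  xba <- find_sites(v$sequence, get_enzyme("XbaI"))
  xho <- find_sites(v$sequence, get_enzyme("XhoI"))
  checks <- list(
    .chk("XbaI site count == 1", nrow(xba) == 1L, sprintf("found %d", nrow(xba))),
    .chk("XhoI site count == 1", nrow(xho) == 1L, sprintf("found %d", nrow(xho))))
  uk <- uns_member(uns_set, v$uns_pair[1])
  ux <- uns_member(uns_set, "UNSX")
  frs <- digest(v$sequence, list(get_enzyme("XbaI"), get_enzyme("XhoI")))
  cassette <- NULL
  for (f in frs) {
    fs <- f$sequence$residues
    if (.count_fixed(fs, uk) == 1L && .count_fixed(fs, ux) == 1L) cassette <- fs
  }
  checks[[length(checks) + 1L]] <-
    .chk("cassette carries UNS_k then UNSX",
         !is.null(cassette) &&
           regexpr(uk, cassette, fixed = TRUE) <
           regexpr(ux, cassette, fixed = TRUE))
  census <- .uns_census(s, uns_set)
  expected <- stats::setNames(rep(0L, length(uns_set$members)),
                              names(uns_set$members))
  expected[v$uns_pair] <- 1L
  checks[[length(checks) + 1L]] <-
    .chk("UNS census", all(census == expected),
         paste(names(census)[census != expected], collapse = ","))
  .layout_report(checks)
}

#' Generate a complete synthetic part library and vector set
#'
#' Deterministic fixture generator emulating a realistic assembly campaign:
#' promoters of 0.2-1.5 kb, genes of 0.7-3 kb, a 250-bp insulator stand-in,
#' a 220-bp polyA, 0.9-kb selection markers and 2-3 kb backbones, all free
#' of the framework's restriction sites; a freshly designed orthogonal UNS
#' set sized for the circuit; one carrier; Kan and Tet adaptors for every
#' possible closing position; and one position vector per transcription
#' unit. A `repeat_fraction` > 0 rebuilds that fraction of the later TUs
#' from the first TU's promoter and gene, emulating circuits with repeated
#' parts.
#'
#' @param rng_seed Integer seed; all randomness (parts and UNS design) is
#'   deterministic in it.
#' @param n_tus Number of transcription units (>= 1).
#' @param part_size_ranges Named list of c(min,max) bp for `promoter` and
#'   `gene`.
#' @param repeat_fraction Fraction in `[0,1]` of TUs after the first that
#'   reuse TU1's promoter and gene.
#' @param positions Circuit positions to build vectors for (default
#'   `1:n_tus`); the UNS set is sized to `max(positions) + 1` numbered
#'   members.
#' @param uns_set Optional pre-designed `uns_set` to build against.
#' @param carrier_flavor Passed to [make_carrier_vector()].
#' @param carrier_relay Relay addresses for a hierarchical carrier.
#' @return List with `parts`, `uns_set`, `layout`, `position_vectors`,
#'   `carrier`, `adaptors`, `design` (a [circuit_design()]), and `registry`.
#' @export
make_fixture_library <- function(rng_seed, n_tus,
                                 part_size_ranges = list(
                                   promoter = c(200, 1500),
                                   gene = c(700, 3000)),
                                 repeat_fraction = 0,
                                 positions = seq_len(n_tus),
                                 uns_set = NULL,
                                 carrier_flavor = "standard",
                                 carrier_relay = NULL) {
  stopifnot(n_tus >= 1, length(positions) == n_tus)
  n_top <- max(positions) + 1L
  if (is.null(uns_set)) {
    cfg <- design_config(rng_seed = rng_seed,
                         n_candidates = 4L * (n_top + 1L) + 24L)
    uns_set <- design_uns_set(n_top, cfg)
  } else if (uns_numbered(uns_set) < n_top) {
    stop(sprintf("supplied UNS set has %d numbered members; need %d",
                 uns_numbered(uns_set), n_top))
  }
  .with_seed(rng_seed + 104729L, function() {
    rint <- function(r) sample(seq.int(r[1], r[2]), 1L)
    insulator <- part("cIns_core", "insulator", random_dna(250L))
    polyA <- part("pA_syn", "polyA", random_dna(220L))
    dest_backbone <- part("pDest_backbone", "backbone", random_dna(2400L))
    layout <- destination_layout(dest_backbone, insulator, polyA)

    proms <- list(); genes <- list()
    n_rep <- if (n_tus > 1L) min(n_tus - 1L, floor(repeat_fraction * n_tus)) else 0L
    reuse <- if (n_rep > 0L) seq.int(n_tus - n_rep + 1L, n_tus) else integer()
    for (i in seq_len(n_tus)) {
      if (i %in% reuse) {
        proms[[i]] <- proms[[1L]]
        genes[[i]] <- genes[[1L]]
      } else {
        proms[[i]] <- part(sprintf("P%d", i), "promoter",
                           random_dna(rint(part_size_ranges$promoter)))
        genes[[i]] <- part(sprintf("G%d", i), "gene",
                           random_dna(rint(part_size_ranges$gene)))
      }
    }
    pos_vecs <- list()
    for (i in seq_len(n_tus)) {
      pv <- gateway_lr_compose(proms[[i]], genes[[i]], layout, uns_set,
                               positions[i])
      pos_vecs[[pv$sequence$name]] <- pv
    }
    carrier_backbone <- part("pCarrier_backbone", "backbone", random_dna(2600L))
    carrier <- make_carrier_vector(uns_set, carrier_backbone,
                                   flavor = carrier_flavor,
                                   relay = carrier_relay)
    kan <- part("KanR", "selection_marker", random_dna(950L))
    tet <- part("TetR", "selection_marker", random_dna(1200L))
    adaptor_backbone <- part("pAdaptor_backbone", "backbone", random_dna(2100L))
    adaptors <- list()
    for (k in seq.int(2L, n_top)) {
      for (m in c("Kan", "Tet")) {
        mk <- if (m == "Kan") kan else tet
        ad <- make_adaptor_vector(uns_set, k, m, mk, adaptor_backbone)
        adaptors[[ad$sequence$name]] <- ad
      }
    }
    parts <- c(list(insulator, polyA, dest_backbone, carrier_backbone,
                    adaptor_backbone, kan, tet), proms, genes)
    names(parts) <- vapply(parts, function(p) p$name, character(1))
    parts <- parts[!duplicated(names(parts))]
    registry <- list(parts = parts, position_vectors = pos_vecs,
                     adaptors = adaptors,
                     carriers = stats::setNames(list(carrier),
                                                carrier$sequence$name))
    design <- circuit_design(names(pos_vecs), carrier$sequence$name)
    list(parts = parts, uns_set = uns_set, layout = layout,
         position_vectors = pos_vecs, carrier = carrier, adaptors = adaptors,
         design = design, registry = registry)
  })
}

#' Two-round hierarchical assembly fixture
#'
#' Emulates recursive circuit construction: round one assembles
#' `n_module_tus` transcription units into a hierarchical carrier whose
#' relay addresses come from a second, independently designed UNS set;
#' round two reuses the whole assembled module as the position 1-2 part
#' next to `n_tail_tus` fresh TUs. Returns everything both rounds need.
#'
#' @param rng_seed Integer seed.
#' @param n_module_tus TUs inside the round-one module (default 7).
#' @param n_tail_tus Fresh TUs added in round two (default 5).
#' @return List with `round1` (fixture + plan), `module` (assembled circular
#'   `dna_sequence`), `round2` (fixture), `design_tail`, and `uns_set_round2`.
#' @export
make_hierarchical_fixture <- function(rng_seed, n_module_tus = 7L,
                                      n_tail_tus = 5L) {
  n_entries2 <- n_tail_tus + 1L
  cfg2 <- design_config(rng_seed = rng_seed + 1L,
                        n_candidates = 4L * (n_entries2 + 2L) + 24L)
  set2 <- design_uns_set(n_entries2 + 1L, cfg2)
  fx1 <- make_fixture_library(rng_seed, n_module_tus,
                              carrier_flavor = "hierarchical",
                              carrier_relay = list(
                                uns1 = uns_member(set2, "UNS1"),
                                uns2 = uns_member(set2, "UNS2")))
  plan1 <- plan_assembly(fx1$design, fx1$uns_set, fx1$registry)
  module <- plan1$predicted_sequence
  fx2 <- make_fixture_library(rng_seed + 2L, n_tail_tus,
                              positions = seq.int(2L, n_tail_tus + 1L),
                              uns_set = set2)
  design_tail <- circuit_design(names(fx2$position_vectors),
                                fx2$carrier$sequence$name,
                                previous_round_marker = plan1$adaptor$marker)
  list(round1 = list(fixture = fx1, plan = plan1), module = module,
       round2 = fx2, design_tail = design_tail, uns_set_round2 = set2)
}
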