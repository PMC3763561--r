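#' Ordered circuit design
#'
#' The user-facing description of a circuit: the ordered list of position
#' vectors (one per transcription unit, positions 1..n), the carrier to
#' close the circle on, and the selection marker used in the previous
#' assembly round (so the planner can alternate Kan/Tet).
#'
#' @param entries Character vector of position-vector names, in circuit
#'   order.
#' @param carrier Carrier vector name.
#' @param previous_round_marker `"none"`, `"Kan"` or `"Tet"`.
#' @return Object of class `circuit_design`.
#' @export
circuit_design <- function(entries, carrier,
                           previous_round_marker = c("none", "Kan", "Tet")) {
  previous_round_marker <- match.arg(previous_round_marker)
  # zero entries is allowed only as the tail of a hierarchical design
  structure(list(entries = entries, carrier = carrier,
                 previous_round_marker = previous_round_marker),
            class = "circuit_design")
}

#' Assign UNS addresses to a circuit design
#'
#' Entry i receives the consecutive flank pair `(UNS_i, UNS_{i+1})`; the
#' adaptor bridges `(UNS_{n+1}, UNSX)` and the carrier closes
#' `UNSX -> UNS1`, so an n-entry circuit consumes n + 2 distinct addresses.
#'
#' @param design A [circuit_design()].
#' @param uns_set An `uns_set`; must provide `UNS1`..`UNS_{n+1}` plus
#'   `UNSX`.
#' @return List with `entries` (data.frame position/name/uns_left/uns_right)
#'   and `adaptor` (named pair).
#' @export
assign_positions <- function(design, uns_set) {
  n <- length(design$entries)
  have <- uns_numbered(uns_set)
  if (have < n + 1L) {
    stop(sprintf("design needs UNS1-%d + X but the set has only %d numbered members",
                 n + 1L, have))
  }
  entries <- data.frame(position = seq_len(n), name = design$entries,
                        uns_left = paste0("UNS", seq_len(n)),
                        uns_right = paste0("UNS", seq_len(n) + 1L),
                        stringsAsFactors = FALSE)
  list(entries = entries,
       adaptor = c(left = paste0("UNS", n + 1L), right = "UNSX"))
}

#' Select the adaptor for a circuit, alternating markers between rounds
#'
#' Returns the adaptor at address `(UNS_{n+1}, UNSX)` whose selection marker
#' differs from the previous round's, so parental modules can be selected
#' against. The first round (previous marker `"none"`) defaults to Kan.
#'
#' @param n Number of circuit entries.
#' @param previous_round_marker `"none"`, `"Kan"` or `"Tet"`.
#' @param library Named list of `adaptor_vector` objects.
#' @return An `adaptor_vector`.
#' @export
select_adaptor <- function(n, previous_round_marker = c("none", "Kan", "Tet"),
                           library) {
  previous_round_marker <- match.arg(previous_round_marker)
  want_marker <- switch(previous_round_marker,
                        none = "Kan", Kan = "Tet", Tet = "Kan")
  want_left <- paste0("UNS", n + 1L)
  for (ad in library) {
    if (identical(ad$uns_pair[1], want_left) &&
        identical(ad$marker, want_marker)) return(ad)
  }
  stop(sprintf("adaptor library has no %s adaptor at address (%s, UNSX)",
               want_marker, want_left))
}

# Extract the UNS-flanked insert body from a digested vector: the fragment
# containing both flank sequences, trimmed to [left UNS start, right UNS
# end] (flap removal).
.insert_body <- function(circular_seq, enzymes, uns_left_seq, uns_right_seq,
                         what = "vector") {
  frs <- digest(circular_seq, enzymes)
  for (f in frs) {
    fs <- f$sequence$residues
    pl <- regexpr(uns_left_seq, fs, fixed = TRUE)
    pr <- regexpr(uns_right_seq, fs, fixed = TRUE)
    if (pl > 0L && pr > 0L && pl < pr) {
      return(list(body = substr(fs, pl, pr + nchar(uns_right_seq) - 1L),
                  flap_left = as.integer(pl) - 1L,
                  flap_right = nchar(fs) - (as.integer(pr) + nchar(uns_right_seq) - 1L),
                  raw = fs))
    }
  }
  stop(sprintf("digestion of %s released no fragment flanked by the expected UNS pair",
               what))
}

#' Plan a one-pot assembly
#'
#' Turns a circuit design into an executable plan: per-input digestion
#' instructions (I-SceI for position vectors, XbaI + XhoI for the adaptor,
#' the linearization enzyme for the carrier), the fragment roster with
#' expected UNS flanks, the marker-alternated adaptor, the default pooling
#' quantities (70 fmol per position-vector digest, 280 fmol adaptor,
#' 140 fmol carrier, 7 fmol of each digested part into the one-pot
#' reaction), and the predicted final circular sequence.
#'
#' Two entries claiming the same UNS pair are a positional conflict and an
#' error: such rosters produce ambiguous junctions.
#'
#' @param design A [circuit_design()].
#' @param uns_set The `uns_set` the vectors were built against.
#' @param registry List with `position_vectors`, `adaptors`, `carriers`
#'   (as produced by [make_fixture_library()]).
#' @param module Optional pre-digested module entry (internal; see
#'   [plan_hierarchical()]).
#' @return Object of class `assembly_plan`.
#' @export
plan_assembly <- function(design, uns_set, registry, module = NULL) {
  stopifnot(inherits(design, "circuit_design"))
  if (length(design$entries) < 1L) stop("design has no entries")
  addr <- assign_positions(design, uns_set)
  n <- nrow(addr$entries)

  entry_bodies <- vector("list", n)
  entry_raws <- vector("list", n)
  pairs_seen <- character()
  roster <- list()
  for (i in seq_len(n)) {
    nm <- addr$entries$name[i]
    if (!is.null(module) && identical(nm, module$name)) {
      pv_pair <- module$uns_pair
      body <- module$body
      raw <- module$raw
      len_bp <- module$length_bp
      kind <- "module"
      enzymes <- "I-SceI"
    } else {
      pv <- registry$position_vectors[[nm]]
      if (is.null(pv)) stop(sprintf("position vector '%s' not in registry", nm))
      rep <- validate_layout(pv, uns_set)
      if (!rep$pass) {
        stop(sprintf("position vector '%s' fails layout validation (%s)", nm,
                     paste(rep$checks$check[!rep$checks$pass], collapse = "; ")))
      }
      pv_pair <- pv$uns_pair
      info <- .insert_body(pv$sequence, get_enzyme("I-SceI"),
                           uns_member(uns_set, pv_pair[1]),
                           uns_member(uns_set, pv_pair[2]), nm)
      body <- info$body
      raw <- info$raw
      len_bp <- nchar(pv$sequence$residues)
      kind <- "position"
      enzymes <- "I-SceI"
    }
    key <- paste(pv_pair, collapse = "-")
    if (key %in% pairs_seen) {
      stop(sprintf("positional conflict: two entries carry UNS pair %s", key))
    }
    pairs_seen <- c(pairs_seen, key)
    expected <- c(addr$entries$uns_left[i], addr$entries$uns_right[i])
    if (!identical(unname(pv_pair), expected)) {
      stop(sprintf("entry %d ('%s') carries pair %s but position %d requires %s",
                   i, nm, key, i, paste(expected, collapse = "-")))
    }
    entry_bodies[[i]] <- body
    entry_raws[[i]] <- raw
    roster[[length(roster) + 1L]] <-
      data.frame(input = nm, kind = kind, enzymes = enzymes,
                 uns_left = expected[1], uns_right = expected[2],
                 length_bp = len_bp,
                 fmol_digest = if (kind == "module") 140 else 70,
                 fmol_pool = 7,
                 stringsAsFactors = FALSE)
  }

  adaptor <- select_adaptor(n, design$previous_round_marker, registry$adaptors)
  ad_info <- .insert_body(adaptor$sequence,
                          list(get_enzyme("XbaI"), get_enzyme("XhoI")),
                          uns_member(uns_set, adaptor$uns_pair[1]),
                          uns_member(uns_set, "UNSX"),
                          adaptor$sequence$name)
  ad_body <- ad_info$body
  roster[[length(roster) + 1L]] <-
    data.frame(input = adaptor$sequence$name, kind = "adaptor",
               enzymes = "XbaI+XhoI",
               uns_left = adaptor$uns_pair[1], uns_right = "UNSX",
               length_bp = nchar(adaptor$sequence$residues),
               fmol_digest = 280, fmol_pool = 7, stringsAsFactors = FALSE)

  carrier <- registry$carriers[[design$carrier]]
  if (is.null(carrier)) stop(sprintf("carrier '%s' not in registry", design$carrier))
  ca_info <- .insert_body(carrier$sequence,
                          get_enzyme(carrier$linearization_enzyme),
                          uns_member(uns_set, "UNSX"),
                          uns_member(uns_set, "UNS1"),
                          carrier$sequence$name)
  ca_body <- ca_info$body
  roster[[length(roster) + 1L]] <-
    data.frame(input = carrier$sequence$name, kind = "carrier",
               enzymes = carrier$linearization_enzyme,
               uns_left = "UNSX", uns_right = "UNS1",
               length_bp = nchar(carrier$sequence$residues),
               fmol_digest = 140, fmol_pool = 7, stringsAsFactors = FALSE)
  roster <- do.call(rbind, roster)

  plan <- structure(list(design = design, uns_set = uns_set,
                         registry = registry, roster = roster,
                         adaptor = list(name = adaptor$sequence$name,
                                        uns_pair = adaptor$uns_pair,
                                        marker = adaptor$marker),
                         carrier_enzyme = carrier$linearization_enzyme,
                         bodies = c(entry_bodies, list(ad_body, ca_body)),
                         fragments_raw = stats::setNames(
                           c(entry_raws, list(ad_info$raw, ca_info$raw)),
                           roster$input),
                         junction_order = c(paste0("UNS", seq_len(n + 1L)), "UNSX"),
                         module = module),
                    class = "assembly_plan")
  plan$predicted_sequence <- predict_final_sequence(plan)
  plan
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(sprintf("<assembly_plan> %d inputs (%d entries + adaptor[%s] + carrier), predicted %d bp circular\n",
              nrow(x$roster), nrow(x$roster) - 2L, x$adaptor$marker,
              nchar(x$predicted_sequence$residues)))
  invisible(x)
}

#' Predict the final assembled sequence of a plan
#'
#' Deterministic concatenation around the circle of the UNS-trimmed insert
#' bodies, counting each shared address exactly once: entry bodies run
#' `UNS_i ... UNS_{i+1}`, the adaptor `UNS_{n+1} ... UNSX`, and the carrier
#' `UNSX ... UNS1`, whose terminal `UNS1` closes onto the first entry.
#' Restriction remnants outside the UNSs were already trimmed from the
#' bodies (complete flap removal). The result is annotated with every UNS
#' and reported with `UNS1` at the origin.
#'
#' @param plan An `assembly_plan`.
#' @return Circular annotated `dna_sequence`.
#' @export
predict_final_sequence <- function(plan) {
  bodies <- plan$bodies
  m <- length(bodies)
  out <- bodies[[1L]]
  for (i in seq.int(2L, m)) {
    b <- bodies[[i]]
    stopifnot(substr(out, nchar(out) - 39L, nchar(out)) == substr(b, 1L, 40L))
    out <- paste0(out, substr(b, 41L, nchar(b)))
  }
  # carrier body ends in UNS1 == start of entry 1: drop it to close the circle
  stopifnot(substr(out, nchar(out) - 39L, nchar(out)) == substr(out, 1L, 40L))
  out <- substr(out, 1L, nchar(out) - 40L)
  feats <- list()
  for (u in plan$junction_order) {
    us <- uns_member(plan$uns_set, u)
    p <- regexpr(us, out, fixed = TRUE)
    if (p > 0L) {
      feats[[length(feats) + 1L]] <-
        data.frame(label = u, start = as.integer(p) - 1L,
                   end = as.integer(p) + 39L, strand = "+",
                   stringsAsFactors = FALSE)
    }
  }
  dna_sequence(out, "circular", name = "pCircuit_predicted",
               features = do.call(rbind, feats))
}

#' Plan a hierarchical (re-entrant) assembly round
#'
#' Uses a previously assembled circuit vector as the position 1-2 part of a
#' new, larger circuit: the module vector is digested with I-SceI, the
#' released piece must be flanked by this round's `UNS1` and `UNS2` (which a
#' hierarchical carrier embedded around its backbone), and the tail entries
#' occupy positions 2 onward. Module-internal addresses are scanned against
#' every address this round uses; any collision is an error, because a
#' shared UNS would create ambiguous junctions.
#'
#' @param module_vector Assembled circuit: a circular `dna_sequence`, an
#'   `assembly_product`, or a plan's `predicted_sequence`.
#' @param design_tail A [circuit_design()] whose entries are the additional
#'   position vectors (built at positions 2..); its
#'   `previous_round_marker` should name the module round's marker.
#' @param uns_set This round's `uns_set`.
#' @param registry Registry holding the tail vectors, adaptors and carrier.
#' @param module_name Name for the module entry in the roster.
#' @return An `assembly_plan` with the module at position 1.
#' @export
plan_hierarchical <- function(module_vector, design_tail, uns_set, registry,
                              module_name = "module_1_2") {
  if (inherits(module_vector, "assembly_product")) {
    module_vector <- module_vector$sequence
  }
  module_vector <- as_dna(module_vector, topology = "circular")
  u1 <- uns_member(uns_set, "UNS1")
  u2 <- uns_member(uns_set, "UNS2")
  ins <- .insert_body(module_vector, get_enzyme("I-SceI"), u1, u2,
                      "module vector")

  n_tail <- length(design_tail$entries)
  used <- c(paste0("UNS", seq_len(n_tail + 2L)), "UNSX")
  internal <- setdiff(used, c("UNS1", "UNS2"))
  colliding <- character()
  for (u in internal) {
    us <- uns_member(uns_set, u)
    if (.count_fixed(ins$body, us) + .count_fixed(ins$body, .revcomp_chr(us)) > 0L) {
      colliding <- c(colliding, u)
    }
  }
  if (.count_fixed(ins$body, u1) + .count_fixed(ins$body, u2) != 2L) {
    colliding <- c(colliding, "UNS1/UNS2 (extra internal copy)")
  }
  if (length(colliding)) {
    stop(sprintf("module-internal UNS collision with this round's addresses: %s",
                 paste(colliding, collapse = ", ")))
  }
  module <- list(name = module_name, uns_pair = c("UNS1", "UNS2"),
                 body = ins$body, raw = ins$raw,
                 length_bp = nchar(module_vector$residues))
  design <- circuit_design(c(module_name, design_tail$entries),
                           design_tail$carrier,
                           design_tail$previous_round_marker)
  plan_assembly(design, uns_set, registry, module = module)
}

#' Bench protocol sheet for an assembly plan
#'
#' Converts the plan's pooling table into masses and volumes using the
#' average double-stranded base-pair mass of 650 g/mol:
#' `mass_ng = fmol * length_bp * 650e-6`. Digestion inputs default to the
#' protocol's quantities (70 fmol per position vector, 280 fmol adaptor,
#' 140 fmol carrier); 7 fmol of each digested part enters the one-pot
#' reaction.
#'
#' @param plan An `assembly_plan`.
#' @param concentrations ng/ul per input: scalar or named vector.
#' @return data.frame of class `protocol_sheet` with per-input digest and
#'   pool masses and volumes.
#' @export
protocol_sheet <- function(plan, concentrations = 50) {
  r <- plan$roster
  conc <- if (length(concentrations) == 1L) {
    stats::setNames(rep(as.numeric(concentrations), nrow(r)), r$input)
  } else concentrations[r$input]
  if (any(is.na(conc)) || any(conc <= 0)) {
    stop("concentrations must be positive for every input")
  }
  sheet <- data.frame(
    input = r$input, kind = r$kind, enzymes = r$enzymes,
    length_bp = r$length_bp,
    fmol_digest = r$fmol_digest,
    mass_digest_ng = r$fmol_digest * r$length_bp * 650e-6,
    fmol_pool = r$fmol_pool,
    mass_pool_ng = r$fmol_pool * r$length_bp * 650e-6,
    conc_ng_ul = unname(conc),
    volume_digest_ul = r$fmol_digest * r$length_bp * 650e-6 / unname(conc),
    stringsAsFactors = FALSE)
  class(sheet) <- c("protocol_sheet", class(sheet))
  sheet
}

#' Mass of a DNA amount
#'
#' `fmol * length_bp * 650e-6` nanograms (650 g/mol per average bp).
#' @param fmol Amount in femtomoles.
#' @param length_bp Fragment length in bp.
#' @return Mass in nanograms.
#' @export
fmol_to_ng <- function(fmol, length_bp) {
  stopifnot(all(fmol >= 0), all(length_bp >= 0))
  fmol * length_bp * 650e-6
}

#' Digested fragments entering the one-pot reaction
#'
#' The pool the bench protocol combines: for each entry the UNS-flanked
#' I-SceI insert (restriction remnants still attached), the adaptor's
#' XbaI/XhoI bridging cassette, and the linearized carrier. Backbone
#' fragments are omitted, as on the bench they are removed by selection.
#'
#' @param plan An `assembly_plan`.
#' @return Named list of linear `dna_sequence` fragments, one per roster
#'   input.
#' @export
plan_fragments <- function(plan) {
  stopifnot(inherits(plan, "assembly_plan"))
  out <- lapply(names(plan$fragments_raw), function(nm) {
    dna_sequence(plan$fragments_raw[[nm]], "linear", name = nm)
  })
  stats::setNames(out, names(plan$fragments_raw))
}
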