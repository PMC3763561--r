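#' Agarose gel resolution model
#'
#' Two bands are distinguishable when the larger exceeds the smaller by at
#' least `resolution_fraction` (ratio rule), and only bands inside the
#' resolvable size window count.
#'
#' @param min_size,max_size Resolvable range in bp (defaults 250-20000).
#' @param resolution_fraction Minimum ratio excess (default 0.08, i.e. 8%).
#' @return Object of class `gel_model`.
#' @export
gel_model <- function(min_size = 250, max_size = 20000,
                      resolution_fraction = 0.08) {
  stopifnot(min_size < max_size, resolution_fraction > 0)
  structure(list(min_size = min_size, max_size = max_size,
                 resolution_fraction = resolution_fraction),
            class = "gel_model")
}

#' Predict a diagnostic restriction map
#'
#' Digests the construct with the whole enzyme panel in one (joint)
#' reaction and annotates each predicted band with its gel visibility:
#' whether it falls in the resolvable window and whether it is separable
#' from every other band under the ratio rule. Co-migrating bands are
#' grouped.
#'
#' @param construct A `dna_sequence` (circular or linear).
#' @param panel A `restriction_enzyme`, list of them, or character names.
#' @param gel A [gel_model()].
#' @return Object of class `restriction_map` with `sizes` (sorted
#'   descending), `in_range`, `distinguishable`, `groups`, `uncut`,
#'   `construct_length` and the panel names.
#' @export
restriction_map <- function(construct, panel, gel = gel_model()) {
  if (inherits(panel, "restriction_enzyme")) panel <- list(panel)
  if (is.character(panel)) panel <- lapply(panel, get_enzyme)
  if (!length(panel)) stop("empty enzyme panel")
  construct <- as_dna(construct, topology = "circular")
  frs <- digest(construct, panel)
  uncut <- isTRUE(frs[[1]]$uncut)
  sizes <- sort(fragment_lengths(frs), decreasing = TRUE)
  in_range <- sizes >= gel$min_size & sizes <= gel$max_size
  rf <- 1 + gel$resolution_fraction
  m <- length(sizes)
  comigrate <- function(a, b) max(a, b) / min(a, b) < rf
  groups <- integer(m)
  g <- 0L
  for (i in seq_len(m)) {
    if (i == 1L || !comigrate(sizes[i - 1L], sizes[i])) g <- g + 1L
    groups[i] <- g
  }
  dist <- vapply(seq_len(m), function(i) {
    in_range[i] && sum(groups == groups[i]) == 1L &&
      (i == 1L || !comigrate(sizes[i - 1L], sizes[i])) &&
      (i == m || !comigrate(sizes[i], sizes[i + 1L]))
  }, logical(1))
  structure(list(panel = vapply(panel, function(e) e$name, character(1)),
                 sizes = as.integer(sizes), in_range = in_range,
                 distinguishable = dist, groups = groups, uncut = uncut,
                 construct_length = nchar(construct$residues), gel = gel),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("<restriction_map> %s on %d bp: bands %s%s\n",
              paste(x$panel, collapse = "+"), x$construct_length,
              paste(x$sizes, collapse = ", "),
              if (x$uncut) " (uncut)" else ""))
  invisible(x)
}

# Band-pattern comparison under the gel model: two maps are
# distinguishable when their visible (in-range) band lists differ in count
# or any size-ranked pair differs by at least the resolution ratio.
.maps_distinguishable <- function(a, b, gel) {
  rf <- 1 + gel$resolution_fraction
  va <- a$sizes[a$sizes >= gel$min_size & a$sizes <= gel$max_size]
  vb <- b$sizes[b$sizes >= gel$min_size & b$sizes <= gel$max_size]
  if (length(va) != length(vb)) return(TRUE)
  if (!length(va)) return(FALSE)
  any(pmax(va, vb) / pmin(va, vb) >= rf)
}

#' Score a diagnostic panel
#'
#' First component: fraction of alternative (misassembly) constructs whose
#' band pattern is gel-distinguishable from the correct construct's.
#' Second component (tie-break): fraction of the correct map's bands that
#' are in-range and pairwise distinguishable. Both in `[0, 1]`, compared
#' lexicographically.
#'
#' @param map_correct `restriction_map` of the intended construct.
#' @param maps_alternatives Non-empty list of `restriction_map`s of the
#'   misassembly hypotheses.
#' @param gel A [gel_model()].
#' @return Named numeric `c(distinguishability, resolution)`.
#' @export
panel_score <- function(map_correct, maps_alternatives, gel = gel_model()) {
  stopifnot(length(maps_alternatives) >= 1)
  d <- mean(vapply(maps_alternatives, function(m) {
    .maps_distinguishable(map_correct, m, gel)
  }, logical(1)))
  r <- mean(map_correct$distinguishable)
  c(distinguishability = d, resolution = r)
}

#' Misassembly alternatives for a plan
#'
#' The failure-mode constructs a diagnostic digest must separate from the
#' correct circuit: the re-circularized (undigested) carrier, and for each
#' entry a hypothetical single-dropout circle with that entry's segment
#' deleted from the predicted sequence.
#'
#' @param plan An `assembly_plan`.
#' @return Named list of circular `dna_sequence` alternatives.
#' @export
misassembly_alternatives <- function(plan) {
  out <- list()
  carrier <- plan$registry$carriers[[plan$design$carrier]]
  out[["carrier_self"]] <- carrier$sequence
  pred <- plan$predicted_sequence$residues
  ent <- plan$roster[plan$roster$kind %in% c("position", "module"), ,
                     drop = FALSE]
  for (i in seq_len(nrow(ent))) {
    uL <- uns_member(plan$uns_set, ent$uns_left[i])
    uR <- uns_member(plan$uns_set, ent$uns_right[i])
    pL <- regexpr(uL, pred, fixed = TRUE)
    pR <- regexpr(uR, pred, fixed = TRUE)
    if (pL > 0L && pR > 0L && pL < pR) {
      dropped <- paste0(substr(pred, 1L, pL - 1L),
                        substr(pred, pR, nchar(pred)))
      out[[sprintf("dropout_%s", ent$input[i])]] <-
        dna_sequence(dropped, "circular",
                     name = sprintf("dropout_%s", ent$input[i]))
    }
  }
  out
}

#' Choose the best diagnostic enzyme panel
#'
#' Exhaustive search over all panels of up to `max_enzymes` candidate
#' enzymes (joint digests), maximizing [panel_score()] lexicographically.
#' Ties prefer fewer enzymes, then the alphabetically first panel. Panels
#' larger than 3 enzymes are refused rather than approximated.
#'
#' @param construct Correct construct (`dna_sequence`).
#' @param alternatives Non-empty list of alternative constructs.
#' @param candidate_enzymes Character names or list of
#'   `restriction_enzyme`s.
#' @param gel A [gel_model()].
#' @param max_enzymes Maximum panel size (default 2, hard cap 3).
#' @return List with `panel` (character names), `score`, `warning`
#'   (message when no panel separates anything, else `NULL`).
#' @export
select_diagnostic_panel <- function(construct, alternatives,
                                    candidate_enzymes, gel = gel_model(),
                                    max_enzymes = 2L) {
  if (max_enzymes > 3L) {
    stop("panels larger than 3 enzymes are refused (exhaustive search only)")
  }
  if (is.character(candidate_enzymes)) {
    candidate_enzymes <- lapply(unique(candidate_enzymes), get_enzyme)
  }
  nms <- vapply(candidate_enzymes, function(e) e$name, character(1))
  candidate_enzymes <- candidate_enzymes[!duplicated(nms)]
  nms <- nms[!duplicated(nms)]
  if (!length(candidate_enzymes)) stop("candidate enzyme list is empty")
  stopifnot(length(alternatives) >= 1)
  best <- NULL
  for (size in seq_len(min(max_enzymes, length(candidate_enzymes)))) {
    idx <- utils::combn(length(candidate_enzymes), size)
    for (c_i in seq_len(ncol(idx))) {
      sel <- idx[, c_i]
      panel <- candidate_enzymes[sel]
      mc <- restriction_map(construct, panel, gel)
      ma <- lapply(alternatives, restriction_map, panel = panel, gel = gel)
      sc <- panel_score(mc, ma, gel)
      key <- list(score = sc, n = size, names = sort(nms[sel]))
      better <- is.null(best) ||
        sc[1] > best$score[1] ||
        (sc[1] == best$score[1] && sc[2] > best$score[2]) ||
        (all(sc == best$score) && size < best$n) ||
        (all(sc == best$score) && size == best$n &&
           paste(key$names, collapse = "+") <
           paste(best$names, collapse = "+"))
      if (better) best <- key
    }
  }
  warn <- if (best$score[1] == 0) {
    "no candidate panel distinguishes any alternative from the correct construct"
  } else NULL
  list(panel = best$names, score = best$score, warning = warn)
}

#' Probability that all screened colonies are incorrect
#'
#' With per-colony success probability `p_correct`, the chance that none of
#' `k` screened colonies carries the correct construct is
#' `(1 - p_correct)^k`; screening two colonies of an assembly with
#' p >= 0.7 leaves under 10% risk.
#'
#' @param p_correct Per-colony probability of the correct construct.
#' @param k Number of colonies screened (>= 1).
#' @return Probability in `[0, 1]`.
#' @export
screening_stats <- function(p_correct, k) {
  if (any(p_correct < 0 | p_correct > 1)) stop("p_correct must lie in [0, 1]")
  if (any(k < 1)) stop("k must be >= 1")
  (1 - p_correct)^k
}

#' Colonies needed to reach a target failure risk
#'
#' Smallest k with `(1 - p)^k <= risk`, i.e. `ceil(log(risk)/log(1 - p))`;
#' one colony suffices when p = 1.
#'
#' @param p_correct Per-colony success probability in `(0, 1]`.
#' @param risk Acceptable probability that every colony is wrong, in
#'   `(0, 1)`.
#' @return Integer number of colonies.
#' @export
colonies_for_risk <- function(p_correct, risk) {
  stopifnot(risk > 0, risk < 1)
  if (p_correct <= 0) stop("unachievable risk: p_correct must exceed 0")
  if (p_correct > 1) stop("p_correct must lie in (0, 1]")
  if (p_correct == 1) return(1L)
  k <- as.integer(ceiling(log(risk) / log(1 - p_correct)))
  k <- max(k, 1L)
  while (k > 1L && (1 - p_correct)^(k - 1L) <= risk) k <- k - 1L
  while ((1 - p_correct)^k > risk) k <- k + 1L
  k
}
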