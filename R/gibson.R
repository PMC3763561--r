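#' Parameters of the one-pot isothermal assembly model
#'
#' `chew_window` emulates finite 5'->3' exonuclease processivity: only the
#' terminal windows of each fragment can anneal, so internal homology
#' (e.g. repeated promoters) cannot create junctions. `min_overlap` is the
#' shortest annealing overlap accepted (the 40-bp addresses exceed it by
#' design); `flap_tolerance` is the longest non-homologous terminal flap
#' (restriction remnants outside the UNSs) removed during assembly.
#'
#' @param min_overlap Minimum junction overlap in nt (default 20).
#' @param chew_window Terminal window searched for homology, nt (default 80).
#' @param flap_tolerance Maximum trimmed flap, nt (default 15).
#' @param require_all_fragments Demand every fragment in the product.
#' @return Object of class `gibson_params`.
#' @export
gibson_params <- function(min_overlap = 20L, chew_window = 80L,
                          flap_tolerance = 15L, require_all_fragments = TRUE) {
  stopifnot(min_overlap >= 0, chew_window >= 0, flap_tolerance >= 0,
            min_overlap <= chew_window)
  structure(list(min_overlap = as.integer(min_overlap),
                 chew_window = as.integer(chew_window),
                 flap_tolerance = as.integer(flap_tolerance),
                 require_all_fragments = isTRUE(require_all_fragments)),
            class = "gibson_params")
}

# All maximal common-substring runs between strings a and b:
# data.frame(len, end_a, end_b), 1-based inclusive end coordinates.
.lcs_runs <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  len <- integer(); end_a <- integer(); end_b <- integer()
  if (n == 0L || m == 0L) {
    return(data.frame(len = len, end_a = end_a, end_b = end_b))
  }
  prev <- integer(m)
  for (i in seq_len(n)) {
    shifted <- c(0L, prev[-m])
    cur <- integer(m)
    hit <- x[i] == y
    cur[hit] <- shifted[hit] + 1L
    # a run ending at (i, j) is maximal iff it cannot extend to (i+1, j+1)
    nxt <- if (i < n) {
      ext <- logical(m)
      ext[-m] <- x[i + 1L] == y[-1L]
      ext
    } else logical(m)
    ends <- which(cur > 0L & !nxt)
    if (length(ends)) {
      len <- c(len, cur[ends])
      end_a <- c(end_a, rep.int(i, length(ends)))
      end_b <- c(end_b, ends)
    }
    prev <- cur
  }
  data.frame(len = len, end_a = end_a, end_b = end_b)
}

# Best junction between the 3' window of strand sa and the 5' window of
# strand sb, both taken as written (no orientation search).
.junction_fixed <- function(sa, sb, params) {
  La <- nchar(sa); Lb <- nchar(sb)
  wa_len <- min(params$chew_window, La)
  wb_len <- min(params$chew_window, Lb)
  wa <- substr(sa, La - wa_len + 1L, La)
  wb <- substr(sb, 1L, wb_len)
  runs <- .lcs_runs(wa, wb)
  if (!nrow(runs)) return(NULL)
  runs$flap_a <- wa_len - runs$end_a
  runs$flap_b <- runs$end_b - runs$len
  ok <- runs$flap_a <= params$flap_tolerance &
    runs$flap_b <= params$flap_tolerance &
    runs$len >= params$min_overlap
  if (!any(ok)) return(NULL)
  runs <- runs[ok, , drop = FALSE]
  runs <- runs[order(-runs$len, runs$flap_a + runs$flap_b, runs$end_b), ,
               drop = FALSE]
  best <- runs[1L, ]
  ov_start_b <- best$end_b - best$len + 1L
  list(overlap = best$len,
       sequence = substr(wb, ov_start_b, best$end_b),
       flap_a = best$flap_a, flap_b = best$flap_b)
}

#' Best terminal junction between two fragments
#'
#' Longest exact match between the terminal chew window at the 3' end of
#' `a` (top strand) and the 5' window of `b`, considering both orientations
#' of `b`, subject to the flap tolerance on the unmatched terminal residues
#' on either side of the match. Returns `NULL` when the best feasible match
#' is shorter than `min_overlap`.
#'
#' @param a,b Linear fragments (`dna_fragment`, `dna_sequence` or
#'   character).
#' @param params A [gibson_params()].
#' @return List with `overlap`, `sequence`, `orientation` (of `b`),
#'   `flap_a`, `flap_b`, or `NULL`.
#' @export
terminal_homology <- function(a, b, params = gibson_params()) {
  sa <- .fragment_seq(a)
  sb <- .fragment_seq(b)
  best <- NULL
  for (or in c("+", "-")) {
    sbo <- if (or == "+") sb else .revcomp_chr(sb)
    j <- .junction_fixed(sa, sbo, params)
    if (!is.null(j)) {
      j$orientation <- or
      if (is.null(best) || j$overlap > best$overlap) best <- j
    }
  }
  best
}

.fragment_seq <- function(x) {
  if (inherits(x, "dna_fragment")) return(x$sequence$residues)
  .residues(x)
}

.fragment_name <- function(x, fallback) {
  if (inherits(x, "dna_fragment")) return(x$sequence$name)
  if (inherits(x, "dna_sequence")) return(x$name)
  fallback
}

#' Simulate a one-pot isothermal (Gibson) assembly
#'
#' Builds the directed junction graph over oriented fragment ends
#' (annealing restricted to terminal chew windows) and enumerates every
#' simple cycle; a cycle is a candidate circular product. The reaction is
#' `unique_circular` when exactly one distinct product exists, it uses
#' every fragment exactly once, and no fragment end can anneal to more than
#' one partner (otherwise `ambiguous`). Products are spliced with the
#' junction overlap counted once and terminal flaps trimmed, reported in
#' canonical circular form, so the result is invariant to input order.
#'
#' @param fragments List (>= 2) of `dna_fragment`, `dna_sequence` or
#'   character sequences.
#' @param params A [gibson_params()].
#' @return List of class `one_pot_result`: `status` (one of
#'   `unique_circular`, `multiple_products`, `ambiguous`, `incomplete`),
#'   `products` (list of `assembly_product`), and `end_partners`
#'   (per-end partner counts).
#' @export
simulate_one_pot <- function(fragments, params = gibson_params()) {
  if (length(fragments) < 2L) stop("need at least 2 fragments")
  seqs <- vapply(fragments, .fragment_seq, character(1))
  nms <- make.unique(vapply(seq_along(fragments), function(i) {
    .fragment_name(fragments[[i]], sprintf("fragment%d", i))
  }, character(1)))
  k <- length(seqs)
  ord <- order(nms)            # canonical, input-order independent
  seqs <- seqs[ord]; nms <- nms[ord]

  rcs <- vapply(seqs, .revcomp_chr, character(1))
  oriented <- function(i, o) if (o == "+") seqs[[i]] else rcs[[i]]
  # successors[[node]] = list of (j, oj, junction); node key = i * 2 - (o=="+")
  node_key <- function(i, o) paste0(i, o)
  succ <- new.env(parent = emptyenv())
  for (i in seq_len(k)) for (oi in c("+", "-")) {
    lst <- list()
    for (j in seq_len(k)) {
      if (i == j) next
      for (oj in c("+", "-")) {
        jn <- .junction_fixed(oriented(i, oi), oriented(j, oj), params)
        if (!is.null(jn)) {
          lst[[length(lst) + 1L]] <- list(j = j, oj = oj, junction = jn)
        }
      }
    }
    assign(node_key(i, oi), lst, envir = succ)
  }

  end_partners <- integer(0)
  ambiguous <- FALSE
  for (i in seq_len(k)) for (oi in c("+", "-")) {
    lst <- get(node_key(i, oi), envir = succ)
    partners <- unique(vapply(lst, function(e) e$j, integer(1)))
    end_partners[node_key(i, oi)] <- length(partners)
    if (length(partners) > 1L) ambiguous <- TRUE
  }

  # enumerate simple cycles; each cycle is rooted at its smallest fragment
  # index (post name-sort) in "+" orientation, which kills rotation and
  # mirror duplicates
  cycles <- list()
  for (s in seq_len(k)) {
    path <- list(list(j = s, oj = "+", junction = NULL))
    used <- rep(FALSE, k); used[s] <- TRUE
    dfs <- function() {
      cur <- path[[length(path)]]
      for (e in get(node_key(cur$j, cur$oj), envir = succ)) {
        if (e$j == s && e$oj == "+" && length(path) > 1L) {
          cyc <- path
          cyc[[1L]]$junction <- e$junction   # closing junction into start
          cycles[[length(cycles) + 1L]] <<- cyc
        } else if (e$j > s && !used[e$j]) {
          used[e$j] <<- TRUE
          path[[length(path) + 1L]] <<- e
          dfs()
          path[[length(path)]] <<- NULL
          used[e$j] <<- FALSE
        }
      }
    }
    dfs()
  }

  build_product <- function(cyc) {
    m <- length(cyc)
    pieces <- character(m)
    junctions <- list()
    for (t in seq_len(m)) {
      nxt <- if (t == m) 1L else t + 1L
      jn_in <- cyc[[t]]$junction       # junction entering fragment t
      jn_out <- cyc[[nxt]]$junction    # junction leaving fragment t
      s <- oriented(cyc[[t]]$j, cyc[[t]]$oj)
      ltrim <- jn_in$flap_b + jn_in$overlap
      rtrim <- jn_out$flap_a
      pieces[t] <- substr(s, ltrim + 1L, nchar(s) - rtrim)
      junctions[[t]] <- data.frame(
        left = nms[cyc[[t]]$j], right = nms[cyc[[nxt]]$j],
        overlap = jn_out$overlap, overlap_seq = jn_out$sequence,
        flap_left = jn_out$flap_a, flap_right = jn_out$flap_b,
        stringsAsFactors = FALSE)
    }
    seq_raw <- paste(pieces, collapse = "")
    structure(list(
      sequence = dna_sequence(canonical_circular(seq_raw), "circular",
                              name = "assembly_product"),
      composition = data.frame(
        fragment = vapply(cyc, function(e) nms[e$j], character(1)),
        orientation = vapply(cyc, function(e) e$oj, character(1)),
        stringsAsFactors = FALSE),
      junctions = do.call(rbind, junctions),
      n_fragments = m,
      status = NA_character_),
      class = "assembly_product")
  }

  products <- lapply(cycles, build_product)
  if (length(products)) {
    canon <- vapply(products, function(p) p$sequence$residues, character(1))
    keep <- !duplicated(canon)
    products <- products[keep]
    products <- products[order(vapply(products,
                                      function(p) p$sequence$residues,
                                      character(1)))]
  }
  covers_all <- vapply(products, function(p) p$n_fragments == k, logical(1))

  status <- if (ambiguous) "ambiguous"
  else if (length(products) == 1L &&
           (covers_all[1L] || !params$require_all_fragments)) "unique_circular"
  else if (length(products) == 0L) "incomplete"
  else if (length(products) == 1L) "incomplete"
  else "multiple_products"

  products <- lapply(products, function(p) { p$status <- status; p })
  structure(list(status = status, products = products,
                 end_partners = end_partners),
            class = "one_pot_result")
}

#' @export
print.one_pot_result <- function(x, ...) {
  cat(sprintf("<one_pot_result> status %s, %d product(s)\n",
              x$status, length(x$products)))
  for (p in x$products) {
    cat(sprintf("  - %d bp circular from %d fragment(s)\n",
                nchar(p$sequence$residues), p$n_fragments))
  }
  invisible(x)
}

#' Verify the UNS anatomy of an assembled product
#'
#' Checks that every junction overlap contains exactly one full UNS member
#' (on either strand) and that the addresses occur around the circle in
#' the order `UNS1, UNS2, ..., UNSX`.
#'
#' @param product An `assembly_product`.
#' @param uns_set The `uns_set` used for the assembly.
#' @return List with `pass`, `junctions` (per-junction data.frame) and
#'   `order` (observed circular UNS order).
#' @export
verify_junctions <- function(product, uns_set) {
  stopifnot(inherits(product, "assembly_product"))
  jt <- product$junctions
  mem <- uns_set$members
  count_uns <- function(ovseq) {
    sum(vapply(mem, function(u) {
      grepl(u, ovseq, fixed = TRUE) || grepl(.revcomp_chr(u), ovseq, fixed = TRUE)
    }, logical(1)))
  }
  which_uns <- function(ovseq) {
    hit <- names(mem)[vapply(mem, function(u) {
      grepl(u, ovseq, fixed = TRUE) || grepl(.revcomp_chr(u), ovseq, fixed = TRUE)
    }, logical(1))]
    if (length(hit) == 1L) hit else NA_character_
  }
  jt$uns_count <- vapply(jt$overlap_seq, count_uns, numeric(1))
  jt$uns <- vapply(jt$overlap_seq, which_uns, character(1))
  jt$pass <- jt$uns_count == 1L
  rownames(jt) <- NULL

  s <- product$sequence$residues
  pos <- vapply(names(mem), function(nm) {
    p <- regexpr(mem[[nm]], s, fixed = TRUE)
    if (p < 0L) p <- regexpr(.revcomp_chr(mem[[nm]]), s, fixed = TRUE)
    as.integer(p)
  }, integer(1))
  present <- names(pos)[pos > 0L]
  order_obs <- present[order(pos[present])]
  # normalize: start at UNS1, in the direction where UNS2 follows
  expected_n <- length(present) - 1L
  expected <- c(paste0("UNS", seq_len(expected_n)), "UNSX")
  ord_ok <- FALSE
  if ("UNS1" %in% order_obs && length(order_obs) == length(expected)) {
    i1 <- match("UNS1", order_obs)
    fwd <- order_obs[((seq_along(order_obs) + i1 - 2L) %% length(order_obs)) + 1L]
    rev_obs <- rev(order_obs)
    i1r <- match("UNS1", rev_obs)
    bwd <- rev_obs[((seq_along(rev_obs) + i1r - 2L) %% length(rev_obs)) + 1L]
    ord_ok <- identical(fwd, expected) || identical(bwd, expected)
  }
  list(pass = all(jt$pass) && ord_ok, junctions = jt, order = order_obs,
       order_ok = ord_ok)
}
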