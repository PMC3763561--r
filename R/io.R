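#' Write sequences to FASTA
#'
#' @param seqs A `dna_sequence`, `uns_set`, or named character vector/list
#'   of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "uns_set")) seqs <- as.list(seqs$members)
  if (inherits(seqs, "dna_sequence")) {
    seqs <- stats::setNames(list(seqs$residues), seqs$name)
  }
  chr <- vapply(seqs, .residues, character(1))
  set <- Biostrings::DNAStringSet(chr)
  names(set) <- names(chr)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write an annotated construct as a GenBank flat file
#'
#' Minimal writer covering the subset this toolkit round-trips: LOCUS line
#' with length and topology, `misc_feature` entries with `/label`
#' qualifiers (1-based inclusive coordinates, `complement(..)` for the
#' minus strand), and the ORIGIN sequence block.
#'
#' @param seq A `dna_sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path) {
  stopifnot(inherits(seq, "dna_sequence"))
  s <- seq$residues
  L <- nchar(s)
  if (L == 0L) stop("refusing to write an empty-sequence record")
  con <- file(path, "w")
  on.exit(close(con))
  nm <- gsub("[[:space:]]+", "_", seq$name)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-1980",
                     substr(nm, 1, 16), L,
                     ifelse(seq$topology == "circular", "circular", "linear")),
             con)
  writeLines(sprintf("DEFINITION  %s.", seq$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- seq$features
  if (!is.null(f) && nrow(f)) {
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (identical(f$strand[i], "-")) loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", f$label[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  low <- tolower(s)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(low, off, min(off + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path GenBank file.
#' @return A `dna_sequence` with features.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop(sprintf("malformed GenBank record '%s': no LOCUS line", path))
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  name <- toks[2]
  topology <- if (any(toks == "circular")) "circular" else "linear"
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop(sprintf("malformed GenBank record '%s': no ORIGIN", path))
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  if (is.na(end)) end <- length(lines) + 1L
  s <- if (end - 1L >= ori[1] + 1L) {
    seq_lines <- lines[(ori[1] + 1L):(end - 1L)]
    toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  } else ""
  if (nchar(s) == 0L) stop(sprintf("malformed GenBank record '%s': empty sequence", path))

  feats <- list()
  fi <- grep("^     misc_feature", lines)
  for (i in fi) {
    loc <- trimws(sub("^     misc_feature", "", lines[i]))
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
    if (length(m) != 3L) next
    label <- ""
    if (i + 1L <= length(lines) && grepl("/label=", lines[i + 1L])) {
      label <- sub('^.*?/label="?([^"]*)"?.*$', "\\1", lines[i + 1L])
    }
    feats[[length(feats) + 1L]] <-
      data.frame(label = label, start = as.integer(m[2]) - 1L,
                 end = as.integer(m[3]), strand = strand,
                 stringsAsFactors = FALSE)
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  dna_sequence(s, topology, name, features)
}

#' Read a part registry from JSON
#'
#' The registry maps part names to roles and sequences. Each entry needs
#' `name`, `role`, and either `sequence` (literal) or `fasta` (path to a
#' single-record FASTA, resolved relative to the registry file).
#'
#' @param path JSON file.
#' @return Named list of `part` objects.
#' @export
read_part_registry <- function(path) {
  reg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed registry JSON '%s': %s",
                                 path, conditionMessage(e)))
                  })
  parts <- list()
  for (i in seq_along(reg)) {
    e <- reg[[i]]
    if (is.null(e$name) || is.null(e$role)) {
      stop(sprintf("registry entry %d in '%s' lacks name/role", i, path))
    }
    s <- if (!is.null(e$sequence)) e$sequence
    else if (!is.null(e$fasta)) {
      unname(read_fasta(file.path(dirname(path), e$fasta))[1])
    } else stop(sprintf("registry entry '%s' has neither sequence nor fasta",
                        e$name))
    parts[[e$name]] <- part(e$name, e$role, s)
  }
  parts
}

#' Serialize an assembly plan to JSON
#'
#' @param plan An `assembly_plan`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(
    entries = plan$design$entries,
    carrier = plan$design$carrier,
    adaptor = plan$adaptor,
    carrier_enzyme = plan$carrier_enzyme,
    roster = plan$roster,
    junction_order = plan$junction_order,
    predicted_length_bp = nchar(plan$predicted_sequence$residues))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tool configuration
#'
#' Bundles the sub-configurations of the designer, the assembly simulator
#' and the gel model, plus file-path defaults.
#'
#' @param design A [design_config()].
#' @param gibson A [gibson_params()].
#' @param gel A [gel_model()].
#' @param paths Named list of file locations.
#' @param log_level One of "quiet", "info", "debug".
#' @return Object of class `tool_config`.
#' @export
tool_config <- function(design = design_config(), gibson = gibson_params(),
                        gel = gel_model(), paths = list(),
                        log_level = "info") {
  stopifnot(inherits(design, "design_config"),
            inherits(gibson, "gibson_params"), inherits(gel, "gel_model"))
  structure(list(design = design, gibson = gibson, gel = gel, paths = paths,
                 log_level = log_level),
            class = "tool_config")
}

#' Read a tool configuration from YAML
#'
#' Unknown keys are rejected with their location, so typos never silently
#' fall back to defaults.
#'
#' @param path YAML file with optional blocks `design`, `gibson`, `gel`,
#'   `paths`, `log_level`.
#' @return A [tool_config()].
#' @export
read_tool_config <- function(path) {
  y <- yaml::read_yaml(path)
  known_top <- c("design", "gibson", "gel", "paths", "log_level")
  extra <- setdiff(names(y), known_top)
  if (length(extra)) {
    stop(sprintf("unknown key '%s' at top level of '%s'", extra[1], path))
  }
  build <- function(fn, block, where) {
    args <- y[[block]]
    if (is.null(args)) return(fn())
    known <- names(formals(fn))
    extra <- setdiff(names(args), known)
    if (length(extra)) {
      stop(sprintf("unknown key '%s' in block '%s' of '%s'", extra[1], where,
                   path))
    }
    do.call(fn, args)
  }
  tool_config(design = build(design_config, "design", "design"),
              gibson = build(gibson_params, "gibson", "gibson"),
              gel = build(gel_model, "gel", "gel"),
              paths = if (is.null(y$paths)) list() else y$paths,
              log_level = if (is.null(y$log_level)) "info" else y$log_level)
}
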