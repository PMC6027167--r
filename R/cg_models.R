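#' Coarse-grained bead registry
#'
#' The mesoscopic models use nine bead types: lecithin is built from a
#' hydrophilic head bead `L1`, a neck bead `L2` and hydrophobic tail beads
#' `L3`; capsaicin from head/neck/tail beads `C1`, `C2`, `C3`; chitosan from
#' one bead per monomer, `G` for d-glucosamine (GlcN, deacetylated) and `A`
#' for N-acetyl-d-glucosamine (GlucNA); water is a single solvent bead `W`.
#' All beads carry unit reduced mass by default.
#'
#' @return A data.frame with columns `name`, `role` and `mass`, one row per
#'   bead type, in the canonical type order used by interaction matrices.
#' @export
#' @examples
#' bead_registry()
bead_registry <- function() {
  data.frame(
    name = c("L1", "L2", "L3", "C1", "C2", "C3", "G", "A", "W"),
    role = c("head", "neck", "tail", "head", "neck", "tail",
             "glucosamine", "acetyl-glucosamine", "solvent"),
    mass = 1,
    stringsAsFactors = FALSE
  )
}

#' Canonical bead type names
#'
#' @return Character vector of the nine bead type labels in canonical order.
#' @export
bead_types <- function() bead_registry()$name

# ---------------------------------------------------------------------------
# Chitosan sequences
# ---------------------------------------------------------------------------

new_chitosan_sequence <- function(monomers) {
  stopifnot(is.character(monomers))
  if (length(monomers) == 0L) {
    stop("chitosan sequence must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(monomers), c("G", "A"))
  if (length(bad) > 0L) {
    stop("unknown monomer code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(monomers = monomers), class = "chitosan_sequence")
}

#' Coerce to a chitosan sequence
#'
#' Accepts a `chitosan_sequence`, a character vector of single-letter monomer
#' codes (`"G"`/`"A"`), or a single string such as `"GGAGG"`.
#'
#' @param x Object to coerce.
#' @return A `chitosan_sequence`.
#' @export
as_chitosan_sequence <- function(x) {
  if (inherits(x, "chitosan_sequence")) return(x)
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
    return(new_chitosan_sequence(x))
  }
  stop("cannot coerce object of class ", class(x)[1L],
       " to chitosan_sequence", call. = FALSE)
}

#' @export
format.chitosan_sequence <- function(x, ...) paste(x$monomers, collapse = "")

#' @export
print.chitosan_sequence <- function(x, ...) {
  cat(sprintf("<chitosan_sequence> %d monomers, acetyl fraction %.3f\n%s\n",
              length(x$monomers), degree_of_acetylation(x), format(x)))
  invisible(x)
}

#' @export
length.chitosan_sequence <- function(x) length(x$monomers)

#' Parse a block-notation chitosan sequence specification
#'
#' Chitosan acetylation patterns are conventionally written in a compact
#' block notation, e.g. `"[GlucNA[GlcN]3GlucNA[GlcN]3GlucNAGlcN]5"`: the
#' tokens `GlucNA` (N-acetyl-d-glucosamine, bead `A`) and `GlcN`
#' (d-glucosamine, bead `G`) may be grouped in square brackets with a
#' positive integer repeat count following the closing bracket; groups nest
#' to arbitrary depth and a count may also follow a bare token. Decorative
#' dashes and minus signs between tokens (as printed in the literature) are
#' stripped before tokenization, as is whitespace. Single-letter codes `G`
#' and `A` are accepted as synonyms of the full monomer names.
#'
#' @param spec A single string in block notation.
#' @return A `chitosan_sequence` containing the fully expanded monomer list.
#' @export
#' @examples
#' s <- parse_sequence_spec("[-GlucNA-[GlcN]3-GlucNA-[GlcN]3-GlucNA-GlcN-]5")
#' length(s)                  # 50
#' degree_of_acetylation(s)   # 0.3
parse_sequence_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  # strip separators: ASCII hyphen, unicode minus/en-dash, whitespace
  s <- gsub("[-−–—[:space:]]+", "", spec)
  if (!nzchar(s)) stop("empty sequence specification", call. = FALSE)

  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""

  read_count <- function() {
    # optional positive integer; defaults to 1
    start <- pos
    while (pos <= n && grepl("[0-9]", substr(s, pos, pos))) pos <<- pos + 1L
    if (pos == start) return(1L)
    k <- as.integer(substr(s, start, pos - 1L))
    if (is.na(k) || k <= 0L) {
      stop("zero or negative repeat count in sequence spec", call. = FALSE)
    }
    k
  }

  read_token <- function() {
    for (tok in c("GlucNA", "GlcN", "A", "G")) {
      if (pos + nchar(tok) - 1L <= n &&
          substr(s, pos, pos + nchar(tok) - 1L) == tok) {
        pos <<- pos + nchar(tok)
        return(if (tok %in% c("GlucNA", "A")) "A" else "G")
      }
    }
    stop("unknown token in sequence spec at position ", pos, ": '",
         substr(s, pos, min(n, pos + 7L)), "'", call. = FALSE)
  }

  parse_group <- function(closing) {
    out <- character(0)
    repeat {
      ch <- peek()
      if (ch == "") {
        if (closing) stop("unbalanced brackets in sequence spec", call. = FALSE)
        break
      }
      if (ch == "]") {
        if (!closing) stop("unbalanced brackets in sequence spec", call. = FALSE)
        pos <<- pos + 1L
        break
      }
      if (ch == "[") {
        pos <<- pos + 1L
        grp <- parse_group(TRUE)
        out <- c(out, rep(grp, read_count()))
      } else if (grepl("[0-9]", ch)) {
        stop("repeat count with no preceding token or group", call. = FALSE)
      } else {
        tok <- read_token()
        out <- c(out, rep(tok, read_count()))
      }
    }
    out
  }

  monomers <- parse_group(FALSE)
  new_chitosan_sequence(monomers)
}

#' Degree of N-acetylation of a chitosan sequence
#'
#' The acetyl fraction: the proportion of N-acetyl-d-glucosamine (`A`)
#' monomers along the chain, in `[0, 1]`. (The literature sometimes reports
#' the complementary deacetylated fraction; this package standardizes on the
#' acetyl fraction.)
#'
#' @param seq A `chitosan_sequence` (or anything `as_chitosan_sequence()`
#'   accepts).
#' @return Numeric scalar in `[0, 1]`.
#' @export
degree_of_acetylation <- function(seq) {
  seq <- as_chitosan_sequence(seq)
  mean(seq$monomers == "A")
}

#' Built-in chitosan sequences S1 and S2
#'
#' Two 50-mer chitosan sequences with identical composition (15 of 50
#' monomers acetylated, acetyl fraction 0.30) but different acetylation
#' patterns: `S1` distributes single GlucNA units quasi-uniformly along the
#' chain, `[GlucNA [GlcN]3 GlucNA [GlcN]3 GlucNA GlcN]5`, while `S2` is
#' blocky, `[[GlucNA]4 [GlcN]9]3 [GlucNA]3 [GlcN]8`.
#'
#' @param name `"S1"` or `"S2"`.
#' @return A `chitosan_sequence` of length 50.
#' @export
#' @examples
#' degree_of_acetylation(builtin_sequence("S2"))  # 0.3
builtin_sequence <- function(name = c("S1", "S2")) {
  name <- match.arg(name)
  spec <- switch(name,
    S1 = "[GlucNA[GlcN]3GlucNA[GlcN]3GlucNAGlcN]5",
    S2 = "[[GlucNA]4[GlcN]9]3[GlucNA]3[GlcN]8"
  )
  parse_sequence_spec(spec)
}

# ---------------------------------------------------------------------------
# Molecule topologies
# ---------------------------------------------------------------------------

new_molecule_topology <- function(species, beads, bonds) {
  stopifnot(is.character(species), length(species) == 1L,
            is.character(beads), length(beads) >= 1L)
  bad <- setdiff(unique(beads), bead_types())
  if (length(bad) > 0L) {
    stop("unknown bead type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  nb <- length(beads)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L) {
    if (any(bonds < 0L) || any(bonds >= nb)) {
      stop("bond index out of range", call. = FALSE)
    }
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bond", call. = FALSE)
    key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                 pmax(bonds[, 1L], bonds[, 2L]))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
  }
  topo <- structure(
    list(species = species, beads = beads, bonds = bonds),
    class = "molecule_topology"
  )
  if (!topology_is_connected(topo)) {
    stop("bond graph of '", species, "' is not connected", call. = FALSE)
  }
  topo
}

topology_is_connected <- function(topo) {
  nb <- length(topo$beads)
  if (nb == 1L) return(TRUE)
  if (nrow(topo$bonds) == 0L) return(FALSE)
  seen <- logical(nb)
  queue <- 1L
  seen[1L] <- TRUE
  adj <- vector("list", nb)
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[k, 1L] + 1L
    j <- topo$bonds[k, 2L] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("<molecule_topology> %s: %d beads (%s), %d bonds\n",
              x$species, length(x$beads),
              paste(rle(x$beads)$values, collapse = "-"), nrow(x$bonds)))
  invisible(x)
}

#' Lecithin bead-spring topology
#'
#' One hydrophilic head bead `L1` bonded to a neck bead `L2`, from which
#' `n_tails` linear chains of `beads_per_tail` hydrophobic `L3` beads hang —
#' the coarse-grained image of a two-tailed phosphatidylcholine. The default
#' (two tails of three beads) gives 8 beads and 7 bonds.
#'
#' @param n_tails Number of acyl tails (>= 1).
#' @param beads_per_tail Tail beads per chain (>= 1).
#' @return A `molecule_topology` with species `"lecithin"`.
#' @export
lecithin_topology <- function(n_tails = 2L, beads_per_tail = 3L) {
  n_tails <- as.integer(n_tails)
  beads_per_tail <- as.integer(beads_per_tail)
  if (is.na(n_tails) || n_tails < 1L || is.na(beads_per_tail) ||
      beads_per_tail < 1L) {
    stop("n_tails and beads_per_tail must be positive", call. = FALSE)
  }
  beads <- c("L1", "L2", rep("L3", n_tails * beads_per_tail))
  bonds <- list(c(0L, 1L))  # head-neck
  idx <- 2L
  for (t in seq_len(n_tails)) {
    prev <- 1L  # each tail roots at the neck
    for (b in seq_len(beads_per_tail)) {
      bonds[[length(bonds) + 1L]] <- c(prev, idx)
      prev <- idx
      idx <- idx + 1L
    }
  }
  new_molecule_topology("lecithin", beads, do.call(rbind, bonds))
}

#' Capsaicin bead-spring topology
#'
#' A linear three-bead chain `C1`-`C2`-`C3` (vanillyl head, amide neck,
#' hydrophobic aliphatic tail).
#'
#' @return A `molecule_topology` with species `"capsaicin"`.
#' @export
capsaicin_topology <- function() {
  new_molecule_topology("capsaicin", c("C1", "C2", "C3"),
                        rbind(c(0L, 1L), c(1L, 2L)))
}

#' Chitosan bead-spring topology from a sequence
#'
#' A linear chain with one bead per monomer (`G` or `A`), consecutive beads
#' bonded.
#'
#' @param seq A `chitosan_sequence` (or coercible).
#' @return A `molecule_topology` with species `"chitosan"`.
#' @export
chitosan_topology <- function(seq = builtin_sequence("S1")) {
  seq <- as_chitosan_sequence(seq)
  nb <- length(seq$monomers)
  bonds <- if (nb > 1L) cbind(0:(nb - 2L), 1:(nb - 1L)) else NULL
  new_molecule_topology("chitosan", seq$monomers, bonds)
}

#' Solvent (water) topology
#'
#' A single `W` bead.
#'
#' @return A `molecule_topology` with species `"water"`.
#' @export
water_topology <- function() {
  new_molecule_topology("water", "W", NULL)
}

#' Serialize a topology to a plain-text config block
#'
#' @param topo A `molecule_topology`.
#' @return A named list (species, beads, bonds) suitable for YAML output.
#' @export
topology_to_config <- function(topo) {
  stopifnot(inherits(topo, "molecule_topology"))
  list(
    species = topo$species,
    beads = topo$beads,
    bonds = if (nrow(topo$bonds) > 0L) {
      lapply(seq_len(nrow(topo$bonds)), function(k) as.integer(topo$bonds[k, ]))
    } else list()
  )
}

#' Rebuild a topology from its config block
#'
#' @param cfg A list as produced by [topology_to_config()].
#' @return A `molecule_topology`.
#' @export
topology_from_config <- function(cfg) {
  bonds <- if (length(cfg$bonds) > 0L) {
    do.call(rbind, lapply(cfg$bonds, as.integer))
  } else NULL
  new_molecule_topology(cfg$species, unlist(cfg$beads), bonds)
}
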