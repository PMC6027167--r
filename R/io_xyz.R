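# Extended-XYZ trajectory I/O. Per-frame comment line carries the box
# (Lattice=...), the step counter, and the column layout (Properties=...);
# columns are species, molecule id, x, y, z in reduced units.

xyz_comment <- function(box, step) {
  sprintf(
    'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:molecule:I:1:pos:R:3 step=%d pbc="T T T"',
    box[1], box[2], box[3], as.integer(step))
}

#' Write a trajectory (or single state) as extended XYZ
#'
#' @param x A `dpd_trajectory` or `simulation_state`.
#' @param path Output file path.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, append = FALSE) {
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  emit <- function(pos, species, molecule_id, box, step) {
    writeLines(as.character(nrow(pos)), con)
    writeLines(xyz_comment(box, step), con)
    writeLines(sprintf("%s %d %.8f %.8f %.8f", species, molecule_id,
                       pos[, 1L], pos[, 2L], pos[, 3L]), con)
  }
  if (inherits(x, "simulation_state")) {
    emit(x$positions, x$species, x$molecule_id, x$box, x$step)
  } else if (inherits(x, "dpd_trajectory")) {
    for (fr in x$frames) {
      emit(fr$positions, x$species, x$molecule_id, x$box, fr$step)
    }
  } else {
    stop("expected a dpd_trajectory or simulation_state", call. = FALSE)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Reads files written by [write_xyz()] (species, molecule id and position
#' columns; box and step from the comment line).
#'
#' @param path File path.
#' @return A `dpd_trajectory`-like object (frames with positions and step;
#'   species, molecule ids and box from the first frame; no velocities or
#'   bonds).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  species <- NULL
  molecule_id <- NULL
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i,
                       call. = FALSE)
    comment <- lines[i + 1L]
    lat <- regmatches(comment,
                      regexec('Lattice="([^"]+)"', comment))[[1L]][2L]
    latv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1L]])
    fbox <- latv[c(1L, 5L, 9L)]
    stp <- regmatches(comment, regexec("step=([0-9]+)", comment))[[1L]][2L]
    stp <- if (is.na(stp)) length(frames) else as.integer(stp)
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(rows, "\\s+")
    sp <- vapply(parts, `[[`, character(1), 1L)
    mid <- as.integer(vapply(parts, `[[`, character(1), 2L))
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 3:5))), ncol = 3L,
                  byrow = TRUE)
    if (is.null(species)) {
      species <- sp
      molecule_id <- mid
      box <- fbox
    }
    frames[[length(frames) + 1L]] <- list(step = stp, positions = pos,
                                          velocities = NULL, images = NULL)
    i <- i + 2L + n
  }
  # recover molecule species labels from bead composition
  first_bead <- species[!duplicated(molecule_id)][order(unique(molecule_id))]
  mol_species <- c(L1 = "lecithin", L2 = "lecithin", L3 = "lecithin",
                   C1 = "capsaicin", C2 = "capsaicin", C3 = "capsaicin",
                   G = "chitosan", A = "chitosan", W = "water")[first_bead]
  structure(list(frames = frames, box = box, species = species,
                 molecule_id = molecule_id,
                 molecule_species = unname(mol_species),
                 bonds = matrix(integer(0), ncol = 2L), thermo = NULL,
                 state = NULL, seed = NA_integer_),
            class = "dpd_trajectory")
}
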