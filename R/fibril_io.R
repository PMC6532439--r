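# Structure I/O. Coordinates are nm inside the package and Angstrom on disk
# (the PDB convention); conversion happens at the file boundary.

#' Write fibril coordinates to a PDB file
#'
#' C-alpha-only records; a [fibril_trajectory()] is written as one MODEL per
#' frame. Coordinates are converted from nm to Angstrom.
#'
#' @param x A [fibril_coords()] or [fibril_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fibril_pdb <- function(x, path) {
  if (inherits(x, "fibril_coords")) {
    frames <- list(x)
  } else if (inherits(x, "fibril_trajectory")) {
    frames <- x$frames
  } else {
    stop("`x` must be fibril_coords or fibril_trajectory", call. = FALSE)
  }
  a <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) {
    as.vector(t(coords_matrix(f) * 10)) # nm -> Angstrom
  }))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = a$resno, chain = a$chain,
    resid = rep("ALA", nrow(a)), elety = rep("CA", nrow(a))
  )
  invisible(path)
}

#' Read fibril coordinates from a PDB file
#'
#' Extracts C-alpha atoms for the requested chains and residue range and
#' returns coordinates in nm. Multi-MODEL files yield a
#' [fibril_trajectory()] (one frame per MODEL).
#'
#' @param path PDB file path.
#' @param chains Chain identifiers to keep, in the stacking order used by
#'   [order_parameter()]; `NULL` keeps all chains in file order.
#' @param residues Residue numbers to keep (e.g. `17:42`); `NULL` keeps all.
#' @param times Frame times (ns) for multi-MODEL files; default frame index.
#' @param axis Fibril axis to record; `NULL` estimates it from the chain
#'   centroids (see [fibril_coords()]).
#' @return A [fibril_coords()] or [fibril_trajectory()].
#' @export
read_fibril <- function(path, chains = NULL, residues = NULL, times = NULL,
                        axis = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  ca <- at$elety == "CA"
  if (!any(ca)) stop("no C-alpha atoms in ", path, call. = FALSE)
  if (is.null(chains)) chains <- unique(at$chain[ca])
  missing_ch <- setdiff(chains, at$chain[ca])
  if (length(missing_ch)) {
    stop(
      "chain(s) not present with C-alpha atoms: ",
      paste(missing_ch, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- ca & at$chain %in% chains
  if (!is.null(residues)) {
    for (ch in chains) {
      have <- at$resno[keep & at$chain == ch]
      gap <- setdiff(residues, have)
      if (length(gap)) {
        stop(sprintf(
          "chain %s is missing C-alpha atoms for residue(s) %s",
          ch, paste(gap, collapse = ", ")
        ), call. = FALSE)
      }
    }
    keep <- keep & at$resno %in% residues
  }
  idx <- which(keep)
  n_frames <- nrow(pdb$xyz)
  make_frame <- function(fr) {
    xyz <- matrix(pdb$xyz[fr, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    atoms <- tibble::tibble(
      chain = at$chain[idx], resno = at$resno[idx],
      x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10
    )
    atoms <- atoms[order(match(atoms$chain, chains), atoms$resno), ]
    fibril_coords(atoms, axis = axis)
  }
  if (n_frames == 1L) {
    make_frame(1L)
  } else {
    fibril_trajectory(
      lapply(seq_len(n_frames), make_frame),
      times = times %||% (seq_len(n_frames) - 1)
    )
  }
}
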