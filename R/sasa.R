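# Solvent-accessible surface area by sphere-point (Shrake-Rupley style)
# sampling. Points are a deterministic golden-spiral set, so results are
# reproducible without an RNG.

golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    sin(phi) * cos(theta),
    sin(phi) * sin(theta),
    cos(phi)
  )
}

#' Solvent-accessible surface area of a set of spheres
#'
#' Numerical SASA: each atom is inflated by the probe radius, `n_points`
#' quasi-uniform surface points are tested against all neighbouring inflated
#' spheres, and the accessible fraction scales the analytic sphere area.
#'
#' @param xyz n x 3 matrix of atom centres (nm).
#' @param radii Atomic radii (nm), recycled to n. Default 0.17 nm, a
#'   C-alpha pseudo-atom radius for backbone-only models.
#' @param probe Probe (solvent) radius in nm; default 0.14 (water).
#' @param n_points Surface sample points per atom; default 960.
#' @return Total SASA in nm^2.
#' @export
sasa <- function(xyz, radii = 0.17, probe = 0.14, n_points = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
  n <- nrow(xyz)
  radii <- rep_len(radii, n)
  rp <- radii + probe
  pts <- golden_spiral_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    surf <- sweep(pts * rp[i], 2, xyz[i, ], "+")
    # neighbours whose inflated sphere can reach atom i's surface
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rp + rp[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, xyz[j, ])^2)
      # relative tolerance: points exactly on a neighbour's surface are buried
      acc <- acc & dj2 > rp[j]^2 * (1 + 1e-9)
      if (!any(acc)) break
    }
    total <- total + mean(acc) * 4 * pi * rp[i]^2
  }
  total
}

#' Buried interface area between two groups of a complex
#'
#' Computes the SASA of group A alone, group B alone, and the complex, and
#' reports the buried interface as half the SASA lost on complexation:
#' `interface = (sasa_A + sasa_B - sasa_complex) / 2`.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` (nm) and optionally
#'   `radius` (nm; default 0.17), or a [fibril_coords()].
#' @param group Vector (recycled against rows) with exactly two distinct
#'   values partitioning the atoms, or, for `fibril_coords` input, a list of
#'   two chain-label vectors.
#' @inheritParams sasa
#' @return A one-row tibble: `sasa_a`, `sasa_b`, `sasa_complex`,
#'   `interface_area` (all nm^2).
#' @examples
#' at <- data.frame(x = c(0, 0.2), y = 0, z = 0)
#' interface_area(at, group = c("A", "B"))
#' @export
interface_area <- function(atoms, group, probe = 0.14, n_points = 960L) {
  if (inherits(atoms, "fibril_coords")) {
    stopifnot(is.list(group), length(group) == 2)
    ab <- ifelse(atoms$atoms$chain %in% group[[1]], "A",
      ifelse(atoms$atoms$chain %in% group[[2]], "B", NA)
    )
    atoms <- atoms$atoms
    group <- ab
  }
  atoms <- tibble::as_tibble(atoms)
  group <- rep_len(group, nrow(atoms))
  if (anyNA(group) || length(unique(group)) != 2) {
    stop("`group` must split the atoms into exactly two non-empty groups",
      call. = FALSE
    )
  }
  radii <- if ("radius" %in% names(atoms)) atoms$radius else 0.17
  radii <- rep_len(radii, nrow(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lv <- unique(group)
  ia <- group == lv[1]
  if (!any(ia) || all(ia)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  s_a <- sasa(xyz[ia, , drop = FALSE], radii[ia], probe, n_points)
  s_b <- sasa(xyz[!ia, , drop = FALSE], radii[!ia], probe, n_points)
  s_ab <- sasa(xyz, radii, probe, n_points)
  tibble::tibble(
    sasa_a = s_a, sasa_b = s_b, sasa_complex = s_ab,
    interface_area = (s_a + s_b - s_ab) / 2
  )
}
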