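#' Simulate a C3-symmetric toy trimer with planted interface residues
#'
#' Builds a three-chain Calpha-only structure in which chains A, B and C are
#' related by 120 degree rotations about the z axis. Non-pocket residues sit
#' on a shell at radius `2 * interface_radius` from the axis, which places
#' them at least `sqrt(3) * 2 * interface_radius` (> 1.5 x `interface_radius`)
#' from every other chain. Planted pocket residues are pulled onto a tight
#' inner ring near the symmetry axis at radius
#' `0.9 * interface_radius / sqrt(3)`, so each lies within `interface_radius`
#' of its symmetry mate in the adjacent chain and the planted set forms one
#' spatial cluster. The geometry is a detection fixture, not a protein fold:
#' the guarantee is the distance contrast, not stereochemistry.
#'
#' @param n_residues_per_chain Residues per chain.
#' @param pocket_residues Residue numbers (within `[1, n_residues_per_chain]`)
#'   planted at the inter-subunit interface; may be empty.
#' @param interface_radius Angstrom; the planted contact distance scale
#'   (default 8, matching the detector's default Calpha cutoff).
#' @param seed RNG seed for the small coordinate jitter.
#' @return List with `structure` (a [trimer_structure()]) and `truth`
#'   (`planted_truth` with `pocket_residues` as (chain, resno) pairs for
#'   chain A and the `interface_radius` used).
#' @export
simulate_trimer <- function(n_residues_per_chain, pocket_residues = integer(0),
                            interface_radius = 8, seed = 1) {
  assert_scalar(interface_radius, "interface_radius", positive = TRUE)
  pocket_residues <- sort(unique(as.integer(pocket_residues)))
  if (n_residues_per_chain < 1L) stop("need at least one residue", call. = FALSE)
  if (length(pocket_residues) &&
      (min(pocket_residues) < 1L || max(pocket_residues) > n_residues_per_chain)) {
    stop("pocket_residues must lie in [1, n_residues_per_chain]", call. = FALSE)
  }
  shell_r <- 2 * interface_radius
  pocket_r <- 0.9 * interface_radius / sqrt(3)
  spacing <- 3.8  # Calpha-Calpha rise along z for shell residues

  with_seed(seed, {
    n <- n_residues_per_chain
    z <- seq_len(n) * spacing + stats::runif(n, -0.1, 0.1)
    r <- rep(shell_r, n)
    theta <- rep(0, n)
    if (length(pocket_residues)) {
      # tight ring near the axis, centred on the mean pocket height
      z_center <- mean(pocket_residues) * spacing
      k <- seq_along(pocket_residues)
      z[pocket_residues] <- z_center + (k - (length(k) + 1) / 2) * 1.5
      r[pocket_residues] <- pocket_r
      theta[pocket_residues] <- (k - (length(k) + 1) / 2) * (pi / 180)
    }
    chains <- c("A", "B", "C")
    rows <- lapply(seq_along(chains), function(ci) {
      ang <- theta + (ci - 1) * 2 * pi / 3
      data.frame(
        chain = chains[ci], resno = seq_len(n), resid = "ALA", elety = "CA",
        x = r * cos(ang), y = r * sin(ang), z = z, stringsAsFactors = FALSE
      )
    })
    structure_out <- trimer_structure(do.call(rbind, rows))
    truth <- structure(
      list(pocket_residues = if (length(pocket_residues))
             data.frame(chain = "A", resno = pocket_residues,
                        stringsAsFactors = FALSE)
           else data.frame(chain = character(0), resno = integer(0)),
           interface_radius = interface_radius),
      class = "planted_truth"
    )
    list(structure = structure_out, truth = truth)
  })
}
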