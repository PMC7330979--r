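# Synthetic-structure generator: ideal secondary-structure backbones with
# planted side-chain interactions, so the whole pipeline is exercisable
# without any external coordinate files.

#' Fixture specification
#'
#' @param n_residues chain length (>= 4)
#' @param secondary_structure "helix" (phi -57, psi -47) or "strand"
#'   (phi -120, psi +120)
#' @param planted_interactions list of plants, each a list with `i`, `j`
#'   (1-based positions, both with full flanks: 2 <= pos <= n-1), `kind`
#'   ("hydrogen_bond", "ionic" or "disulfide") and `distance` (target
#'   interaction distance, below the kind's cutoff)
#' @param seed integer seed controlling the torsion jitter
#' @param torsion_jitter_deg s.d. of Gaussian noise added to phi/psi
#'   (default 0: ideal geometry)
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(n_residues = 20,
                         secondary_structure = c("helix", "strand"),
                         planted_interactions = list(), seed = 1L,
                         torsion_jitter_deg = 0) {
  secondary_structure <- match.arg(secondary_structure)
  stopifnot(n_residues >= 4)
  for (pl in planted_interactions) {
    stopifnot(all(c("i", "j", "kind", "distance") %in% names(pl)))
    if (pl$i < 2 || pl$j < 2 || pl$i > n_residues - 1 ||
        pl$j > n_residues - 1 || pl$i == pl$j)
      stop("planted positions must have full flanks: 2 <= pos <= n-1")
    if (pl$distance >= INTERACTION_CUTOFFS[[pl$kind]])
      stop("planted distance ", pl$distance, " not below the ", pl$kind,
           " cutoff ", INTERACTION_CUTOFFS[[pl$kind]])
  }
  structure(list(n_residues = n_residues,
                 secondary_structure = secondary_structure,
                 planted_interactions = planted_interactions,
                 seed = as.integer(seed),
                 torsion_jitter_deg = torsion_jitter_deg),
            class = "fixture_spec")
}

# place atom D given A, B, C with |C-D| = bond, angle(B,C,D) = angle_deg,
# torsion(A,B,C,D) = torsion_deg (natural extension reference frame)
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# residue identities used for each planted interaction kind; the first
# element sits at the lower sequence position
PLANT_RESIDUES <- list(
  hydrogen_bond = c("SER", "THR"),
  ionic = c("ARG", "ASP"),
  disulfide = c("CYS", "CYS")
)

#' Build a synthetic structure from a fixture specification
#'
#' Generates an ideal-geometry backbone (N, CA, C, O; bond lengths and
#' angles from standard peptide geometry, omega 180) under the requested
#' secondary-structure torsions, adds CB atoms, and plants side-chain atoms
#' so each requested interaction is detected at (numerically exactly) the
#' requested distance: hydrogen bonds as SER OG / THR OG1, ionic pairs as
#' ARG CZ / ASP CG-OD1-OD2, disulfides as CYS SG / SG.  Deterministic for a
#' given spec and seed.
#'
#' @param spec a `fixture_spec`
#' @param id structure label
#' @return a cleaned `prot_structure`
#' @export
make_fixture <- function(spec, id = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  tor <- if (spec$secondary_structure == "helix") c(phi = -57, psi = -47)
         else c(phi = -120, psi = 120)
  phi <- rep(tor["phi"], n)
  psi <- rep(tor["psi"], n)
  if (spec$torsion_jitter_deg > 0) {
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = globalenv()))
    set.seed(spec$seed)
    phi <- phi + stats::rnorm(n, 0, spec$torsion_jitter_deg)
    psi <- psi + stats::rnorm(n, 0, spec$torsion_jitter_deg)
  }
  # backbone chain by sequential placement
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, -1, 0), N[1, ], CA[1, ], 1.525, 111.2, 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         1.525, 111.2, phi[i])
  }
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                         psi[i] + 180)
  }
  CB <- t(vapply(1:n, function(i)
    place_atom(C[i, ], N[i, ], CA[i, ], 1.521, 110.5, -122), numeric(3)))

  resname <- rep("ALA", n)
  extra <- vector("list", n)     # extra side-chain atoms per residue
  for (pl in spec$planted_interactions) {
    i <- min(pl$i, pl$j); j <- max(pl$i, pl$j)
    ids <- PLANT_RESIDUES[[pl$kind]]
    resname[i] <- ids[1]; resname[j] <- ids[2]
    u <- CB[j, ] - CB[i, ]
    d_cb <- sqrt(sum(u^2))
    u <- u / d_cb
    reach <- d_cb - 1.8 - pl$distance   # distance left for atom_j's bond
    if (reach < 0.8 || reach > 3.0)
      stop("infeasible plant at positions ", i, "/", j, ": CB separation ",
           round(d_cb, 2), " A cannot host a ", pl$kind, " at ",
           pl$distance, " A")
    xi <- CB[i, ] + 1.8 * u
    xj <- xi + pl$distance * u
    add <- function(pos, atom, xyz)
      extra[[pos]] <<- rbind(extra[[pos]],
                             data.frame(atom = atom, x = xyz[1],
                                        y = xyz[2], z = xyz[3],
                                        stringsAsFactors = FALSE))
    if (pl$kind == "hydrogen_bond") {
      add(i, "OG", xi)
      add(j, "OG1", xj)
    } else if (pl$kind == "disulfide") {
      add(i, "SG", xi)
      add(j, "SG", xj)
    } else {                       # ionic: ARG CZ vs ASP carboxylate
      add(i, "CZ", xi)
      add(j, "CG", xj)
      perp <- pracma::cross(u, c(0, 0, 1))
      if (sqrt(sum(perp^2)) < 1e-6) perp <- pracma::cross(u, c(0, 1, 0))
      perp <- perp / sqrt(sum(perp^2))
      add(j, "OD1", xj + 1.25 * (0.5 * u + 0.866 * perp))
      add(j, "OD2", xj + 1.25 * (0.5 * u - 0.866 * perp))
    }
  }
  rows <- list()
  for (i in 1:n) {
    at <- data.frame(atom = c("N", "CA", "C", "O", "CB"),
                     x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1], CB[i, 1]),
                     y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2], CB[i, 2]),
                     z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3], CB[i, 3]),
                     stringsAsFactors = FALSE)
    if (!is.null(extra[[i]])) at <- rbind(at, extra[[i]])
    rows[[i]] <- data.frame(chain = "A", resno = i, insert = "",
                            resname = resname[i], atom = at$atom,
                            element = element_from_name(at$atom),
                            x = at$x, y = at$y, z = at$z, occ = 1,
                            stringsAsFactors = FALSE)
  }
  structure_from_atoms(do.call(rbind, rows), id = id)
}

#' Random rigid transform
#'
#' Draws a uniformly random rotation (QR of a Gaussian matrix,
#' sign-corrected to det +1) and a uniform translation in
#' [-span, span]^3.
#'
#' @param seed integer seed
#' @param span translation half-range, Angstrom
#' @return a `rigid_transform`
#' @export
random_rigid_transform <- function(seed = 1L, span = 20) {
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()))
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  rot <- qr.Q(qr_dec)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  rigid_transform(rot, stats::runif(3, -span, span))
}

#' Strip a site pair to alanine backbone
#'
#' Replaces the side chains of the two given residues by a bare CB and
#' renames them ALA: the standard way to turn a template structure into a
#' search target whose planted interaction has been removed.
#'
#' @param s a `prot_structure`
#' @param keys character vector of residue keys to strip
#' @return modified `prot_structure`
#' @export
strip_to_alanine <- function(s, keys) {
  a <- s$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  drop <- key %in% keys & !a$atom %in% c(BACKBONE_ATOMS, "CB")
  a <- a[!drop, , drop = FALSE]
  key <- residue_key(a$chain, a$resno, a$insert)
  a$resname[key %in% keys] <- "ALA"
  structure_from_atoms(a, id = s$id)
}
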