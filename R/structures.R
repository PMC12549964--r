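## Atom clouds: loading from PDB, synthetic globular clouds, rigid rotation.
## The lab frame is right-handed with the explosion origin at the cloud's
## center of mass; all detector geometry is defined in this frame.

#' Construct an AtomCloud
#'
#' Positions are translated so the center of mass sits at the origin (the
#' explosion and detector origin). Masses default to standard atomic
#' weights of the elements. Clouds outside the 100-4000 atom regime the
#' method targets are accepted with a warning.
#'
#' @param positions numeric N x 3 matrix, Angstrom.
#' @param elements integer atomic numbers, or character element symbols.
#' @param charges integer elementary charges (default all 0: pre-ionization).
#' @param masses numeric amu; defaults to standard atomic weights.
#' @param label character(1) identifier.
#' @return an \linkS4class{AtomCloud}.
#' @export
atomCloud <- function(positions, elements, charges = NULL, masses = NULL,
                      label = "cloud") {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (is.character(elements)) elements <- elementNumber(elements)
  elements <- as.integer(elements)
  if (is.null(masses)) masses <- elementMass(elements)
  if (is.null(charges)) charges <- integer(length(elements))
  n <- nrow(positions)
  if (n < 100L || n > 4000L)
    warning(sprintf(
      "cloud '%s' has %d atoms, outside the 100-4000 atom regime the method targets",
      label, n))
  com <- colSums(positions * masses) / sum(masses)
  positions <- sweep(positions, 2, com)
  new("AtomCloud", positions = positions, elements = elements,
      masses = as.numeric(masses), charges = as.integer(charges),
      label = label)
}

#' Read an atom cloud from a PDB file
#'
#' Parses ATOM/HETATM records. Waters are excluded by default, alternate
#' locations keep the first conformer, the first model of multi-model files
#' is used, and hydrogens are kept when present. The cloud is centered at
#' its center of mass.
#'
#' @param path PDB file path.
#' @param excludeWaters drop HOH/WAT/H2O residues (default TRUE).
#' @param label identifier; defaults to the file name without extension.
#' @return an \linkS4class{AtomCloud}.
#' @examples
#' pdb <- system.file("extdata", "synthetic-globule.pdb",
#'                    package = "ionFootprint")
#' cloud <- readPDB(pdb)   # 120-atom synthetic example structure
#' nAtoms(cloud)
#' @export
readPDB <- function(path, excludeWaters = TRUE, label = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  ## altloc: keep blank or the first letter encountered
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    alts <- sort(unique(at$alt[nzchar(at$alt) & !is.na(at$alt)]))
    keep <- is.na(at$alt) | !nzchar(at$alt) | at$alt == alts[1]
    at <- at[keep, , drop = FALSE]
  }
  if (excludeWaters)
    at <- at[!(at$resid %in% c("HOH", "WAT", "H2O")), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no atoms left after filtering (file may contain only waters)")
  sym <- trimws(at$elesy)
  missing <- is.na(sym) | !nzchar(sym)
  if (any(missing)) {
    ## fall back on the first letter of the atom name
    sym[missing] <- substr(trimws(at$elety[missing]), 1, 1)
  }
  Z <- tryCatch(elementNumber(sym), error = function(e) {
    bad <- which(is.na(match(
      paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 2))),
      .elementTable$symbol)))
    stop("unknown element symbol in '", path, "' at atom record(s) ",
         paste(utils::head(at$eleno[bad], 5), collapse = ", "),
         call. = FALSE)
  })
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  atomCloud(cbind(at$x, at$y, at$z), Z, label = label)
}

#' Synthesize a globular protein-like atom cloud
#'
#' Atoms are placed uniformly inside a sphere of radius
#' \code{radiusScale * nAtoms^(1/3)} (the n^(1/3) scaling keeps the number
#' density constant, as for globular proteins), with a rejection step
#' enforcing a minimum interatomic distance. Elements are drawn from a
#' protein-like composition. Reproducible from the seed.
#'
#' @param nAtoms number of atoms (>= 2).
#' @param compositionWeights named numeric vector of element fractions by
#'   atom count; default approximates average protein stoichiometry.
#' @param radiusScale radius prefactor, Angstrom (default 1.3, matching
#'   typical protein atomic number density of about 0.11 atoms/A^3).
#' @param minDistance minimum interatomic distance, Angstrom (default 1.0).
#' @param seed integer seed.
#' @param label identifier.
#' @return an \linkS4class{AtomCloud}.
#' @examples
#' cl <- synthesizeCloud(500, seed = 7)
#' nAtoms(cl)
#' @export
synthesizeCloud <- function(nAtoms,
                            compositionWeights = c(H = 0.50, C = 0.32,
                                                   N = 0.09, O = 0.085,
                                                   S = 0.005),
                            radiusScale = 1.3, minDistance = 1.0,
                            seed = NULL, label = "synthetic") {
  stopifnot(nAtoms >= 2)
  w <- compositionWeights / sum(compositionWeights)
  R <- radiusScale * nAtoms^(1 / 3)
  withSeed(seed, {
    Z <- elementNumber(sample(names(w), nAtoms, replace = TRUE, prob = w))
    pos <- matrix(NA_real_, nAtoms, 3)
    placed <- 0L
    attempts <- 0L
    maxAttempts <- 200L * nAtoms
    while (placed < nAtoms) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("cannot place ", nAtoms, " atoms with minimum distance ",
             minDistance, " A in radius ", signif(R, 4),
             " A; increase radiusScale")
      ## uniform in the ball via radius ~ U^(1/3)
      u <- stats::runif(1)^(1 / 3) * R
      dir <- stats::rnorm(3)
      p <- u * dir / sqrt(sum(dir^2))
      if (placed > 0L) {
        d2 <- rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2, p)^2)
        if (min(d2) < minDistance^2) next
      }
      placed <- placed + 1L
      pos[placed, ] <- p
    }
    atomCloud(pos, Z, label = label)
  })
}

#' Rigidly rotate an atom cloud about the origin
#'
#' @param cloud an \linkS4class{AtomCloud}.
#' @param q numeric(4) unit quaternion.
#' @return the rotated \linkS4class{AtomCloud}; pairwise distances and the
#'   center of mass are preserved.
#' @export
rotateCloud <- function(cloud, q) {
  assertUnitQuat(q)
  out <- cloud
  out@positions <- quatRotate(cloud@positions, q)
  out
}

#' Perturb atomic coordinates with isotropic Gaussian jitter
#'
#' Emulates the structural heterogeneity between explosion realizations:
#' each coordinate receives independent N(0, sigma^2) noise, after which
#' the cloud is re-centered at its center of mass.
#'
#' @param cloud an \linkS4class{AtomCloud}.
#' @param sigma jitter standard deviation, Angstrom (default 0.3).
#' @param seed integer seed.
#' @return a jittered \linkS4class{AtomCloud}.
#' @export
jitterCloud <- function(cloud, sigma = 0.3, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(cloud)
  n <- nAtoms(cloud)
  pos <- cloud@positions +
    withSeed(seed, matrix(stats::rnorm(3 * n, sd = sigma), n, 3))
  com <- colSums(pos * cloud@masses) / sum(cloud@masses)
  out <- cloud
  out@positions <- sweep(pos, 2, com)
  out
}
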