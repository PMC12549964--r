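## Desk-scale Coulomb-explosion stand-in: stochastic sudden ionization
## followed by classical softened-Coulomb N-body dynamics from rest.

## Coulomb constant e^2/(4 pi eps0) = 14.3996 eV*A, converted to internal
## amu*A^3/fs^2 units (1 amu*A^2/fs^2 = 103.6426966 eV).
.EV_PER_INTERNAL <- 103.6426966
.K_COULOMB_EV_A <- 14.3996
.K_INTERNAL <- .K_COULOMB_EV_A / .EV_PER_INTERNAL
## 1 A/fs = 1e5 m/s
.MS_PER_A_FS <- 1e5

#' Construct an XFEL pulse model
#'
#' @param fluence photons/nm^2 (default 5e6).
#' @param photonEnergy keV (default 2).
#' @param peakTime pulse peak, fs (default 20).
#' @param fwhm pulse FWHM, fs (default 10).
#' @return a \linkS4class{PulseModel}.
#' @export
pulseModel <- function(fluence = 5e6, photonEnergy = 2,
                       peakTime = 20, fwhm = 10) {
  new("PulseModel", fluence = fluence, photonEnergy = photonEnergy,
      peakTime = peakTime, fwhm = fwhm)
}

#' Assign stochastic per-atom charges (sudden ionization)
#'
#' Each atom's charge is drawn from a Poisson distribution whose mean is
#' proportional to an element weight (by default the atomic number Z, so
#' heavier atoms ionize more) and scaled so the expected total charge is
#' \code{meanIonization * nAtoms} at the reference fluence of 5e6
#' photons/nm^2. The expected total scales linearly with the pulse fluence
#' relative to that reference. Draws are capped at the element's electron
#' count, which biases the realized mean slightly below the target for
#' hydrogen-rich compositions (about 2 percent at the defaults).
#'
#' @param cloud an \linkS4class{AtomCloud}.
#' @param pulse a \linkS4class{PulseModel}; only the fluence enters (as a
#'   linear scaling of the expected ionization).
#' @param meanIonization target mean charges per atom at the reference
#'   fluence (default 1.2, just above the +1 per atom at which a protein
#'   is fully atomized).
#' @param ionizationWeights per-atom Poisson weights; default
#'   \code{atomElements(cloud)} (proportional to Z).
#' @param seed integer seed.
#' @return the cloud with integer charges assigned.
#' @export
assignCharges <- function(cloud, pulse = pulseModel(),
                          meanIonization = 1.2,
                          ionizationWeights = NULL, seed = NULL) {
  if (meanIonization <= 0) stop("meanIonization must be positive")
  n <- nAtoms(cloud)
  w <- if (is.null(ionizationWeights)) as.numeric(cloud@elements)
       else as.numeric(ionizationWeights)
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    stop("ionizationWeights must be ", n, " non-negative values, not all 0")
  fluenceScale <- pulse@fluence / 5e6
  lambda <- meanIonization * fluenceScale * n * w / sum(w)
  ch <- withSeed(seed, stats::rpois(n, lambda))
  ch <- pmin(ch, cloud@elements)  # cannot strip more electrons than exist
  out <- cloud
  out@charges <- as.integer(ch)
  out
}

#' Simulate a Coulomb explosion
#'
#' Velocity-Verlet integration of pairwise softened Coulomb repulsion
#' (Plummer potential k q_i q_j / sqrt(r^2 + eps^2)) among the charged
#' atoms, starting from rest, until \code{maxTime} or until the remaining
#' potential energy drops below \code{stopPotentialFrac} of the conserved
#' total. The step size starts at \code{dt} and grows adaptively (up to
#' 64 dt) as 1/sqrt(max acceleration) once the cloud has expanded and the
#' forces decayed; accuracy is guarded by the energy-conservation check
#' rather than by a fixed step. Neutral atoms feel and exert no force; by
#' default they are excluded from the ejecta (they are not accelerated and
#' will not reach a distant detector). Deterministic given the charged
#' cloud and \code{dt}.
#'
#' @param cloud a charged \linkS4class{AtomCloud} (see
#'   \code{\link{assignCharges}}).
#' @param dt base integration step, fs (default 0.5).
#' @param maxTime integration horizon, fs (default 250).
#' @param softening Plummer softening length, Angstrom (default 0.1).
#' @param stopPotentialFrac early-termination threshold: stop once the
#'   potential energy is below this fraction of the total (default 0.01).
#' @param includeNeutrals keep charge-0 atoms in the ejecta, at rest, with
#'   their radial position as direction (default FALSE).
#' @param realizationSeed integer recorded as metadata (the seed that
#'   produced the charge realization); the dynamics themselves are
#'   deterministic.
#' @return an \linkS4class{IonEjecta} with asymptotic unit directions and
#'   speeds in m/s.
#' @examples
#' cl <- synthesizeCloud(150, seed = 3)
#' cl <- assignCharges(cl, seed = 3)
#' ej <- simulateExplosion(cl)
#' median(ionSpeeds(ej))
#' @export
simulateExplosion <- function(cloud, dt = 0.5, maxTime = 250,
                              softening = 0.1, stopPotentialFrac = 0.01,
                              includeNeutrals = FALSE,
                              realizationSeed = NA_integer_) {
  stopifnot(dt > 0, maxTime > 0, softening >= 0)
  charged <- which(cloud@charges > 0L)
  if (length(charged) == 0L)
    stop("nothing to explode: the cloud carries no charge")
  res <- .explodeVerlet(cloud@positions[charged, , drop = FALSE],
                        as.numeric(cloud@charges[charged]),
                        cloud@masses[charged],
                        dt, maxTime, softening, .K_INTERNAL,
                        stopPotentialFrac)
  if (res$maxEnergyDrift > 0.05)
    stop(sprintf(
      "energy conservation violated (drift %.1f%% > 5%%); use a smaller dt",
      100 * res$maxEnergyDrift))
  vel <- res$velocities
  spd <- sqrt(rowSums(vel^2))
  if (any(spd == 0))
    spd[spd == 0] <- .Machine$double.eps  # degenerate: ion never moved
  dirs <- vel / spd
  speeds <- spd * .MS_PER_A_FS
  chargesOut <- cloud@charges[charged]
  massesOut <- cloud@masses[charged]
  if (includeNeutrals) {
    neutral <- which(cloud@charges == 0L)
    if (length(neutral)) {
      p <- cloud@positions[neutral, , drop = FALSE]
      pn <- sqrt(rowSums(p^2))
      pn[pn == 0] <- 1
      dirs <- rbind(dirs, p / pn)
      speeds <- c(speeds, rep(0, length(neutral)))
      chargesOut <- c(chargesOut, cloud@charges[neutral])
      massesOut <- c(massesOut, cloud@masses[neutral])
    }
  }
  ej <- new("IonEjecta", directions = dirs, speeds = speeds,
            charges = as.integer(chargesOut), masses = massesOut,
            sourceLabel = cloud@label,
            realizationSeed = as.integer(realizationSeed))
  attr(ej, "diagnostics") <- list(
    kineticEnergy = res$kineticEnergy,
    potentialEnergy = res$potentialEnergy,
    totalEnergy0 = res$totalEnergy0,
    maxEnergyDrift = res$maxEnergyDrift,
    momentum = res$momentum,
    timeRun = res$timeRun)
  ej
}

#' Integration diagnostics of an explosion
#'
#' @param ejecta an \linkS4class{IonEjecta} returned by
#'   \code{\link{simulateExplosion}}.
#' @return list with kinetic/potential energy (internal amu A^2/fs^2
#'   units), initial total energy, maximum relative energy drift, final
#'   total momentum (amu A/fs) and the integrated time (fs).
#' @export
explosionDiagnostics <- function(ejecta) {
  d <- attr(ejecta, "diagnostics")
  if (is.null(d)) stop("no diagnostics attached to this ejecta")
  d
}

#' Rigidly rotate ejecta directions
#'
#' Rotating the ejecta after the explosion is equivalent to having exploded
#' the rotated cloud: the dynamics are rotation-equivariant.
#'
#' @param ejecta an \linkS4class{IonEjecta}.
#' @param q numeric(4) unit quaternion.
#' @return the rotated \linkS4class{IonEjecta}.
#' @export
rotateEjecta <- function(ejecta, q) {
  assertUnitQuat(q)
  out <- ejecta
  out@directions <- quatRotate(ejecta@directions, q)
  out
}
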