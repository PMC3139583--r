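# Line-source approximation (LSA) of extracellular potentials in a purely
# resistive, homogeneous medium.  Each compartment is a finite line of
# uniformly distributed transmembrane current; superposition over
# compartments is exact by linearity of the medium.

#' Per-compartment LSA coefficients
#'
#' Geometric transfer coefficients phi_i = coef_i * I_i for an electrode at a
#' fixed position: `coef_i = rho / (4 pi L) * ln |(sqrt(h^2+r^2) - h) /
#' (sqrt(l^2+r^2) - l)|` with `r` the radial distance of the electrode from
#' the compartment axis, `h` and `l = h + L` the axial distances to the two
#' ends. For an electrode nearly collinear with the segment (r -> 0 outside
#' the segment) the expression reduces to the regularized log form with `r`
#' floored at 10 nm, which is the standard way to tame the logarithmic
#' singularity.
#'
#' @param cell a [CellModel-class] object (for the segment geometry).
#' @param electrode an [Electrode-class] object.
#' @param medium a [Medium-class] object.
#' @return numeric vector, uV per nA, one per compartment.
#' @export
lsaCoefficients <- function(cell, electrode, medium = grclfp::medium()) {
  cp <- cell@compartments
  pos <- electrode@position
  n <- nrow(cp)
  coef <- numeric(n)
  rho <- medium@resistivity            # Ohm*cm
  for (i in seq_len(n)) {
    a <- c(cp$x0[i], cp$y0[i], cp$z0[i])
    b <- c(cp$x1[i], cp$y1[i], cp$z1[i])
    L <- sqrt(sum((b - a)^2))
    u <- (b - a) / L
    w <- pos - a
    h <- sum(w * u)                    # axial coordinate of electrode, um
    r2 <- sum(w * w) - h^2
    r2 <- max(r2, 0)
    if (h > 0 && h < L && sqrt(r2) < cp$diam[i] / 2)
      stop("electrode lies inside compartment ", i)
    r2 <- max(r2, 1e-2^2)              # regularization floor, 0.01 um
    # distances from electrode to the two segment ends along the axis
    hh <- -h                           # to the proximal end
    ll <- L - h                        # to the distal end
    num <- sqrt(hh^2 + r2) - hh
    den <- sqrt(ll^2 + r2) - ll
    # rho [Ohm*cm] * I [nA] / (4 pi L [um]) -> convert to uV:
    # Ohm*cm * nA / um = 1e-4 m * 1e-9 A * Ohm / 1e-6 m = 0.1 uV... do it
    # explicitly: phi[V] = rho[Ohm*m]/(4 pi L[m]) * I[A] * ln(.)
    scale <- (rho * 1e-2) / (4 * pi * (L * 1e-6)) * 1e-9 * 1e6  # uV per nA
    coef[i] <- scale * log(abs(num / den))
  }
  coef
}

#' Extracellular potential of each compartment (LSA)
#'
#' Applies the line-source approximation to every compartment of a simulation
#' run, giving the potential each compartment alone generates at the
#' electrode. The total potential is their sum (superposition is exact).
#'
#' @param currents a [CompartmentCurrents-class] object.
#' @param electrode an [Electrode-class] object.
#' @param medium a [Medium-class] object.
#' @return matrix (time step x compartment) of potentials, uV.
#' @examples
#' \donttest{
#' cell <- attachSynapses(buildGranuleCell(),
#'                        stimulusProtocol("single_pulse", 4, 4),
#'                        plasticityState(1, "normal"))
#' cc <- simulateCell(cell, 60, seed = 1)
#' phi <- lsaPotential(cc, electrode())
#' }
#' @export
lsaPotential <- function(currents, electrode, medium = grclfp::medium()) {
  stopifnot(is(currents, "CompartmentCurrents"))
  coef <- lsaCoefficients(currents@cell, electrode, medium)
  sweep(currents@im, 2, coef, `*`)
}

#' Compose a single-cell kernel from compartment potentials
#'
#' Sums the per-compartment extracellular potentials over the compartment
#' groups seen by the electrode view: a granular-layer electrode sums
#' dendrites + soma + axon hillock (the spike sink side), an electrode in the
#' ascending-axon bundle sums the axonal compartments (the return source
#' side). The spike deflection polarity is opposite in the two views.
#'
#' @param potentials matrix from [lsaPotential()] (time step x compartment).
#' @param electrode the [Electrode-class] the potentials were computed for.
#' @param cell the [CellModel-class] (for compartment groups).
#' @param dt_ms sampling step of the source simulation.
#' @param combo integer c(n_mf, n_goc) recorded in the kernel metadata.
#' @param onset_ms stimulus onset.
#' @return A [Kernel-class] object.
#' @export
composeKernel <- function(potentials, electrode, cell, dt_ms,
                          combo = c(NA_integer_, NA_integer_), onset_ms = 0) {
  grp <- cell@compartments$group
  keep <- if (electrode@view == "granular_layer_sink")
    grp %in% c("dendrite", "soma", "hillock") else grp == "axon"
  if (ncol(potentials) != length(grp))
    stop("potential matrix does not match the cell (mismatched sampling?)")
  tr <- rowSums(potentials[, keep, drop = FALSE])
  new("Kernel", trace = tr, dt = dt_ms, combo = as.integer(combo),
      onset_ms = onset_ms, electrode = electrode)
}

#' View-masked LSA coefficients
#'
#' LSA coefficients with compartments outside the electrode's view zeroed;
#' multiplying the transmembrane current matrix by this vector gives the
#' composed kernel trace directly. Used by the fast simulation path.
#'
#' @inheritParams lsaCoefficients
#' @return numeric vector, uV per nA.
#' @export
viewCoefficients <- function(cell, electrode, medium = grclfp::medium()) {
  coef <- lsaCoefficients(cell, electrode, medium)
  grp <- cell@compartments$group
  keep <- if (electrode@view == "granular_layer_sink")
    grp %in% c("dendrite", "soma", "hillock") else grp == "axon"
  coef[!keep] <- 0
  coef
}

#' Point-source extracellular potential
#'
#' Closed-form monopole potential `rho I / (4 pi r)`, the far-field limit the
#' line-source approximation must converge to.
#'
#' @param i_nA current, nA.
#' @param r_um distance, um.
#' @param medium a [Medium-class] object.
#' @return potential, uV.
#' @export
pointSourcePotential <- function(i_nA, r_um, medium = grclfp::medium()) {
  (medium@resistivity * 1e-2) / (4 * pi * (r_um * 1e-6)) * (i_nA * 1e-9) * 1e6
}
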