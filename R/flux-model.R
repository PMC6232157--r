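## Coupled water/glycerol flux model.
##
## Van 't Hoff ideal osmometry with a constant surface area A(V0) and an
## osmotically inactive volume fraction beta:
##
##   dV/dt  = Pf  * A * Vw * (osm_in - osm_out_total)
##   dNg/dt = Pgly * A * (c_gly_out - c_gly_in)
##
## with osm_in = (N_imp + Ng) / (V - beta*V0), c_gly_in = Ng / (V - beta*V0),
## osm_out_total = osm_out_impermeant + c_gly_out (infinite external bath).
## Internally the state is non-dimensionalized (v = V/V0) and concentrations
## carried in mol/cm^3, so Pf/Pgly in cm/s, A in cm^2 and V0 in cm^3 combine
## consistently.

#' Simulate a relative-volume trajectory under osmotic shock
#'
#' Integrates the coupled two-parameter water/glycerol flux system and
#' returns relative volume and internal glycerol concentration over time.
#' With an inward glycerol gradient the solution shows the classical biphasic
#' signature: fast osmotic shrinkage followed by slower swelling as glycerol
#' (and water) re-enter.
#'
#' @param params a [FluxParams-class] (Pf, Pgly in cm/s, Vw in cm^3/mol).
#' @param geom a [VesicleGeometry-class] (V0 in cm^3, A in cm^2, beta).
#' @param shock a [ShockCondition-class]; impermeant osmolarities in osmol/L,
#'   glycerol in mol/L.
#' @param times output times in seconds, starting at 0.
#' @param rtol,atol integrator tolerances (adaptive stiff-capable `lsoda`).
#' @return A [VolumeTrajectory-class] with `vRel[1] == 1`.
#' @examples
#' geom <- sphereGeometry(6.5e-11, inactiveFraction = 0.55)
#' shock <- shockCondition(osmOutImpermeant = 0.7, cGlyOut = 1.05,
#'                         osmInImpermeant0 = 1.4)
#' traj <- simulateVolumeTrace(fluxParams(5e-3, 2e-5), geom, shock,
#'                             times = seq(0, 20, by = 0.05))
#' @export
simulateVolumeTrace <- function(params, geom, shock, times,
                                rtol = 1e-8, atol = rtol * 1e-4) {
  stopifnot(is(params, "FluxParams"), is(geom, "VesicleGeometry"),
            is(shock, "ShockCondition"))
  validObject(params); validObject(geom); validObject(shock)
  times <- as.numeric(times)
  if (length(times) < 2L || times[1L] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and be strictly increasing")

  beta <- geom@inactiveFraction
  aOverV0 <- geom@area / geom@v0            # 1/cm
  ml <- 1e-3                                # mol/L -> mol/cm^3
  osmOut <- (shock@osmOutImpermeant + shock@cGlyOut) * ml
  cgOut <- shock@cGlyOut * ml
  nImp <- shock@osmInImpermeant0 * ml * (1 - beta)  # N_imp / V0, mol/cm^3
  y0 <- c(v = 1, q = shock@cGlyIn0 * ml * (1 - beta)) # q = Ng / V0

  deriv <- function(t, y, p) {
    vact <- y[[1L]] - beta
    cg <- y[[2L]] / vact
    osmIn <- (nImp + y[[2L]]) / vact
    list(c(params@pf * aOverV0 * params@vw * (osmIn - osmOut),
           params@pgly * aOverV0 * (cgOut - cg)))
  }

  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop(sprintf(paste0("volume ODE solver failed (istate = %d); last state:",
                        " t = %.4g, vRel = %.6g"),
                 istate[1L], sol[nrow(sol), 1L], sol[nrow(sol), 2L]))
  if (nrow(sol) < length(times))
    stop("volume ODE solver returned a truncated solution")

  vrel <- unname(sol[, 2L])
  q <- unname(sol[, 3L])
  newVolumeTrajectory(times = times, vRel = vrel,
                      cGlyIn = q / (vrel - beta) / ml,
                      inactiveFraction = beta)
}

#' Closed-form osmotic equilibrium volume
#'
#' For an impermeant-only shock the steady state of the flux model follows
#' from the osmotic balance `osm_in = osm_out`:
#' `vRel = beta + (1 - beta) * osm_in_0 / osm_out`. When external glycerol is
#' present and Pgly > 0, glycerol equilibrates (`c_in -> c_out`) and drops out
#' of the balance, so the same expression holds with the impermeant
#' osmolarities alone.
#'
#' @param geom a [VesicleGeometry-class].
#' @param shock a [ShockCondition-class] with `osmOutImpermeant > 0`.
#' @return The equilibrium relative volume.
#' @export
equilibriumVolume <- function(geom, shock) {
  stopifnot(is(geom, "VesicleGeometry"), is(shock, "ShockCondition"))
  if (shock@osmOutImpermeant <= 0)
    stop("equilibrium requires a positive external impermeant osmolarity")
  beta <- geom@inactiveFraction
  beta + (1 - beta) * shock@osmInImpermeant0 / shock@osmOutImpermeant
}
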