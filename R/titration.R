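## Tonicity arithmetic, Hill pH-titration and Arrhenius temperature analysis.

#' Tonicity of an osmotic challenge
#'
#' `Lambda = osm_after / osm_before`: the ratio of the final to the initial
#' external osmolarity. For the standard equal-volume stopped-flow mix of a
#' 1.4 osmol/L suspension with a 2.1 osmol/L challenge solution,
#' `tonicity(1.4, equalVolumeMix(1.4, 2.1))` gives 1.25.
#'
#' @param osmBefore external osmolarity before the challenge, osmol/L (> 0).
#' @param osmAfter external osmolarity after mixing, osmol/L.
#' @return Lambda, unitless.
#' @export
tonicity <- function(osmBefore, osmAfter) {
  if (osmBefore <= 0) stop("osmBefore must be > 0")
  osmAfter / osmBefore
}

#' External osmolarity after an equal-volume mix
#'
#' Mixing equal volumes of two solutions yields the mean of their
#' osmolarities; an optional additive buffer term covers assays where the
#' buffer contributes measurably (ignored by default, consistent with
#' sorbitol-only arithmetic).
#'
#' @param osmA,osmB osmolarities of the two solutions, osmol/L.
#' @param buffer additional buffer osmolarity present in both, osmol/L.
#' @return osmolarity of the mixture, osmol/L.
#' @export
equalVolumeMix <- function(osmA, osmB, buffer = 0) {
  (osmA + osmB) / 2 + buffer
}

#' Ideal (van 't Hoff) osmolarity of a solute
#'
#' Molar concentration times the dissociation number: 2 for 1:1 salts such as
#' NaCl (so 0.5 M NaCl is iso-osmotic with 1 M glycerol), 1 for
#' non-electrolytes.
#'
#' @param conc molar concentration, mol/L.
#' @param solute one of `"NaCl"`, `"KCl"`, `"CaCl2"`, `"glycerol"`,
#'   `"sorbitol"`, `"mannitol"`, `"sucrose"`, or any name when `i` is given.
#' @param i optional explicit dissociation number overriding the table.
#' @return osmolarity, osmol/L.
#' @export
idealOsmolarity <- function(conc, solute = "glycerol", i = NULL) {
  table <- c(NaCl = 2, KCl = 2, CaCl2 = 3, glycerol = 1, sorbitol = 1,
             mannitol = 1, sucrose = 1)
  if (is.null(i)) {
    if (!solute %in% names(table))
      stop("unknown solute '", solute, "'; supply a dissociation number i")
    i <- table[[solute]]
  }
  conc * i
}

#' Normalize glycerol permeabilities for titration analysis
#'
#' Elementwise `(Pgly - Pgly_control) / Pgly_max`, the per-dataset
#' normalization used before Hill fitting.
#'
#' @param pgly glycerol permeabilities, cm/s.
#' @param pglyControl control-strain permeabilities, same length or scalar.
#' @param pglyMax normalization amplitude, cm/s (> 0).
#' @return normalized permeabilities.
#' @export
normalizePgly <- function(pgly, pglyControl, pglyMax) {
  if (pglyMax <= 0) stop("pglyMax must be > 0")
  (pgly - pglyControl) / pglyMax
}

#' Hill curve in pH
#'
#' `p(pH) = pMax / (1 + 10^(n * (pH - pK)))`. With `n > 0` the curve rises
#' towards acidic pH (acid-activated transport); with `n < 0` it rises
#' towards alkaline pH.
#'
#' @param ph pH values.
#' @param pK midpoint pH.
#' @param n signed Hill coefficient.
#' @param pMax amplitude.
#' @return curve values, bounded in `[0, pMax]`.
#' @export
hillCurve <- function(ph, pK, n, pMax = 1) {
  pMax / (1 + 10^(n * (ph - pK)))
}

#' Fit a Hill equation to a pH titration
#'
#' Levenberg-Marquardt fit of [hillCurve()] to normalized permeabilities.
#' Starting values come from the data (amplitude from the range, direction
#' from the pH/permeability correlation, pK from the half-maximum crossing).
#' Data with no detectable pH dependence are flagged degenerate.
#'
#' @param ph pH values (at least 4 distinct).
#' @param pNorm normalized permeabilities, same length.
#' @return A [HillFit-class].
#' @examples
#' ph <- seq(4.5, 8, length.out = 8)
#' hillFit(ph, hillCurve(ph, pK = 6, n = 2))
#' @export
hillFit <- function(ph, pNorm) {
  if (length(ph) != length(pNorm)) stop("ph and pNorm must match in length")
  if (length(unique(ph)) < 4L) stop("need at least 4 distinct pH points")
  if (diff(range(pNorm)) <= 1e-9 * max(1, max(abs(pNorm))) ||
      abs(stats::cor(ph, pNorm)) < 1e-8) {
    return(new("HillFit", pK = NA_real_, n = NA_real_,
               pMax = mean(pNorm), rss = sum((pNorm - mean(pNorm))^2),
               degenerate = TRUE))
  }
  pMax0 <- max(pNorm)
  n0 <- if (stats::cor(ph, pNorm) < 0) 1.5 else -1.5
  pK0 <- ph[which.min(abs(pNorm - pMax0 / 2))]
  fit <- minpack.lm::nlsLM(
    pNorm ~ pMax / (1 + 10^(n * (ph - pK))),
    start = list(pMax = pMax0, n = n0, pK = pK0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  new("HillFit", pK = est[["pK"]], n = est[["n"]], pMax = est[["pMax"]],
      rss = sum(stats::residuals(fit)^2), degenerate = FALSE)
}

#' Activation energy from an Arrhenius plot
#'
#' Ordinary least squares of `ln Pgly` on `1/T`; the slope times the gas
#' constant gives the activation energy, reported with a positive sign for
#' thermally activated transport: `Ea = -slope * R`, in kJ/mol.
#'
#' @param temps temperatures in K (at least 2; 3 or more for a standard
#'   error).
#' @param pgly permeabilities, all > 0, same length.
#' @return An [ArrheniusFit-class].
#' @examples
#' temps <- seq(283, 307, by = 4)
#' arrheniusEa(temps, exp(3 - 20e3 / (8.314 * temps)))
#' @export
arrheniusEa <- function(temps, pgly) {
  if (length(temps) != length(pgly))
    stop("temps and pgly must match in length")
  if (length(temps) < 2L) stop("need at least 2 temperatures")
  if (any(pgly <= 0)) stop("all pgly values must be > 0")
  R <- 8.314
  invT <- 1 / temps
  fit <- stats::lm(log(pgly) ~ invT)
  slope <- stats::coef(fit)[["invT"]]
  seSlope <- if (length(temps) > 2L) {
    ## summary.lm warns on exact data; the SE (0) is still well defined
    suppressWarnings(summary(fit)$coefficients["invT", "Std. Error"])
  } else NA_real_
  new("ArrheniusFit", ea = -slope * R / 1000,
      lnPrefactor = stats::coef(fit)[["(Intercept)"]], slope = slope,
      seEa = seSlope * R / 1000)
}
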