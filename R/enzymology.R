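# Small exact computations around the lyase assays: DM/DAc from released
# substituents, substrate-to-bond-concentration conversion, specific
# activity from A235 slopes, and Michaelis-Menten fitting via the
# Hanes-Woolf linearization.

#' DM and DAc from released methanol and acetate
#'
#' DM is the percentage of methoxylated GalA moieties out of total GalA;
#' DAc the percentage of acetyl-substituted GalA. With saponification
#' releasing one methanol per methyl ester and one acetate per acetyl
#' group, `DM = 100 * methanol / gala`, `DAc = 100 * acetate / gala`.
#'
#' @param methanol,acetate Released substituent, umol/g dry matter.
#' @param gala GalA content, umol/g dry matter (> 0).
#' @return Named numeric vector `c(dm = , dac = )` in percent.
#' @export
dm_dac <- function(methanol, acetate, gala) {
  if (any(gala <= 0)) stop("GalA content must be > 0", call. = FALSE)
  c(dm = 100 * methanol / gala, dac = 100 * acetate / gala)
}

#' GalA-bond concentration of a pectin solution
#'
#' Converts a mass concentration to the molar concentration of bonds
#' between GalA moieties using the substrate's GalA content. For polymeric
#' pectin, bonds per GalA approaches 1, so bonds are taken equal to GalA
#' moles (the (n-1)/n end correction is negligible and no chain-length
#' assay informs it).
#'
#' @param substrate_g_per_l Substrate concentration, g/L.
#' @param gala_umol_per_g GalA content, umol/g dry matter (> 0), e.g. from
#'   [pectin_presets()].
#' @return Bond concentration in mM GalA.
#' @examples
#' bond_concentration(1, 3875)   # ~3.88 mM, 1 g/L apple pectin
#' @export
bond_concentration <- function(substrate_g_per_l, gala_umol_per_g) {
  if (any(gala_umol_per_g <= 0)) stop("GalA content must be > 0",
                                      call. = FALSE)
  substrate_g_per_l * gala_umol_per_g / 1000
}

#' Specific activity from an A235 slope
#'
#' One unit (U) is the amount of enzyme forming one umol of
#' 4,5-unsaturated galacturonide per minute. Beer-Lambert inversion of the
#' absorbance slope gives the rate in M/min, the reaction volume converts
#' to umol/min, and division by the enzyme mass gives U/mg.
#'
#' @param slope_per_min Absorbance change at 235 nm per minute (>= 0).
#' @param extinction Molar extinction coefficient, default 5500 1/(M cm).
#' @param path_cm Optical path length, cm.
#' @param volume_l Reaction volume, L.
#' @param enzyme_mg Enzyme mass in the reaction, mg.
#' @return Specific activity, U/mg.
#' @examples
#' rate_from_A235(0.055, volume_l = 1e-3, enzyme_mg = 0.001)  # 10 U/mg
#' @export
rate_from_A235 <- function(slope_per_min, extinction = 5500, path_cm = 1,
                           volume_l = 1e-3, enzyme_mg = 1) {
  if (any(slope_per_min < 0)) stop("slope must be >= 0", call. = FALSE)
  if (extinction <= 0 || path_cm <= 0 || volume_l <= 0 || enzyme_mg <= 0)
    stop("assay configuration values must be > 0", call. = FALSE)
  rate_M <- slope_per_min / (extinction * path_cm)
  rate_M * volume_l * 1e6 / enzyme_mg
}

#' Michaelis-Menten fit via the Hanes-Woolf linearization
#'
#' Least-squares regression of `S/v` on `S`: the slope is `1/Vmax` and the
#' intercept `Km/Vmax`. This mirrors the classical analysis of lyase
#' kinetics on pectin substrates; [michaelis_menten_nls()] provides a
#' nonlinear cross-check for diagnostics.
#'
#' When `enzyme_molar_mass` (g/mol) and `vmax_unit` permit, `kcat` is
#' derived from Vmax: with v in U/mg (umol/min/mg),
#' `kcat = Vmax * MW / 60000` per second.
#'
#' @param S Substrate concentrations (mM GalA bonds; > 0).
#' @param v Initial rates (> 0), any consistent unit.
#' @param enzyme_molar_mass Optional enzyme molar mass in g/mol for kcat
#'   (assumes v in umol/min/mg).
#' @return List of class `kinetic_fit`: `Km` (mM), `Vmax` (unit of v),
#'   `kcat` (1/s or NA), `r_squared` of the linearized fit.
#' @export
hanes_woolf <- function(S, v, enzyme_molar_mass = NULL) {
  if (length(S) != length(v) || length(S) < 3L)
    stop("need >= 3 matched (S, v) points", call. = FALSE)
  if (any(S <= 0)) stop("S must be > 0", call. = FALSE)
  if (any(v <= 0)) stop("v must be > 0 (Hanes-Woolf transform divides by v)",
                        call. = FALSE)
  y <- S / v
  fit <- stats::lm(y ~ S)
  slope <- stats::coef(fit)[["S"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  if (slope <= 0) stop("nonpositive Hanes-Woolf slope: data do not follow ",
                       "saturable kinetics", call. = FALSE)
  vmax <- 1 / slope
  km <- intercept / slope
  kcat <- if (is.null(enzyme_molar_mass)) NA_real_
          else vmax * enzyme_molar_mass / 60000
  structure(list(Km = km, Vmax = vmax, kcat = kcat,
                 r_squared = summary(fit)$r.squared),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km = %.3g mM, Vmax = %.3g%s (R2 %.3f)\n",
              x$Km, x$Vmax,
              if (is.na(x$kcat)) "" else sprintf(", kcat = %.3g 1/s", x$kcat),
              x$r_squared))
  invisible(x)
}

#' Nonlinear Michaelis-Menten cross-check
#'
#' Direct `nls` fit of `v = Vmax * S / (Km + S)`, initialized from the
#' Hanes-Woolf estimates. Diagnostic companion to [hanes_woolf()], which
#' remains the primary fit.
#'
#' @inheritParams hanes_woolf
#' @return List with `Km` and `Vmax` from the nonlinear fit.
#' @export
michaelis_menten_nls <- function(S, v) {
  start <- hanes_woolf(S, v)
  fit <- stats::nls(v ~ Vmax * S / (Km + S),
                    start = list(Vmax = start$Vmax, Km = start$Km))
  as.list(stats::coef(fit))[c("Km", "Vmax")]
}

#' Synthetic Michaelis-Menten rate data
#'
#' Generates initial-rate observations `v = Vmax * S / (Km + S)` with
#' optional multiplicative Gaussian noise, for parameter-recovery studies.
#'
#' @param S Substrate concentrations (mM).
#' @param Km,Vmax True parameters.
#' @param noise_cv Coefficient of variation of multiplicative noise (0 for
#'   noiseless data).
#' @param seed Optional integer seed.
#' @return data.frame `S, v`.
#' @export
simulate_mm_rates <- function(S, Km, Vmax, noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- Vmax * S / (Km + S)
  if (noise_cv > 0)
    v <- v * pmax(1e-8, 1 + stats::rnorm(length(S), 0, noise_cv))
  data.frame(S = S, v = v)
}
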