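# Gibbs free energy of complete nitrification under in situ conditions.
#
# The reaction is the balanced one-step sum of ammonia oxidation and nitrite
# oxidation:  NH4+ + 2 O2 -> NO3- + 2 H+ + H2O.
# Energetics follow dG = dG0(T) + R T ln Q with Q built from activities, and
# dG0(T) from a constant-dH van't Hoff correction of the 25 C formation data.

#' Load standard-state thermodynamic constants
#'
#' Reads the shipped table of standard Gibbs free energies and enthalpies of
#' formation (25 \eqn{^\circ}C, 1 bar) for the species of the complete
#' nitrification reaction, or a user-supplied table in the same format
#' (tab-separated, `#` comment header, columns `species`, `dGf_kJ_mol`,
#' `dHf_kJ_mol`).
#'
#' @param path Path to a constants table. Default: the table shipped with the
#'   package (values from Amend & Shock 2001).
#' @return A list of class `thermo_constants` with elements
#'   `standard_gibbs_formation` and `standard_enthalpy_formation` (named
#'   numeric vectors, kJ/mol) and `gas_constant` (kJ/mol/K).
#' @examples
#' tc <- thermo_constants()
#' tc$standard_gibbs_formation[["NO3-"]]
#' @export
thermo_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thermo_constants.tsv", package = "nitrocrust")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("species", "dGf_kJ_mol", "dHf_kJ_mol") %in% names(tab)))
  out <- list(
    standard_gibbs_formation    = stats::setNames(tab$dGf_kJ_mol, tab$species),
    standard_enthalpy_formation = stats::setNames(tab$dHf_kJ_mol, tab$species),
    gas_constant                = 0.0083145
  )
  required <- names(nitrification_reaction())
  missing <- setdiff(required, tab$species)
  if (length(missing) > 0) {
    stop("constants table lacks required species: ", paste(missing, collapse = ", "))
  }
  structure(out, class = "thermo_constants")
}

#' Stoichiometry of complete nitrification
#'
#' Balanced reaction \eqn{NH_4^+ + 2 O_2 \rightarrow NO_3^- + 2 H^+ + H_2O};
#' products carry positive, reactants negative coefficients.
#'
#' @return Named numeric vector of stoichiometric coefficients.
#' @export
nitrification_reaction <- function() {
  c("NH4+" = -1, "O2(aq)" = -2, "NO3-" = 1, "H+" = 2, "H2O(l)" = 1)
}

#' Standard Gibbs free energy of a reaction at temperature
#'
#' Evaluates \eqn{\Delta G^\circ(T)} from 25 \eqn{^\circ}C formation data by
#' the constant-\eqn{\Delta H^\circ} van't Hoff (Gibbs-Helmholtz)
#' approximation:
#' \deqn{\Delta G^\circ(T) = \Delta H^\circ_{298} -
#'   T (\Delta H^\circ_{298} - \Delta G^\circ_{298}) / 298.15,}
#' with \eqn{T} in kelvin. At 25 \eqn{^\circ}C this reduces exactly to
#' \eqn{\sum \nu_i \Delta G^\circ_{f,i}}.
#'
#' @param constants A [thermo_constants()] object.
#' @param reaction Named numeric vector of stoichiometric coefficients
#'   (products positive, reactants negative); default the complete
#'   nitrification reaction.
#' @param temperature Temperature in degrees Celsius.
#' @return \eqn{\Delta G^\circ(T)} in kJ/mol.
#' @export
standard_gibbs_at_temperature <- function(constants,
                                          reaction = nitrification_reaction(),
                                          temperature = 25) {
  stopifnot(inherits(constants, "thermo_constants"),
            is.numeric(reaction), !is.null(names(reaction)),
            temperature > -273.15)
  unknown <- setdiff(names(reaction), names(constants$standard_gibbs_formation))
  if (length(unknown) > 0) {
    stop("unknown species in reaction: ", paste(unknown, collapse = ", "))
  }
  dg298 <- sum(reaction * constants$standard_gibbs_formation[names(reaction)])
  dh298 <- sum(reaction * constants$standard_enthalpy_formation[names(reaction)])
  tk <- temperature + 273.15
  dh298 - tk * (dh298 - dg298) / 298.15
}

#' In situ reaction conditions for nitrification
#'
#' Bundles the temperature, pressure, and chemical activities at which the
#' Gibbs free energy of complete nitrification is evaluated. Activities are
#' taken equal to molar concentrations (ideal dilute solution) and the water
#' activity defaults to 1. The default pH of 7.9 is a deep Atlantic
#' seawater-like value; pressure is carried for documentation and only enters
#' the energy when a constant-volume correction is requested in
#' [gibbs_free_energy()].
#'
#' @param activity_nh4,activity_o2,activity_no3 Activities (mol/L) of
#'   ammonium, dissolved oxygen, and nitrate.
#' @param temperature Temperature, degrees Celsius (default 1.5, the cold
#'   ridge-flank aquifer value).
#' @param pressure Pressure, bar (default 450, ~4.5 km water depth).
#' @param ph pH (dimensionless, in \[0, 14\]); the proton activity is
#'   \eqn{10^{-pH}}.
#' @param activity_h2o Water activity (default 1).
#' @return A list of class `reaction_conditions`.
#' @examples
#' rc <- reaction_conditions(activity_nh4 = 1.5e-7, activity_o2 = 2.1e-4,
#'                           activity_no3 = 2.11e-5)
#' @export
reaction_conditions <- function(activity_nh4, activity_o2, activity_no3,
                                temperature = 1.5, pressure = 450,
                                ph = 7.9, activity_h2o = 1) {
  acts <- c(activity_nh4, activity_o2, activity_no3, activity_h2o)
  if (any(!is.finite(acts)) || any(acts <= 0)) {
    stop("all activities must be finite and > 0")
  }
  stopifnot(temperature > -273.15, ph >= 0, ph <= 14, pressure > 0)
  structure(list(
    temperature = temperature, pressure = pressure,
    activity_nh4 = activity_nh4, activity_o2 = activity_o2,
    activity_no3 = activity_no3, ph = ph, activity_h2o = activity_h2o
  ), class = "reaction_conditions")
}

#' Gibbs free energy of complete nitrification at in situ conditions
#'
#' \eqn{\Delta G = \Delta G^\circ(T) + R T \ln Q} with the reaction quotient
#' \deqn{Q = \frac{a_{NO_3^-} \, a_{H^+}^2 \, a_{H_2O}}
#'               {a_{NH_4^+} \, a_{O_2}^2},}
#' \eqn{a_{H^+} = 10^{-pH}}. A negative result means the reaction is
#' thermodynamically favorable. The pressure correction is off by default; set
#' `pressure_correction = TRUE` with a molar volume change to add
#' \eqn{\Delta V (P - 1)} (constant-\eqn{\Delta V}), which is small relative
#' to the hundreds of kJ/mol margin in the crustal setting.
#'
#' @param constants A [thermo_constants()] object.
#' @param conditions A [reaction_conditions()] object.
#' @param pressure_correction Logical; apply a constant-volume pressure term?
#' @param reaction_delta_v Reaction volume change, cm\eqn{^3}/mol (used only
#'   when `pressure_correction` is TRUE).
#' @return \eqn{\Delta G} in kJ per mole of NH4+ oxidized.
#' @examples
#' tc <- thermo_constants()
#' rc <- reaction_conditions(activity_nh4 = 1.5e-7, activity_o2 = 2.1e-4,
#'                           activity_no3 = 2.11e-5)
#' gibbs_free_energy(tc, rc)  # strongly negative: favorable
#' @export
gibbs_free_energy <- function(constants, conditions,
                              pressure_correction = FALSE,
                              reaction_delta_v = 0) {
  stopifnot(inherits(constants, "thermo_constants"),
            inherits(conditions, "reaction_conditions"))
  dg0 <- standard_gibbs_at_temperature(constants, nitrification_reaction(),
                                       conditions$temperature)
  tk <- conditions$temperature + 273.15
  a_h <- 10^(-conditions$ph)
  q <- (conditions$activity_no3 * a_h^2 * conditions$activity_h2o) /
       (conditions$activity_nh4 * conditions$activity_o2^2)
  dg <- dg0 + constants$gas_constant * tk * log(q)
  if (isTRUE(pressure_correction)) {
    # dV [cm^3/mol] x dP [bar]: 1 cm^3 bar = 0.1 J = 1e-4 kJ
    dg <- dg + reaction_delta_v * (conditions$pressure - 1) * 1e-4
  }
  dg
}

#' Gibbs free energy grid over ammonium and oxygen concentrations
#'
#' Evaluates [gibbs_free_energy()] on a log-spaced grid of NH4+ and O2
#' activities with nitrate, pH, temperature, and water activity held at the
#' values in `fixed`. This reproduces the energy-surface construction used to
#' assess favorability over the full range of crustal fluid compositions.
#'
#' @param constants A [thermo_constants()] object.
#' @param nh4_range,o2_range Length-2 positive numeric vectors, (min, max)
#'   activity in mol/L; axes are log10-spaced and ascending.
#' @param points_per_axis Number of grid points per axis (>= 1).
#' @param fixed A [reaction_conditions()] object supplying temperature,
#'   pressure, pH, nitrate, and water activities.
#' @param threshold Favorability threshold in kJ/mol; default -10, the
#'   theoretical minimal energy quantum of life.
#' @return A list of class `energy_grid` with `nh4_axis`, `o2_axis`
#'   (ascending, mol/L), `delta_g` (matrix indexed \[nh4, o2\], kJ/mol),
#'   `threshold`, and a `metadata` list recording the fixed conditions and
#'   the ideal-dilute activity convention.
#' @export
energy_grid <- function(constants, nh4_range, o2_range, points_per_axis,
                        fixed, threshold = -10) {
  stopifnot(length(nh4_range) == 2, length(o2_range) == 2,
            all(nh4_range > 0), all(o2_range > 0),
            points_per_axis >= 1, inherits(fixed, "reaction_conditions"))
  if (nh4_range[1] > nh4_range[2] || o2_range[1] > o2_range[2]) {
    stop("range bounds must be ascending (min, max)")
  }
  log_axis <- function(rng, n) {
    if (n == 1) rng[1] else 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  }
  nh4_axis <- log_axis(nh4_range, points_per_axis)
  o2_axis  <- log_axis(o2_range, points_per_axis)
  dg <- matrix(NA_real_, nrow = length(nh4_axis), ncol = length(o2_axis),
               dimnames = list(signif(nh4_axis, 6), signif(o2_axis, 6)))
  for (i in seq_along(nh4_axis)) {
    for (j in seq_along(o2_axis)) {
      cond <- reaction_conditions(
        activity_nh4 = nh4_axis[i], activity_o2 = o2_axis[j],
        activity_no3 = fixed$activity_no3, temperature = fixed$temperature,
        pressure = fixed$pressure, ph = fixed$ph,
        activity_h2o = fixed$activity_h2o)
      dg[i, j] <- gibbs_free_energy(constants, cond)
    }
  }
  structure(list(
    nh4_axis = nh4_axis, o2_axis = o2_axis, delta_g = dg,
    threshold = threshold,
    metadata = list(
      temperature_C = fixed$temperature, pressure_bar = fixed$pressure,
      ph = fixed$ph, activity_no3 = fixed$activity_no3,
      activity_h2o = fixed$activity_h2o,
      activity_model = "ideal dilute: activity = molar concentration")
  ), class = "energy_grid")
}

#' Favorability mask of an energy grid
#'
#' TRUE where \eqn{\Delta G \le} threshold (boundary inclusive), i.e. where
#' complete nitrification yields at least the minimal energy quantum.
#'
#' @param grid An [energy_grid()] object.
#' @return Logical matrix with the same shape and dimnames as `grid$delta_g`.
#' @export
favorability_mask <- function(grid) {
  stopifnot(inherits(grid, "energy_grid"))
  grid$delta_g <= grid$threshold
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("Gibbs free energy grid: %d x %d (NH4+ x O2)\n",
              length(x$nh4_axis), length(x$o2_axis)))
  cat(sprintf("  NH4+: %.3g .. %.3g mol/L; O2: %.3g .. %.3g mol/L\n",
              min(x$nh4_axis), max(x$nh4_axis),
              min(x$o2_axis), max(x$o2_axis)))
  cat(sprintf("  T = %.1f C, pH = %.2f, a(NO3-) = %.3g\n",
              x$metadata$temperature_C, x$metadata$ph, x$metadata$activity_no3))
  cat(sprintf("  dG range: %.1f .. %.1f kJ/mol; threshold %.1f (%.1f%% favorable)\n",
              min(x$delta_g), max(x$delta_g), x$threshold,
              100 * mean(favorability_mask(x))))
  invisible(x)
}
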