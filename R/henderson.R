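# Liquid junction potentials via the generalized Henderson equation, with a
# table of limiting equivalent conductivities for the ions of standard
# patch-clamp solutions.

#' Limiting ionic mobility table
#'
#' Limiting equivalent conductivities (S cm^2 / equiv at 25 C) for the ionic
#' species of common recording solutions, from standard physico-chemical
#' tables. Organic buffer and nucleotide anions carry generic
#' large-anion values; edit or extend the table to add species.
#'
#' @return data.frame with columns `species`, `z` (valence) and `lambda`
#'   (limiting equivalent conductivity).
#' @export
mobility_table <- function() {
  data.frame(
    species = c("K", "Na", "Cs", "Li", "Ca", "Mg", "Cl", "HCO3", "H2PO4",
                "gluconate", "HEPES", "EGTA", "phosphocreatine", "ATP",
                "GTP", "QX314", "acetate", "SO4"),
    z = c(1, 1, 1, 1, 2, 2, -1, -1, -1,
          -1, -1, -2, -2, -2, -2, 1, -1, -2),
    lambda = c(73.5, 50.11, 77.2, 38.7, 59.5, 53.06, 76.35, 44.5, 33.0,
               24.3, 22.05, 24.0, 25.0, 24.0, 24.0, 25.0, 40.9, 80.0),
    stringsAsFactors = FALSE
  )
}

#' Ionic composition of a solution
#'
#' @param species character vector of ion names (must appear in the
#'   mobility table unless `mobility` is supplied).
#' @param conc_mM ionic concentrations, mM.
#' @param table mobility table (see [mobility_table()]).
#' @param z,mobility optional explicit valences and limiting equivalent
#'   conductivities overriding the table.
#' @return An object of class `"solution_composition"` (data.frame species,
#'   conc_mM, z, lambda).
#' @export
solution_composition <- function(species, conc_mM, table = mobility_table(),
                                 z = NULL, mobility = NULL) {
  stopifnot(length(species) == length(conc_mM), all(conc_mM >= 0))
  if (is.null(z) || is.null(mobility)) {
    idx <- match(species, table$species)
    if (anyNA(idx))
      stop("no mobility entry for species: ",
           paste(species[is.na(idx)], collapse = ", "))
    z <- table$z[idx]
    mobility <- table$lambda[idx]
  }
  structure(data.frame(species = species, conc_mM = conc_mM, z = z,
                       lambda = mobility, stringsAsFactors = FALSE),
            class = c("solution_composition", "data.frame"))
}

# fraction of a monoprotic buffer in its deprotonated (anionic) form
.hh_anion_fraction <- function(pH, pKa) 1 / (1 + 10^(pKa - pH))

#' Standard bicarbonate-buffered ACSF
#'
#' Ionic composition of the standard recording ACSF (mM salts: 124 NaCl,
#' 2.5 KCl, 26 NaHCO3, 1 NaH2PO4, 2 CaCl2, 1 MgCl2, 10 glucose) fully
#' dissociated into ions; glucose is neutral and omitted.
#'
#' @return a [solution_composition()].
#' @export
acsf_standard <- function() {
  solution_composition(
    species = c("Na", "K", "Cl", "HCO3", "H2PO4", "Ca", "Mg"),
    conc_mM = c(124 + 26 + 1,               # NaCl + NaHCO3 + NaH2PO4
                2.5,
                124 + 2.5 + 2 * 2 + 2 * 1,  # NaCl + KCl + CaCl2 + MgCl2
                26, 1, 2, 1))
}

#' Potassium-gluconate intracellular solution
#'
#' Ionic composition of the K-gluconate internal used for excitatory-current
#' recordings (mM: 120 K-gluconate, 10 HEPES, 10 EGTA, 2 MgCl2, 5
#' Na2-phosphocreatine, 2 Na2ATP, 0.5 Na2GTP, 5 QX-314 Cl, pH 7.2). HEPES
#' (pKa 7.5) contributes its anionic fraction at the stated pH; EGTA and the
#' phosphagen/nucleotide species enter as divalent anions.
#'
#' @param pH solution pH (default 7.2).
#' @return a [solution_composition()].
#' @export
internal_kgluconate <- function(pH = 7.2) {
  f_hepes <- .hh_anion_fraction(pH, 7.5)
  solution_composition(
    species = c("K", "gluconate", "HEPES", "EGTA", "Mg", "Cl",
                "Na", "phosphocreatine", "ATP", "GTP", "QX314"),
    conc_mM = c(120, 120, 10 * f_hepes, 10, 2,
                2 * 2 + 5,                    # MgCl2 + QX314-Cl
                2 * 5 + 2 * 2 + 2 * 0.5,      # Na2PCr + Na2ATP + Na2GTP
                5, 2, 0.5, 5))
}

#' Potassium-chloride intracellular solution
#'
#' Ionic composition of the KCl internal used for inhibitory-current
#' recordings (mM: 125 KCl, 4 NaCl, 10 HEPES, 10 EGTA, 1 CaCl2, 4 MgATP,
#' 0.5 Na2GTP, pH 7.2).
#'
#' @param pH solution pH (default 7.2).
#' @return a [solution_composition()].
#' @export
internal_kcl <- function(pH = 7.2) {
  f_hepes <- .hh_anion_fraction(pH, 7.5)
  solution_composition(
    species = c("K", "Cl", "Na", "HEPES", "EGTA", "Ca", "Mg", "ATP", "GTP"),
    conc_mM = c(125,
                125 + 4 + 2 * 1,              # KCl + NaCl + CaCl2
                4 + 2 * 0.5,                  # NaCl + Na2GTP
                10 * f_hepes, 10, 1, 4, 4, 0.5))
}

#' Liquid junction potential by the generalized Henderson equation
#'
#' Computes the junction potential of the bath relative to the pipette
#' solution,
#' \deqn{V_L = \frac{RT}{F}\,
#'  \frac{\sum_i z_i u_i (c_i^b - c_i^p)}{\sum_i z_i^2 u_i (c_i^b - c_i^p)}
#'  \ln \frac{\sum_i z_i^2 u_i c_i^p}{\sum_i z_i^2 u_i c_i^b},}
#' with mobilities proportional to the limiting equivalent conductivities
#' and activities approximated by concentrations. The sign convention
#' matches standard electrophysiology calculators: a K-gluconate pipette in
#' ACSF gives a positive value (pipette negative relative to the bath).
#'
#' @param pipette,bath [solution_composition()] objects.
#' @param temperature_C temperature in degrees Celsius.
#' @return junction potential in mV.
#' @export
junction_potential_henderson <- function(pipette, bath,
                                         temperature_C = 25) {
  R <- 8.314462618; Fc <- 96485.332
  Tk <- 273.15 + temperature_C
  sp <- union(pipette$species, bath$species)
  get <- function(comp, what) {
    v <- stats::setNames(rep(0, length(sp)), sp)
    v[comp$species] <- comp[[what]]
    v
  }
  cp <- get(pipette, "conc_mM"); cb <- get(bath, "conc_mM")
  zz <- stats::setNames(rep(NA_real_, length(sp)), sp)
  uu <- zz
  for (comp in list(pipette, bath)) {
    zz[comp$species] <- comp$z
    uu[comp$species] <- comp$lambda / abs(comp$z)  # mobility per ion
  }
  if (anyNA(zz)) stop("missing valence/mobility for: ",
                      paste(sp[is.na(zz)], collapse = ", "))
  num <- sum(zz * uu * (cb - cp))
  den <- sum(zz^2 * uu * (cb - cp))
  s_p <- sum(zz^2 * uu * cp)
  s_b <- sum(zz^2 * uu * cb)
  if (den == 0 || s_p <= 0 || s_b <= 0) return(0)
  1000 * (R * Tk / Fc) * (num / den) * log(s_p / s_b)
}
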