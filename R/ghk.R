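#' Define an ion species with a relative permeability
#'
#' @param name Species label, e.g. `"Cl"` or `"K"`.
#' @param valence Integer charge; only monovalent ions (+1 or -1) are
#'   supported by the reversal-potential machinery.
#' @param permeability Relative permeability, dimensionless and >= 0.
#' @return A list of class `ion_species`.
#' @examples
#' ion_species("Cl", -1, 100)
#' @export
ion_species <- function(name, valence, permeability = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!valence %in% c(-1L, 1L)) {
    stop("only monovalent ions (valence +1 or -1) are supported", call. = FALSE)
  }
  if (!is.finite(permeability) || permeability < 0) {
    stop("permeability must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(name = name, valence = as.integer(valence), permeability = permeability),
    class = "ion_species"
  )
}

#' Ionic conditions of a bilayer chamber pair
#'
#' Bundles the permeant species with their cis ("In", the side the protein is
#' added to, mapped to the ER lumen) and trans ("Ex", cytoplasmic face)
#' concentrations. This object drives the Nernst and Goldman-Hodgkin-Katz
#' (GHK) reversal-potential calculations.
#'
#' @param species List of [ion_species()] objects.
#' @param conc_cis,conc_trans Numeric vectors of concentrations in mM, one
#'   entry per species, in the same order.
#' @param temperature Absolute temperature in K (default 298.15, i.e. 25 C).
#' @return A list of class `ionic_conditions` with a per-species `table`
#'   (data.frame with name, valence, permeability, conc_cis, conc_trans) and
#'   the `temperature`.
#' @examples
#' # asymmetric KCl, 150 mM cis / 15 mM trans, anion 100x more permeant
#' ionic_conditions(
#'   list(ion_species("K", +1, 1), ion_species("Cl", -1, 100)),
#'   conc_cis = c(150, 150), conc_trans = c(15, 15)
#' )
#' @export
ionic_conditions <- function(species, conc_cis, conc_trans,
                             temperature = .T_DEFAULT) {
  if (inherits(species, "ion_species")) species <- list(species)
  stopifnot(is.list(species), length(species) >= 1L)
  ok <- vapply(species, inherits, logical(1), "ion_species")
  if (!all(ok)) stop("species must be a list of ion_species objects", call. = FALSE)
  n <- length(species)
  stopifnot(length(conc_cis) == n, length(conc_trans) == n)
  if (any(conc_cis < 0) || any(conc_trans < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  tab <- data.frame(
    name = vapply(species, `[[`, character(1), "name"),
    valence = vapply(species, `[[`, integer(1), "valence"),
    permeability = vapply(species, `[[`, numeric(1), "permeability"),
    conc_cis = as.numeric(conc_cis),
    conc_trans = as.numeric(conc_trans),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tab$name)) stop("species names must be unique", call. = FALSE)
  perm <- tab$permeability > 0
  if (any(perm & (tab$conc_cis + tab$conc_trans) <= 0)) {
    stop("every permeant species needs a non-zero concentration on at least one side",
         call. = FALSE)
  }
  structure(list(table = tab, temperature = temperature),
            class = "ionic_conditions")
}

#' Nernst equilibrium potential
#'
#' Equilibrium potential of a single ion species across the membrane, using
#' the package convention V = V_cis - V_trans:
#' `E = (RT / zF) * ln(conc_trans / conc_cis)` in mV. For an anion (z = -1)
#' with a 150/15 mM cis/trans gradient at 25 C this gives +59.2 mV.
#'
#' @param valence Ion charge (non-zero integer; formula keeps general z).
#' @param conc_trans,conc_cis Concentrations in mM, both > 0.
#' @param temperature Absolute temperature in K.
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(-1, conc_trans = 15, conc_cis = 150) # +59.2 mV
#' @export
nernst_potential <- function(valence, conc_trans, conc_cis,
                             temperature = .T_DEFAULT) {
  if (valence == 0) stop("valence must be non-zero", call. = FALSE)
  if (!is.finite(conc_trans) || conc_trans <= 0 ||
      !is.finite(conc_cis) || conc_cis <= 0) {
    stop("concentrations must be positive for a Nernst potential", call. = FALSE)
  }
  rt_over_f_mv(temperature) / valence * log(conc_trans / conc_cis)
}

# Numerator/denominator of the GHK log ratio: cations contribute trans
# concentrations to the numerator and cis to the denominator; anions the
# reverse (standard GHK voltage equation with V = V_cis - V_trans).
.ghk_ratio_terms <- function(tab) {
  cation <- tab$valence > 0
  num <- ifelse(cation, tab$conc_trans, tab$conc_cis) * tab$permeability
  den <- ifelse(cation, tab$conc_cis, tab$conc_trans) * tab$permeability
  list(num = sum(num), den = sum(den))
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Multi-ion GHK voltage equation for monovalent ions,
#' `E_rev = (RT/F) * ln((sum_cat P c_trans + sum_an P c_cis) /
#' (sum_cat P c_cis + sum_an P c_trans))`, in mV. With a single permeant
#' species this reduces exactly to [nernst_potential()] (identical formula
#' path). With K+ (P = 1) and Cl- (P = 100) in 150/15 mM cis/trans KCl it
#' gives +56.7 mV, matching the measured reversal of an anion-selective
#' channel with ~100:1 Cl-:K+ permeability.
#'
#' @param conditions An [ionic_conditions()] object.
#' @return Reversal potential in mV.
#' @examples
#' cond <- ionic_conditions(
#'   list(ion_species("K", +1, 1), ion_species("Cl", -1, 100)),
#'   conc_cis = c(150, 150), conc_trans = c(15, 15)
#' )
#' ghk_reversal(cond) # ~56.7 mV
#' @export
ghk_reversal <- function(conditions) {
  stopifnot(inherits(conditions, "ionic_conditions"))
  tab <- conditions$table
  if (all(tab$permeability == 0)) {
    stop("at least one species must have permeability > 0", call. = FALSE)
  }
  terms <- .ghk_ratio_terms(tab)
  if (terms$num <= 0 || terms$den <= 0) {
    stop("GHK log argument is non-positive under these conditions", call. = FALSE)
  }
  rt_over_f_mv(conditions$temperature) * log(terms$num / terms$den)
}

#' Invert the two-ion GHK equation for a permeability ratio
#'
#' Given a measured reversal potential, solves the GHK voltage equation
#' restricted to two named species for the ratio `r = P(first) / P(second)`
#' such that [ghk_reversal()] with permeabilities `(r, 1)` reproduces the
#' input reversal. The restricted equation is linear in `r`, so the solution
#' is closed-form. Under asymmetric 150/15 mM KCl a reversal of +56.8 mV
#' yields P(Cl-)/P(K+) of roughly 100.
#'
#' @param reversal Measured reversal potential in mV.
#' @param conditions An [ionic_conditions()] object containing both species
#'   (permeabilities in `conditions` are ignored; concentrations and valences
#'   are used).
#' @param pair Character vector of two species names, `(numerator species,
#'   reference species)`.
#' @return The dimensionless permeability ratio.
#' @examples
#' cond <- ionic_conditions(
#'   list(ion_species("Cl", -1), ion_species("K", +1)),
#'   conc_cis = c(150, 150), conc_trans = c(15, 15)
#' )
#' permeability_ratio_from_reversal(56.8, cond, c("Cl", "K")) # ~103
#' @export
permeability_ratio_from_reversal <- function(reversal, conditions, pair) {
  stopifnot(inherits(conditions, "ionic_conditions"),
            is.character(pair), length(pair) == 2L)
  tab <- conditions$table
  idx <- match(pair, tab$name)
  if (anyNA(idx)) {
    stop("species not found in conditions: ",
         paste(pair[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sub <- tab[idx, ]
  cation <- sub$valence > 0
  # per-species contributions to the GHK numerator (n) and denominator (d)
  n <- ifelse(cation, sub$conc_trans, sub$conc_cis)
  d <- ifelse(cation, sub$conc_cis, sub$conc_trans)
  q <- exp(reversal / rt_over_f_mv(conditions$temperature))
  denom <- n[1] - q * d[1]
  if (abs(denom) < .Machine$double.eps * max(1, abs(n[1]), abs(q * d[1]))) {
    stop("GHK equation is not invertible for this pair at E_rev = ",
         format(reversal), " mV (degenerate denominator)", call. = FALSE)
  }
  r <- (q * d[2] - n[2]) / denom
  if (!is.finite(r) || r <= 0) {
    stop("no positive permeability ratio reproduces E_rev = ",
         format(reversal), " mV under these conditions (solution ",
         format(r), ")", call. = FALSE)
  }
  r
}

#' Linear single-channel current-voltage model
#'
#' @param conductance Slope conductance in pS (>= 0).
#' @param reversal Reversal potential in mV.
#' @return A list of class `linear_iv`.
#' @examples
#' linear_iv(39.9, 56.8)
#' @export
linear_iv <- function(conductance, reversal) {
  if (!is.finite(conductance) || conductance < 0) {
    stop("conductance must be finite and non-negative", call. = FALSE)
  }
  stopifnot(is.finite(reversal))
  structure(list(conductance = conductance, reversal = reversal),
            class = "linear_iv")
}

#' Single-channel current from a linear i-V model
#'
#' `i = g * (V - E_rev)` with the pS x mV -> 10^-3 pA scaling handled
#' internally, so 39.9 pS at a -56.8 mV driving force gives -2.27 pA.
#'
#' @param model A [linear_iv()] object.
#' @param voltage Membrane potential(s) in mV (vectorised).
#' @return Current in pA.
#' @examples
#' linear_iv_current(linear_iv(39.9, 56.8), 0)  # -2.27 pA
#' linear_iv_current(linear_iv(39.9, 56.8), 90) # +1.32 pA
#' @export
linear_iv_current <- function(model, voltage) {
  stopifnot(inherits(model, "linear_iv"), is.numeric(voltage))
  1e-3 * model$conductance * (voltage - model$reversal)
}
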