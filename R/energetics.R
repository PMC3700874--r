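# Thermodynamic registry.  Standard-state Gibbs free energies and
# enthalpies of formation at 25 degC (kJ/mol), charges, Debye-Hueckel ion
# size parameters (angstrom) and elemental compositions.  Values are taken
# from the CODATA key values and the SUPCRT-consistent compilations widely
# used for aqueous organisms' energetics; ferrihydrite from mineral
# solubility compilations (its value varies with crystallinity).
.thermo_registry <- list(
  "H2O"        = list(dGf0 = -237.18,  dHf0 = -285.83, charge = 0, a0 = 0,
                      phase = "water",   elements = c(H = 2, O = 1)),
  "H+"         = list(dGf0 = 0,        dHf0 = 0,       charge = 1, a0 = 9.0,
                      phase = "aqueous", elements = c(H = 1)),
  "SO4--"      = list(dGf0 = -744.00,  dHf0 = -909.34, charge = -2, a0 = 4.0,
                      phase = "aqueous", elements = c(S = 1, O = 4)),
  "HS-"        = list(dGf0 = 12.05,    dHf0 = -17.60,  charge = -1, a0 = 3.5,
                      phase = "aqueous", elements = c(H = 1, S = 1)),
  "H2(aq)"     = list(dGf0 = 17.72,    dHf0 = -4.20,   charge = 0, a0 = 0,
                      phase = "aqueous", elements = c(H = 2)),
  "CH4(aq)"    = list(dGf0 = -34.35,   dHf0 = -87.80,  charge = 0, a0 = 0,
                      phase = "aqueous", elements = c(C = 1, H = 4)),
  "HCO3-"      = list(dGf0 = -586.85,  dHf0 = -689.93, charge = -1, a0 = 4.5,
                      phase = "aqueous", elements = c(H = 1, C = 1, O = 3)),
  "Fe++"       = list(dGf0 = -78.87,   dHf0 = -89.10,  charge = 2, a0 = 6.0,
                      phase = "aqueous", elements = c(Fe = 1)),
  "Fe(OH)3(s)" = list(dGf0 = -711.0,   dHf0 = -827.0,  charge = 0, a0 = 0,
                      phase = "mineral", elements = c(Fe = 1, O = 3, H = 3))
)

#' Thermodynamic species registry
#'
#' @param overrides optional named list; each element a list with any of
#'   `dGf0`, `dHf0` (kJ/mol) replacing the embedded constants.
#' @return named list of species entries (dGf0, dHf0, charge, a0, phase,
#'   elements).
#' @export
thermo_registry <- function(overrides = NULL) {
  reg <- .thermo_registry
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(reg)) stop("unknown species in override: ", nm)
      reg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    }
  }
  reg
}

.reaction <- function(name, stoichiometry, electrons) {
  structure(list(name = name, stoichiometry = stoichiometry,
                 electrons = electrons),
            class = "redox_reaction")
}

#' Catalog of modelled respiratory reactions
#'
#' All reactions are written with aqueous species, one mole of terminal
#' electron acceptor (or of CH4 for the methane reactions), and H2 as the
#' electron donor where applicable:
#' \itemize{
#'   \item `sulfate_reduction_h2`: SO4-- + 4 H2(aq) + H+ -> HS- + 4 H2O
#'   \item `methanogenesis_h2`:    HCO3- + 4 H2(aq) + H+ -> CH4(aq) + 3 H2O
#'   \item `aom_reverse`: the exact reversal of `methanogenesis_h2`
#'     (anaerobic methane oxidation via reverse methanogenesis, producing H2)
#'   \item `aom_sulfate_coupled`:  CH4(aq) + SO4-- -> HCO3- + HS- + H2O
#'   \item `iron_reduction_h2`:    2 Fe(OH)3(s) + H2(aq) + 4 H+ ->
#'     2 Fe++ + 6 H2O
#' }
#' Every reaction is element- and charge-balanced (see
#' [check_reaction_balance()]).
#'
#' @return named list of `redox_reaction` objects.
#' @export
reaction_catalog <- function() {
  meth <- c("HCO3-" = -1, "H2(aq)" = -4, "H+" = -1, "CH4(aq)" = 1, "H2O" = 3)
  list(
    sulfate_reduction_h2 = .reaction(
      "sulfate_reduction_h2",
      c("SO4--" = -1, "H2(aq)" = -4, "H+" = -1, "HS-" = 1, "H2O" = 4), 8),
    methanogenesis_h2 = .reaction("methanogenesis_h2", meth, 8),
    aom_reverse = .reaction("aom_reverse", -meth, 8),
    aom_sulfate_coupled = .reaction(
      "aom_sulfate_coupled",
      c("CH4(aq)" = -1, "SO4--" = -1, "HCO3-" = 1, "HS-" = 1, "H2O" = 1), 8),
    iron_reduction_h2 = .reaction(
      "iron_reduction_h2",
      c("Fe(OH)3(s)" = -2, "H2(aq)" = -1, "H+" = -4, "Fe++" = 2, "H2O" = 6), 2)
  )
}

#' Check element and charge balance of a reaction
#'
#' @param rxn a `redox_reaction`.
#' @param registry a species registry, see [thermo_registry()].
#' @return TRUE invisibly; errors describing any imbalance otherwise.
#' @export
check_reaction_balance <- function(rxn, registry = thermo_registry()) {
  v <- rxn$stoichiometry
  unknown <- setdiff(names(v), names(registry))
  if (length(unknown) > 0) {
    stop("species not in registry: ", paste(unknown, collapse = ", "))
  }
  elements <- new.env()
  charge <- 0
  balance <- list()
  for (sp in names(v)) {
    ent <- registry[[sp]]
    charge <- charge + v[[sp]] * ent$charge
    for (el in names(ent$elements)) {
      balance[[el]] <- (balance[[el]] %||% 0) + v[[sp]] * ent$elements[[el]]
    }
  }
  bal <- unlist(balance)
  if (any(abs(bal) > 1e-9)) {
    stop("reaction '", rxn$name, "' not element-balanced: ",
         paste(names(bal)[abs(bal) > 1e-9], collapse = ", "))
  }
  if (abs(charge) > 1e-9) {
    stop("reaction '", rxn$name, "' not charge-balanced (net ", charge, ")")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard-state free energy of reaction at temperature T
#'
#' dG0 at 298.15 K is the stoichiometric sum of free energies of
#' formation; the temperature correction uses the integrated
#' Gibbs-Helmholtz relation with constant reaction enthalpy,
#' dG0_T = dG0_298 * (T/298.15) + dH0 * (1 - T/298.15), adequate over the
#' narrow 12--16 degC span of aquifer groundwater.
#'
#' @param rxn a `redox_reaction`.
#' @param temperature_k absolute temperature, K, in (273, 323).
#' @param registry species registry.
#' @return dG0_T in kJ/mol of reaction.
#' @export
standard_free_energy_at_T <- function(rxn, temperature_k,
                                      registry = thermo_registry()) {
  if (temperature_k <= 273 || temperature_k >= 323) {
    stop("temperature ", temperature_k, " K outside supported range (273, 323)")
  }
  v <- rxn$stoichiometry
  unknown <- setdiff(names(v), names(registry))
  if (length(unknown) > 0) {
    stop("species not in registry: ", paste(unknown, collapse = ", "))
  }
  dG298 <- sum(vapply(names(v), function(sp) v[[sp]] * registry[[sp]]$dGf0, 0))
  dH <- sum(vapply(names(v), function(sp) v[[sp]] * registry[[sp]]$dHf0, 0))
  tau <- temperature_k / 298.15
  dG298 * tau + dH * (1 - tau)
}

# Debye-Hueckel A (kg^1/2 mol^-1/2) and B (angstrom^-1 kg^1/2 mol^-1/2)
# parameters for water, 0-50 degC, standard compilation; linearly
# interpolated.
.dh_table <- list(
  temperature = c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50),
  A = c(0.4911, 0.4943, 0.4976, 0.5012, 0.5050, 0.5092, 0.5135, 0.5182,
        0.5231, 0.5282, 0.5336),
  B = c(0.3244, 0.3251, 0.3258, 0.3266, 0.3274, 0.3283, 0.3292, 0.3301,
        0.3312, 0.3323, 0.3334)
)

#' Extended Debye-Hueckel activity coefficient
#'
#' log10 y = -A(T) z^2 sqrt(I) / (1 + B(T) a0 sqrt(I)).  Neutral aqueous
#' species are assigned unit activity coefficient.
#'
#' @param charge ion charge z.
#' @param a0 ion size parameter, angstrom.
#' @param ionic_strength mol/kg, >= 0.
#' @param temperature_k absolute temperature, K.
#' @return dimensionless activity coefficient y.
#' @export
activity_coefficient <- function(charge, a0, ionic_strength,
                                 temperature_k = 298.15) {
  if (any(ionic_strength < 0)) stop("ionic strength must be >= 0")
  if (charge == 0) return(rep(1, length(ionic_strength))[seq_along(ionic_strength)])
  tc <- temperature_k - 273.15
  tc <- min(max(tc, min(.dh_table$temperature)), max(.dh_table$temperature))
  A <- stats::approx(.dh_table$temperature, .dh_table$A, xout = tc)$y
  B <- stats::approx(.dh_table$temperature, .dh_table$B, xout = tc)$y
  sqI <- sqrt(ionic_strength)
  10^(-A * charge^2 * sqI / (1 + B * a0 * sqI))
}

#' Build the in situ solution state for a well
#'
#' Assembles molalities (mol/kg), the ionic strength and activity
#' coefficients for the species participating in the modelled reactions
#' from a single row of a well-chemistry table.  DIC is treated entirely
#' as bicarbonate (it dominates between pH 7.1 and 7.9); the H+ activity
#' is taken directly from pH (activity coefficient 1 by construction);
#' sulfide and ferrous iron are not measured and take configurable default
#' molalities.  Water and minerals have unit activity.
#'
#' @param chem a one-row `well_chem` data.frame (or a list with the same
#'   fields).
#' @param config list of options: `censor_policy` (see
#'   [resolve_censored()]), `hs_molal` (default 1e-5), `fe2_molal`
#'   (default 1e-5), `conductivity_k` (default 1.6e-5), `ionic_strength`
#'   (override, mol/kg), `registry_overrides`.
#' @return list with `temperature_k`, `ionic_strength`, `molality` (named,
#'   mol/kg; NA when unmeasured), `activity` (named gamma*m), `registry`.
#' @export
solution_state <- function(chem, config = list()) {
  pol <- config$censor_policy %||% "limit"
  reg <- thermo_registry(config$registry_overrides)
  tk <- chem$temperature + 273.15
  I <- config$ionic_strength %||%
    estimate_ionic_strength(chem$spec_cond, config$conductivity_k %||% 1.6e-5)
  m <- c(
    "SO4--"   = resolve_censored(chem$so4, chem$so4_status, pol) * 1e-3,
    "CH4(aq)" = resolve_censored(chem$ch4, chem$ch4_status, pol) * 1e-6,
    "H2(aq)"  = resolve_censored(chem$h2, chem$h2_status, pol) * 1e-9,
    "HCO3-"   = resolve_censored(chem$dic, chem$dic_status, pol) * 1e-3,
    "HS-"     = config$hs_molal %||% 1e-5,
    "Fe++"    = config$fe2_molal %||% 1e-5,
    "H+"      = 10^(-chem$ph)
  )
  gamma <- vapply(names(m), function(sp) {
    ent <- reg[[sp]]
    if (sp == "H+") 1 else activity_coefficient(ent$charge, ent$a0, I, tk)
  }, 0)
  list(temperature_k = tk, ionic_strength = I, molality = m,
       activity = gamma * m, gamma = gamma, registry = reg)
}

#' Natural-log reaction quotient
#'
#' ln Q = sum_i v_i ln(y_i m_i) over aqueous species; water and minerals
#' contribute nothing (unit activity).
#'
#' @param rxn a `redox_reaction`.
#' @param state a solution state, see [solution_state()].
#' @return ln Q (dimensionless).
#' @export
reaction_quotient <- function(rxn, state) {
  v <- rxn$stoichiometry
  lnq <- 0
  for (sp in names(v)) {
    ent <- state$registry[[sp]]
    if (is.null(ent)) stop("species not in registry: ", sp)
    if (ent$phase %in% c("water", "mineral")) next
    a <- state$activity[[sp]]
    if (is.na(a)) stop("no molality for species ", sp)
    if (a <= 0) {
      stop("zero activity for species ", sp,
           ": supply a floor value or exclude the well")
    }
    lnq <- lnq + v[[sp]] * log(a)
  }
  lnq
}

.R_KJ <- 8.314462618e-3  # gas constant, kJ / (mol K)

#' Available energy of a respiratory reaction in one well
#'
#' dG_r = dG0_T + R T ln Q; the available energy is dG_A = -dG_r,
#' the per-electron value dG_A / n_e, and viability requires
#' dG_A >= dG_min (default 10 kJ/mol, the minimum free energy an organism
#' must conserve for the reaction to support growth).
#'
#' @param rxn a `redox_reaction` (see [reaction_catalog()]).
#' @param chem one-row `well_chem` data.frame.
#' @param config options passed to [solution_state()], plus `dG_min`
#'   (kJ/mol, default 10).
#' @return data.frame row: well_id, reaction, dG0_T, lnQ, dG_r, dG_A,
#'   per_electron, viable, computable, missing (comma-separated analytes).
#' @export
available_energy <- function(rxn, chem, config = list()) {
  state <- solution_state(chem, config)
  v <- rxn$stoichiometry
  need <- names(v)[vapply(names(v), function(sp)
    state$registry[[sp]]$phase == "aqueous", TRUE)]
  missing_sp <- need[is.na(state$molality[need])]
  base <- data.frame(well_id = chem$well_id, reaction = rxn$name,
                     stringsAsFactors = FALSE)
  if (length(missing_sp) > 0) {
    base$dG0_T <- NA_real_; base$lnQ <- NA_real_; base$dG_r <- NA_real_
    base$dG_A <- NA_real_; base$per_electron <- NA_real_
    base$viable <- NA; base$computable <- FALSE
    base$missing <- paste(missing_sp, collapse = ",")
    return(base)
  }
  dg0 <- standard_free_energy_at_T(rxn, state$temperature_k, state$registry)
  lnq <- reaction_quotient(rxn, state)
  dgr <- dg0 + .R_KJ * state$temperature_k * lnq
  dga <- -dgr
  base$dG0_T <- dg0; base$lnQ <- lnq; base$dG_r <- dgr; base$dG_A <- dga
  base$per_electron <- dga / rxn$electrons
  base$viable <- dga >= (config$dG_min %||% 10)
  base$computable <- TRUE
  base$missing <- ""
  base
}

#' Available-energy table across wells and reactions
#'
#' @param chem a `well_chem` data.frame.
#' @param reactions list of `redox_reaction`s (default: full catalog).
#' @param config see [available_energy()].
#' @return data.frame with one row per well x reaction, plus the sulfate
#'   class of each well.
#' @export
energy_table <- function(chem, reactions = reaction_catalog(),
                         config = list()) {
  cls <- sulfate_classes(chem)
  rows <- lapply(seq_len(nrow(chem)), function(i) {
    w <- chem[i, ]
    do.call(rbind, lapply(reactions, available_energy, chem = w,
                          config = config))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$sulfate_class <- cls[out$well_id]
  out
}

#' H2 threshold at which anaerobic methane oxidation becomes favorable
#'
#' AOM modelled as reverse hydrogenotrophic methanogenesis produces 4 H2
#' per CH4, so its dG_A falls as H2 rises; the threshold is the H2(aq)
#' molality at which dG_A crosses zero.  Found by bisection on log10(H2)
#' and checked against the closed-form root
#' ln a_H2 = (-dG0_T / RT - ln Q_rest) / 4.
#'
#' @param chem one-row `well_chem` data.frame (CH4, DIC, pH, temperature
#'   required).
#' @param config see [solution_state()]; plus `bracket` (default
#'   `c(1e-15, 1e-3)` mol/kg) and `tol_kj` (default 1e-9).
#' @return list with `h2_molal` (bisection root, mol/kg), `h2_nM`,
#'   `closed_form_molal`, and the residual `dG_A` at the root.
#' @export
h2_threshold_aom <- function(chem, config = list()) {
  rxn <- reaction_catalog()$aom_reverse
  state <- solution_state(chem, config)
  need <- c("CH4(aq)", "HCO3-")
  if (any(is.na(state$molality[need]))) {
    stop("H2 threshold needs measured CH4 and DIC for well ", chem$well_id)
  }
  dga_at <- function(h2_molal) {
    st <- state
    st$molality[["H2(aq)"]] <- h2_molal
    st$activity[["H2(aq)"]] <- h2_molal * st$gamma[["H2(aq)"]]
    dg0 <- standard_free_energy_at_T(rxn, st$temperature_k, st$registry)
    -(dg0 + .R_KJ * st$temperature_k * reaction_quotient(rxn, st))
  }
  bracket <- config$bracket %||% c(1e-15, 1e-3)
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  flo <- dga_at(10^lo); fhi <- dga_at(10^hi)
  if (sign(flo) == sign(fhi)) {
    stop("no sign change of dG_A(AOM) in H2 bracket [",
         bracket[1], ", ", bracket[2], "] mol/kg")
  }
  tol <- config$tol_kj %||% 1e-9
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- dga_at(10^mid)
    if (abs(fm) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  root <- 10^mid
  # closed form: dG_r(aom) = dG0 + RT (lnQ_rest + 4 ln aH2) = 0
  st0 <- state
  st0$molality[["H2(aq)"]] <- 1
  st0$activity[["H2(aq)"]] <- 1  # contributes 0 to lnQ_rest
  dg0 <- standard_free_energy_at_T(rxn, state$temperature_k, state$registry)
  lnq_rest <- reaction_quotient(rxn, st0)
  ln_a_h2 <- (-dg0 / (.R_KJ * state$temperature_k) - lnq_rest) / 4
  closed <- exp(ln_a_h2) / state$gamma[["H2(aq)"]]
  list(h2_molal = root, h2_nM = root * 1e9, closed_form_molal = closed,
       closed_form_nM = closed * 1e9, residual_dG_A = fm)
}

#' Sensitivity of available energy to an assumed (unmeasured) molality
#'
#' Recomputes dG_A over a log-spaced sweep of one assumed molality
#' (sulfide by default).  Because the species enters ln Q linearly in
#' log-space the response is a straight line with slope
#' -v_i * R T ln(10) kJ/mol per decade (about 5.5 kJ/mol per decade for a
#' product with v = 1 at 14 degC).
#'
#' @param rxn a `redox_reaction`.
#' @param chem one-row `well_chem` data.frame.
#' @param param `"hs_molal"` or `"fe2_molal"`.
#' @param values molalities to sweep (default `10^seq(-7, -3)`).
#' @param config see [available_energy()].
#' @return data.frame with the swept molality, dG_A, and the fitted
#'   kJ/mol-per-decade slope as attribute `"slope_per_decade"`.
#' @export
assumption_sensitivity <- function(rxn, chem, param = "hs_molal",
                                   values = 10^seq(-7, -3), config = list()) {
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg[[param]] <- v
    res <- available_energy(rxn, chem, cfg)
    data.frame(molal = v, dG_A = res$dG_A)
  })
  out <- do.call(rbind, rows)
  fit <- stats::lm(dG_A ~ log10(molal), data = out)
  attr(out, "slope_per_decade") <- unname(stats::coef(fit)[2])
  out
}
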