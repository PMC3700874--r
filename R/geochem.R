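# Analyte columns of the well-chemistry schema and the unit each is
# reported in (the printed scale of the source table).
.analytes <- c(so4 = "mM", ch4 = "uM", h2 = "nM", dic = "mM", doc = "mg/L")

#' Parse a chemistry cell that may be censored or missing
#'
#' Groundwater tables report analytes as a plain number, as "< limit" when
#' the analyte was not detected, or as "n/a" when it was not measured.
#'
#' @param x character vector of raw cells.
#' @return data.frame with numeric `value` (the measurement, the detection
#'   limit, or NA) and `status` in `"measured"`, `"below_detection"`,
#'   `"missing"`.
#' @export
parse_censored <- function(x) {
  x <- trimws(as.character(x))
  status <- rep("measured", length(x))
  value <- rep(NA_real_, length(x))
  miss <- is.na(x) | tolower(x) %in% c("n/a", "na", "")
  status[miss] <- "missing"
  cens <- !miss & grepl("^<", x)
  status[cens] <- "below_detection"
  num <- !miss
  raw <- sub("^<\\s*", "", x)
  suppressWarnings(value[num] <- as.numeric(raw[num]))
  bad <- num & is.na(value)
  if (any(bad)) {
    stop("malformed numeric cell(s): ", paste(sQuote(x[bad]), collapse = ", "))
  }
  if (any(value[!is.na(value)] < 0)) {
    stop("negative concentration encountered")
  }
  data.frame(value = value, status = status, stringsAsFactors = FALSE)
}

#' Read a well-chemistry table
#'
#' Reads a delimited table in the standard schema (well id, temperature in
#' deg C, pH, specific conductance in uS/cm, SO4 in mM, CH4 in uM, H2 in nM,
#' DIC in mM, DOC in mg/L).  Cells may be "n/a" (missing) or "< x"
#' (below a detection limit of x); both are resolved into an explicit
#' status column per analyte.
#'
#' @param path file path of a UTF-8 TSV/CSV with a header row.
#' @param sep field separator, default tab.
#' @param col_map optional named character vector mapping schema names
#'   (`well_id`, `temperature`, `ph`, `spec_cond`, `so4`, `ch4`, `h2`,
#'   `dic`, `doc`, optionally `formation`, `reported_class`) to the file's
#'   column names.  Defaults to identity.
#' @return a `well_chem` data.frame: one row per well, numeric columns for
#'   temperature/ph/spec_cond, and for each analyte a numeric column plus a
#'   `<analyte>_status` column.
#' @export
read_well_table <- function(path, sep = "\t", col_map = NULL) {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  want <- c("well_id", "temperature", "ph", "spec_cond", names(.analytes))
  map <- stats::setNames(want, want)
  extra <- c("formation", "reported_class")
  map <- c(map, stats::setNames(extra, extra))
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  missing_cols <- want[!(map[want] %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop("input table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(well_id = raw[[map["well_id"]]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$well_id)) {
    stop("duplicate well_id: ",
         paste(unique(out$well_id[duplicated(out$well_id)]), collapse = ", "))
  }
  out$formation <- if (map["formation"] %in% names(raw)) {
    raw[[map["formation"]]]
  } else {
    rep("unknown", n)
  }
  num_col <- function(nm) {
    v <- suppressWarnings(as.numeric(raw[[map[nm]]]))
    bad <- is.na(v) & !(tolower(raw[[map[nm]]]) %in% c("n/a", "na", ""))
    if (any(bad)) {
      stop("malformed numeric cell in column '", nm, "', row(s) ",
           paste(which(bad), collapse = ", "))
    }
    v
  }
  out$temperature <- num_col("temperature")
  out$ph <- num_col("ph")
  out$spec_cond <- num_col("spec_cond")
  for (a in names(.analytes)) {
    parsed <- tryCatch(parse_censored(raw[[map[a]]]),
                       error = function(e) {
                         stop("column '", a, "': ", conditionMessage(e))
                       })
    out[[a]] <- parsed$value
    out[[paste0(a, "_status")]] <- parsed$status
  }
  if (map["reported_class"] %in% names(raw)) {
    out$reported_class <- raw[[map["reported_class"]]]
  }
  ok_t <- is.na(out$temperature) | (out$temperature > 0 & out$temperature < 50)
  ok_ph <- is.na(out$ph) | (out$ph > 4 & out$ph < 11)
  if (!all(ok_t)) stop("temperature outside (0, 50) degC for: ",
                       paste(out$well_id[!ok_t], collapse = ", "))
  if (!all(ok_ph)) stop("pH outside (4, 11) for: ",
                        paste(out$well_id[!ok_ph], collapse = ", "))
  class(out) <- c("well_chem", "data.frame")
  out
}

#' Write a well-chemistry table
#'
#' Serializes a `well_chem` data.frame back to TSV using the same censoring
#' tokens the reader understands ("n/a", "< limit"), so that
#' write-then-read is the identity on values and status flags.
#'
#' @param chem a `well_chem` data.frame.
#' @param path output path.
#' @export
write_well_table <- function(chem, path) {
  fmt_num <- function(v) ifelse(is.na(v), "n/a", format(v, trim = TRUE,
                                                        scientific = FALSE))
  out <- data.frame(well_id = chem$well_id, stringsAsFactors = FALSE)
  if (!is.null(chem$reported_class)) out$reported_class <- chem$reported_class
  out$formation <- chem$formation
  out$temperature <- fmt_num(chem$temperature)
  out$ph <- fmt_num(chem$ph)
  out$spec_cond <- fmt_num(chem$spec_cond)
  for (a in names(.analytes)) {
    v <- fmt_num(chem[[a]])
    st <- chem[[paste0(a, "_status")]]
    v[st == "below_detection"] <- paste("<", v[st == "below_detection"])
    v[st == "missing"] <- "n/a"
    out[[a]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bundled aquifer well-chemistry table
#'
#' The 25-well groundwater chemistry table for the Mahomet aquifer
#' (east-central Illinois) shipped with the package, including the
#' sulfate-zone grouping the wells were originally reported under
#' (column `reported_class`).
#'
#' @return a `well_chem` data.frame with 25 rows.
#' @export
mahomet_wells <- function() {
  path <- system.file("extdata", "mahomet_well_chemistry.tsv",
                      package = "mahomet", mustWork = TRUE)
  read_well_table(path)
}

#' Classify wells by sulfate concentration
#'
#' Sulfate zonation used for the Mahomet aquifer: high sulfate
#' (HS, > 0.2 mM), low sulfate (LS, 0.03--0.2 mM) and negligible sulfate
#' (NS, <= 0.03 mM).  The interval boundaries are assigned so that 0.03 mM
#' falls in NS and 0.2 mM in LS, which reproduces the reported zone
#' membership of wells sitting exactly on the NS/LS boundary.  Values
#' below a detection limit are classified at the limit.
#'
#' @param so4 numeric vector, sulfate in mM (measurement or detection limit).
#' @param status optional status vector; `"missing"` entries are an error.
#' @return character vector of `"HS"`, `"LS"`, `"NS"`.
#' @export
classify_sulfate <- function(so4, status = NULL) {
  if (!is.null(status) && any(status == "missing")) {
    stop("cannot classify wells with missing sulfate")
  }
  if (any(is.na(so4))) stop("cannot classify wells with missing sulfate")
  ifelse(so4 > 0.2, "HS", ifelse(so4 <= 0.03, "NS", "LS"))
}

#' Sulfate classes for a chemistry table
#'
#' Applies [classify_sulfate()] to every well, with an optional per-well
#' override (e.g. to reproduce a historical grouping in which a well just
#' above a threshold was kept in its long-term zone).
#'
#' @param chem a `well_chem` data.frame.
#' @param override optional named character vector, `well_id -> class`.
#' @return named character vector of classes, one per well.
#' @export
sulfate_classes <- function(chem, override = NULL) {
  cls <- stats::setNames(classify_sulfate(chem$so4, chem$so4_status),
                         chem$well_id)
  if (!is.null(override)) {
    unknown <- setdiff(names(override), names(cls))
    if (length(unknown) > 0) {
      stop("override names unknown well(s): ", paste(unknown, collapse = ", "))
    }
    if (!all(override %in% c("HS", "LS", "NS"))) {
      stop("override classes must be HS, LS or NS")
    }
    cls[names(override)] <- override
  }
  cls
}

#' Resolve censored concentrations for arithmetic use
#'
#' @param value numeric vector (measurement or detection limit).
#' @param status status vector as produced by [parse_censored()].
#' @param policy `"limit"` (use the detection limit, the conservative
#'   default), `"half"` (half the limit), or `"exclude"` (return NA).
#' @return numeric vector; `"missing"` entries are always NA.
#' @export
resolve_censored <- function(value, status,
                             policy = c("limit", "half", "exclude")) {
  policy <- match.arg(policy)
  out <- value
  bd <- status == "below_detection"
  out[bd] <- switch(policy,
                    limit = value[bd],
                    half = value[bd] / 2,
                    exclude = NA_real_)
  out[status == "missing"] <- NA_real_
  out
}

#' Ionic strength from specific conductance
#'
#' Standard hydrochemical proxy I = k * SC with k defaulting to
#' 1.6e-5 mol/kg per uS/cm, used when a full major-ion analysis is not
#' available.
#'
#' @param spec_cond specific conductance, uS/cm.
#' @param k proportionality constant, mol/kg per uS/cm.
#' @return ionic strength, mol/kg.
#' @export
estimate_ionic_strength <- function(spec_cond, k = 1.6e-5) {
  if (any(is.na(spec_cond))) {
    stop("specific conductance missing: supply ionic strength directly")
  }
  if (any(spec_cond < 0)) stop("specific conductance must be >= 0")
  k * spec_cond
}

# Ostwald solubility coefficients L (dimensionless, volume of gas dissolved
# per volume of water) at 1 atm, 0-30 degC, compiled from standard gas
# solubility data for freshwater.  Linear interpolation in temperature.
.ostwald_table <- list(
  temperature = c(0, 5, 10, 15, 20, 25, 30),
  CH4 = c(0.0552, 0.0481, 0.0425, 0.0383, 0.0349, 0.0321, 0.0301),
  H2  = c(0.0214, 0.0204, 0.0196, 0.0190, 0.0186, 0.0183, 0.0181),
  CO2 = c(1.71,   1.42,   1.19,   1.02,   0.88,   0.76,   0.67)
)

#' Ostwald solubility coefficient, temperature corrected
#'
#' @param species `"CH4"`, `"H2"` or `"CO2"`.
#' @param temperature deg C; must lie within the tabulated 0--30 degC range.
#' @return dimensionless Ostwald coefficient L(T).
#' @export
ostwald_coefficient <- function(species = c("CH4", "H2", "CO2"), temperature) {
  species <- match.arg(species)
  tab_t <- .ostwald_table$temperature
  if (any(temperature < min(tab_t) | temperature > max(tab_t))) {
    stop("temperature outside the tabulated Ostwald range [",
         min(tab_t), ", ", max(tab_t), "] degC; refusing to extrapolate")
  }
  stats::approx(tab_t, .ostwald_table[[species]], xout = temperature)$y
}

#' Convert a gas-sampler reading to an aqueous concentration
#'
#' Passive diffusion samplers report a gas-phase mole fraction and the
#' total dissolved gas pressure.  The partial pressure
#' p = mole_fraction * total_pressure is converted to an aqueous
#' concentration with the temperature-corrected Ostwald coefficient:
#' c_aq = L(T) * p / (R * T_K), R = 0.08206 L atm / (mol K).
#'
#' @param species `"CH4"`, `"H2"` or `"CO2"`.
#' @param gas_mole_fraction dimensionless, in \[0, 1\].
#' @param total_pressure_atm total dissolved gas pressure, atm (> 0).
#' @param temperature deg C.
#' @return aqueous concentration, mol/L.
#' @export
gas_to_aqueous <- function(species, gas_mole_fraction, total_pressure_atm,
                           temperature) {
  if (any(gas_mole_fraction < 0 | gas_mole_fraction > 1)) {
    stop("gas mole fraction must be in [0, 1]")
  }
  if (any(total_pressure_atm <= 0)) stop("total pressure must be > 0")
  L <- ostwald_coefficient(species, temperature)
  p <- gas_mole_fraction * total_pressure_atm
  L * p / (0.08206 * (temperature + 273.15))
}
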