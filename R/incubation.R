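#' Soil physical sample
#'
#' One auger sample with wet and dry masses, used to derive moisture content,
#' bulk density and total moisture capacity. Default particle densities are
#' 1.6 g cm^-3 for peat and 2.65 g cm^-3 for mineral substrates.
#'
#' @param mass_wet sample mass before drying at 105 C, g.
#' @param mass_dry sample mass after drying, g (> 0, <= mass_wet).
#' @param auger_volume auger volume, cm^3 (> 0).
#' @param particle_density solid-phase density, g cm^-3, in (1, 3); use
#'   [particle_density_default()] for the standard peat/mineral values.
#' @return Object of class `soil_sample`.
#' @export
soil_sample <- function(mass_wet, mass_dry, auger_volume,
                        particle_density = 2.65) {
  check_number(mass_dry, "mass_dry", lower = 0, allow_lower = FALSE)
  check_number(mass_wet, "mass_wet", lower = mass_dry)
  check_number(auger_volume, "auger_volume", lower = 0, allow_lower = FALSE)
  check_number(particle_density, "particle_density", lower = 1, upper = 3,
               allow_lower = FALSE, allow_upper = FALSE)
  structure(list(mass_wet = mass_wet, mass_dry = mass_dry,
                 auger_volume = auger_volume,
                 particle_density = particle_density,
                 water_density = 1.0),
            class = "soil_sample")
}

#' @rdname soil_sample
#' @param substrate `"peat"` or `"mineral"`.
#' @export
particle_density_default <- function(substrate = c("mineral", "peat")) {
  switch(match.arg(substrate), peat = 1.6, mineral = 2.65)
}

#' Moisture, bulk density and total moisture capacity of a sample
#'
#' Computes the gravimetric moisture content
#' \eqn{W_\% = 100 (m_w - m_s)/m_s}, the dry bulk density
#' \eqn{\rho_b = m_s / V_t}, and the total moisture capacity (water content at
#' full pore saturation)
#' \eqn{W_s = \rho_w (1/\rho_b - 1/\rho_s)}, in g water per g solid and as
#' percent.
#'
#' @param sample a [soil_sample()].
#' @return List with `moisture_percent`, `bulk_density` (g cm^-3),
#'   `total_moisture_capacity` (g/g) and `total_moisture_capacity_percent`.
#' @export
soil_physical_state <- function(sample) {
  if (!inherits(sample, "soil_sample"))
    stop_invalid("`sample` must be a soil_sample")
  rho_b <- sample$mass_dry / sample$auger_volume
  if (rho_b > sample$particle_density)
    stop_invalid("bulk density ", format(rho_b), " g/cm^3 exceeds particle ",
                 "density ", sample$particle_density,
                 " g/cm^3 (negative porosity): inconsistent sample")
  ws <- sample$water_density * (1 / rho_b - 1 / sample$particle_density)
  list(moisture_percent = 100 * (sample$mass_wet - sample$mass_dry) /
         sample$mass_dry,
       bulk_density = rho_b,
       total_moisture_capacity = ws,
       total_moisture_capacity_percent = 100 * ws)
}

#' Closed-vial incubation record
#'
#' One CO2 increment measurement from a sealed-flask incubation. All unit
#' conversions are owned by the package: gas volume is supplied in mL and
#' converted internally to m^3; temperature must be absolute (use
#' [read_incubation()] for files recorded in Celsius).
#'
#' @param co2_increment volumetric CO2 increase over the atmospheric level
#'   during incubation, percent. Small negatives (> -0.5) are tolerated as
#'   measurement noise and clamp to zero in [respiration_rate()].
#' @param gas_volume_ml gas-phase volume in the flask, mL (> 0).
#' @param temperature_k incubation temperature, K, in (250, 330).
#' @param pressure_pa atmospheric pressure, Pa, in (8e4, 1.1e5).
#' @param solid_mass_kg dry mass of the solid phase, kg (> 0).
#' @param duration_h incubation interval, h (> 0; typically 20-26 h).
#' @return Object of class `incubation_record`.
#' @export
incubation_record <- function(co2_increment, gas_volume_ml, temperature_k,
                              pressure_pa, solid_mass_kg, duration_h) {
  if (!is.numeric(co2_increment) || length(co2_increment) != 1L ||
      !is.finite(co2_increment))
    stop_invalid("`co2_increment` must be a single finite number")
  check_number(gas_volume_ml, "gas_volume_ml", lower = 0, allow_lower = FALSE)
  check_number(temperature_k, "temperature_k", lower = 250, upper = 330,
               allow_lower = FALSE, allow_upper = FALSE)
  check_number(pressure_pa, "pressure_pa", lower = 8e4, upper = 1.1e5,
               allow_lower = FALSE, allow_upper = FALSE)
  check_number(solid_mass_kg, "solid_mass_kg", lower = 0, allow_lower = FALSE)
  check_number(duration_h, "duration_h", lower = 0, allow_lower = FALSE)
  structure(list(co2_increment = co2_increment,
                 gas_volume_ml = gas_volume_ml,
                 temperature_k = temperature_k,
                 pressure_pa = pressure_pa,
                 solid_mass_kg = solid_mass_kg,
                 duration_h = duration_h,
                 molar_mass_co2 = 44,       # g/mol
                 gas_constant = 8.314),     # J/(mol K)
            class = "incubation_record")
}

#' Basal respiration rate from a closed-vial record
#'
#' Ideal-gas conversion of the volumetric CO2 increment into a mass flux:
#' \deqn{U_m = \frac{P M V_g \Delta X_\%}{100\, R\, T\, m_s\, \Delta t},}
#' with the gas volume converted from mL to m^3 and the result reported in
#' mg CO2 kg^-1 h^-1. Increments in (-0.5, 0) clamp to zero with a warning;
#' increments at or below -0.5 signal a measurement error.
#'
#' @param rec an [incubation_record()].
#' @return Respiration rate U_m, mg CO2 kg^-1 h^-1.
#' @examples
#' r <- incubation_record(1.0, 100, 298.15, 101325, 0.05, 24)
#' respiration_rate(r)  # ~ 1.50 mg/kg/h
#' @export
respiration_rate <- function(rec) {
  if (!inherits(rec, "incubation_record"))
    stop_invalid("`rec` must be an incubation_record")
  dx <- rec$co2_increment
  if (dx <= -0.5)
    stop_invalid("CO2 increment ", dx, "% <= -0.5%: measurement error ",
                 "(loss of CO2 exceeds the noise tolerance)")
  if (dx < 0) {
    warning("negative CO2 increment ", format(dx), "% clamped to 0",
            call. = FALSE)
    dx <- 0
  }
  v_m3 <- rec$gas_volume_ml * 1e-6
  # moles of CO2 produced, times molar mass (g/mol), times 1000 for mg
  1000 * rec$pressure_pa * rec$molar_mass_co2 * v_m3 * dx /
    (100 * rec$gas_constant * rec$temperature_k * rec$solid_mass_kg *
       rec$duration_h)
}

#' Percent of initial mass retained
#'
#' Field decomposition index \eqn{D_\% = 100\, m_t / m_0}: the fraction of the
#' initial sample mass still present after exposure time t.
#'
#' @param m0 initial dry mass, g (> 0).
#' @param mt dry mass after exposure, g (>= 0). A value above `m0` (apparent
#'   gain, possible contamination) triggers a warning but is still returned.
#' @return D percent retained.
#' @export
mass_loss_percent <- function(m0, mt) {
  check_number(m0, "m0", lower = 0, allow_lower = FALSE)
  check_number(mt, "mt", lower = 0)
  if (mt > m0)
    warning("retained mass exceeds initial mass (possible contamination)",
            call. = FALSE)
  100 * mt / m0
}

#' Classify biological activity from basal respiration
#'
#' Ordinal classification of respiration intensity. The default thresholds
#' (mg CO2 kg^-1 h^-1) are the package's own convention for mineral and
#' organo-mineral substrates — published grading systems differ — and can be
#' replaced wholesale.
#'
#' @param u_m respiration rate(s), mg CO2 kg^-1 h^-1.
#' @param thresholds increasing named numeric vector of lower bounds for each
#'   class above the first.
#' @return Factor with the threshold-table class labels.
#' @export
classify_biological_activity <- function(u_m,
                                         thresholds = c(low = 2, medium = 5,
                                                        high = 10,
                                                        very_high = 30)) {
  check_numeric_vector(u_m, "u_m", lower = 0)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_invalid("`thresholds` must be strictly increasing")
  labels <- c("very_low", names(thresholds))
  cut(u_m, breaks = c(-Inf, thresholds, Inf), labels = labels, right = FALSE)
}

#' Read a batch of incubation records
#'
#' Delimited text with header
#' `dx_percent,v_gas_ml,temp_c,pressure_pa,mass_kg,dt_h`. Temperatures are
#' recorded in Celsius and converted to Kelvin on load.
#'
#' @param path file path.
#' @return List of [incubation_record()] objects.
#' @export
read_incubation <- function(path) {
  d <- load_dataset(path, c(dx_percent = "numeric", v_gas_ml = "numeric",
                            temp_c = "numeric", pressure_pa = "numeric",
                            mass_kg = "numeric", dt_h = "numeric"))
  lapply(seq_len(nrow(d)), function(i)
    incubation_record(d$dx_percent[i], d$v_gas_ml[i], d$temp_c[i] + 273.15,
                      d$pressure_pa[i], d$mass_kg[i], d$dt_h[i]))
}

#' Mean respiration over replicate vials
#'
#' Replicate handling: by default U_m is computed per vial and then averaged;
#' alternatively the raw increments are averaged first and Eq-level quantities
#' computed once (requires identical vial geometry).
#'
#' @param records list of [incubation_record()].
#' @param average one of `"per_vial"` (default) or `"increment_first"`.
#' @return Mean respiration rate, mg CO2 kg^-1 h^-1.
#' @export
mean_respiration <- function(records, average = c("per_vial",
                                                  "increment_first")) {
  average <- match.arg(average)
  if (!length(records) || !all(vapply(records, inherits, logical(1),
                                      "incubation_record")))
    stop_invalid("`records` must be a non-empty list of incubation_record")
  if (average == "per_vial")
    return(mean(vapply(records, respiration_rate, numeric(1))))
  base <- records[[1]]
  base$co2_increment <- mean(vapply(records, `[[`, numeric(1),
                                    "co2_increment"))
  respiration_rate(base)
}
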