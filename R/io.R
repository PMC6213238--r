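#' Load and validate a delimited dataset
#'
#' Comma-delimited text with a header that must match the schema exactly
#' (same names, same order; unknown columns are rejected). Every cell is
#' validated; offending rows are reported with their line numbers in the
#' file (header = line 1).
#'
#' @param path file path.
#' @param schema named character vector mapping column names to types
#'   (currently `"numeric"`).
#' @return data.frame with validated, typed columns.
#' @export
load_dataset <- function(path, schema) {
  if (!file.exists(path))
    stop_schema("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!identical(names(raw), names(schema)))
    stop_schema("header mismatch in ", path, ": expected `",
                paste(names(schema), collapse = ","), "` but found `",
                paste(names(raw), collapse = ","), "`")
  bad <- integer(0)
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- union(bad, which(is.na(v) | !is.finite(v)))
      raw[[col]] <- v
    }
  }
  if (length(bad))
    stop_schema("non-numeric or missing cells in ", path, " at line(s) ",
                paste(sort(bad) + 1L, collapse = ", "))
  raw
}

# ---- command-line interface ------------------------------------------------

# Parse "--key value" pairs into a named character vector.
parse_flags <- function(args) {
  out <- character(0)
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop_invalid("unexpected argument `", args[i], "` (flags are --key value)")
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args))
      stop_invalid("flag --", key, " is missing its value")
    out[key] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

flag_num <- function(flags, name, default = NULL) {
  if (!name %in% names(flags)) {
    if (is.null(default)) stop_invalid("required flag --", name, " missing")
    return(default)
  }
  v <- suppressWarnings(as.numeric(flags[[name]]))
  if (is.na(v)) stop_invalid("flag --", name, " must be numeric")
  v
}

flag_chr <- function(flags, name, default = NULL) {
  if (!name %in% names(flags)) {
    if (is.null(default)) stop_invalid("required flag --", name, " missing")
    return(default)
  }
  flags[[name]]
}

emit_report <- function(report, flags) {
  fmt <- flag_chr(flags, "format", "json")
  if (fmt == "json") {
    cat(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"), "\n")
  } else {
    for (nm in names(report))
      cat(sprintf("%s: %s\n", nm, paste(format(report[[nm]]),
                                        collapse = " ")))
  }
  invisible(report)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; install the companion script
#' (`inst/cli/soildeg.R`) or call with a character vector of arguments.
#' Subcommands: `respiration` (closed-vial batch to U_m), `kinetics`
#' (respiration to decay constant and characteristic times), `fit-response`
#' (moisture-response fit on a grid file), `fit-kt` (exponential k(T) law),
#' `simulate` (forced decay with the arid sinusoid or a forcing file),
#' `depth-fit`, `nomograph`, `wrc-fit`, and `synth` (seeded generators).
#' Reports are JSON on standard output (`--format text` for key-value
#' lines); given the same arguments and seed, output is byte-identical.
#'
#' @param args character vector, e.g.
#'   `c("kinetics", "--u-carbon", "30", "--c-percent", "30")`.
#' @return The report list, invisibly.
#' @export
soildeg_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop_invalid("usage: soildeg <subcommand> [--flag value ...]; ",
                 "subcommands: respiration kinetics fit-response fit-kt ",
                 "simulate depth-fit nomograph wrc-fit synth")
  cmd <- args[1]
  flags <- parse_flags(args[-1])
  report <- switch(
    cmd,
    "respiration" = {
      recs <- read_incubation(flag_chr(flags, "in"))
      u <- vapply(recs, respiration_rate, numeric(1))
      list(command = cmd, n_vials = length(u), u_m = u, u_m_mean = mean(u),
           activity_class = as.character(classify_biological_activity(
             mean(u))))
    },
    "kinetics" = {
      est <- k_from_respiration(flag_num(flags, "u-carbon"),
                                flag_num(flags, "c-percent"),
                                flag_num(flags, "tb", 365))
      c(list(command = cmd), unclass(est))
    },
    "fit-response" = {
      d <- read_response_grid(flag_chr(flags, "in"))
      resp <- fit_moisture_response(d$w_rel, d$u_m)
      list(command = cmd, a = resp$a, b = resp$b, w_opt = resp$w_opt,
           u_max = resp$u_max, r_squared = attr(resp, "r_squared"),
           approx_error = attr(resp, "approx_error"),
           formula = attr(resp, "formula"))
    },
    "fit-kt" = {
      d <- load_dataset(flag_chr(flags, "in"),
                        c(temp_c = "numeric", k_per_year = "numeric"))
      law <- fit_rate_temperature(d$temp_c, d$k_per_year)
      list(command = cmd, k0 = law$k0, s = law$s,
           q10_implied = law$q10_implied,
           r_squared = attr(law, "r_squared"))
    },
    "simulate" = {
      forcing <- if ("in" %in% names(flags))
        read_forcing_series(flag_chr(flags, "in"))$temperature
      else sinusoid_forcing(flag_num(flags, "t0", 38.14),
                            flag_num(flags, "amp", 4.45),
                            flag_num(flags, "period", 23.85),
                            flag_num(flags, "phase", 4.18))
      model <- dynamic_decay_model(
        c0 = flag_num(flags, "c0", 100),
        temperature_forcing = forcing,
        rate_law = exp_rate_law(flag_num(flags, "k0", 0.2834),
                                flag_num(flags, "s", 0.0435)))
      traj <- simulate_decay(model, flag_num(flags, "horizon"))
      if ("out" %in% names(flags)) write_trajectory(traj, flags[["out"]])
      list(command = cmd, horizon_h = flag_num(flags, "horizon"),
           loss_percent = total_loss_percent(traj),
           final_c = traj$c[nrow(traj)])
    },
    "depth-fit" = {
      d <- load_dataset(flag_chr(flags, "in"),
                        c(h = "numeric", u_m = "numeric"))
      prof <- fit_depth_profile(d$h, d$u_m)
      hd <- characteristic_depths(prof$attenuation)
      list(command = cmd, u_inf = prof$u_inf, amplitude = prof$amplitude,
           attenuation = prof$attenuation, h_half = unname(hd["h_half"]),
           h_95 = unname(hd["h_95"]), r_squared = attr(prof, "r_squared"))
    },
    "nomograph" = {
      mode <- switch(flag_chr(flags, "mode", "b"),
                     b = "attenuation", h95 = "active_layer",
                     stop_invalid("--mode must be `b` or `h95`"))
      if ("b" %in% names(flags) || "h95" %in% names(flags)) {
        n <- flag_num(flags, "n")
        h <- if (mode == "attenuation")
          burial_depth(n, attenuation = flag_num(flags, "b"))
        else burial_depth(n, active_layer = flag_num(flags, "h95"))
        list(command = cmd, n = n, depth_cm = h,
             depth_cm_rounded = round(h))
      } else {
        tab <- nomograph_table(mode = mode)
        if ("out" %in% names(flags)) write_nomograph(tab, flags[["out"]])
        list(command = cmd, mode = mode, rows = nrow(tab))
      }
    },
    "wrc-fit" = {
      d <- read_wrc(flag_chr(flags, "in"))
      params <- fit_wrc(d)
      cm <- capacity_metrics(params, flag_num(flags, "fc-pressure", 33))
      list(command = cmd, theta_r = params$theta_r, theta_s = params$theta_s,
           alpha = params$alpha, n_shape = params$n_shape,
           r_squared = attr(params, "r_squared"),
           total_capacity = cm$total_capacity,
           field_capacity = cm$field_capacity)
    },
    "synth" = {
      what <- flag_chr(flags, "what")
      seed <- as.integer(flag_num(flags, "seed", 1))
      out_path <- flag_chr(flags, "out")
      switch(
        what,
        "response-grid" = {
          g <- gen_response_grid(moisture_response(4.84, 2.35, u_max = 30),
                                 temperature_response(),
                                 noise_sd = flag_num(flags, "noise", 0),
                                 seed = seed)
          utils::write.csv(g, out_path, row.names = FALSE, quote = FALSE)
        },
        "decay-series" = {
          s <- gen_decay_series(flag_num(flags, "k", 0.77),
                                noise_sd = flag_num(flags, "noise", 0),
                                seed = seed)
          write_mass_loss(s, out_path)
        },
        "depth-profile" = {
          g <- gen_depth_profile(depth_profile(0.5, 20, 0.3),
                                 noise_sd = flag_num(flags, "noise", 0),
                                 seed = seed)
          utils::write.csv(g, out_path, row.names = FALSE, quote = FALSE)
        },
        "wrc" = {
          g <- gen_wrc_dataset(vg_params(5, 40, 0.1, 2),
                               noise_sd = flag_num(flags, "noise", 0),
                               seed = seed)
          utils::write.csv(as.data.frame(g), out_path, row.names = FALSE,
                           quote = FALSE)
        },
        stop_invalid("--what must be one of response-grid, decay-series, ",
                     "depth-profile, wrc"))
      list(command = cmd, what = what, seed = seed, out = out_path)
    },
    stop_invalid("unknown subcommand `", cmd, "`"))
  emit_report(report, flags)
}
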