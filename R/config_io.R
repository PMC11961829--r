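# Minimal TOML-subset reader/writer. No TOML package ships with the
# supported environment, and the configuration needs only [section] tables
# with scalar keys (numbers, booleans, quoted strings) and flat arrays, so a
# small dedicated parser is used. Nested tables, dates and multi-line strings
# are out of scope and rejected.

strip_toml_comment <- function(line) {
  out <- character(0)
  in_str <- FALSE
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  for (ch in chars) {
    if (ch == '"') in_str <- !in_str
    if (ch == "#" && !in_str) break
    out <- c(out, ch)
  }
  paste(out, collapse = "")
}

parse_toml_value <- function(txt, key) {
  txt <- trimws(txt)
  if (txt == "") stop(sprintf("config: empty value for key '%s'", key), call. = FALSE)
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(substr(txt, 2L, nchar(txt) - 1L))
    if (inner == "") return(numeric(0))
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
    return(unlist(lapply(parts, parse_toml_value, key = key)))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  if (grepl('^".*"$', txt)) return(substr(txt, 2L, nchar(txt) - 1L))
  num <- suppressWarnings(as.numeric(txt))
  if (is.na(num)) {
    stop(sprintf("config: cannot parse value '%s' for key '%s'", txt, key),
         call. = FALSE)
  }
  num
}

read_toml <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (raw in lines) {
    line <- trimws(strip_toml_comment(raw))
    if (line == "") next
    if (grepl("^\\[.+\\]$", line)) {
      section <- trimws(gsub("^\\[|\\]$", "", line))
      if (grepl("\\.", section)) {
        stop(sprintf("config: nested table [%s] not supported", section),
             call. = FALSE)
      }
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0L) {
      stop(sprintf("config: cannot parse line '%s'", raw), call. = FALSE)
    }
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- parse_toml_value(substr(line, eq + 1L, nchar(line)), key)
    if (is.null(section)) {
      out[[key]] <- val
    } else {
      out[[section]][[key]] <- val
    }
  }
  out
}

toml_value_str <- function(v) {
  if (is.character(v)) {
    paste0('"', v, '"')
  } else if (is.logical(v)) {
    ifelse(v, "true", "false")
  } else {
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
}

write_toml <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    lines <- c(lines, sprintf("[%s]", section))
    tab <- config[[section]]
    for (key in names(tab)) {
      v <- tab[[key]]
      val <- if (length(v) > 1L) {
        paste0("[", paste(vapply(v, toml_value_str, character(1L)),
                          collapse = ", "), "]")
      } else {
        toml_value_str(v)
      }
      lines <- c(lines, sprintf("%s = %s", key, val))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

config_known_keys <- list(
  sim = c("d", "dx", "dt", "nn", "bc_margin", "gravity", "bc_type",
          "damping", "paper_literal_scaling", "seed"),
  material = c("mu0", "lambda0", "E", "nu", "xi", "theta_c", "theta_s",
               "k_c", "k_s", "plasticity_mode"),
  specimen = c("extents", "particles_per_cell", "jitter", "density",
               "fixed_frac", "load_frac", "corner"),
  experiment = c("kind", "pull_rate", "duration", "applied_stress",
                 "target_strain", "hold_duration", "hold_mode",
                 "record_every", "damping")
)

experiment_defaults <- function() {
  list(kind = "relax", pull_rate = 0.2, duration = 0.3,
       applied_stress = 500, target_strain = 0.10, hold_duration = 0.2,
       hold_mode = "static", record_every = 10, damping = NA_real_)
}

#' Load and validate a simulation configuration
#'
#' Reads a TOML configuration with optional tables `[sim]`, `[material]`,
#' `[specimen]` and `[experiment]`, fills in the documented defaults for
#' everything absent (an empty file yields the full default configuration),
#' warns on unknown keys, and validates every value through the constructors
#' (errors name the offending key). The `[material]` table accepts either
#' `mu0`/`lambda0` directly or `E`/`nu`, which are converted through
#' [lame_coefficients()].
#'
#' @param path Path to a TOML file.
#' @return A list with elements `cfg` ([sim_config()]), `params`
#'   ([material_params()]), `spec` ([specimen_spec()]) and `experiment`
#'   (a named list of experiment settings).
#' @export
load_config <- function(path) {
  raw <- read_toml(path)
  top_unknown <- setdiff(names(raw), names(config_known_keys))
  if (length(top_unknown) > 0L) {
    warning(sprintf("config: unknown section(s) ignored: %s",
                    paste(top_unknown, collapse = ", ")), call. = FALSE)
  }
  for (section in intersect(names(raw), names(config_known_keys))) {
    unknown <- setdiff(names(raw[[section]]), config_known_keys[[section]])
    if (length(unknown) > 0L) {
      warning(sprintf("config: unknown key(s) in [%s] ignored: %s", section,
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
    raw[[section]] <- raw[[section]][intersect(names(raw[[section]]),
                                               config_known_keys[[section]])]
  }

  sim <- raw$sim %||% list()
  cfg <- do.call(sim_config, sim)

  mat <- raw$material %||% list()
  if (!is.null(mat$E) || !is.null(mat$nu)) {
    if (is.null(mat$E) || is.null(mat$nu)) {
      stop("config: [material] must give both 'E' and 'nu' (or neither)",
           call. = FALSE)
    }
    lam <- lame_coefficients(mat$E, mat$nu)
    mat$mu0 <- lam$mu0
    mat$lambda0 <- lam$lambda0
    mat$E <- NULL
    mat$nu <- NULL
  }
  params <- do.call(material_params, mat)

  spc <- raw$specimen %||% list()
  spec <- do.call(specimen_spec, spc)
  if (length(spec$extents) != cfg$d) {
    stop("config: specimen 'extents' length must equal sim 'd'", call. = FALSE)
  }

  expd <- experiment_defaults()
  exp_in <- raw$experiment %||% list()
  for (nm in names(exp_in)) expd[[nm]] <- exp_in[[nm]]
  if (!expd$kind %in% c("tear", "creep", "relax")) {
    stop(sprintf("config: experiment 'kind' must be tear, creep or relax (got '%s')",
                 expd$kind), call. = FALSE)
  }

  list(cfg = cfg, params = params, spec = spec, experiment = expd)
}

#' Normalize a configuration to its fully-defaulted form
#'
#' Expands a loaded configuration back into the four plain TOML tables with
#' every default filled in, suitable for [dump_config()]. `dump_config()`
#' followed by [load_config()] round-trips to the same normalized form.
#'
#' @param conf A list as returned by [load_config()].
#' @return A named list of the four configuration tables.
#' @export
config_normalize <- function(conf) {
  cfg <- conf$cfg
  params <- conf$params
  spec <- conf$spec
  sim <- list(d = cfg$d, dx = cfg$dx, dt = cfg$dt, nn = cfg$nn,
              bc_margin = cfg$bc_margin, gravity = cfg$gravity,
              bc_type = cfg$bc_type, damping = cfg$damping,
              paper_literal_scaling = cfg$paper_literal_scaling,
              seed = cfg$seed)
  material <- params[c("mu0", "lambda0", "xi", "theta_c", "theta_s",
                       "k_c", "k_s", "plasticity_mode")]
  specimen <- spec[c("extents", "particles_per_cell", "jitter", "density",
                     "fixed_frac", "load_frac")]
  if (!is.null(spec$corner)) specimen$corner <- spec$corner
  experiment <- conf$experiment
  experiment$damping <- if (is.na(experiment$damping)) NULL else experiment$damping
  list(sim = sim, material = material, specimen = specimen,
       experiment = experiment[!vapply(experiment, is.null, logical(1L))])
}

#' Write a configuration to a TOML file
#'
#' @param conf A list as returned by [load_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
dump_config <- function(conf, path) {
  write_toml(config_normalize(conf), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
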