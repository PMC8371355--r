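# Canonical internal units: concentrations mg/dL, volumes L, times h,
# rates L/h, generation mg/dL*L/h.  Clinical rate inputs in mL/min are
# converted once at the boundary: 1 mL/min = 0.06 L/h.

ML_MIN_TO_L_H <- 0.06

#' Bundle kinetic-model parameters in canonical units
#'
#' Constructs the parameter set describing one clinical time interval of the
#' one-compartment creatinine model: initial serum creatinine `cr0`,
#' creatinine generation rate `gen`, kinetic GFR `gfr_k`, initial volume of
#' distribution `v0` (typically total body water, ~42 L) and the constant
#' net volume-change rate `dv_dt` from fluid inputs/outputs.
#'
#' Rates may be given in the units clinicians use (`"mL/min"` for GFR and
#' generation) or already in canonical `"L/h"`; they are stored internally
#' in L/h (generation in mg/dL·L/h).
#'
#' @param cr0 Initial serum creatinine, mg/dL.
#' @param gen Creatinine generation rate; unit given by `gen_unit`. In
#'   `"mg/dL.mL/min"` this is the familiar product of a steady-state
#'   creatinine and its matching GFR (e.g. 1.0 mg/dL x 90 mL/min = 90).
#' @param gfr_k Kinetic GFR; unit given by `gfr_unit`.
#' @param v0 Initial volume of distribution, L.
#' @param dv_dt Net rate of change of the volume of distribution; unit given
#'   by `dv_unit`. Positive = net fluid gain.
#' @param gfr_unit,gen_unit,dv_unit Unit labels for the three rate fields.
#' @return An object of class `kinetic_params`: a list with fields `cr0`,
#'   `gen`, `gfr_k`, `v0`, `dv_dt`, all in canonical units.
#' @examples
#' p <- kinetic_params(cr0 = 1.0, gen = 90, gfr_k = 90, v0 = 42, dv_dt = 0.25)
#' p$gfr_k  # 5.4 L/h
#' @seealso [to_canonical()] for unit-tagged input, [validate_params()]
#' @export
kinetic_params <- function(cr0, gen, gfr_k, v0, dv_dt = 0,
                           gfr_unit = c("mL/min", "L/h"),
                           gen_unit = c("mg/dL.mL/min", "mg/dL.L/h"),
                           dv_unit = c("L/h", "mL/min")) {
  gfr_unit <- match.arg(gfr_unit)
  gen_unit <- match.arg(gen_unit)
  dv_unit <- match.arg(dv_unit)
  vals <- c(cr0 = cr0, gen = gen, gfr_k = gfr_k, v0 = v0, dv_dt = dv_dt)
  if (!all(is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (gfr_unit == "mL/min") gfr_k <- gfr_k * ML_MIN_TO_L_H
  if (gen_unit == "mg/dL.mL/min") gen <- gen * ML_MIN_TO_L_H
  if (dv_unit == "mL/min") dv_dt <- dv_dt * ML_MIN_TO_L_H
  structure(
    list(cr0 = cr0, gen = gen, gfr_k = gfr_k, v0 = v0, dv_dt = dv_dt),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic creatinine parameters (canonical units)\n")
  cat(sprintf("  Cr0   : %g mg/dL\n", x$cr0))
  cat(sprintf("  Gen   : %g mg/dL.L/h  (%g mg/dL.mL/min)\n",
              x$gen, x$gen / ML_MIN_TO_L_H))
  cat(sprintf("  GFR_K : %g L/h  (%g mL/min)\n",
              x$gfr_k, x$gfr_k / ML_MIN_TO_L_H))
  cat(sprintf("  V0    : %g L\n", x$v0))
  cat(sprintf("  dV/dt : %g L/h\n", x$dv_dt))
  invisible(x)
}

# unit -> (canonical unit, multiplicative factor)
.unit_table <- list(
  "mg/dL" = c(kind = "concentration", factor = 1),
  "mL/min" = c(kind = "rate", factor = ML_MIN_TO_L_H),
  "L/h" = c(kind = "rate", factor = 1),
  "L" = c(kind = "volume", factor = 1),
  "h" = c(kind = "time", factor = 1),
  "min" = c(kind = "time", factor = 1 / 60),
  # generation carries a concentration factor; same rate conversion applies
  "mg/dL.mL/min" = c(kind = "genrate", factor = ML_MIN_TO_L_H),
  "mg/dL.L/h" = c(kind = "genrate", factor = 1)
)

.convert_unit <- function(value, unit, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("field '", field, "': value must be a single finite number")
  }
  entry <- .unit_table[[unit]]
  if (is.null(entry)) {
    stop("field '", field, "': unknown unit '", unit, "' (supported: ",
         paste(names(.unit_table), collapse = ", "), ")")
  }
  value * as.numeric(entry[["factor"]])
}

#' Convert a unit-tagged parameter bundle to canonical units
#'
#' Accepts a list in which each parameter carries an explicit unit label,
#' e.g. `list(cr0 = list(value = 1, unit = "mg/dL"), gfr_k = list(value = 90,
#' unit = "mL/min"), ...)` — the shape of a JSON config file — and returns a
#' [kinetic_params] object in canonical units (L, h, mg/dL, L/h).
#' The generation rate may be tagged `"mL/min"` or `"mg/dL.mL/min"`
#' interchangeably (the concentration factor is unaffected by conversion).
#' Idempotent on already-canonical input.
#'
#' @param x Named list with entries `cr0`, `gen`, `gfr_k`, `v0`, `dv_dt`,
#'   each either a bare number (assumed canonical) or
#'   `list(value =, unit =)`.
#' @return A [kinetic_params] object.
#' @export
to_canonical <- function(x) {
  need <- c("cr0", "gen", "gfr_k", "v0", "dv_dt")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  default_unit <- c(cr0 = "mg/dL", gen = "mg/dL.L/h", gfr_k = "L/h",
                    v0 = "L", dv_dt = "L/h")
  # "mL/min" on gen means mg/dL.mL/min; normalise before lookup
  get <- function(field) {
    entry <- x[[field]]
    if (is.numeric(entry)) {
      value <- entry
      unit <- default_unit[[field]]
    } else {
      value <- entry$value
      unit <- entry$unit
      if (field == "gen" && identical(unit, "mL/min")) unit <- "mg/dL.mL/min"
      if (field == "gen" && identical(unit, "L/h")) unit <- "mg/dL.L/h"
    }
    .convert_unit(value, unit, field)
  }
  kinetic_params(
    cr0 = get("cr0"), gen = get("gen"), gfr_k = get("gfr_k"),
    v0 = get("v0"), dv_dt = get("dv_dt"),
    gfr_unit = "L/h", gen_unit = "mg/dL.L/h", dv_unit = "L/h"
  )
}

#' Check a parameter set against the model's clinical validity rules
#'
#' The model's variables are constrained by clinical reality:
#' \describe{
#'   \item{A}{creatinine positive: `cr0 > 0`}
#'   \item{B}{volume of distribution positive: `v0 > 0`}
#'   \item{C}{kinetic GFR non-negative: `gfr_k >= 0` (strict-clinical mode
#'     only; extended-math mode allows any finite GFR so tangents can be
#'     examined at mathematically legal but non-physiologic points)}
#'   \item{D}{generation rate positive: `gen > 0`}
#'   \item{E}{the volume-change rate cannot drain the whole volume within
#'     the horizon: `dv_dt > -v0/horizon`. There is no theoretical upper
#'     bound; values above `dv_dt_warn` only raise an advisory note.}
#' }
#' All rules are checked independently; every violated rule is reported,
#' not just the first. Violations are data, not errors.
#'
#' @param params A [kinetic_params] object.
#' @param horizon Duration of the clinical interval, h (>= 0).
#' @param mode `"strict-clinical"` (default) or `"extended-math"`.
#' @param dv_dt_warn Advisory upper bound on `dv_dt` in L/h (default 10);
#'   exceeding it adds a warning entry, never a violation.
#' @return An object of class `kgfr_validation`: list with `valid` (logical),
#'   `violations` (data.frame with columns `rule`, `message`), `warnings`
#'   (character) and `mode`.
#' @examples
#' p <- kinetic_params(1.0, 90, 90, 42, 0.25)
#' validate_params(p, horizon = 24)$valid
#' @export
validate_params <- function(params, horizon,
                            mode = c("strict-clinical", "extended-math"),
                            dv_dt_warn = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(horizon), length(horizon) == 1L, horizon >= 0)
  rules <- character(0)
  msgs <- character(0)
  add <- function(rule, msg) {
    rules <<- c(rules, rule)
    msgs <<- c(msgs, msg)
  }
  if (!(params$cr0 > 0)) {
    add("A", sprintf("initial creatinine must be positive (cr0 = %g)", params$cr0))
  }
  if (!(params$v0 > 0)) {
    add("B", sprintf("initial volume must be positive (v0 = %g)", params$v0))
  }
  if (mode == "strict-clinical" && params$gfr_k < 0) {
    add("C", sprintf("kinetic GFR must be non-negative (gfr_k = %g L/h)", params$gfr_k))
  }
  if (!(params$gen > 0)) {
    add("D", sprintf("generation rate must be positive (gen = %g)", params$gen))
  }
  if (horizon > 0 && params$v0 > 0 && params$dv_dt <= -params$v0 / horizon) {
    add("E", sprintf(
      "volume-change rate %g L/h would exhaust the %g L volume within %g h (bound: dv_dt > %g)",
      params$dv_dt, params$v0, horizon, -params$v0 / horizon))
  }
  warnings <- character(0)
  if (params$dv_dt > dv_dt_warn) {
    warnings <- sprintf("dv_dt = %g L/h exceeds the advisory bound of %g L/h",
                        params$dv_dt, dv_dt_warn)
  }
  structure(
    list(
      valid = length(rules) == 0L,
      violations = data.frame(rule = rules, message = msgs,
                              stringsAsFactors = FALSE),
      warnings = warnings,
      mode = mode
    ),
    class = "kgfr_validation"
  )
}

#' @export
print.kgfr_validation <- function(x, ...) {
  cat(sprintf("Parameter validation (%s mode): %s\n", x$mode,
              if (x$valid) "valid" else "INVALID"))
  if (nrow(x$violations)) {
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  rule %s: %s\n", x$violations$rule[i], x$violations$message[i]))
    }
  }
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

# internal: stop with the full violation list if invalid
.assert_valid <- function(params, horizon, mode = "strict-clinical") {
  rep <- validate_params(params, horizon, mode)
  if (!rep$valid) {
    stop("invalid parameters (rule ",
         paste(rep$violations$rule, collapse = ", "), "): ",
         paste(rep$violations$message, collapse = "; "), call. = FALSE)
  }
  invisible(rep)
}
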