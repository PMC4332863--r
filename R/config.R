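#' Read a run configuration file
#'
#' Parses a flat TOML-dialect configuration: `key = value` pairs, `#`
#' comments, optional `[section]` headers that prefix the keys that follow
#' (`[intensity_law]` / `kind = "stevens_power"` becomes
#' `intensity_law.kind`). Values may be numbers, booleans or quoted strings.
#'
#' Recognized keys: `beta`, `gamma`, `nu`, `A0_deg`, `AP_deg`, `L`, `Lgz`,
#' `GSA_deg`, `variant`, solver options (`dt`, `t_end`, `nodes`,
#' `output_every`), and an `[intensity_law]` section with `kind` and the
#' law's coefficients (`a`, `b` or `c`, `d`). Angles are in degrees in the
#' file (flagged by the `_deg` suffix) and converted to radians on read.
#'
#' @param path Path to the configuration file.
#' @return A list with `params` ([tropic_params()]), `variant`,
#'   `law` ([intensity_law()] or `NULL`), `solver` (list), and `raw`
#'   (all parsed keys, echoed into output sidecars).
#' @export
read_params_config <- function(path) {
  raw <- parse_flat_config(path)
  num <- function(key, default = NULL) {
    v <- raw[[key]]
    if (is.null(v)) return(default)
    if (!is.numeric(v)) stop("config key '", key, "' must be numeric")
    v
  }
  L <- num("L", 1)
  params <- tropic_params(
    beta = num("beta", 0), gamma = num("gamma", 0), nu = num("nu", 0),
    A0 = num("A0_deg", 0) * pi / 180,
    A_P = num("AP_deg", 0) * pi / 180,
    L = L, L_gz = num("Lgz", L),
    GSA = num("GSA_deg", 0) * pi / 180)
  variant <- raw[["variant"]]
  if (!is.null(variant)) check_variant(variant)
  law <- NULL
  kind <- raw[["intensity_law.kind"]]
  if (!is.null(kind)) {
    kind <- switch(kind,
                   power = , stevens = , stevens_power = "stevens_power",
                   log = , weber_fechner = ,
                   weber_fechner_log = "weber_fechner_log",
                   stop("unknown intensity_law.kind: ", kind))
    law <- if (kind == "stevens_power") {
      intensity_law(kind, a = num("intensity_law.a", 1),
                    b = num("intensity_law.b", -0.4))
    } else {
      intensity_law(kind, c = num("intensity_law.c", 0),
                    d = num("intensity_law.d", 1))
    }
  }
  solver <- list(dt = num("dt"), t_end = num("t_end"),
                 nodes = num("nodes", 201),
                 output_every = num("output_every"))
  list(params = params, variant = variant, law = law, solver = solver,
       raw = raw)
}

parse_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  prefix <- ""
  for (k in seq_along(lines)) {
    line <- sub("#.*$", "", lines[k])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      prefix <- paste0(sub("^\\[(.*)\\]$", "\\1", line), ".")
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      stop("config parse error at line ", k, " of ", path, ": '", line, "'")
    }
    key <- paste0(prefix, m[2])
    val <- trimws(m[3])
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (grepl("^\".*\"$", val) || grepl("^'.*'$", val)) {
    return(substr(val, 2, nchar(val) - 1))
  }
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  numval <- suppressWarnings(as.numeric(val))
  if (!is.na(numval)) return(numval)
  val
}
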