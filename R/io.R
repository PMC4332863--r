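#' Read and write organ shapes, kinematics and equilibrium tables
#'
#' @description
#' All on-disk formats are plain delimited text with explicit unit headers,
#' so degree/radian mixups cannot pass silently:
#' \itemize{
#'   \item shape tables: comment header `# units: rad` (or `deg`), then
#'     columns `s,angle,curvature`;
#'   \item kinematics tables: long format, columns `s,t,angle,curvature`,
#'     same unit header, with run metadata (parameters, variant, solver) in
#'     a JSON sidecar `<path>.json`;
#'   \item equilibrium (PGEA) tables: columns
#'     `protocol,A0_deg,AP_deg,I,tip_angle_deg,replicate` — degrees at the
#'     file boundary, radians in memory.
#' }
#' Angles are converted to radians on read when the header declares degrees;
#' writes are always in radians for shapes/kinematics and degrees for PGEA
#' tables, as their column names state.
#'
#' @param shape An [organ_shape()].
#' @param path File path.
#' @name tropism_io
NULL

#' @rdname tropism_io
#' @export
write_shape <- function(shape, path) {
  validate_organ_shape(shape)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# organ_shape", "# units: rad"), con)
  write_csv_full(
    data.frame(s = shape$s, angle = shape$angle,
               curvature = shape$curvature),
    con)
  invisible(path)
}

# CSV writer at full double precision (17 significant digits), so that
# write -> read round trips are bitwise lossless
write_csv_full <- function(df, con) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  units <- "rad"
  unit_line <- grep("^\\s*#\\s*units:", lines, value = TRUE)
  if (length(unit_line)) {
    units <- trimws(sub("^\\s*#\\s*units:\\s*", "", unit_line[1]))
    units <- trimws(strsplit(units, ",")[[1]][1])
    if (!units %in% c("rad", "deg")) {
      stop("unit error in ", path, ": angular units must be 'rad' or 'deg', got '",
           units, "'")
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("no data in ", path)
  df <- utils::read.csv(text = lines[body_idx], stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(required, c("protocol", "replicate"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(trimws(df[[cn]])))
    if (length(bad) == 0 && anyNA(v)) bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed row in ", path, " at line ",
           body_idx[1 + bad[1]], ": column '", cn,
           "' is not numeric")
    }
    df[[cn]] <- v
  }
  attr(df, "units") <- units
  df
}

#' @rdname tropism_io
#' @export
read_shape <- function(path) {
  df <- read_table_checked(path, c("s", "angle", "curvature"))
  if (attr(df, "units") == "deg") {
    df$angle <- df$angle * pi / 180
    df$curvature <- df$curvature * pi / 180
  }
  organ_shape(df$s, angle = df$angle, curvature = df$curvature)
}

#' @rdname tropism_io
#' @param kin A `kinematics` object.
#' @export
write_kinematics <- function(kin, path) {
  stopifnot(inherits(kin, "kinematics"))
  con <- file(path, "w")
  long <- data.frame(
    s = rep(kin$s, times = length(kin$t)),
    t = rep(kin$t, each = length(kin$s)),
    angle = as.vector(kin$A),
    curvature = as.vector(kin$C))
  writeLines(c("# kinematics", "# units: rad"), con)
  write_csv_full(long, con)
  close(con)
  meta <- list(variant = kin$variant,
               params = unclass(kin$params),
               solver = list(dt = kin$dt, method = kin$method, T_B = kin$T_B,
                             sine_law = kin$sine_law,
                             n_nodes = length(kin$s), t_end = max(kin$t)),
               seed = kin$seed, noise_sigma = kin$noise_sigma,
               tool = paste0("tropism ",
                             as.character(utils::packageVersion("tropism"))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname tropism_io
#' @export
read_kinematics <- function(path) {
  df <- read_table_checked(path, c("s", "t", "angle", "curvature"))
  if (attr(df, "units") == "deg") {
    df$angle <- df$angle * pi / 180
    df$curvature <- df$curvature * pi / 180
  }
  s <- sort(unique(df$s))
  t <- sort(unique(df$t))
  if (nrow(df) != length(s) * length(t)) {
    stop("schema error in ", path, ": kinematics table is not a full s x t grid")
  }
  ord <- order(df$t, df$s)
  A <- matrix(df$angle[ord], nrow = length(s))
  C <- matrix(df$curvature[ord], nrow = length(s))
  meta_path <- paste0(path, ".json")
  params <- NULL
  variant <- "AC"
  dt <- NA_real_
  method <- "file"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pm <- meta$params
    params <- tropic_params(beta = pm$beta, gamma = pm$gamma, nu = pm$nu,
                            A0 = pm$A0, A_P = pm$A_P, L = pm$L,
                            L_gz = pm$L_gz, GSA = pm$GSA)
    variant <- meta$variant
    dt <- meta$solver$dt
    method <- meta$solver$method
  }
  new_kinematics(t, s, A, C, params, variant, dt = dt, method = method)
}

#' @rdname tropism_io
#' @param data A PGEA data frame (radians), e.g. from
#'   [generate_pgea_dataset()].
#' @export
write_pgea <- function(data, path) {
  need <- c("protocol", "A0", "A_P", "I", "tip_angle", "replicate")
  stopifnot(all(need %in% names(data)))
  out <- data.frame(protocol = data$protocol,
                    A0_deg = data$A0 * 180 / pi,
                    AP_deg = data$A_P * 180 / pi,
                    I = data$I,
                    tip_angle_deg = data$tip_angle * 180 / pi,
                    replicate = data$replicate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pgea dataset; angles in degrees as the column names state",
             con)
  write_csv_full(out, con)
  invisible(path)
}

#' @rdname tropism_io
#' @export
read_pgea <- function(path) {
  df <- read_table_checked(path,
                           c("protocol", "A0_deg", "AP_deg", "I",
                             "tip_angle_deg", "replicate"))
  data.frame(protocol = df$protocol,
             A0 = df$A0_deg * pi / 180,
             A_P = df$AP_deg * pi / 180,
             I = df$I,
             tip_angle = df$tip_angle_deg * pi / 180,
             replicate = df$replicate,
             stringsAsFactors = FALSE)
}
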