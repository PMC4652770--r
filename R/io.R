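# ---- unit parsing ----------------------------------------------------------

#' Parse a concentration string with a unit suffix to molar
#'
#' Accepts `"M"`, `"mM"`, `"uM"`/`"µM"`, `"nM"`, `"pM"` suffixes (case
#' sensitive on the prefix) or a bare number, which is taken as molar.
#'
#' @param x character (or numeric) scalar/vector, e.g. `"10 uM"`.
#' @return concentration(s), mol L^-1.
#' @examples
#' parse_concentration("10 uM")
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(x)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(M|mM|uM|µM|nM|pM)?$", s))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("cannot parse concentration: '", s, "'")
    val <- as.numeric(m[2])
    if (is.na(val)) stop("cannot parse concentration: '", s, "'")
    unit <- if (m[3] == "") "M" else m[3]
    val * scale[[unit]]
  }, 0, USE.NAMES = FALSE)
}

# ---- generic commented-header tables ---------------------------------------

# write "# key: value" headers followed by a CSV body
.write_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 15)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# read the "# key: value" headers and CSV body; numeric columns validated
# with line numbers in error messages
.read_table <- function(path, required_cols) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body_start <- which(!is_meta)[1]
  df <- tryCatch(
    utils::read.csv(text = lines[!is_meta], stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse table in ", path, ": ", conditionMessage(e)))
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in required_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' of ", path,
           " at line ", body_start + bad[1],
           " ('", df[[col]][bad[1]], "')")
    df[[col]] <- vals
  }
  list(data = df, meta = meta)
}

# ---- titrations ------------------------------------------------------------

#' Write an ITC titration to delimited text
#'
#' Columns `injection_volume_uL`, `heat_ucal`; the experiment metadata
#' (cell volume, concentrations, temperature) is stored in commented
#' `# key: value` header lines so a file round-trips losslessly.
#'
#' @param exp a `titration_experiment` with heats.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_titration_csv <- function(exp, path) {
  stopifnot(inherits(exp, "titration_experiment"), !is.null(exp$heats))
  .write_table(data.frame(injection_volume_uL = exp$injection_volumes_uL,
                          heat_ucal = exp$heats),
               path,
               meta = list(cell_volume_uL = exp$cell_volume_uL,
                           cell_conc_M = exp$cell_conc,
                           syringe_conc_M = exp$syringe_conc,
                           temperature_K = exp$T))
}

#' Read an ITC titration from delimited text
#'
#' @param path file written by [write_titration_csv()] (or hand-prepared in
#'   the same dialect).
#' @return a `titration_experiment`.
#' @export
read_titration_csv <- function(path) {
  tb <- .read_table(path, c("injection_volume_uL", "heat_ucal"))
  need <- c("cell_volume_uL", "cell_conc_M", "syringe_conc_M", "temperature_K")
  miss <- setdiff(need, names(tb$meta))
  if (length(miss))
    stop("missing metadata in ", path, ": ", paste(miss, collapse = ", "))
  titration_experiment(cell_conc = parse_concentration(tb$meta$cell_conc_M),
                       syringe_conc = parse_concentration(tb$meta$syringe_conc_M),
                       injection_volumes_uL = tb$data$injection_volume_uL,
                       cell_volume_uL = as.numeric(tb$meta$cell_volume_uL),
                       T = as.numeric(tb$meta$temperature_K),
                       heats = tb$data$heat_ucal)
}

# ---- melting curves --------------------------------------------------------

#' Write a melting curve to delimited text
#'
#' Columns `temperature_C`, `signal`; `C_T` (molar) and molecularity in
#' commented headers.
#'
#' @param curve a [melt_curve()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_melt_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melt_curve"))
  .write_table(data.frame(temperature_C = curve$temperature_C,
                          signal = curve$signal),
               path,
               meta = list(C_T_molar = attr(curve, "C_T"),
                           molecularity = attr(curve, "molecularity")))
}

#' Read a melting curve from delimited text
#'
#' Temperatures must be strictly increasing; violations and malformed
#' numeric cells are reported with line numbers.
#'
#' @param path file in the [write_melt_csv()] dialect.
#' @return a [melt_curve()].
#' @export
read_melt_csv <- function(path) {
  tb <- .read_table(path, c("temperature_C", "signal"))
  tC <- tb$data$temperature_C
  bad <- which(diff(tC) <= 0)
  if (length(bad))
    stop("non-monotone temperature in ", path, " near line ",
         which(!grepl("^#", readLines(path)))[1] + bad[1])
  melt_curve(tC, tb$data$signal,
             C_T = if (!is.null(tb$meta$C_T_molar))
               parse_concentration(tb$meta$C_T_molar) else NA_real_,
             molecularity = if (!is.null(tb$meta$molecularity))
               tb$meta$molecularity else "heteroduplex")
}

#' Read a vicinal-coupling set from delimited text
#'
#' Expects a CSV with the three ribose coupling columns
#' `J_H1p_H2p`, `J_H2p_H3p`, `J_H3p_H4p` (Hz), one row per nucleoside; an
#' optional `name` column labels the rows.
#'
#' @param path CSV file.
#' @return a named list of coupling vectors (one per row), each suitable
#'   for [fit_two_state()].
#' @export
read_couplings_csv <- function(path) {
  cols <- c("J_H1p_H2p", "J_H2p_H3p", "J_H3p_H4p")
  tb <- .read_table(path, cols)
  out <- lapply(seq_len(nrow(tb$data)), function(i)
    unlist(tb$data[i, cols]))
  names(out) <- if ("name" %in% names(tb$data)) tb$data$name
                else as.character(seq_along(out))
  out
}

# ---- angle series and umbrella windows -------------------------------------

#' Write a dihedral-angle series as two-column text
#'
#' @param angles angle series, degrees.
#' @param path output file (columns: frame index, angle in degrees).
#' @return the path, invisibly.
#' @export
write_angle_series <- function(angles, path) {
  utils::write.table(data.frame(frame = seq_along(angles), angle_deg = angles),
                     path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a dihedral-angle series from two-column text
#'
#' @param path file with columns frame index and angle (degrees).
#' @return numeric vector of angles, degrees.
#' @export
read_angle_series <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (ncol(df) < 2) stop("angle series must have two columns: frame, angle_deg")
  as.numeric(df[[2]])
}

#' Write an umbrella window file
#'
#' Header lines carry `center_deg`, `k_kcal_per_mol_deg2` and
#' `temperature_K`; the body is one sampled angle per line.
#'
#' @param window an [umbrella_window()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_umbrella_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center_deg: %.10g", window$center),
               sprintf("# k_kcal_per_mol_deg2: %.10g", window$k),
               sprintf("# temperature_K: %.10g", window$T),
               format(window$samples, digits = 12, trim = TRUE)), con)
  invisible(path)
}

#' Read an umbrella window file
#'
#' @param path file in the [write_umbrella_window()] dialect.
#' @return an [umbrella_window()].
#' @export
read_umbrella_window <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- as.numeric(m[3])
  }
  need <- c("center_deg", "k_kcal_per_mol_deg2", "temperature_K")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("missing window metadata in ", path, ": ", paste(miss, collapse = ", "))
  samples <- suppressWarnings(as.numeric(lines[!is_meta & nzchar(lines)]))
  if (anyNA(samples)) stop("non-numeric sample line in ", path)
  umbrella_window(meta$center_deg, meta$k_kcal_per_mol_deg2,
                  samples, meta$temperature_K)
}

#' Read a manifest of umbrella window files
#'
#' @param path text file listing one window-file path per line (relative
#'   paths resolved against the manifest's directory).
#' @return list of [umbrella_window()] objects.
#' @export
read_umbrella_manifest <- function(path) {
  entries <- trimws(readLines(path))
  entries <- entries[nzchar(entries) & !grepl("^#", entries)]
  base <- dirname(path)
  lapply(entries, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_umbrella_window(full)
  })
}

# ---- report ----------------------------------------------------------------

#' Assemble a duplex-thermodynamics analysis report
#'
#' Collects per-duplex thermodynamic states (observed and, where the
#' homodimer correction applies, corrected), melting temperatures and
#' modified-vs-native comparisons into one structure with a rendered text
#' table and machine-readable JSON. Every `dG`/`dH`/`TdS` triple is checked
#' against the triangle identity and all states must share a temperature.
#'
#' @param states named list of [thermo_state()] objects (one per duplex).
#' @param Tm_C optional named numeric of melting temperatures, degrees C.
#' @param comparisons optional named list; each entry `c(modified, native)`
#'   giving two names from `states` to difference via [delta_delta()].
#' @param provenance optional list (inputs, seeds, versions) carried
#'   through to the JSON verbatim.
#' @return object of class `analysis_report`: list with `table`
#'   (data.frame), `deltas` (list), `text` (character), `json` (string).
#' @export
build_report <- function(states, Tm_C = NULL, comparisons = NULL,
                         provenance = NULL) {
  if (!length(states)) stop("at least one thermodynamic state is required")
  stopifnot(all(vapply(states, inherits, TRUE, "thermo_state")))
  Ts <- vapply(states, `[[`, 0, "T")
  if (diff(range(Ts)) > 1e-9)
    stop("all states must share a temperature for a joint report")
  for (nm in names(states)) {
    s <- states[[nm]]
    if (abs(s$dG - (s$dH - s$TdS)) > 1e-9)
      stop("state '", nm, "' violates dG = dH - TdS")
  }
  tab <- data.frame(
    duplex = names(states),
    Kd_nM = vapply(states, function(s) s$Kd * 1e9, 0),
    dH_kcal_mol = vapply(states, `[[`, 0, "dH"),
    TdS_kcal_mol = vapply(states, `[[`, 0, "TdS"),
    dG_kcal_mol = vapply(states, `[[`, 0, "dG"),
    Tm_C = if (is.null(Tm_C)) NA_real_ else unname(Tm_C[names(states)]),
    row.names = NULL)
  deltas <- NULL
  if (!is.null(comparisons)) {
    deltas <- lapply(comparisons, function(pair) {
      dd <- delta_delta(states[[pair[1]]], states[[pair[2]]])
      dd$dTm_C <- if (!is.null(Tm_C)) unname(Tm_C[pair[1]] - Tm_C[pair[2]]) else NA_real_
      dd
    })
  }
  txt <- c(sprintf("Duplex thermodynamics at %.2f K", Ts[1]),
           sprintf("%-12s %10s %8s %8s %8s %8s",
                   "duplex", "Kd(nM)", "dH", "TdS", "dG", "Tm(C)"),
           sprintf("%-12s %10.3g %8.2f %8.2f %8.2f %8.2f",
                   tab$duplex, tab$Kd_nM, tab$dH_kcal_mol, tab$TdS_kcal_mol,
                   tab$dG_kcal_mol, tab$Tm_C))
  if (!is.null(deltas)) {
    txt <- c(txt, "",
             sprintf("%-24s %8s %8s %10s %8s",
                     "comparison", "ddG", "ddH", "ddS(cal)", "dTm(C)"),
             vapply(names(deltas), function(nm) {
               d <- deltas[[nm]]
               sprintf("%-24s %8.2f %8.2f %10.1f %8.1f",
                       nm, d$ddG, d$ddH, d$ddS, d$dTm_C)
             }, ""))
  }
  json <- jsonlite::toJSON(
    list(temperature_K = Ts[1], table = tab, deltas = deltas,
         units = list(energy = "kcal/mol", ddS = "cal/mol/K",
                      Kd = "nM", Tm = "degC"),
         provenance = provenance),
    auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(table = tab, deltas = deltas, text = txt, json = json),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
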