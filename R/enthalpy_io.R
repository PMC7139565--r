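# Ledger file I/O and the quantum-chemistry log scraper.
#
# File schema (this package's own; no standard exists for species-state
# enthalpy ledgers):
#   CSV:  comment header lines "# unit: hartree|kJ/mol" and
#         "# temperature: <K>", then columns
#         compound_id, solvent, state_code, enthalpy
#   JSON: {"unit": ..., "temperature": ..., "compounds": [
#           {"compound_id", "solvent", "sites", "equivalent_sites",
#            "states": {"<state_code>": <enthalpy>}} ]}
# The unit is declared per file, never per row.

#' Read species-enthalpy ledgers from a file
#'
#' Reads a CSV or JSON ledger file (see the package vignette for the
#' schema) and returns one [enthalpy_ledger()] per compound. Enthalpies are
#' converted to kJ/mol if the file declares `unit: hartree`. Duplicate
#' (compound, state) rows, malformed state codes and a missing
#' all-protonated parent state are errors.
#'
#' @param path path to the ledger file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return named list of `enthalpy_ledger` objects, keyed by compound id.
#' @export
read_ledger <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") read_ledger_json(path) else read_ledger_csv(path)
}

read_ledger_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- parse_header_meta(hdr)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("ledger CSV has no data rows", call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "solvent", "state_code", "enthalpy")
  if (!all(need %in% names(df))) {
    stop("ledger CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  build_ledgers(df, unit = meta$unit)
}

read_ledger_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  unit <- tolower(obj$unit %||% "kJ/mol")
  out <- list()
  for (cmp in obj$compounds) {
    vals <- unlist(cmp$states)
    if (unit == "hartree") vals <- hartree_to_kjmol(vals)
    eq <- NULL
    if (!is.null(cmp$equivalent_sites)) {
      eq <- lapply(cmp$equivalent_sites, function(g) unlist(g))
    }
    led <- enthalpy_ledger(
      compound_id = cmp$compound_id,
      sites = unlist(cmp$sites),
      entries = vals,
      solvent = cmp$solvent %||% "methanol",
      equivalent_sites = eq
    )
    if (led$compound_id %in% names(out)) {
      stop("duplicate compound in ledger file: ", led$compound_id,
           call. = FALSE)
    }
    out[[led$compound_id]] <- led
  }
  if (!length(out)) stop("ledger JSON holds no compounds", call. = FALSE)
  out
}

build_ledgers <- function(df, unit = "kJ/mol") {
  unit <- tolower(unit)
  if (!unit %in% c("kj/mol", "hartree")) {
    stop("ledger unit must be 'kJ/mol' or 'hartree', got '", unit, "'",
         call. = FALSE)
  }
  vals <- as.numeric(df$enthalpy)
  if (unit == "hartree") vals <- hartree_to_kjmol(vals)
  out <- list()
  for (id in unique(df$compound_id)) {
    rows <- df$compound_id == id
    codes <- df$state_code[rows]
    # site set comes from the states themselves; every row must agree
    sites <- names(parse_state_code(codes[[1]])$states)
    keys <- vapply(codes,
                   function(k) state_code(parse_state_code(k, sites = sites)),
                   character(1))
    if (anyDuplicated(keys)) {
      stop("duplicate species state for compound '", id, "': ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "),
           call. = FALSE)
    }
    out[[id]] <- enthalpy_ledger(
      compound_id = id, sites = sites,
      entries = stats::setNames(vals[rows], codes),
      solvent = unique(df$solvent[rows])[[1]]
    )
  }
  out
}

parse_header_meta <- function(hdr) {
  meta <- list(unit = "kJ/mol", temperature = 298.15)
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L) {
      key <- tolower(m[[2]])
      if (key == "unit") meta$unit <- m[[3]]
      if (key == "temperature") meta$temperature <- as.numeric(m[[3]])
    }
  }
  meta
}

#' Write species-enthalpy ledgers to a file
#'
#' Inverse of [read_ledger()]; always writes kJ/mol.
#'
#' @param ledgers a single `enthalpy_ledger` or a list of them.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @param temperature temperature recorded in the file header, kelvin.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledgers, path, format = c("auto", "csv", "json"),
                         temperature = 298.15) {
  format <- match.arg(format)
  if (inherits(ledgers, "enthalpy_ledger")) ledgers <- list(ledgers)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- list(
      unit = "kJ/mol", temperature = temperature,
      compounds = lapply(ledgers, function(l) {
        cmp <- list(compound_id = l$compound_id, solvent = l$solvent,
                    sites = l$sites, states = as.list(l$entries))
        if (!is.null(l$equivalent_sites)) {
          cmp$equivalent_sites <- l$equivalent_sites
        }
        cmp
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(ledgers, function(l) {
      data.frame(compound_id = l$compound_id, solvent = l$solvent,
                 state_code = names(l$entries),
                 enthalpy = unname(l$entries), stringsAsFactors = FALSE)
    }))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# unit: kJ/mol",
                 paste0("# temperature: ", temperature)), con)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Scrape the final thermochemistry from a quantum-chemistry log
#'
#' Extracts the "Sum of electronic and thermal Enthalpies" value from a
#' Gaussian-style text log. When the log holds several matches (one per
#' optimization step), the last one is returned. Matching ignores case,
#' leading whitespace and line numbering.
#'
#' @param log character vector of log lines, a single string with embedded
#'   newlines, or a path to a log file.
#' @return the enthalpy in Hartree (convert with [hartree_to_kjmol()]).
#' @export
scrape_qm_enthalpy <- function(log) {
  if (length(log) == 1L && !grepl("\n", log) && file.exists(log)) {
    log <- readLines(log, warn = FALSE)
  }
  lines <- unlist(strsplit(as.character(log), "\n", fixed = TRUE))
  pat <- "sum of electronic and thermal enthalpies\\s*=\\s*(-?[0-9]*\\.?[0-9]+(?:[dDeE][+-]?[0-9]+)?)"
  m <- regmatches(lines, regexec(pat, lines, ignore.case = TRUE))
  hits <- vapply(m[lengths(m) == 2L], `[`, character(1), 2L)
  if (!length(hits)) stop("no thermochemistry found", call. = FALSE)
  as.numeric(sub("[dD]", "e", hits[[length(hits)]]))
}

#' Round half away from zero
#'
#' Display rounding used in report tables (printed tables use integer
#' kJ/mol); `base::round()` rounds half to even, which would print 100.5
#' as 100.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a per-site descriptor report
#'
#' Writes the CSV report of per-site descriptors with, for declared
#' equivalent-site groups, the group-averaged column and integer-rounded
#' display values alongside the full-precision numbers.
#'
#' @param descriptors output of [descriptor_table()], or a list of
#'   [descriptor_set()] objects (converted via `descriptor_table()`).
#' @param path output CSV path.
#' @return the report data frame, invisibly.
#' @export
write_descriptor_report <- function(descriptors, path) {
  tab <- if (is.data.frame(descriptors)) descriptors
         else descriptor_table(descriptors)
  if (nrow(tab)) {
    for (col in c("bde", "pa", "ete", "bde_avg", "pa_avg", "ete_avg")) {
      tab[[paste0(col, "_display")]] <- round_half_up(tab[[col]])
    }
  } else {
    for (col in c("bde", "pa", "ete", "bde_avg", "pa_avg", "ete_avg")) {
      tab[[paste0(col, "_display")]] <- numeric(0)
    }
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
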