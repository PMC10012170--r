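#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate approx as.formula chisq.test cor median
#'   predict quantile rbinom rnorm runif sd setNames var hclust cutree dist
#' @importFrom utils read.csv write.csv head combn
NULL

# ---------------------------------------------------------------------------
# Dataset schema
# ---------------------------------------------------------------------------

#' Hazard classes, from most to least hazardous
#'
#' The three-state cytotoxicity outcome used throughout the pipeline,
#' following the ISO 10993-5 viability thresholds: `very_toxic` (< 30%
#' viability), `toxic` (30--70%), `safe` (>= 70%).  The order encodes
#' increasing safety and is relied upon by the precautionary tie-break in
#' [predict_class()].
#'
#' @return Character vector `c("very_toxic", "toxic", "safe")`.
#' @export
hazard_classes <- function() c("very_toxic", "toxic", "safe")

#' Column schema of the experiment table
#'
#' One row per canonical column with its role (`numeric_input`,
#' `categorical_input`, `output`, `identifier`) and storage type.  System-
#' independent descriptors (XPS atomic concentrations, TEM core size,
#' spherical surface area, XRD crystallinity / crystallite size, coating)
#' are constant per nanoform; system-dependent descriptors (DLS hydrodynamic
#' size and polydispersity index at t0 and t24) vary with the exposure
#' condition and may be missing.
#'
#' @return A data.frame with columns `column`, `role`, `type`.
#' @export
dataset_schema <- function() {
  num <- c("o1s_at", "ag3d_at", "c1s_at", "na1s_at", "n1s_at",
           "core_size", "spherical_surface_area", "crystallinity",
           "avg_crystallite_size",
           "hydro_size_t0", "hydro_size_t24", "pdi_t0", "pdi_t24",
           "dose", "duration")
  cat <- c("coating", "organ", "cell_line", "cell_type", "multiwell",
           "pretreatment", "assay")
  data.frame(
    column = c("erm_id", num, cat, "viability"),
    role = c("identifier",
             rep("numeric_input", length(num)),
             rep("categorical_input", length(cat)),
             "output"),
    type = c("character",
             rep("numeric", length(num)),
             rep("character", length(cat)),
             "numeric"),
    stringsAsFactors = FALSE
  )
}

schema_columns <- function(role = NULL) {
  sc <- dataset_schema()
  if (is.null(role)) sc$column else sc$column[sc$role %in% role]
}

# system-dependent numeric descriptors measured in medium (DLS)
dls_columns <- function() {
  c("hydro_size_t0", "hydro_size_t24", "pdi_t0", "pdi_t24")
}

#' Default column-name aliases for reading external tables
#'
#' Maps spreadsheet-style headers (e.g. `"Ag 3d_Atomic concentration"`) onto
#' the canonical schema names.  Users can extend or override entries by
#' passing a modified map to [read_dataset()].
#'
#' @return Named character vector: names are external headers (matched
#'   case-insensitively after squashing whitespace), values are canonical
#'   column names.
#' @export
default_aliases <- function() {
  c("erm" = "erm_id",
    "erm code" = "erm_id",
    "erm identifier" = "erm_id",
    "na 1s_atomic concentration" = "na1s_at",
    "o 1s_atomic concentration" = "o1s_at",
    "ag 3d_atomic concentration" = "ag3d_at",
    "c 1s_atomic concentration" = "c1s_at",
    "n 1s_atomic concentration" = "n1s_at",
    "na 1s_atomic" = "na1s_at",
    "o 1s_atomic" = "o1s_at",
    "ag 3d_atomic" = "ag3d_at",
    "c 1s_atomic" = "c1s_at",
    "n 1s_atomic" = "n1s_at",
    "core size" = "core_size",
    "spherical surface area" = "spherical_surface_area",
    "crystallinity" = "crystallinity",
    "average crystallite sizes" = "avg_crystallite_size",
    "av crystallite sizes" = "avg_crystallite_size",
    "coating" = "coating",
    "hydrodynamic size (z-average) t0" = "hydro_size_t0",
    "hydrodynamic size (z-average) t24" = "hydro_size_t24",
    "hydrodynamic size t0" = "hydro_size_t0",
    "hydrodynamic size t24" = "hydro_size_t24",
    "polydispersity index t0" = "pdi_t0",
    "polydispersity index t24" = "pdi_t24",
    "pol index t0" = "pdi_t0",
    "pol index t24" = "pdi_t24",
    "organ" = "organ",
    "cell line (code)" = "cell_line",
    "cell line" = "cell_line",
    "cell type" = "cell_type",
    "multiwell" = "multiwell",
    "pretreatment" = "pretreatment",
    "exposure dose" = "dose",
    "exposure duration" = "duration",
    "assay" = "assay",
    "cellular viability" = "viability")
}

normalize_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# ---------------------------------------------------------------------------
# Reading and writing
# ---------------------------------------------------------------------------

#' Read an experiment table from CSV, TSV or XLSX
#'
#' Reads a flat table with one row per in-vitro exposure condition, renames
#' headers onto the canonical schema via the alias map, coerces column
#' types, and keeps empty cells as explicit `NA`.  Units are taken as
#' declared (nm, %, ppm); no conversion is performed.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"xlsx"`; `"auto"`
#'   guesses from the file extension.
#' @param aliases Alias map as in [default_aliases()].
#' @param sheet Sheet name for XLSX input (default `"v01"`, falling back to
#'   the first sheet when absent).
#' @return A data.frame in canonical column order (missing optional columns
#'   are absent, not invented).
#' @export
read_dataset <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                         aliases = default_aliases(), sheet = "v01") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  raw <- switch(format,
    csv = read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA")),
    tsv = read.csv(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA")),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package")
      sheets <- readxl::excel_sheets(path)
      if (!sheet %in% sheets) sheet <- sheets[[1L]]
      as.data.frame(readxl::read_excel(path, sheet = sheet),
                    stringsAsFactors = FALSE)
    })
  canonical <- dataset_schema()$column
  nm <- names(raw)
  norm <- normalize_header(nm)
  alias_norm <- normalize_header(names(aliases))
  mapped <- ifelse(norm %in% canonical, norm,
                   unname(aliases[match(norm, alias_norm)]))
  unknown <- nm[is.na(mapped)]
  if (length(unknown))
    warning("ignoring unrecognized column(s): ",
            paste(unknown, collapse = ", "))
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]

  mandatory <- c("erm_id", "dose", "viability", "cell_line", "assay")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("schema error: mandatory column(s) missing: ",
         paste(missing_cols, collapse = ", "))

  sc <- dataset_schema()
  for (col in intersect(names(raw), sc$column)) {
    type <- sc$type[sc$column == col]
    if (type == "numeric" && !is.numeric(raw[[col]])) {
      vals <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(vals))
      if (length(bad))
        stop("parse error: non-numeric value in column '", col,
             "' at row(s) ", paste(head(bad, 5), collapse = ", "))
      raw[[col]] <- vals
    }
    if (type == "character") raw[[col]] <- as.character(raw[[col]])
  }
  ord <- intersect(canonical, names(raw))
  raw[, c(ord, setdiff(names(raw), ord)), drop = FALSE]
}

#' Write an experiment table to CSV
#'
#' Inverse of [read_dataset()]: values are written at full precision and
#' missing cells as empty strings, so a write/read round trip preserves
#' records and order exactly.
#'
#' @param dataset A data.frame in canonical schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export the column schema as JSON
#'
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
schema_to_json <- function(path = NULL) {
  txt <- jsonlite::toJSON(dataset_schema(), pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---------------------------------------------------------------------------
# Closed-form derived quantities
# ---------------------------------------------------------------------------

#' Spherical surface area from the tabulated core size
#'
#' Assumes a perfectly spherical particle and applies `4 * pi * s^2` with
#' the tabulated core-size value `s` plugged directly into the squared term
#' (i.e. treated as the radius).  This convention reproduces the tabulated reference
#' tabulated bin edges: `4 * pi * 17.8^2 = 3981.45` and
#' `4 * pi * 20^2 = 5026.55`.
#'
#' @param core_size Core size in nm (non-negative).
#' @return Surface area in nm^2.
#' @export
spherical_surface_area <- function(core_size) {
  if (any(!is.na(core_size) & core_size < 0))
    stop("core_size must be non-negative")
  4 * pi * core_size^2
}

#' Map cellular viability to a hazard class
#'
#' ISO 10993-5 thresholds: viability >= 70% is `safe`, 30--70% (left-closed)
#' is `toxic`, below 30% is `very_toxic`.  Values above 100% (assay noise)
#' are retained and classify as `safe`.
#'
#' @param viability Numeric vector of viability percentages.
#' @return Factor with levels [hazard_classes()].
#' @export
classify_viability <- function(viability) {
  if (any(is.na(viability)))
    stop("viability must be observed (no missing values)")
  if (any(!is.finite(viability)))
    stop("viability must be finite")
  cls <- ifelse(viability >= 70, "safe",
                ifelse(viability >= 30, "toxic", "very_toxic"))
  factor(cls, levels = hazard_classes())
}

# ---------------------------------------------------------------------------
# Dataset validation
# ---------------------------------------------------------------------------

#' Validate schema invariants of an experiment table
#'
#' Checks (and reports, never repairs): 24 h exposure duration; the cell
#' line / assay pairing (A549 with MTT or AlamarBlue, HCT-116 with WST-1);
#' digestion pretreatment restricted to HCT-116; and constancy of the
#' system-independent profile per ERM identifier.
#'
#' @param dataset A data.frame in canonical schema.
#' @return Character vector of human-readable violations (empty when clean).
#' @export
validate_dataset <- function(dataset) {
  problems <- character()
  if ("duration" %in% names(dataset)) {
    bad <- which(!is.na(dataset$duration) & dataset$duration != 24)
    if (length(bad))
      problems <- c(problems, sprintf(
        "%d row(s) with exposure duration != 24 h", length(bad)))
  }
  if (all(c("cell_line", "assay") %in% names(dataset))) {
    bad <- with(dataset,
      (cell_line == "A549" & !assay %in% c("MTT", "AlamarBlue")) |
      (cell_line == "HCT-116" & assay != "WST-1"))
    if (any(bad, na.rm = TRUE))
      problems <- c(problems, sprintf(
        "%d row(s) with incompatible cell line / assay pairing",
        sum(bad, na.rm = TRUE)))
  }
  if (all(c("cell_line", "pretreatment") %in% names(dataset))) {
    bad <- with(dataset,
      pretreatment %in% c("digested", "non-digested") &
        cell_line != "HCT-116")
    if (any(bad, na.rm = TRUE))
      problems <- c(problems, sprintf(
        "%d row(s) with digestion pretreatment outside HCT-116",
        sum(bad, na.rm = TRUE)))
  }
  prof_cols <- intersect(
    c("coating", "o1s_at", "ag3d_at", "c1s_at", "na1s_at", "n1s_at",
      "core_size", "spherical_surface_area", "crystallinity",
      "avg_crystallite_size"),
    names(dataset))
  if ("erm_id" %in% names(dataset) && length(prof_cols)) {
    for (col in prof_cols) {
      n_distinct <- tapply(dataset[[col]], dataset$erm_id,
                           function(v) length(unique(v[!is.na(v)])))
      off <- names(n_distinct)[!is.na(n_distinct) & n_distinct > 1]
      if (length(off))
        problems <- c(problems, sprintf(
          "profile column '%s' varies within erm_id(s): %s",
          col, paste(off, collapse = ", ")))
    }
  }
  problems
}
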