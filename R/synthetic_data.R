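# ---------------------------------------------------------------------------
# Synthetic study-design generator
# ---------------------------------------------------------------------------

#' Default nanoform profiles
#'
#' Six silver-nanoform fingerprints keyed by their ERM identifiers, with
#' system-independent descriptor values fixed once per profile inside the
#' ranges the study design spans: two hydroxyethylcellulose-coated variants
#' (solution and powder), an uncoated and a PVP-coated reference, a
#' HEC-ratio variant and a curcumin-coated variant.  `hydro_base` and
#' `pdi_base` are the dispersion anchors in cell-culture medium at t0;
#' `ec50_base` the midpoint dose (ppm) of the Hill dose-response for A549.
#'
#' @return data.frame, one row per nanoform.
#' @export
default_profiles <- function() {
  p <- data.frame(
    erm_id = c("ERM00000548", "ERM00000549", "ERM00000552",
               "ERM00000559", "ERM00000575", "ERM00000580"),
    coating = c("PVP", "none", "HEC", "HEC", "HEC", "CUR"),
    o1s_at = c(20.0, 14.2, 34.0, 34.5, 40.0, 25.0),
    ag3d_at = c(16.0, 30.0, 1.5, 0.19, 0.12, 0.30),
    c1s_at = c(60.0, 54.3, 61.0, 62.0, 58.0, 63.0),
    na1s_at = c(0.5, 0.0, 1.2, 1.5, 1.8, 0.0),
    n1s_at = c(1.0, 0.0, 0.0, 0.0, 0.0, 0.4),
    core_size = c(20.0, 25.0, 17.8, 7.0, 10.0, 15.0),
    crystallinity = c(61.0, 65.0, 60.0, 22.9, 45.0, 55.0),
    avg_crystallite_size = c(117.0, 120.0, 98.0, 46.0, 60.0, 80.0),
    hydro_base = c(150, 300, 220, 60, 90, 130),
    pdi_base = c(0.30, 0.55, 0.45, 0.20, 0.25, 0.35),
    ec50_base = c(8, 5, 40, 60, 80, 20),
    stringsAsFactors = FALSE
  )
  p$spherical_surface_area <- spherical_surface_area(p$core_size)
  p
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic study design.  Defaults reproduce the
#' layout of the measured dataset: 6 nanoforms, lung exposures (A549 with
#' MTT and Alamar blue) over 0.1--100 ppm, intestinal exposures (HCT-116
#' with WST-1, digested and non-digested) over 1.25--100 ppm, triplicates --
#' 900 rows in total -- with 47% missingness on the four DLS columns and 19%
#' on spherical surface area.
#'
#' @param profiles data.frame as [default_profiles()].
#' @param dose_grid Optional single dose grid (ppm) used for both organs;
#'   overrides the two organ-specific grids.
#' @param dose_grid_lung,dose_grid_intestinal Dose grids (ppm) per organ.
#' @param replicates Replicate measurements per condition.
#' @param hill_slope Hill coefficient of the dose-response (> 0).
#' @param noise_sd Standard deviation of viability noise (% viability).
#' @param cellline_ec50_mult Named multipliers applied to `ec50_base` per
#'   cell line.
#' @param digested_ec50_mult EC50 multiplier for digested pretreatment
#'   (simulated gastrointestinal passage attenuates silver toxicity).
#' @param agglomeration_rate Fractional growth of hydrodynamic size from t0
#'   to t24 per log10(1 + dose) unit.
#' @param dose_size_rate Mild dose dependence of the t0 hydrodynamic size.
#' @param missing_rates Named per-column missingness probabilities.
#' @param anchor_doses Optional "measured-dose subset" mode: when non-NULL,
#'   DLS columns are blanked deterministically at every dose not in this
#'   set (instead of at random), to exercise dose interpolation.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(profiles = default_profiles(),
                             dose_grid = NULL,
                             dose_grid_lung =
                               c(0.1, 0.5, 1, 2.5, 5, 10, 15, 20, 25,
                                 40, 50, 75, 100),
                             dose_grid_intestinal =
                               c(1.25, 2.5, 5, 10, 15, 20, 25, 40, 50,
                                 60, 75, 100),
                             replicates = 3,
                             hill_slope = 1.5,
                             noise_sd = 8,
                             cellline_ec50_mult = c("A549" = 1,
                                                    "HCT-116" = 1.5),
                             digested_ec50_mult = 2.5,
                             agglomeration_rate = 0.35,
                             dose_size_rate = 0.05,
                             missing_rates = c(
                               hydro_size_t0 = 0.47, hydro_size_t24 = 0.47,
                               pdi_t0 = 0.47, pdi_t24 = 0.47,
                               spherical_surface_area = 0.19),
                             anchor_doses = NULL,
                             seed = 1L) {
  if (!is.null(dose_grid)) {
    dose_grid_lung <- dose_grid
    dose_grid_intestinal <- dose_grid
  }
  if (!nrow(profiles)) stop("config error: empty profile list")
  if (!length(dose_grid_lung) || !length(dose_grid_intestinal))
    stop("config error: empty dose grid")
  if (any(profiles$ec50_base <= 0)) stop("config error: ec50 must be > 0")
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("config error: missing_rates must be in [0, 1]")
  structure(list(
    profiles = profiles,
    dose_grid_lung = sort(dose_grid_lung),
    dose_grid_intestinal = sort(dose_grid_intestinal),
    replicates = replicates,
    hill_slope = hill_slope,
    noise_sd = noise_sd,
    cellline_ec50_mult = cellline_ec50_mult,
    digested_ec50_mult = digested_ec50_mult,
    agglomeration_rate = agglomeration_rate,
    dose_size_rate = dose_size_rate,
    missing_rates = missing_rates,
    anchor_doses = anchor_doses,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Read a generator configuration from a key/value text file
#'
#' Plain-text `key: value` lines (YAML subset); vector values are
#' comma-separated, named vectors use `name=value` pairs.  Unknown keys
#' raise an error naming the key.
#'
#' @param path File path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = FALSE)
  args <- list()
  for (pair in kv) {
    key <- trimws(pair[[1L]])
    val <- trimws(paste(pair[-1L], collapse = ":"))
    parts <- trimws(strsplit(val, ",")[[1L]])
    if (all(grepl("=", parts))) {
      nv <- strsplit(parts, "=")
      out <- vapply(nv, function(x) as.numeric(trimws(x[[2L]])), 0)
      names(out) <- vapply(nv, function(x) trimws(x[[1L]]), "")
      args[[key]] <- out
    } else {
      num <- suppressWarnings(as.numeric(parts))
      args[[key]] <- if (any(is.na(num))) parts else num
    }
  }
  known <- names(formals(generator_config))
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(generator_config, args)
}

ec50_for <- function(config, profile_row, cell_line, pretreatment) {
  e <- profile_row$ec50_base * config$cellline_ec50_mult[[cell_line]]
  if (identical(pretreatment, "digested")) e <- e * config$digested_ec50_mult
  e
}

hill_viability <- function(dose, ec50, slope) {
  100 / (1 + (dose / ec50)^slope)
}

#' Generate a synthetic experiment table
#'
#' Builds the full condition grid (nanoform x cell-line-compatible assay x
#' pretreatment x dose x replicate), draws viability from a Hill
#' dose-response `V = 100 / (1 + (dose/EC50)^h) + e`,
#' `e ~ Normal(0, noise_sd)`, models agglomeration as
#' `hydro_size_t24 = hydro_size_t0 * (1 + rate * log10(1 + dose))` with the
#' polydispersity index tracking the relative size growth, and finally
#' injects missingness at the configured rates.  Deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return data.frame in canonical schema.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  profiles <- config$profiles
  grid_list <- list()
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    lung <- expand.grid(assay = c("MTT", "AlamarBlue"),
                        dose = config$dose_grid_lung,
                        stringsAsFactors = FALSE)
    lung$cell_line <- "A549"; lung$organ <- "lung"
    lung$pretreatment <- "none"
    lung$cell_type <- "alveolar epithelial"
    lung$multiwell <- "96-well"
    gut <- expand.grid(assay = "WST-1",
                       pretreatment = c("digested", "non-digested"),
                       dose = config$dose_grid_intestinal,
                       stringsAsFactors = FALSE)
    gut$cell_line <- "HCT-116"; gut$organ <- "intestine"
    gut$cell_type <- "colon epithelial"
    gut$multiwell <- "96-well"
    cond <- rbind(lung[, c("assay", "pretreatment", "dose", "cell_line",
                           "organ", "cell_type", "multiwell")],
                  gut[, c("assay", "pretreatment", "dose", "cell_line",
                          "organ", "cell_type", "multiwell")])
    cond <- cond[rep(seq_len(nrow(cond)), each = config$replicates), ]
    cond$replicate <- rep(seq_len(config$replicates),
                          times = nrow(cond) / config$replicates)
    for (col in c("erm_id", "coating"))
      cond[[col]] <- pr[[col]]
    for (col in c("o1s_at", "ag3d_at", "c1s_at", "na1s_at", "n1s_at",
                  "core_size", "spherical_surface_area", "crystallinity",
                  "avg_crystallite_size"))
      cond[[col]] <- pr[[col]]
    ec50 <- vapply(seq_len(nrow(cond)), function(j)
      ec50_for(config, pr, cond$cell_line[[j]], cond$pretreatment[[j]]), 0)
    cond$ec50 <- ec50
    cond$hydro_base <- pr$hydro_base
    cond$pdi_base <- pr$pdi_base
    grid_list[[i]] <- cond
  }
  dat <- do.call(rbind, grid_list)
  rownames(dat) <- NULL

  # dispersion state: deterministic given stratum and dose
  logd <- log10(1 + dat$dose)
  dat$hydro_size_t0 <- dat$hydro_base * (1 + config$dose_size_rate * logd)
  growth <- config$agglomeration_rate * logd
  dat$hydro_size_t24 <- dat$hydro_size_t0 * (1 + growth)
  dat$pdi_t0 <- dat$pdi_base
  dat$pdi_t24 <- pmin(dat$pdi_base * (1 + 0.6 * growth), 1.5)

  set.seed(config$seed)
  eps <- if (config$noise_sd > 0)
    rnorm(nrow(dat), 0, config$noise_sd) else 0
  dat$viability <- hill_viability(dat$dose, dat$ec50, config$hill_slope) + eps
  dat$duration <- 24
  dat$ec50 <- dat$hydro_base <- dat$pdi_base <- dat$replicate <- NULL

  ord <- intersect(dataset_schema()$column, names(dat))
  dat <- dat[, ord, drop = FALSE]

  if (!is.null(config$anchor_doses)) {
    blank <- !dat$dose %in% config$anchor_doses
    for (col in dls_columns()) dat[[col]][blank] <- NA_real_
  }
  inject_missingness(dat, config$missing_rates, seed = config$seed + 1L)
}

#' Blank cells at random (missing completely at random)
#'
#' Independently blanks each targeted cell with its per-column probability.
#' Outcome and identifier columns may never be blanked.
#'
#' @param dataset data.frame in canonical schema.
#' @param missing_rates Named vector of probabilities per column.
#' @param seed Integer seed (deterministic given the seed).
#' @return The dataset with `NA`s injected.
#' @export
inject_missingness <- function(dataset, missing_rates, seed = 1L) {
  if (!length(missing_rates)) return(dataset)
  protected <- schema_columns(c("output", "identifier"))
  bad <- intersect(names(missing_rates), protected)
  if (length(bad))
    stop("config error: missingness requested on protected column(s): ",
         paste(bad, collapse = ", "))
  absent <- setdiff(names(missing_rates), names(dataset))
  if (length(absent))
    stop("config error: missingness target column(s) not in dataset: ",
         paste(absent, collapse = ", "))
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("config error: rates must be in [0, 1]")
  set.seed(seed)
  for (col in names(missing_rates)) {
    r <- missing_rates[[col]]
    if (r == 0) next
    hit <- runif(nrow(dataset)) < r
    dataset[[col]][hit] <- NA
  }
  dataset
}
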