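#' Percentile rank of a quality indicator against a reference population
#'
#' Mid-rank percentile: `100 * (worse + 0.5 * equal) / n`, where `worse`
#' counts reference values inferior to `value` under the indicator's
#' direction and ties count half. Monotone in `value` for a fixed sample
#' and direction, and symmetric between the two directions.
#'
#' @param value the indicator value for the structure under assessment.
#' @param reference_sample non-empty numeric vector of the indicator over a
#'   reference population.
#' @param direction `"lower-better"` (e.g. clash count) or
#'   `"higher-better"` (e.g. atom inclusion).
#' @return Percentile in `[0, 100]`.
#' @export
percentile_rank <- function(value, reference_sample,
                            direction = c("lower-better", "higher-better")) {
  direction <- match.arg(direction)
  n <- length(reference_sample)
  if (n == 0L) stop("empty reference sample")
  worse <- if (direction == "lower-better") sum(reference_sample > value)
  else sum(reference_sample < value)
  equal <- sum(reference_sample == value)
  100 * (worse + 0.5 * equal) / n
}

# recognized map metadata keys -> display labels
.map_info_keys <- c(reconstruction_method = "reconstruction method",
                    reported_resolution = "reported resolution",
                    resolution_method = "resolution method",
                    imposed_symmetry = "imposed symmetry",
                    number_of_images = "number of images used",
                    microscope = "microscope",
                    imaging_parameters = "imaging parameters",
                    detector = "detector")

#' Build the map information table
#'
#' Normalizes recognized experiment-metadata keys into labeled rows
#' (attaching Angstrom units to the reported resolution), renders missing
#' keys as "not provided", and passes unrecognized keys through under the
#' "other" section. Never fails on sparse metadata.
#'
#' @param metadata named list or character vector of experiment metadata.
#' @return A data frame with columns `field`, `value`, `section`
#'   (`"map"` or `"other"`).
#' @export
map_info_table <- function(metadata = list()) {
  metadata <- as.list(metadata)
  val <- function(key) {
    v <- metadata[[key]]
    if (is.null(v) || length(v) == 0L || (is.character(v) && !nzchar(v[1])))
      return("not provided")
    v <- as.character(v[1])
    if (key == "reported_resolution" && !grepl("Å|A$|Angstrom", v))
      v <- paste0(v, " Å")
    v
  }
  rows <- data.frame(field = unname(.map_info_keys),
                     value = vapply(names(.map_info_keys), val, character(1)),
                     section = "map", stringsAsFactors = FALSE)
  extra <- setdiff(names(metadata), names(.map_info_keys))
  if (length(extra))
    rows <- rbind(rows, data.frame(
      field = extra,
      value = vapply(extra, function(k) as.character(metadata[[k]][1]),
                     character(1)),
      section = "other", stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Read slider reference populations from JSON
#'
#' Schema: an object mapping indicator names to objects with `direction`
#' and numeric arrays `em` and `all` (the indicator over all EM structures
#' and over all archive structures). A small synthetic sample ships at
#' `system.file("extdata", "ref_populations_synthetic.json",
#' package = "emval")`.
#'
#' @param path JSON file path.
#' @return Named list of populations.
#' @export
read_reference_populations <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# per-section error capture: a failed section is recorded, not fatal
try_section <- function(expr) {
  tryCatch(c(list(status = "ok"), expr),
           error = function(e) list(status = "failed",
                                    error = conditionMessage(e)))
}

fingerprint <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "density_map"))
    sprintf("map:%s;voxel=%s;mean=%.8g;rms=%.8g",
            paste(dim(x$data), collapse = "x"),
            paste(signif(x$voxel_size, 8), collapse = ","),
            x$header_stats$mean, x$header_stats$rms)
  else if (inherits(x, "atom_model"))
    sprintf("model:%datoms;coordsum=%.8g",
            nrow(x$atoms), sum(x$atoms$x) + sum(x$atoms$y) + sum(x$atoms$z))
  else sprintf("object:%s", paste(class(x), collapse = ","))
}

#' Assemble an EM validation report
#'
#' Runs every applicable assessment for the inputs provided — map summary
#' statistics, FSC resolution estimation from a half-map pair,
#' trace-geometry and contact checks, atom inclusion — collects the key
#' quality indicators (clashes per 1000 atoms, trace-bond outlier
#' fractions, pseudo-Ramachandran outlier fraction, atom inclusion
#' fraction) and, when reference populations are supplied, their percentile
#' sliders against the EM-only and whole-archive populations. Partial
#' failures are recorded per section and never abort the report.
#'
#' @param map primary [density_map], or `NULL`.
#' @param model an [atom_model], or `NULL`. At least one of `map`/`model`
#'   is required.
#' @param half_maps optional list of two [density_map]s for FSC.
#' @param metadata named list of experiment metadata (see
#'   [map_info_table()]); the key `recommended_contour` feeds atom
#'   inclusion when `contour` is not given.
#' @param references a [reference_distributions]; defaults to the packaged
#'   synthetic set when a model is present.
#' @param populations slider reference populations (see
#'   [read_reference_populations()]), or `NULL` to skip percentiles.
#' @param contour density level for atom inclusion (map units).
#' @param config list of options: `n_bins` (histogram, default 128),
#'   `n_levels` (contour curve, default 64), `overlap_tolerance`,
#'   `sigma_multiplier`, `seed`, `timestamp` (override for reproducible
#'   output).
#' @return An object of class `em_validation_report` (a named list,
#'   serializable with [write_report_json()]).
#' @export
assemble_report <- function(map = NULL, model = NULL, half_maps = NULL,
                            metadata = list(), references = NULL,
                            populations = NULL, contour = NULL,
                            config = list()) {
  if (is.null(map) && is.null(model))
    stop("at least one of 'map' and 'model' is required")
  cfg <- utils::modifyList(list(n_bins = 128L, n_levels = 64L,
                                overlap_tolerance = 0.4,
                                sigma_multiplier = 3, seed = NULL,
                                timestamp = NULL), config)
  if (is.null(references) && !is.null(model))
    references <- default_reference_distributions()
  if (is.null(contour) && !is.null(metadata$recommended_contour))
    contour <- as.numeric(metadata$recommended_contour)

  report <- list(schema_version = "1.0")
  report$map_info <- map_info_table(metadata)

  if (!is.null(map)) {
    report$map <- try_section({
      s <- recompute_stats(map)
      h <- density_histogram(map, cfg$n_bins)
      lv <- seq(s$min, s$max, length.out = cfg$n_levels)
      vc <- volume_vs_contour(map, lv)
      ps <- rotational_power_spectrum(map)
      list(dimensions = dim(map$data), voxel_size = map$voxel_size,
           origin = map$origin, stats = s,
           histogram = list(breaks = h$breaks, counts = h$counts),
           volume_curve = list(levels = vc$levels, volumes = vc$volumes),
           power_spectrum = list(frequencies = ps$frequencies,
                                 power = ps$power))
    })
  }

  if (!is.null(half_maps)) {
    report$fsc <- try_section({
      curve <- compute_fsc(half_maps[[1]], half_maps[[2]])
      est <- estimate_resolutions(curve)
      list(curve = list(frequencies = curve$frequencies,
                        correlations = curve$correlations,
                        shell_counts = curve$shell_counts,
                        nyquist = curve$nyquist),
           estimates = est)
    })
  }

  indicators <- list()
  if (!is.null(model)) {
    report$model <- try_section({
      tr <- classify_trace(model)
      gf <- geometry_findings(model, references,
                              overlap_tolerance = cfg$overlap_tolerance,
                              sigma_multiplier = cfg$sigma_multiplier)
      s <- gf$summary
      inc <- if (!is.null(map) && !is.null(contour))
        atom_inclusion(model, map, contour) else NULL
      ind <- list(
        clash_per_1000_atoms = list(
          value = 1000 * s$clashes / s$n_atoms, direction = "lower-better"),
        caca_outlier_fraction = list(
          value = if (s$caca_evaluated > 0)
            s$caca_outliers / s$caca_evaluated else NA,
          direction = "lower-better"),
        pp_outlier_fraction = list(
          value = if (s$pp_evaluated > 0)
            s$pp_outliers / s$pp_evaluated else NA,
          direction = "lower-better"),
        rama_outlier_fraction = list(
          value = if (!is.na(s$rama_evaluated) && s$rama_evaluated > 0)
            s$rama_outliers / s$rama_evaluated else NA,
          direction = "lower-better"))
      if (!is.null(inc))
        ind$atom_inclusion_fraction <- list(value = inc$fraction,
                                            direction = "higher-better")
      indicators <- ind
      list(trace_annotation = tr, findings_summary = s,
           caca_outliers = gf$caca[gf$caca$outlier, , drop = FALSE],
           pp_outliers = gf$pp[gf$pp$outlier, , drop = FALSE],
           rama_outliers = if (!is.null(gf$rama))
             gf$rama[gf$rama$outlier, , drop = FALSE] else NULL,
           clashes = gf$clashes,
           atom_inclusion = if (!is.null(inc))
             list(contour = contour, fraction = inc$fraction,
                  n_outside = sum(!inc$atoms$inside)) else NULL)
    })
  }

  report$indicators <- lapply(names(indicators), function(nm) {
    ind <- indicators[[nm]]
    out <- list(name = nm, value = ind$value, direction = ind$direction,
                percentile_vs_em = NULL, percentile_vs_all = NULL)
    pop <- populations[[nm]]
    if (!is.null(pop) && !is.na(ind$value)) {
      if (length(pop$em))
        out$percentile_vs_em <- percentile_rank(ind$value, pop$em,
                                                ind$direction)
      if (length(pop$all))
        out$percentile_vs_all <- percentile_rank(ind$value, pop$all,
                                                 ind$direction)
    }
    out
  })

  report$provenance <- list(
    tool = "emval",
    version = as.character(utils::packageVersion("emval")),
    timestamp = if (!is.null(cfg$timestamp)) cfg$timestamp
    else format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = cfg$seed,
    inputs = Filter(Negate(is.null), list(
      map = fingerprint(map), model = fingerprint(model),
      half_map_a = if (!is.null(half_maps)) fingerprint(half_maps[[1]]),
      half_map_b = if (!is.null(half_maps)) fingerprint(half_maps[[2]]))),
    reference_set = if (!is.null(references)) references$id else NULL,
    thresholds = list(pp_short = if (!is.null(references))
      references$pp_short else 4.4,
      pp_long = if (!is.null(references)) references$pp_long else 8.0,
      sigma_multiplier = cfg$sigma_multiplier,
      overlap_tolerance = cfg$overlap_tolerance))

  structure(report, class = "em_validation_report")
}

#' Write a validation report as JSON
#'
#' @param report an `em_validation_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "em_validation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Validate the structure of a report
#'
#' Checks the report against the published schema: required top-level
#' fields, per-section status markers, and percentile ranges.
#'
#' @param report an `em_validation_report` or a list read back from its
#'   JSON serialization.
#' @return `TRUE` invisibly; otherwise an error describing every violation.
#' @export
validate_report <- function(report) {
  problems <- character(0)
  need <- c("schema_version", "map_info", "indicators", "provenance")
  miss <- setdiff(need, names(report))
  if (length(miss))
    problems <- c(problems, paste("missing fields:",
                                  paste(miss, collapse = ", ")))
  for (sec in intersect(c("map", "fsc", "model"), names(report))) {
    st <- report[[sec]]$status
    if (is.null(st) || !st %in% c("ok", "failed"))
      problems <- c(problems, paste0("section '", sec,
                                     "' lacks a valid status"))
  }
  for (ind in report$indicators) {
    for (p in c("percentile_vs_em", "percentile_vs_all")) {
      v <- ind[[p]]
      if (!is.null(v) && (v < 0 || v > 100))
        problems <- c(problems, paste0(ind$name, ": ", p, " out of [0,100]"))
    }
    if (is.null(ind$direction) ||
        !ind$direction %in% c("lower-better", "higher-better"))
      problems <- c(problems, paste0(ind$name, ": invalid direction"))
  }
  if (!is.null(report$provenance) &&
      is.null(report$provenance$version))
    problems <- c(problems, "provenance lacks tool version")
  if (length(problems))
    stop("report schema violations:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Write an atom model as a PDB file
#'
#' @param model an [atom_model].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "atom_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, elesy = a$elesy, o = a$o, b = a$b)
  invisible(path)
}
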