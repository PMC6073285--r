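#' Aggregate pipeline configuration
#'
#' Composes the per-stage configurations with a study mode, seed and output
#' directory. The configuration (plus seed) fully determines a study run;
#' analysis stages contain no randomness of their own.
#'
#' @param mode `"proximity"`, `"accumulation"` or `"timecourse"`.
#' @param synthetic A [synthetic_params] (simulation block).
#' @param segmentation A [segmentation_config].
#' @param proximity A [proximity_config].
#' @param accumulation An [accumulation_config].
#' @param ages,marker Time-course settings (mode `"timecourse"`).
#' @param n_replicates Replicate synthetic fields per age.
#' @param seed Master seed; overrides `synthetic$seed`.
#' @param out_dir Optional output directory; when set, result files are
#'   written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("proximity", "accumulation",
                                     "timecourse"),
                            synthetic = synthetic_params(),
                            segmentation = segmentation_config(),
                            proximity = proximity_config(),
                            accumulation = accumulation_config(),
                            ages = c("P0", "P21", "adult"), marker = "TH",
                            n_replicates = 3L, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "timecourse" && is.null(.positivity_table[[marker]]))
    nmj_config_error(sprintf("no time-course defaults for marker '%s'", marker))
  cfg <- list(mode = mode, synthetic = synthetic,
              segmentation = segmentation, proximity = proximity,
              accumulation = accumulation, ages = ages, marker = marker,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# Deterministic MD5 hash of a configuration (seed included).
config_hash <- function(cfg) {
  x <- cfg
  x$out_dir <- NULL
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

#' Reproducibility metadata for a pipeline run
#'
#' @param cfg A [pipeline_config].
#' @param stage_counts Optional named counts of retained objects per stage.
#' @return List with the configuration hash, seed, package version and
#'   stage counts. Deliberately excludes wall-clock time so that result
#'   files are byte-identical across reruns.
#' @export
log_provenance <- function(cfg, stage_counts = NULL) {
  list(config_hash = config_hash(cfg), seed = cfg$seed,
       package_version = as.character(utils::packageVersion("nmjquant")),
       stage_counts = stage_counts)
}

#' Run a full simulated proximity study
#'
#' simulate -> binarize -> label -> size-filter -> edge-exclude (postsynapse
#' channel only) -> nearest marker -> distance distribution. Per-stage
#' object counts are kept in the provenance record; excluded objects are
#' counted, never silently dropped. Deterministic given the configuration
#' and seed. When `cfg$out_dir` is set, per-NMJ records, the histogram and
#' the provenance are written as CSV/JSON.
#'
#' @param cfg A [pipeline_config] (mode `"proximity"`).
#' @param volume Optional pre-made [volume_image] (channels `BGT` +
#'   marker); when `NULL` the synthetic block is simulated.
#' @return A `proximity_result`: `records`, `fraction_below` (at the
#'   configured cutoff), `distribution`, `stage_counts`, `truth` (when
#'   simulated) and `provenance`.
#' @export
run_proximity_study <- function(cfg = pipeline_config("proximity"),
                                volume = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  if (is.null(volume)) {
    p <- cfg$synthetic
    p$seed <- cfg$seed
    truth <- generate_geometry(p)
    volume <- render_volume(truth, p)
  }
  marker_name <- setdiff(volume$channel_names, "BGT")[1]
  seg <- cfg$segmentation
  if (is.null(seg$intensity_bounds[[marker_name]])) {
    seg$intensity_bounds[[marker_name]] <- c(20, 255)
  }
  nmj_lo <- segment_channel(volume, "BGT", "postsynapse", seg)
  if (nrow(nmj_lo$objects) == 0L)
    nmj_validation_error(
      "no postsynaptic objects retained: check intensity/size bounds and edge exclusion")
  mark_lo <- segment_channel(volume, marker_name, "marker", seg)
  records <- nearest_marker(nmj_lo, mark_lo, volume$voxel_size)
  dist <- distance_distribution(records, cfg$proximity$bin_width_um)
  frac <- proximity_fraction(records, cfg$proximity$threshold_um)
  counts <- list(postsynapse = attr(nmj_lo, "stage_counts"),
                 marker = attr(mark_lo, "stage_counts"))
  prov <- log_provenance(cfg, counts)
  res <- structure(list(records = records, fraction_below = frac,
                        threshold_um = cfg$proximity$threshold_um,
                        distribution = dist, stage_counts = counts,
                        truth = truth, marker = marker_name,
                        provenance = prov),
                   class = "proximity_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(records, file.path(cfg$out_dir, "proximity_records.csv"))
    write_results(dist$histogram,
                  file.path(cfg$out_dir, "distance_histogram.csv"))
    jsonlite::write_json(
      list(provenance = prov,
           fraction_below = stats::setNames(frac,
             sprintf("lt_%g_um", cfg$proximity$threshold_um))),
      file.path(cfg$out_dir, "proximity_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "proximity_result (%s): %d NMJ objects, %.1f%% at < %g um\n",
    x$marker, nrow(x$records), 100 * x$fraction_below, x$threshold_um))
  invisible(x)
}

# standard error of the mean
.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Run a simulated developmental time-course study
#'
#' For each age, renders `n_replicates` synthetic cross-section fields at
#' the marker's configured positivity fraction, runs the accumulation
#' analysis on each, and summarizes the percentage of immunopositive NMJs
#' as mean and SEM over replicates.
#'
#' @param cfg A [pipeline_config] (mode `"timecourse"`).
#' @return A `timecourse_result`: `records` (one row per age x replicate),
#'   `summary` (per-age mean, SEM and truth fraction) and `provenance`.
#' @export
run_timecourse_study <- function(cfg = pipeline_config("timecourse")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  rows <- list()
  for (k in seq_along(cfg$ages)) {
    age <- cfg$ages[k]
    for (rep_i in seq_len(cfg$n_replicates)) {
      sets <- generate_timecourse(
        age, cfg$marker, seed = child_seed(cfg$seed, 1000L * k + rep_i),
        base_params = list(image_shape = cfg$synthetic$image_shape,
                           n_nmjs = cfg$synthetic$n_nmjs))
      vol <- sets[[1]]$volume
      truth <- sets[[1]]$truth
      acc <- accumulation_study(vol, cfg$marker, cfg$accumulation)
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, replicate = rep_i,
        n_analyzed = acc$summary$n_analyzed,
        n_positive = acc$summary$n_positive,
        percent_positive = acc$summary$percent_positive,
        truth_fraction = mean(truth$nmj$positive))
    }
  }
  records <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(records, factor(records$age,
                                                      levels = cfg$ages)),
    function(d) data.frame(age = d$age[1],
                           mean_percent = mean(d$percent_positive),
                           sem_percent = .sem(d$percent_positive),
                           truth_fraction = d$truth_fraction[1],
                           n_replicates = nrow(d))))
  rownames(summ) <- NULL
  prov <- log_provenance(cfg)
  res <- structure(list(records = records, summary = summ, provenance = prov,
                        marker = cfg$marker),
                   class = "timecourse_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(records, file.path(cfg$out_dir, "timecourse_records.csv"))
    write_results(summ, file.path(cfg$out_dir, "timecourse_summary.csv"))
    jsonlite::write_json(prov,
                         file.path(cfg$out_dir, "timecourse_provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat(sprintf("timecourse_result (%s):\n", x$marker))
  print(x$summary)
  invisible(x)
}
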