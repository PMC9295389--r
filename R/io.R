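#' Read a region coordinate table
#'
#' Reads the canonical coordinate file: a CSV/TSV with header
#' \code{region_id, x, y, z}, coordinates in mm. The row order of this file
#' defines the canonical region order for the whole pipeline.
#'
#' @param path file path (delimiter inferred from the extension; .tsv/.txt
#'   are tab-separated).
#' @return list with \code{region_ids} (character) and \code{coords}
#'   (B x 3 matrix).
#' @export
read_region_coordinates <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("region_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate file must have columns region_id, x, y, z")
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  list(region_ids = as.character(df$region_id), coords = coords)
}

#' Write a cohort to per-subject CSV files
#'
#' Writes one CSV per subject (first column \code{region_id}, then one
#' column per feature), a \code{manifest.csv} (subject_id, file) and a
#' \code{labels.csv} (subject_id, group) into \code{dir}.
#'
#' @param cohort a \code{cohort}.
#' @param dir output directory (created if needed).
#' @param region_ids character region ids used in the files.
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, region_ids = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(cohort$B))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$subjects))
  for (p in seq_along(cohort$subjects)) {
    df <- data.frame(region_id = region_ids, cohort$subjects[[p]])
    names(df) <- c("region_id", cohort$feature_names)
    files[p] <- paste0(cohort$subject_ids[p], ".csv")
    utils::write.csv(df, file.path(dir, files[p]), row.names = FALSE)
  }
  manifest <- data.frame(subject_id = cohort$subject_ids, file = files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = cohort$subject_ids,
                              group = cohort$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from per-subject CSV files
#'
#' Loads the layout written by \code{\link{write_cohort}}: a manifest
#' listing one feature CSV per subject plus a label table. When
#' \code{region_ids} is given (normally from the coordinate file), each
#' subject's rows are validated against it and reordered to the canonical
#' order if shuffled; unknown or missing regions are a hard error naming
#' the offenders.
#'
#' @param dir directory containing \code{manifest.csv}, \code{labels.csv}
#'   and the per-subject files.
#' @param region_ids optional canonical region order.
#' @return a \code{cohort}.
#' @export
read_cohort <- function(dir, region_ids = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  labels_df <- utils::read.csv(file.path(dir, "labels.csv"),
                               stringsAsFactors = FALSE)
  missing_lab <- setdiff(manifest$subject_id, labels_df$subject_id)
  if (length(missing_lab) > 0L)
    stop("missing label(s) for subject(s): ",
         paste(missing_lab, collapse = ", "))
  subjects <- vector("list", nrow(manifest))
  feature_names <- NULL
  for (p in seq_len(nrow(manifest))) {
    df <- utils::read.csv(file.path(dir, manifest$file[p]),
                          stringsAsFactors = FALSE)
    if (names(df)[1] != "region_id")
      stop("subject file must start with a region_id column: ",
           manifest$file[p])
    if (!is.null(region_ids)) {
      bad <- setdiff(df$region_id, region_ids)
      lost <- setdiff(region_ids, df$region_id)
      if (length(bad) > 0L || length(lost) > 0L)
        stop(sprintf(
          "region ids in %s do not match the coordinate file (unknown: %s; missing: %s)",
          manifest$file[p],
          paste(utils::head(bad, 5), collapse = ","),
          paste(utils::head(lost, 5), collapse = ",")))
      if (!identical(df$region_id, region_ids)) {
        df <- df[match(region_ids, df$region_id), ]
        message("reordered regions to canonical order in ", manifest$file[p])
      }
    }
    subjects[[p]] <- as.matrix(df[, -1, drop = FALSE])
    if (is.null(feature_names)) feature_names <- names(df)[-1]
  }
  labels <- labels_df$group[match(manifest$subject_id, labels_df$subject_id)]
  new_cohort(subjects, labels, subject_ids = manifest$subject_id,
             feature_names = feature_names)
}

#' Hash a configuration object
#'
#' Stable md5 digest of a configuration list via its canonical (sorted-key)
#' JSON serialization; used to stamp result files so any artifact can be
#' traced to the exact settings that produced it.
#'
#' @param config a list of settings.
#' @return character md5 hex digest.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

#' Write a results table with a JSON sidecar
#'
#' Writes the tidy session results to CSV plus a \code{<path>.json} sidecar
#' recording the package version, a config hash and the creation time, so
#' results can be regenerated from their settings.
#'
#' @param records data frame of session records (may have zero rows).
#' @param path output CSV path.
#' @param config optional configuration list recorded in the sidecar.
#' @return the sidecar list, invisibly.
#' @export
write_results <- function(records, path, config = list()) {
  utils::write.csv(records, path, row.names = FALSE)
  sidecar <- list(
    package = "gemdaug",
    version = as.character(utils::packageVersion("gemdaug")),
    config_hash = config_hash(config),
    n_records = nrow(records),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON) run configuration and rejects unknown top-level
#' keys against the published schema: \code{paths}, \code{graph},
#' \code{gemd}, \code{augment}, \code{connectivity}, \code{classifier},
#' \code{log_level}.
#'
#' @param path YAML or JSON file.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  }
  allowed <- c("paths", "graph", "gemd", "augment", "connectivity",
               "classifier", "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}
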