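#' @name ecocredit-files
#' @title File schemas used by the credit toolkit
#' @description
#' All inputs are delimited text (comma by default, configurable) with a
#' header row, UTF-8, `#` comment lines allowed. Species identifiers are
#' canonicalized (trimmed, whitespace-collapsed, case-folded) on ingestion
#' and duplicated species rows are collapsed with a message.
#' \describe{
#'   \item{flora}{`species_id[, <boolean flag columns>]` — the focal-area
#'     flora, e.g. with a `large_seeded_reliant` flag.}
#'   \item{interaction reference}{`animal_id, plant_id[, source]` — literature
#'     records of the animal's diet/interactions.}
#'   \item{monitoring log}{`time_months, plant_id[, evidence]` — time-stamped
#'     interaction records from post-release monitoring; `evidence` is one of
#'     `fruit_consumption`, `seed_burial`, `other`.}
#'   \item{species pool}{`species_id, occupancy_weight` — weights in (0, 1].}
#' }
NULL

# Shared low-level reader: header, required columns, typed coercion with
# row-level diagnostics (line numbers count the header as line 1).
read_delim_checked <- function(path, required, numeric_cols = character(),
                               delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, sep = delim, comment.char = "#",
                    stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("cannot read ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0L && ncol(df) == 0L) stop("empty file: ", path)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(is.na(raw) | raw == ""))
    if (length(bad)) {
      stop(path, ", line ", bad[1] + 1L, ": cannot parse '", raw[bad[1]],
           "' as a number in column '", col, "'")
    }
    df[[col]] <- v
  }
  df
}

parse_logical_col <- function(x, col, path) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(path, ", line ", bad[1] + 1L, ": cannot parse '", x[bad[1]],
         "' as logical in column '", col, "'")
  }
  out
}

new_flora_list <- function(df, flags = NULL) {
  ids <- canonicalize_species(df$species_id)
  out <- data.frame(species_id = ids, stringsAsFactors = FALSE)
  if (!is.null(flags)) for (nm in names(flags)) out[[nm]] <- flags[[nm]]
  extra <- setdiff(names(df), "species_id")
  for (nm in extra) out[[nm]] <- df[[nm]]
  if (anyDuplicated(out$species_id)) {
    n_dup <- sum(duplicated(out$species_id))
    message("collapsed ", n_dup, " duplicate flora row(s) after ",
            "canonicalization (flags combined with OR)")
    flag_cols <- setdiff(names(out), "species_id")
    agg <- lapply(flag_cols, function(nm) {
      tapply(out[[nm]], out$species_id, function(v) any(v %in% TRUE))
    })
    uids <- sort(unique(out$species_id))
    out <- data.frame(species_id = uids, stringsAsFactors = FALSE)
    for (i in seq_along(flag_cols)) out[[flag_cols[i]]] <- as.logical(agg[[i]][uids])
  }
  rownames(out) <- NULL
  structure(out, class = c("flora_list", "data.frame"))
}

new_interaction_reference <- function(animal_id, plant_ids) {
  plant_ids <- unique(canonicalize_species(plant_ids))
  structure(list(animal_id = as.character(animal_id), plant_ids = plant_ids),
            class = "interaction_reference")
}

new_monitoring_log <- function(df) {
  if (any(df$time_months < 0, na.rm = TRUE) || any(is.na(df$time_months))) {
    stop("monitoring log times must be non-negative months since release")
  }
  ev <- if ("evidence" %in% names(df)) as.character(df$evidence)
        else rep("other", nrow(df))
  bad <- which(!ev %in% evidence_types())
  if (length(bad)) {
    stop("unknown evidence type '", ev[bad[1]], "' (line ", bad[1] + 1L,
         "); expected one of: ", paste(evidence_types(), collapse = ", "))
  }
  out <- data.frame(time_months = as.numeric(df$time_months),
                    plant_id = canonicalize_species(as.character(df$plant_id)),
                    evidence = ev, stringsAsFactors = FALSE)
  out <- out[order(out$time_months), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("monitoring_log", "data.frame"))
}

#' Read a focal-area flora list
#'
#' @param path delimited text file with column `species_id` and optional
#'   boolean flag columns (see [ecocredit-files]).
#' @param delim field delimiter; default comma.
#' @return a `flora_list` data frame with canonical, unique species ids.
#' @export
read_flora <- function(path, delim = ",") {
  df <- read_delim_checked(path, required = "species_id", delim = delim)
  for (col in setdiff(names(df), "species_id")) {
    df[[col]] <- parse_logical_col(df[[col]], col, path)
  }
  new_flora_list(df)
}

#' Read an interaction (diet) reference list
#'
#' @param path delimited text file with columns `animal_id`, `plant_id` and
#'   optional `source`.
#' @param animal which animal to extract when the file records several;
#'   default the only one present (several without a choice is an error).
#' @param delim field delimiter.
#' @return an `interaction_reference` (animal id + unique partner plants).
#' @export
read_interaction_reference <- function(path, animal = NULL, delim = ",") {
  df <- read_delim_checked(path, required = c("animal_id", "plant_id"),
                           delim = delim)
  animals <- unique(canonicalize_species(df$animal_id))
  if (is.null(animal)) {
    if (length(animals) > 1L) {
      stop(path, " records ", length(animals),
           " animals; pick one with the 'animal' argument: ",
           paste(animals, collapse = ", "))
    }
    animal <- animals
  } else {
    animal <- canonicalize_species(animal)
    if (!animal %in% animals) {
      stop("animal '", animal, "' not found in ", path)
    }
  }
  keep <- canonicalize_species(df$animal_id) == animal
  new_interaction_reference(animal, df$plant_id[keep])
}

#' Read a post-release monitoring log
#'
#' @param path delimited text file with columns `time_months`, `plant_id`
#'   and optional `evidence` (one of `fruit_consumption`, `seed_burial`,
#'   `other`; missing column means `other`).
#' @param delim field delimiter.
#' @return a `monitoring_log` data frame, sorted by time (stable ties).
#' @export
read_monitoring_log <- function(path, delim = ",") {
  df <- read_delim_checked(path, required = c("time_months", "plant_id"),
                           numeric_cols = "time_months", delim = delim)
  new_monitoring_log(df)
}

#' Read / write a species pool
#'
#' Pools are serialized as two-column delimited text
#' (`species_id, occupancy_weight`).
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return `read_pool()`: a `species_pool`.
#' @export
read_pool <- function(path, delim = ",") {
  df <- read_delim_checked(path, required = c("species_id", "occupancy_weight"),
                           numeric_cols = "occupancy_weight", delim = delim)
  new_species_pool(df$species_id, df$occupancy_weight)
}

#' @rdname read_pool
#' @param pool a `species_pool` to write.
#' @param provenance optional `#` comment lines written before the header.
#' @export
write_pool <- function(pool, path, provenance = NULL) {
  stopifnot(inherits(pool, "species_pool"))
  write_output(as.data.frame(pool), path, provenance)
}

# All writers funnel through here: optional provenance comment lines, then a
# plain CSV with header. Inputs are never modified in place.
write_output <- function(df, path, provenance = NULL, delim = ",") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.table(as.data.frame(df), con, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a rewiring trajectory to disk
#'
#' `write_trajectory()` emits the long format (`replicate, step,
#' cumulative_richness`); `write_trajectory_summary()` emits the per-step
#' band (`step, mean, min, max, remaining_credit_mean`).
#'
#' @param traj a [simulate_rewiring()] trajectory.
#' @param path output file.
#' @param credit0 credit used for the remaining-credit column; defaults to
#'   the partner degree.
#' @param provenance optional `#` comment lines.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, provenance = NULL) {
  stopifnot(inherits(traj, "rewiring_trajectory"))
  long <- data.frame(
    replicate = rep(seq_len(traj$n_replicates), times = length(traj$steps)),
    step = rep(traj$steps, each = traj$n_replicates),
    cumulative_richness = as.vector(traj$richness)
  )
  long <- long[order(long$replicate, long$step), ]
  write_output(long, path, provenance)
}

#' @rdname write_trajectory
#' @export
write_trajectory_summary <- function(traj, path, credit0 = traj$degree,
                                     provenance = NULL) {
  s <- summarize_trajectory(traj)
  s$remaining_credit_mean <- credit0 - s$mean
  write_output(s, path, provenance)
}

#' Write an accumulation curve with its remaining-credit column
#'
#' @param curve an [accumulation_curve()].
#' @param credit0 initial credit for the remaining-credit column.
#' @param path output file.
#' @param provenance optional `#` comment lines.
#' @return invisibly, `path`.
#' @export
write_accumulation_curve <- function(curve, credit0, path, provenance = NULL) {
  df <- as.data.frame(curve)
  df$remaining_credit <- remaining_credit(curve, credit0)
  write_output(df, path, provenance)
}

#' Path to a packaged example file
#'
#' The package ships small plain-text fixtures under `inst/extdata`: a toy
#' agouti-style case (`toy_flora.csv`, `toy_reference.csv`,
#' `toy_monitoring.csv`; 12 flora species, credit 8, 4 flagged large-seeded,
#' 6 species observed within 15 months) and a larger synthetic emulation of
#' the agouti reintroduction (`synthetic_tnp_flora.csv`,
#' `synthetic_tnp_reference.csv`, `synthetic_tnp_monitoring.csv`; credit 65,
#' 23 flagged, at least 23 species observed within 15 months — synthetic
#' data, not the original study records).
#'
#' @param file file name, or `NULL` to list the available files.
#' @return a path, or a character vector of file names.
#' @examples
#' ecocredit_example()
#' read_flora(ecocredit_example("toy_flora.csv"))
#' @export
ecocredit_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "ecocredit"))
  } else {
    path <- system.file("extdata", file, package = "ecocredit")
    if (path == "") stop("no packaged example file called '", file, "'")
    path
  }
}
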