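#' Estimate the credit of ecological interactions
#'
#' The credit an animal reintroduction can cash in a focal area is the number
#' of plant species present there that are documented interaction partners of
#' the animal: the size of the intersection between the area's flora list and
#' the animal's interaction (diet) reference. The intersection itself — the
#' eligible set — is returned for downstream filtering of monitoring events.
#'
#' @param flora a `flora_list` (see [read_flora()]) or character vector of
#'   plant identifiers present in the focal area.
#' @param reference an `interaction_reference` (see
#'   [read_interaction_reference()]) or character vector of documented
#'   partner plants.
#' @return a `credit_estimate`: list with `credit0` (integer), `eligible`
#'   (character vector of shared species, in flora order) and `animal_id`.
#' @examples
#' est <- estimate_credit(c("A", "B", "C"), c("B", "C", "D"))
#' est$credit0  # 2
#' @export
estimate_credit <- function(flora, reference) {
  flora_ids <- species_ids_of(flora, "flora")
  if (length(flora_ids) == 0L) {
    stop("flora list is empty: cannot estimate a credit without a flora")
  }
  ref_ids <- species_ids_of(reference, "reference")
  animal_id <- if (inherits(reference, "interaction_reference")) {
    reference$animal_id
  } else {
    "animal"
  }
  eligible <- flora_ids[flora_ids %in% ref_ids]
  if (length(eligible) == 0L) {
    warning("flora and interaction reference share no species: ",
            "credit0 = 0, nothing can be rewired by this reintroduction")
  }
  structure(
    list(credit0 = length(eligible), eligible = eligible,
         animal_id = animal_id),
    class = "credit_estimate"
  )
}

# Extract canonical, unique species ids from the various containers the
# credit functions accept.
species_ids_of <- function(x, what) {
  ids <- if (inherits(x, "flora_list")) {
    x$species_id
  } else if (inherits(x, "interaction_reference")) {
    x$plant_ids
  } else if (is.character(x)) {
    canonicalize_species(x)
  } else if (is.data.frame(x) && "species_id" %in% names(x)) {
    canonicalize_species(x$species_id)
  } else {
    stop("cannot interpret ", what, " of class ", class(x)[1])
  }
  unique(ids)
}

#' @export
print.credit_estimate <- function(x, ...) {
  cat("Credit of ecological interactions for '", x$animal_id, "': credit0 = ",
      x$credit0, "\n", sep = "")
  invisible(x)
}

#' Count flagged species among the eligible set
#'
#' Flora lists may carry boolean trait flags (for instance, large-seeded tree
#' species that rely on the reintroduced disperser for recruitment). This
#' counts how many eligible species carry a given flag.
#'
#' @param eligible a [estimate_credit()] result or character vector.
#' @param flora a `flora_list` whose schema contains the flag column.
#' @param flag flag column name, e.g. `"large_seeded_reliant"`.
#' @return integer count.
#' @export
count_flagged <- function(eligible, flora, flag = "large_seeded_reliant") {
  if (inherits(eligible, "credit_estimate")) eligible <- eligible$eligible
  eligible <- canonicalize_species(eligible)
  if (!is.data.frame(flora) || !"species_id" %in% names(flora)) {
    stop("flora must be a flora_list data frame with a species_id column")
  }
  if (!flag %in% names(flora)) {
    stop("unknown flag '", flag, "'; flora columns are: ",
         paste(names(flora), collapse = ", "))
  }
  vals <- flora[[flag]][match(eligible, flora$species_id)]
  sum(vals %in% TRUE)
}

#' Build an interaction accumulation curve from a monitoring log
#'
#' Converts time-stamped interaction records from post-release monitoring
#' into a cumulative curve of interaction richness: per time bin, the number
#' of distinct eligible plant species observed at least once up to the end of
#' that bin. A species is rewired at its first observation of any evidence
#' type; evidence types are kept for reporting only. Events on species
#' outside the eligible set never enter the curve but are tallied as
#' "unexpected interactions"; events beyond the horizon are dropped and
#' counted. Observed richness is a lower bound on true rewiring (no
#' detection-probability correction is applied).
#'
#' Every input event is accounted for exactly once:
#' `eligible first observations + eligible repeats + unexpected +
#' beyond horizon + evidence-filtered = total events`.
#'
#' @param log a `monitoring_log` (see [read_monitoring_log()]) or data frame
#'   with columns `time_months`, `plant_id` and optionally `evidence`.
#' @param eligible a [estimate_credit()] result or character vector of
#'   credit-eligible species.
#' @param bin_width bin width in months (> 0); default 1 month.
#' @param horizon last time covered by the curve, in months; events beyond it
#'   are dropped (with a count in the accounting). Defaults to the latest
#'   event time rounded up to a whole bin; required when the log is empty.
#' @param evidence optional subset of evidence types to keep
#'   (`"fruit_consumption"`, `"seed_burial"`, `"other"`); default all.
#' @return an `accumulation_curve`: list with `bin_start`, `bin_end`,
#'   `cumulative` richness per bin, `n_eligible`, the per-species
#'   `first_observation` table, and the event `accounting`.
#' @examples
#' log <- data.frame(time_months = c(1.2, 3.7, 2.0),
#'                   plant_id = c("x", "x", "y"))
#' curve <- accumulation_curve(log, eligible = c("x", "y"), horizon = 4)
#' curve$cumulative
#' @export
accumulation_curve <- function(log, eligible, bin_width = 1, horizon = NULL,
                               evidence = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (inherits(eligible, "credit_estimate")) eligible <- eligible$eligible
  eligible <- unique(canonicalize_species(eligible))
  events <- as_monitoring_events(log)
  n_total <- nrow(events)

  n_filtered <- 0L
  if (!is.null(evidence)) {
    bad <- setdiff(evidence, evidence_types())
    if (length(bad)) stop("unknown evidence type(s): ", paste(bad, collapse = ", "))
    keep <- events$evidence %in% evidence
    n_filtered <- sum(!keep)
    events <- events[keep, , drop = FALSE]
  }

  if (is.null(horizon)) {
    if (nrow(events) == 0L) {
      stop("horizon is required when the monitoring log has no events")
    }
    horizon <- bin_width * ceiling(max(events$time_months) / bin_width)
  }
  if (horizon <= 0) stop("horizon must be > 0")

  beyond <- events$time_months > horizon
  n_beyond <- sum(beyond)
  events <- events[!beyond, , drop = FALSE]

  is_eligible <- events$plant_id %in% eligible
  n_unexpected <- sum(!is_eligible)
  unexpected_species <- sort(unique(events$plant_id[!is_eligible]))
  elig_events <- events[is_eligible, , drop = FALSE]

  if (nrow(elig_events) > 0L) {
    first_time <- tapply(elig_events$time_months, elig_events$plant_id, min)
    first_observation <- data.frame(
      species_id = names(first_time),
      first_time = as.numeric(first_time),
      stringsAsFactors = FALSE
    )
    first_observation <- first_observation[order(first_observation$first_time,
                                                 first_observation$species_id), ]
    rownames(first_observation) <- NULL
  } else {
    first_observation <- data.frame(species_id = character(),
                                    first_time = numeric())
  }
  n_first <- nrow(first_observation)
  n_repeat <- nrow(elig_events) - n_first

  n_bins <- as.integer(ceiling(horizon / bin_width - 1e-9))
  bin_end <- bin_width * seq_len(n_bins)
  bin_start <- bin_end - bin_width
  cumulative <- vapply(bin_end,
                       function(e) sum(first_observation$first_time <= e),
                       integer(1))

  structure(
    list(bin_start = bin_start, bin_end = bin_end, cumulative = cumulative,
         n_eligible = length(eligible), bin_width = bin_width,
         horizon = horizon, first_observation = first_observation,
         unexpected_species = unexpected_species,
         accounting = list(n_events = n_total,
                           n_eligible_first = n_first,
                           n_eligible_repeat = n_repeat,
                           n_unexpected = n_unexpected,
                           n_beyond_horizon = n_beyond,
                           n_evidence_filtered = n_filtered)),
    class = "accumulation_curve"
  )
}

evidence_types <- function() c("fruit_consumption", "seed_burial", "other")

# Normalise the accepted log representations to a canonical event frame.
as_monitoring_events <- function(log) {
  if (!is.data.frame(log)) stop("monitoring log must be a data frame")
  need <- c("time_months", "plant_id")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("monitoring log lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(is.na(log$time_months)) || any(log$time_months < 0)) {
    stop("event times must be non-negative months since release")
  }
  ev <- if ("evidence" %in% names(log)) as.character(log$evidence)
        else rep("other", nrow(log))
  out <- data.frame(time_months = as.numeric(log$time_months),
                    plant_id = canonicalize_species(as.character(log$plant_id)),
                    evidence = ev, stringsAsFactors = FALSE)
  out[order(out$time_months), , drop = FALSE]  # stable for tied times
}

#' @export
print.accumulation_curve <- function(x, ...) {
  final <- if (length(x$cumulative)) x$cumulative[length(x$cumulative)] else 0L
  cat("Interaction accumulation curve: ", length(x$bin_end), " bins of ",
      x$bin_width, " month(s), horizon ", x$horizon, " months\n",
      "  cumulative richness at horizon: ", final, " of ", x$n_eligible,
      " eligible species (observed minima)\n",
      "  unexpected interactions: ", x$accounting$n_unexpected,
      " event(s) on ", length(x$unexpected_species), " species\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.accumulation_curve <- function(x, ...) {
  data.frame(bin_start = x$bin_start, bin_end = x$bin_end,
             cumulative_richness = x$cumulative)
}

#' @export
plot.accumulation_curve <- function(x, credit0 = NULL, ...) {
  plot(c(0, x$bin_end), c(0, x$cumulative), type = "s",
       xlab = "months since release", ylab = "interaction richness", ...)
  if (!is.null(credit0)) graphics::abline(h = credit0, lty = 2)
  invisible(x)
}

#' Remaining credit per time bin
#'
#' The complement of the accumulation curve: how much of the initial credit
#' of ecological interactions is still to be cashed in each bin.
#' Conservation (`cumulative + remaining = credit0`) holds in every bin.
#'
#' @param curve an [accumulation_curve()].
#' @param credit0 the initial credit, at least the curve's maximum (a curve
#'   exceeding `credit0` signals an eligibility-filter bug upstream).
#' @return numeric vector of remaining credit, one value per bin.
#' @export
remaining_credit <- function(curve, credit0) {
  stopifnot(inherits(curve, "accumulation_curve"))
  if (length(curve$cumulative) && max(curve$cumulative) > credit0) {
    stop("accumulation curve exceeds credit0 (", credit0,
         "): eligible set and credit estimate are inconsistent")
  }
  credit0 - curve$cumulative
}

#' Assess reintroduction success against a credit proportion
#'
#' A reintroduction is considered successful once all the credit of
#' ecological interactions — or an a priori defined proportion of it — has
#' been cashed. The threshold in species counts is `ceiling(proportion *
#' credit0)`, compared with the integer cumulative richness.
#'
#' @param curve an [accumulation_curve()].
#' @param credit0 the initial credit (> 0 for a defined assessment).
#' @param proportion target proportion of the credit, in (0, 1]; default 1.
#' @return a `success_report`: list with `achieved` (logical; `NA` when
#'   `credit0 = 0`, where success is undefined), `proportion_cashed`,
#'   `threshold_species`, and `time_achieved` in months (`NA` = not yet).
#' @examples
#' log <- data.frame(time_months = 1:3, plant_id = c("a", "b", "c"))
#' cv <- accumulation_curve(log, c("a", "b", "c", "d"), horizon = 4)
#' success_assessment(cv, credit0 = 4, proportion = 0.5)
#' @export
success_assessment <- function(curve, credit0, proportion = 1) {
  stopifnot(inherits(curve, "accumulation_curve"))
  if (proportion <= 0 || proportion > 1) {
    stop("proportion must lie in (0, 1]")
  }
  if (credit0 == 0) {
    return(structure(
      list(achieved = NA, proportion_cashed = NA_real_,
           threshold_species = NA_integer_, time_achieved = NA_real_,
           credit0 = 0L, proportion = proportion,
           note = "credit0 is zero: there is nothing to cash, success is undefined"),
      class = "success_report"
    ))
  }
  if (credit0 < 0) stop("credit0 must be non-negative")
  # tolerance keeps ceiling() honest when proportion * credit0 is an integer
  threshold <- as.integer(ceiling(proportion * credit0 - 1e-9))
  cum_max <- if (length(curve$cumulative)) max(curve$cumulative) else 0L
  achieved <- cum_max >= threshold
  hit <- which(curve$cumulative >= threshold)
  structure(
    list(achieved = achieved,
         proportion_cashed = cum_max / credit0,
         threshold_species = threshold,
         time_achieved = if (length(hit)) curve$bin_end[hit[1]] else NA_real_,
         credit0 = as.integer(credit0), proportion = proportion,
         note = NULL),
    class = "success_report"
  )
}

#' @export
print.success_report <- function(x, ...) {
  if (is.na(x$achieved)) {
    cat("Success assessment undefined:", x$note, "\n")
    return(invisible(x))
  }
  cat("Success assessment: target ", x$proportion * 100, "% of credit0 = ",
      x$credit0, " (threshold ", x$threshold_species, " species)\n",
      "  proportion cashed: ", format(x$proportion_cashed, digits = 3),
      "; achieved: ", x$achieved,
      if (x$achieved) paste0(" at month ", x$time_achieved) else " (not yet)",
      "\n", sep = "")
  invisible(x)
}
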