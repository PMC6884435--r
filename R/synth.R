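#' Simulation parameters for synthetic RTLS tracking data
#'
#' Defaults mirror the simulated hospital ward the package targets: 15 zones
#' observed for one hour at a 4-second sampling interval, nurses staying in a
#' zone for at most 120 s, patients for up to the whole hour, and 7 patients
#' per patient type.
#'
#' @param n_nurses number of nurse tags.
#' @param n_patient_types number of patient types (public categories).
#' @param patients_per_type patients per type; total patients is
#'   `n_patient_types * patients_per_type`.
#' @param n_zones number of zones.
#' @param study_duration total observed time in seconds; must be a positive
#'   multiple of `sample_interval`.
#' @param sample_interval RTLS sampling period in seconds.
#' @param nurse_max_stay,patient_max_stay maximum single-zone stay per role,
#'   seconds.
#' @param dropout_rate probability that an individual tracking record is lost
#'   (0 = perfect tracking, the default).
#' @param seed integer seed; generation is deterministic given the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_nurses = 120, n_patient_types = 5, patients_per_type = 7,
                       n_zones = 15, study_duration = 3600, sample_interval = 4,
                       nurse_max_stay = 120, patient_max_stay = 3600,
                       dropout_rate = 0, seed = 1) {
  cfg <- list(
    n_nurses = as.integer(n_nurses),
    n_patient_types = as.integer(n_patient_types),
    patients_per_type = as.integer(patients_per_type),
    n_zones = as.integer(n_zones),
    study_duration = as.integer(study_duration),
    sample_interval = as.integer(sample_interval),
    nurse_max_stay = as.integer(nurse_max_stay),
    patient_max_stay = as.integer(patient_max_stay),
    dropout_rate = as.numeric(dropout_rate),
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_nurses", "n_patient_types", "patients_per_type", "n_zones")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, TRUE))) {
    stop("all counts must be >= 1")
  }
  if (cfg$sample_interval < 1L || cfg$study_duration < 1L ||
      cfg$study_duration %% cfg$sample_interval != 0L) {
    stop("study_duration must be a positive multiple of sample_interval")
  }
  for (fld in c("nurse_max_stay", "patient_max_stay")) {
    if (cfg[[fld]] < cfg$sample_interval || cfg[[fld]] > cfg$study_duration ||
        cfg[[fld]] %% cfg$sample_interval != 0L) {
      stop(fld, " must be a multiple of sample_interval in [sample_interval, study_duration]")
    }
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (cfg$n_patient_types > 26L) stop("at most 26 patient types supported")
  structure(cfg, class = "sim_config")
}

# one tag's trajectory: maximal stays in distinct consecutive zones
sim_tag_periods <- function(tag, role, max_stay, cfg) {
  D <- cfg$study_duration
  dt <- cfg$sample_interval
  nz <- cfg$n_zones
  nmax <- max_stay %/% dt
  st <- integer(0); et <- integer(0); z <- integer(0)
  t <- 0L
  prev <- 0L
  while (t < D) {
    if (nz == 1L) zone <- 1L
    else if (prev == 0L) zone <- sample.int(nz, 1L)
    else {
      zone <- sample.int(nz - 1L, 1L)
      if (zone >= prev) zone <- zone + 1L
    }
    dur <- dt * sample.int(nmax, 1L)
    e <- min(t + dur, D)
    st <- c(st, t); et <- c(et, e); z <- c(z, zone)
    t <- e
    prev <- zone
    if (nz == 1L) { # no distinct zone to move to: stay put until study end
      et[length(et)] <- D
      t <- D
    }
  }
  data.frame(tagID = tag, st = st, et = et, zID = z, tagRole = role,
             stringsAsFactors = FALSE)
}

#' Generate synthetic raw RTLS tracks with ground-truth periods
#'
#' Each tag performs a sequence of stays: the zone is uniform over zones
#' distinct from the previous one, the stay duration uniform on the sampling
#' grid up to the role's maximum, and the final stay is truncated at study
#' end.  A record is emitted at every grid time (then optionally thinned by
#' `dropout_rate`).
#'
#' @param config a [sim_config()].
#' @return list with elements `raw` (data.frame `tagID,tagRole,time,zID`) and
#'   `truth` (the generated stays as a period table, `tagID,st,et,zID,tagRole`).
#' @export
generate_tracks <- function(config) {
  if (!inherits(config, "sim_config")) stop("configuration error: need a sim_config")
  set.seed(config$seed)
  types <- LETTERS[seq_len(config$n_patient_types)]
  nurses <- sprintf("N%03d", seq_len(config$n_nurses))
  n_pat <- config$n_patient_types * config$patients_per_type
  patients <- sprintf("P%03d", seq_len(n_pat))
  pat_roles <- paste0("patient:", rep(types, each = config$patients_per_type))
  per <- vector("list", length(nurses) + length(patients))
  for (i in seq_along(nurses)) {
    per[[i]] <- sim_tag_periods(nurses[i], "nurse", config$nurse_max_stay, config)
  }
  for (j in seq_along(patients)) {
    per[[length(nurses) + j]] <-
      sim_tag_periods(patients[j], pat_roles[j], config$patient_max_stay, config)
  }
  truth <- do.call(rbind, per)
  rownames(truth) <- NULL
  attr(truth, "role_scope") <- "mixed"
  raw <- periods_to_grid(truth, config$sample_interval)
  if (config$dropout_rate > 0) {
    keep <- runif(nrow(raw)) >= config$dropout_rate
    raw <- raw[keep, , drop = FALSE]
    rownames(raw) <- NULL
  }
  list(raw = raw, truth = truth)
}

#' Split raw RTLS data into the two parties' views
#'
#' The hospital receives only patient rows, the labour union only nurse rows;
#' row order is preserved.
#' @param raw data.frame as produced by [generate_tracks()].
#' @return list with data.frames `hospital` and `union`.
#' @export
split_views <- function(raw) {
  is_nurse <- raw$tagRole == "nurse"
  hospital <- raw[!is_nurse, , drop = FALSE]
  union <- raw[is_nurse, , drop = FALSE]
  rownames(hospital) <- rownames(union) <- NULL
  list(hospital = hospital, union = union)
}
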