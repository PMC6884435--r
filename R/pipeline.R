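#' Full run configuration
#'
#' Bundles the simulation, binning, clustering and field parameters together
#' with the execution mode; serialisable to a single YAML file.
#'
#' @param sim a [sim_config()].
#' @param bins a [time_bins()].
#' @param kmeans a [kmeans_config()].
#' @param field field preset name: `"mersenne127"` or `"paper64"`.
#' @param mode `"plaintext"` or `"secure"`.
#' @param addressing cell addressing in secure mode: `"public"` or
#'   `"oblivious"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), bins = time_bins(),
                       kmeans = kmeans_config(), field = "mersenne127",
                       mode = c("plaintext", "secure"),
                       addressing = c("public", "oblivious")) {
  mode <- match.arg(mode)
  addressing <- match.arg(addressing)
  if (!field %in% c("mersenne127", "paper64")) stop("unknown field preset: ", field)
  if (kmeans$k > sim$n_nurses) {
    stop("configuration error: k exceeds the number of nurses")
  }
  structure(list(sim = sim, bins = bins, kmeans = kmeans, field = field,
                 mode = mode, addressing = addressing),
            class = "run_config")
}

field_from_preset <- function(name) {
  switch(name, mersenne127 = field_mersenne127(), paper64 = field_paper64(),
         stop("unknown field preset: ", name))
}

#' Read/write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    sim = unclass(config$sim),
    bins = list(boundaries = config$bins$boundaries),
    kmeans = unclass(config$kmeans),
    field = config$field, mode = config$mode, addressing = config$addressing
  ), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    sim = do.call(sim_config, y$sim),
    bins = time_bins(y$bins$boundaries),
    kmeans = do.call(kmeans_config, y$kmeans),
    field = y$field %||% "mersenne127",
    mode = y$mode %||% "plaintext",
    addressing = y$addressing %||% "public"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message("[wardmpc] ", ...)

#' Run the full analysis pipeline
#'
#' Generates synthetic RTLS data, splits it into the two parties' views,
#' extracts periods locally per party, builds the facing-time table and
#' clusters the nurses -- in plaintext or, for the joint phases, as the
#' two-party secure protocol.  Writes every intermediate artifact under
#' `out_dir` and logs shapes and seeds to stderr.  In secure mode the facing
#' table is never revealed (it stays secret-shared between the phases); the
#' written outputs are the cluster assignment, the convergence flag, and the
#' transcript statistics.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`facing` in
#'   plaintext mode, `clusters`, `converged`, and in secure mode
#'   `gate_counts`/`dealer`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(out_dir, f)
  stage <- "generate"
  res <- tryCatch({
    log_msg("generate: ", config$sim$n_nurses, " nurses, ",
            config$sim$n_patient_types * config$sim$patients_per_type,
            " patients, seed ", config$sim$seed)
    gen <- generate_tracks(config$sim)
    write_raw_rtls(gen$raw, art("raw_rtls.csv"))
    views <- split_views(gen$raw)
    write_raw_rtls(views$hospital, art("hospital_view.csv"))
    write_raw_rtls(views$union, art("union_view.csv"))

    stage <- "preprocess"
    nurse_p <- extract_periods(views$union, config$sim$sample_interval)
    patient_p <- extract_periods(views$hospital, config$sim$sample_interval)
    write_period_table(nurse_p, art("nurse_periods.csv"))
    write_period_table(patient_p, art("patient_periods.csv"))
    log_msg("preprocess: ", nrow(nurse_p), " nurse periods, ",
            nrow(patient_p), " patient periods")

    nurse_ids <- sprintf("N%03d", seq_len(config$sim$n_nurses))
    type_labels <- LETTERS[seq_len(config$sim$n_patient_types)]

    if (config$mode == "plaintext") {
      stage <- "build-table"
      ft <- build_facing_table(nurse_p, patient_p, config$bins, nurse_ids, type_labels)
      write_facing_table(ft, art("facing_table.csv"))
      log_msg("build-table: ", sum(ft$counts), " interactions")
      stage <- "cluster"
      km <- facing_kmeans(ft, config$kmeans)
      out <- list(facing = ft, membership = km$membership,
                  converged = km$converged,
                  clusters = data.frame(nID = nurse_ids, cluster = km$assignments,
                                        stringsAsFactors = FALSE))
    } else {
      stage <- "secure"
      field <- field_from_preset(config$field)
      shape <- list(Nn = length(nurse_ids), Nptype = length(type_labels),
                    Ntimebins = config$bins$n_bins, nP = nrow(nurse_p),
                    pP = nrow(patient_p), k = config$kmeans$k,
                    iterations = config$kmeans$iterations,
                    n_zones = config$sim$n_zones,
                    max_time = config$sim$study_duration,
                    addressing = config$addressing)
      budget <- plan_budget(shape, field)
      if (!budget$ok) {
        stop("configuration error: ", paste(budget$reasons, collapse = "; "))
      }
      ctx <- mpc_session(field, seed = config$sim$seed)
      sn <- share_period_table(ctx, nurse_p, nurse_ids = nurse_ids,
                               addressing = config$addressing)
      sp <- share_period_table(ctx, patient_p, type_labels = type_labels,
                               addressing = config$addressing)
      log_msg("secure phase 1: ", sn$n * sp$n, " period pairs")
      sft <- secure_build_table(ctx, sn, sp, config$bins,
                                n_zones = config$sim$n_zones,
                                max_time = config$sim$study_duration)
      log_msg("secure phase 2: k = ", config$kmeans$k, ", ",
              config$kmeans$iterations, " iterations")
      skm <- secure_kmeans(ctx, sft, config$kmeans,
                           y_bound = as.numeric(sn$n) * as.numeric(sp$n))
      tr <- gate_trace(ctx)
      gate_counts <- as.list(tapply(tr$n, tr$op, sum))
      yaml::write_yaml(list(
        gate_counts = gate_counts,
        dealer = dealer_stats(ctx),
        reveals = as.list(tapply(reveal_log(ctx)$n, reveal_log(ctx)$purpose, sum)),
        budget_bits = budget$bits
      ), art("transcript_stats.yaml"))
      out <- list(membership = skm$membership, converged = skm$converged,
                  clusters = data.frame(nID = nurse_ids,
                                        cluster = max.col(skm$membership, "first"),
                                        stringsAsFactors = FALSE),
                  gate_counts = gate_counts, dealer = dealer_stats(ctx))
    }
    stage <- "write-output"
    write_clusters(out$clusters, out$converged, art("clusters.csv"))
    write_run_config(config, art("config.yaml"))
    log_msg("done: converged = ", out$converged)
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}

# ---- command line ---------------------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  pos <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1
      } else {
        flags[[key]] <- args[i + 1]
        i <- i + 2
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  list(flags = flags, positional = pos)
}

cli_config <- function(flags) {
  config <- if (!is.null(flags$config)) read_run_config(flags$config) else run_config()
  if (!is.null(flags$seed)) {
    config$sim$seed <- as.integer(flags$seed)
    config$kmeans$seed <- as.integer(flags$seed)
  }
  if (!is.null(flags$mode)) config$mode <- match.arg(flags$mode, c("plaintext", "secure"))
  config
}

#' Command-line interface
#'
#' Subcommands: `generate` (synthetic data + party views), `preprocess`
#' (periods from raw views), `build-table`, `cluster`, `run-secure` (both
#' phases in secure mode) and `run-all` (full pipeline in the configured
#' mode).  Flags: `--config <yaml>`, `--seed <int>`, `--mode <mode>`,
#' `--out-dir <dir>`.  A thin Rscript wrapper is installed under
#' `inst/scripts/wardmpc`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
wardmpc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: wardmpc <generate|preprocess|build-table|cluster|run-secure|run-all>",
    "  [--config file.yaml] [--seed n] [--mode plaintext|secure] [--out-dir dir]",
    sep = "\n")
  parsed <- parse_cli_flags(args)
  cmd <- parsed$positional[1]
  if (is.na(cmd) || !cmd %in% c("generate", "preprocess", "build-table",
                                "cluster", "run-secure", "run-all")) {
    message(usage)
    return(invisible(1L))
  }
  out_dir <- parsed$flags$`out-dir` %||% "."
  status <- tryCatch({
    config <- cli_config(parsed$flags)
    art <- function(f) file.path(out_dir, f)
    nurse_ids <- sprintf("N%03d", seq_len(config$sim$n_nurses))
    type_labels <- LETTERS[seq_len(config$sim$n_patient_types)]
    switch(cmd,
      "generate" = {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        gen <- generate_tracks(config$sim)
        write_raw_rtls(gen$raw, art("raw_rtls.csv"))
        views <- split_views(gen$raw)
        write_raw_rtls(views$hospital, art("hospital_view.csv"))
        write_raw_rtls(views$union, art("union_view.csv"))
        log_msg("wrote raw_rtls.csv and party views to ", out_dir)
      },
      "preprocess" = {
        for (v in c("hospital_view", "union_view")) {
          raw <- read_raw_rtls(art(paste0(v, ".csv")))
          per <- extract_periods(raw, config$sim$sample_interval)
          nm <- if (v == "union_view") "nurse_periods.csv" else "patient_periods.csv"
          write_period_table(per, art(nm))
        }
        log_msg("wrote period tables to ", out_dir)
      },
      "build-table" = {
        ft <- build_facing_table(read_period_table(art("nurse_periods.csv")),
                                 read_period_table(art("patient_periods.csv")),
                                 config$bins, nurse_ids, type_labels)
        write_facing_table(ft, art("facing_table.csv"))
        log_msg("wrote facing_table.csv (", sum(ft$counts), " interactions)")
      },
      "cluster" = {
        ft <- read_facing_table(art("facing_table.csv"))
        km <- facing_kmeans(ft, config$kmeans)
        write_clusters(data.frame(nID = ft$nurse_ids, cluster = km$assignments),
                       km$converged, art("clusters.csv"))
        log_msg("wrote clusters.csv (converged = ", km$converged, ")")
      },
      "run-secure" = {
        config$mode <- "secure"
        run_pipeline(config, out_dir)
      },
      "run-all" = {
        run_pipeline(config, out_dir)
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
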