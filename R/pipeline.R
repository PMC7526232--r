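#' Ground-truth presence labels from a manifest
#'
#' @param manifest A [cohort_manifest()] tibble.
#' @return A tibble with `recording_id`, `device`, `crackle_truth`,
#'   `wheeze_truth`.
#' @export
truth_labels <- function(manifest) {
  tibble::tibble(
    recording_id = manifest$recording_id,
    device = manifest$device,
    crackle_truth = vapply(manifest$truth, function(ev) {
      any(vapply(ev, function(e) e$kind == "crackle", logical(1)))
    }, logical(1)),
    wheeze_truth = vapply(manifest$truth, function(ev) {
      any(vapply(ev, function(e) e$kind == "wheeze", logical(1)))
    }, logical(1))
  )
}

#' Drop aberrant recordings
#'
#' Filters excluded rows out of a manifest before analysis, reporting the
#' per-device exclusion counts.
#'
#' @param manifest A manifest tibble with `excluded` flags.
#' @return The manifest restricted to analyzable recordings.
#' @export
exclude_aberrant <- function(manifest) {
  excl <- dplyr::filter(manifest, .data$excluded)
  if (nrow(excl) > 0) {
    counts <- dplyr::count(excl, .data$device)
    message("excluding aberrant recordings: ",
            paste(sprintf("%s: %d", counts$device, counts$n), collapse = ", "))
  }
  out <- dplyr::filter(manifest, !.data$excluded)
  if (nrow(out) == 0) warning("all recordings are excluded", call. = FALSE)
  out
}

#' Render, preprocess and score a cohort
#'
#' Runs every manifest row through the full chain — render the site master,
#' degrade to the device profile, normalize and band-pass, detect, score —
#' one recording at a time (recordings are rendered on demand and never all
#' held in memory). A site's master mix is rendered once and reused for both
#' of its device rows.
#'
#' @param manifest A [cohort_manifest()] tibble (usually already passed
#'   through [exclude_aberrant()]).
#' @param config The [cohort_config()] used to build the manifest.
#' @param control A [detect_control()].
#' @param spec A [filter_spec()].
#' @param scorer Scoring function applied to each preprocessed waveform;
#'   defaults to [score_recording()]. A pluggable hook so a third-party
#'   scorer can stand in for the rule-based detector.
#' @return A tibble with `recording_id`, `device`, `crackle_score`,
#'   `wheeze_score` (plus any extra scorer columns).
#' @export
score_cohort <- function(manifest, config = cohort_config(),
                         control = detect_control(), spec = filter_spec(),
                         scorer = NULL) {
  if (is.null(scorer)) {
    scorer <- function(w) score_recording(w, control)
  }
  idx <- order(manifest$site_seed)
  out <- vector("list", nrow(manifest))
  master <- NULL
  master_seed <- NA_real_
  for (i in idx) {
    row <- manifest[i, ]
    if (!identical(row$site_seed, master_seed)) {
      master <- render_recording(
        row$truth[[1]],
        duration_s = row$duration_s, sample_rate_hz = config$master_rate_hz,
        snr_db = config$snr_db, cycle_period_s = config$cycle_period_s,
        seed = row$site_seed
      )$waveform
      master_seed <- row$site_seed
    }
    w <- apply_device_profile(master, device_profile(row$device))
    w <- preprocess(w, spec)
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(recording_id = row$recording_id, device = row$device),
      scorer(w)
    )
  }
  dplyr::bind_rows(out)
}

#' Evaluate scores against ground truth
#'
#' For each device and sound type, builds the ROC over all achievable score
#' cutoffs and selects the optimal cutoff interval (see
#' [optimal_cutoff_interval()]).
#'
#' @param scores Output of [score_cohort()] (or a drop-in scorer CSV read as
#'   a tibble).
#' @param truth Output of [truth_labels()] restricted to the same
#'   recordings.
#' @param by_device Stratify by device (default) or pool.
#' @param tpr_definition Passed to [ppa_npa()].
#' @return An object of class `auscultr_eval`: list with `points` (all
#'   operating points, columns `device`, `sound`, `cutoff`, counts and
#'   metrics), `optimal` (one interval per device x sound), and `n_recordings`.
#' @export
evaluate_scores <- function(scores, truth, by_device = TRUE,
                            tpr_definition = c("ppa", "precision")) {
  tpr_definition <- match.arg(tpr_definition)
  d <- dplyr::inner_join(scores, truth,
                         by = c("recording_id", "device"))
  if (nrow(d) != nrow(scores)) {
    stop("scores and truth cover different recording sets", call. = FALSE)
  }
  d$device_stratum <- if (by_device) d$device else "all"
  sounds <- c(crackle = "crackle", wheeze = "wheeze")
  combos <- tidyr::expand_grid(device = unique(d$device_stratum),
                               sound = names(sounds))
  points <- list()
  optimal <- list()
  for (i in seq_len(nrow(combos))) {
    dev <- combos$device[i]; snd <- combos$sound[i]
    dd <- d[d$device_stratum == dev, ]
    pts <- if (snd == "crackle") {
      roc(dd, .data$crackle_score, .data$crackle_truth, tpr_definition)
    } else {
      roc(dd, .data$wheeze_score, .data$wheeze_truth, tpr_definition)
    }
    meta <- tibble::tibble(device = dev, sound = snd)
    points[[i]] <- dplyr::bind_cols(meta[rep(1, nrow(pts)), ], pts)
    optimal[[i]] <- dplyr::bind_cols(meta, optimal_cutoff_interval(pts))
  }
  structure(
    list(points = dplyr::bind_rows(points),
         optimal = dplyr::bind_rows(optimal),
         n_recordings = nrow(d)),
    class = "auscultr_eval"
  )
}

#' @export
print.auscultr_eval <- function(x, ...) {
  cat(sprintf("Lung-sound evaluation over %d recordings\n", x$n_recordings))
  cat("Optimized cutoff intervals (strict '>' labelling):\n")
  print(as.data.frame(
    dplyr::mutate(x$optimal, dplyr::across(c("ppa", "npa"), ~ round(.x, 2)))
  ), row.names = FALSE)
  invisible(x)
}

#' Run the full pipeline
#'
#' Simulate the cohort, drop aberrant recordings, render/preprocess/score
#' every remaining recording, and evaluate per device and sound type.
#' Optionally writes the report bundle: `manifest.csv`, `scores.csv`,
#' `roc_points.csv`, `cohort_summary.json` and `report.json` (optimized
#' intervals with PPA/NPA per device and sound type). A persisted
#' configuration plus seed fully determines every output.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param control,spec,scorer Passed to [score_cohort()].
#' @return A list with `manifest`, `scores`, `evaluation` (an
#'   `auscultr_eval`), and `summary` (a [cohort_summary()]).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir = NULL,
                         control = detect_control(), spec = filter_spec(),
                         scorer = NULL) {
  manifest <- cohort_manifest(config, seed)
  summary <- cohort_summary(manifest)
  analyzable <- exclude_aberrant(manifest)
  scores <- score_cohort(analyzable, config, control, spec, scorer)
  truth <- truth_labels(analyzable)
  evaluation <- evaluate_scores(scores, truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      dplyr::select(manifest, "recording_id", "participant_id", "group",
                    "quadrant", "device", "duration_s", "excluded",
                    "exclusion_reason"),
      file.path(out_dir, "manifest.csv")
    )
    readr::write_csv(scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(evaluation$points, file.path(out_dir, "roc_points.csv"))
    jsonlite::write_json(
      list(
        n_participants = summary$n_participants,
        n_recordings = summary$n_recordings,
        demographics = summary$demographics,
        groups = summary$groups
      ),
      file.path(out_dir, "cohort_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    jsonlite::write_json(
      list(seed = seed, n_recordings = evaluation$n_recordings,
           optimal = evaluation$optimal),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  list(manifest = manifest, scores = scores, evaluation = evaluation,
       summary = summary)
}

#' Read a pipeline configuration from YAML
#'
#' Reads keys `seed`, `cohort` (group_sizes, quadrants,
#' exclusions_per_device, duration_s), `devices`, `events` (snr_db,
#' crackle_rate, wheeze_rate, wheeze_given_crackles) and merges them over
#' the [cohort_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (a [cohort_config()]) and `seed`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  ch <- y$cohort
  if (!is.null(ch$group_sizes)) args$group_sizes <- unlist(ch$group_sizes)
  if (!is.null(ch$quadrants)) args$quadrants <- ch$quadrants
  if (!is.null(ch$exclusions_per_device)) {
    args$exclusions_per_device <- ch$exclusions_per_device
  }
  if (!is.null(ch$duration_s)) args$duration_s <- ch$duration_s
  if (!is.null(y$devices)) args$devices <- unlist(y$devices)
  ev <- y$events
  for (key in c("snr_db", "crackle_rate", "wheeze_rate",
                "wheeze_given_crackles")) {
    if (!is.null(ev[[key]])) args[[key]] <- ev[[key]]
  }
  list(config = do.call(cohort_config, args),
       seed = if (is.null(y$seed)) 1L else y$seed)
}
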