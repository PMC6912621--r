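#' Pipeline configuration
#'
#' Ties together a data source (either a [sim_config] for simulation mode
#' or paths to cohort/diary CSVs), the Widmark constants, binge
#' thresholds, the BIC scan range, EM settings, frequent-heavy thresholds
#' and trend contrasts, under a single master seed.
#'
#' @param sim a [sim_config] (simulation mode), or `NULL`.
#' @param cohort_path,diary_path CSV paths (file mode), or `NULL`.
#' @param constants a [widmark_constants].
#' @param binge_thresholds named (`W`, `M`) binge thresholds.
#' @param K_range candidate numbers of hidden states.
#' @param n_restarts,tol,max_iter,restart_iter EM settings, see
#'   [hmm_fit].
#' @param fh_min_days,fh_min_self frequent-heavy identification
#'   thresholds, see [identify_frequent_heavy].
#' @param contrasts list of length-2 character vectors of arms compared
#'   by [drinking_trend] within the frequent-heavy stratum.
#' @param seed master seed; stage seeds are derived from it by fixed
#'   offsets.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, cohort_path = NULL,
                            diary_path = NULL,
                            constants = widmark_constants(),
                            binge_thresholds = c(W = 4, M = 5),
                            K_range = 2:12,
                            n_restarts = 20L, tol = 1e-6,
                            max_iter = 500L, restart_iter = NULL,
                            fh_min_days = 3.5, fh_min_self = 0.5,
                            contrasts = list(c("control", "promillekoll"),
                                             c("partyplanner",
                                               "promillekoll")),
                            seed = 1L) {
  file_mode <- !is.null(cohort_path) || !is.null(diary_path)
  if (is.null(sim) == !file_mode)
    stop("exactly one of sim or cohort_path/diary_path must be given")
  if (file_mode && (is.null(cohort_path) || is.null(diary_path)))
    stop("file mode needs both cohort_path and diary_path")
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) == 0) stop("K_range must be nonempty")
  structure(list(sim = sim, cohort_path = cohort_path,
                 diary_path = diary_path, constants = constants,
                 binge_thresholds = binge_thresholds, K_range = K_range,
                 n_restarts = as.integer(n_restarts), tol = tol,
                 max_iter = as.integer(max_iter),
                 restart_iter = restart_iter,
                 fh_min_days = fh_min_days, fh_min_self = fh_min_self,
                 contrasts = contrasts, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a cohort CSV
#'
#' Expects columns `student_id, gender, age, weight_kg, audit,
#' motivation, arm, addon_arm` (and optionally `true_class`); malformed
#' rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @return a validated students tibble (weight column named `weight`).
#' @export
read_cohort <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("student_id", "gender", "age", "weight_kg", "audit",
            "motivation", "arm", "addon_arm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file lacks columns: ", paste(miss, collapse = ", "))
  line <- function(i) paste(i + 1L, collapse = ", ")  # +1 for header
  bad <- which(!d$gender %in% c("M", "W"))
  if (length(bad)) stop("unknown gender code at line(s) ", line(bad))
  bad <- which(is.na(d$audit) | d$audit < 0 | d$audit > 40)
  if (length(bad)) stop("AUDIT out of 0-40 at line(s) ", line(bad))
  bad <- which(duplicated(d$student_id))
  if (length(bad)) stop("duplicate student_id at line(s) ", line(bad))
  names(d)[names(d) == "weight_kg"] <- "weight"
  d$arm <- factor(d$arm, levels = c("control", "promillekoll",
                                    "partyplanner"))
  if (anyNA(d$arm)) stop("unknown arm code")
  tibble::as_tibble(d)
}

#' Read a diaries CSV
#'
#' Long format `student_id, wave, weekday, drinks, hours` with empty
#' fields for missing values; malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV path.
#' @return a validated diaries tibble.
#' @export
read_diaries <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         student_id = readr::col_character(),
                         wave = readr::col_integer(),
                         weekday = readr::col_integer(),
                         drinks = readr::col_integer(),
                         hours = readr::col_double()))
  need <- c("student_id", "wave", "weekday", "drinks", "hours")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("diary file lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) stop("no observations in diary file")
  line <- function(i) paste(i + 1L, collapse = ", ")
  bad <- which(!is.na(d$drinks) & d$drinks < 0)
  if (length(bad)) stop("negative drinks at line(s) ", line(bad))
  bad <- which(!d$weekday %in% 1:7)
  if (length(bad)) stop("weekday outside 1-7 at line(s) ", line(bad))
  bad <- which(duplicated(d[c("student_id", "wave", "weekday")]))
  if (length(bad))
    stop("duplicate (student, wave, weekday) at line(s) ", line(bad))
  tibble::as_tibble(d)
}

#' Write cohort / diaries CSVs
#'
#' Comma-separated, UTF-8, header row, empty field for missing; the
#' written files round-trip through [read_cohort] / [read_diaries].
#'
#' @param students,diaries tibbles as produced by [simulate_cohort].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(students, path) {
  d <- students
  names(d)[names(d) == "weight"] <- "weight_kg"
  readr::write_csv(d, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_diaries <- function(diaries, path) {
  readr::write_csv(diaries, path, na = "")
  invisible(path)
}

# Table 1-style per-arm cohort summary
cohort_summary <- function(students, outcomes) {
  base <- outcomes[outcomes$wave == 0, ]
  d <- dplyr::left_join(students, base, by = "student_id")
  summar <- function(g) {
    tibble::tibble(
      n = nrow(g),
      pct_women = 100 * mean(g$gender == "W"),
      age_mean = mean(g$age), age_sd = stats::sd(g$age),
      audit_mean = mean(g$audit), audit_sd = stats::sd(g$audit),
      quantity_mean = mean(g$quantity, na.rm = TRUE),
      frequency_mean = mean(g$frequency, na.rm = TRUE),
      binge_mean = mean(g$binge_occasions, na.rm = TRUE),
      weekly_ebac_mean = mean(g$weekly_mean_ebac, na.rm = TRUE),
      peak_ebac_mean = mean(g$peak_ebac_month, na.rm = TRUE),
      pct_excessive = 100 * mean(g$excessive, na.rm = TRUE),
      motivation_mean = mean(g$motivation))
  }
  arms <- split(d, d$arm)
  dplyr::bind_rows(c(list(total = summar(d)), lapply(arms, summar)),
                   .id = "group")
}

#' Assemble the frequent-heavy report
#'
#' Identifies the frequent-heavy state, classifies continual and
#' itinerant members, compares the frequent-heavy group against the rest
#' at baseline, and estimates the arm-wise drinking-probability trend
#' odds ratios within the frequent-heavy stratum.
#'
#' @param fit a `drink_hmm` fit.
#' @param decoding decoding tibble from [decode_cohort].
#' @param students,diaries,outcomes cohort tibbles.
#' @param contrasts list of length-2 arm contrasts.
#' @param fh_min_days,fh_min_self thresholds for
#'   [identify_frequent_heavy].
#' @return a list with `fh_state`, `thresholds`, `members`,
#'   `n_continual`, `n_itinerant`, `group_stats`, `trend` (list of
#'   `drinking_trend` objects keyed by contrast).
#' @export
frequent_heavy_report <- function(fit, decoding, students, diaries,
                                  outcomes,
                                  contrasts = list(c("control",
                                                     "promillekoll")),
                                  fh_min_days = 3.5, fh_min_self = 0.5) {
  fh <- identify_frequent_heavy(fit, min_days = fh_min_days,
                                min_self = fh_min_self)
  if (is.na(fh)) {
    return(list(fh_state = NA_integer_,
                thresholds = c(min_days = fh_min_days,
                               min_self = fh_min_self),
                members = NULL, n_continual = 0L, n_itinerant = 0L,
                group_stats = NULL, trend = NULL))
  }
  membership <- classify_membership(decoding, fh)
  members <- membership[membership$membership != "non_member", ]
  stats <- compare_groups(students, outcomes, membership, wave = 0)
  trends <- lapply(contrasts, function(ct)
    drinking_trend(diaries, students, arms = ct, membership = membership))
  names(trends) <- vapply(contrasts, paste, "", collapse = "_vs_")
  list(fh_state = fh,
       thresholds = c(min_days = fh_min_days, min_self = fh_min_self),
       members = members,
       n_continual = sum(membership$membership == "continual"),
       n_itinerant = sum(membership$membership == "itinerant"),
       group_stats = stats, trend = trends,
       membership = membership)
}

#' Run the full analysis pipeline
#'
#' Simulation or file input, outcome derivation, BIC selection of the
#' HMM, state decoding and labelling, and the frequent-heavy analysis,
#' all under the configuration's master seed. Stage failures abort with
#' the stage name.
#'
#' @param config a [pipeline_config].
#' @return an object of class `analysis_report`: list with
#'   `cohort_summary`, `outcome_summary`, `scan` (the `drink_hmm_scan`),
#'   `bic_table`, `labels`, `fh` (the frequent-heavy report),
#'   `sequence_length`, `config`, `seed`, `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- stage("simulate", simulate_cohort(sim))
    students <- cohort$students
    diaries <- cohort$diaries
  } else {
    students <- stage("read_cohort", read_cohort(config$cohort_path))
    diaries <- stage("read_diaries", read_diaries(config$diary_path))
  }
  outcomes <- stage("outcomes",
                    derive_outcomes(diaries, students,
                                    constants = config$constants,
                                    binge_thresholds =
                                      config$binge_thresholds))
  scan <- stage("fit_hmm",
                hmm_select(diaries, K_range = config$K_range,
                           n_restarts = config$n_restarts,
                           seed = config$seed + 1000L,
                           tol = config$tol, max_iter = config$max_iter,
                           restart_iter = config$restart_iter))
  decoding <- stage("decode", decode_cohort(scan$best, diaries))
  labels <- stage("label_states",
                  label_states(scan$best, decoding,
                               min_days = config$fh_min_days,
                               min_self = config$fh_min_self))
  fh <- stage("state_analysis",
              frequent_heavy_report(scan$best, decoding, students,
                                    diaries, outcomes,
                                    contrasts = config$contrasts,
                                    fh_min_days = config$fh_min_days,
                                    fh_min_self = config$fh_min_self))
  out_sum <- outcomes |>
    dplyr::group_by(.data$wave) |>
    dplyr::summarise(dplyr::across(c("quantity", "frequency",
                                     "binge_occasions",
                                     "weekly_mean_ebac",
                                     "peak_ebac_month"),
                                   ~ mean(.x, na.rm = TRUE)),
                     pct_excessive = 100 * mean(.data$excessive,
                                                na.rm = TRUE),
                     n_observed = sum(!is.na(.data$quantity)),
                     .groups = "drop")
  structure(list(
    cohort_summary = cohort_summary(students, outcomes),
    outcome_summary = out_sum,
    scan = scan, bic_table = tidy(scan),
    labels = labels, fh = fh,
    sequence_length = length(unique(diaries$wave)) * 7L,
    students = students, diaries = diaries, outcomes = outcomes,
    decoding = decoding,
    config = config, seed = config$seed,
    version = as.character(utils::packageVersion("drinkstates"))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> seed", x$seed, "- sequence length",
      x$sequence_length, "days\n")
  cat("Selected K =", x$scan$best_K, "by BIC\n")
  print(x$labels[c("state", "label", "drinking_days_per_week",
                   "self_transition")])
  if (!is.na(x$fh$fh_state))
    cat("Frequent-heavy state", x$fh$fh_state, ":", x$fh$n_continual,
        "continual /", x$fh$n_itinerant, "itinerant members\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the report as JSON (fitted parameters, labels, frequent-heavy
#' members and trend odds ratios, config echo) plus CSV tables: cohort
#' and outcome summaries, the BIC curve, the baseline comparison table
#' and the per-wave drinking proportions.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- report$scan$best$params
  js <- list(
    seed = report$seed, version = report$version,
    sequence_length = report$sequence_length,
    selected_K = report$scan$best_K,
    initial = p$initial, transition = p$transition,
    p_drink = p$p_drink, lambda = p$lambda,
    labels = report$labels$label,
    fh_state = report$fh$fh_state,
    n_continual = report$fh$n_continual,
    n_itinerant = report$fh$n_itinerant,
    trend = lapply(report$fh$trend, function(t)
      as.list(t$or[c("odds_ratio", "conf_low", "conf_high", "p_value")])))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$cohort_summary,
                   file.path(dir, "cohort_summary.csv"))
  readr::write_csv(report$outcome_summary,
                   file.path(dir, "outcome_summary.csv"))
  readr::write_csv(report$bic_table, file.path(dir, "bic.csv"))
  if (!is.null(report$fh$group_stats))
    readr::write_csv(report$fh$group_stats,
                     file.path(dir, "group_comparison.csv"))
  if (!is.null(report$fh$trend)) {
    props <- dplyr::bind_rows(lapply(report$fh$trend, `[[`, "proportions"),
                              .id = "contrast")
    readr::write_csv(props, file.path(dir, "drinking_proportions.csv"))
  }
  invisible(dir)
}
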