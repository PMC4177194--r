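# Discrete-event scheduler: one time step is one day. Patients circulate
# between the outpatient block (arm-specific) and the shared inpatient block;
# death is absorbing and removes the patient from further simulation. Every
# patient owns one named RNG substream per pathway, so results are
# reproducible draw-for-draw and enlarging the cohort never perturbs the
# trajectories of existing patients.

STATUS_OUTPATIENT <- 1L
STATUS_HOSPITALIZED <- 2L
STATUS_DEAD <- 3L

# Growable column accumulator (environment with doubling growth) used for
# event and cost-line logs; building a tibble row per event would dominate
# the runtime.
new_acc <- function(proto, n = 256L) {
  a <- new.env(parent = emptyenv())
  a$n <- 0L
  a$cols <- lapply(proto, function(template) rep(template, length.out = n))
  a
}

acc_add <- function(a, ...) {
  vals <- list(...)
  i <- a$n + 1L
  if (i > length(a$cols[[1]])) {
    a$cols <- lapply(a$cols, function(col) c(col, col))  # double capacity
  }
  for (j in seq_along(vals)) {
    a$cols[[j]][i] <- vals[[j]]
  }
  a$n <- i
  invisible(a)
}

acc_tibble <- function(a) {
  tibble::as_tibble(lapply(a$cols, function(col) col[seq_len(a$n)]))
}

# Does `day` open a new accounting month?
is_month_start <- function(day) {
  day == 0L || floor(day / DAYS_PER_MONTH) > floor((day - 1) / DAYS_PER_MONTH)
}

#' Initialise a cohort for one simulation run
#'
#' Creates the mutable cohort state advanced by [step_day()]: patient
#' vectors (NYHA class drawn from the scenario's initial distribution,
#' everyone outpatient), one RNG substream per patient per pathway (initial
#' class, outpatient cycle, inpatient admissions, routine visits), the
#' pre-drawn routine visit schedules, and the run's event/cost accumulators.
#'
#' @param cfg An `hf_scenario`.
#' @param run_index 1-based run number; combined with `cfg$seed` it
#'   determines every draw of the run.
#' @return An environment of class `hf_cohort`.
#' @export
init_cohort <- function(cfg, run_index = 1L) {
  n <- cfg$n_patients
  ch <- new.env(parent = emptyenv())
  ch$n <- n
  ch$run_index <- as.integer(run_index)
  ch$status <- rep(STATUS_OUTPATIENT, n)
  ch$nyha <- integer(n)
  ch$days_remaining <- integer(n)
  ch$pending_death <- logical(n)
  ch$pending_nyha <- rep(NA_integer_, n)
  ch$stream_out <- vector("list", n)
  ch$stream_in <- vector("list", n)
  ch$visit_day <- vector("list", n)
  ch$visit_kind <- vector("list", n)
  ch$visit_ptr <- rep(1L, n)
  lab <- function(pid, path) sprintf("run%03d/patient%06d/%s",
                                     run_index, pid, path)
  for (i in seq_len(n)) {
    init_stream <- rng_stream(cfg$seed, lab(i, "init"))
    ch$nyha[i] <- draw_categorical(cfg$nyha_distribution, init_stream)
    ch$stream_out[[i]] <- rng_stream(cfg$seed, lab(i, "outpatient"))
    ch$stream_in[[i]] <- rng_stream(cfg$seed, lab(i, "inpatient"))
    vs <- schedule_routine_visits(cfg$nyha_params[[ch$nyha[i]]],
                                  cfg$horizon_days,
                                  rng_stream(cfg$seed, lab(i, "visits")))
    ch$visit_day[[i]] <- vs$day
    ch$visit_kind[[i]] <- vs$kind
  }
  ch$events <- new_acc(list(day = NA_integer_, patient_id = NA_integer_,
                            kind = NA_character_, nyha = NA_integer_))
  ch$costs <- new_acc(list(day = NA_integer_, patient_id = NA_integer_,
                           category = NA_character_, amount_cents = NA_integer_))
  ch$admissions <- new_acc(list(
    patient_id = NA_integer_, admit_day = NA_integer_, ward_days = NA_integer_,
    icu_days = NA_integer_, imp_codes = NA_character_,
    died_in_hospital = NA, nyha_at_admit = NA_integer_,
    nyha_at_discharge = NA_integer_, discharge_day = NA_integer_))
  class(ch) <- "hf_cohort"
  ch
}

# Book an admission for patient i at `day`: draws the stay, logs it, emits
# the inpatient cost lines (stamped at the admission day - case flat rates
# are billed per case) and flips the patient to hospitalized.
.admit <- function(ch, cfg, i, day) {
  params <- cfg$nyha_params[[ch$nyha[i]]]
  stub <- list(id = i, nyha = ch$nyha[i], arm = cfg$arm, status = "outpatient")
  rec <- run_admission(stub, params, ch$stream_in[[i]], admit_day = day)
  acc_add(ch$admissions, rec$patient_id, rec$admit_day, rec$ward_days,
          rec$icu_days, paste(rec$imp_codes, collapse = ";"),
          rec$died_in_hospital, rec$nyha_at_admit, rec$nyha_at_discharge,
          rec$discharge_day)
  ldf <- cfg$ldf[[ch$nyha[i]]]
  epp <- cfg$tariffs$euro_per_ldf_point
  total <- rec$ward_days + rec$icu_days
  acc_add(ch$costs, day, i, "ward",
          as_cents(ldf_reimbursement(total, ldf, epp)))
  if (rec$icu_days > 0) {
    acc_add(ch$costs, day, i, "icu",
            as_cents(icu_supplement(rec$icu_days, ldf, epp)))
  }
  for (code in rec$imp_codes) {
    acc_add(ch$costs, day, i, "imp",
            as_cents(imp_cost(code, cfg$imp_catalogue, epp)))
  }
  ch$status[i] <- STATUS_HOSPITALIZED
  ch$days_remaining[i] <- total
  ch$pending_death[i] <- rec$died_in_hospital
  ch$pending_nyha[i] <- rec$nyha_at_discharge
  invisible(NULL)
}

.outpatient_cost_line <- function(ch, cfg, i, day, kind) {
  amt <- outpatient_event_cost(kind, cfg$tariffs, cfg$toggles)
  if (amt > 0) {
    acc_add(ch$costs, day, i, "outpatient_standard", as_cents(amt))
  }
  invisible(NULL)
}

#' Advance the cohort by one day
#'
#' Hospitalized patients count down their stay and are discharged (applying
#' the NYHA transition drawn at admission) or die when it ends; outpatients
#' receive any routine visits scheduled for the day and run their arm's
#' pathway (conventional: daily worsening cycle; telemedical: weekly control
#' cycle on days 6, 13, 20, ...); new admissions are simulated immediately
#' and costed; telemonitoring fees accrue at the start of each accounting
#' month (30.4375 days) for patients alive that day.
#'
#' @param cohort An `hf_cohort` from [init_cohort()]; mutated in place.
#' @param cfg The scenario.
#' @param day Simulation day, `0 <= day < horizon_days`.
#' @return Invisibly, a list with the day's `events` and `cost_lines` as
#'   plain vector lists (the full run logs live in the cohort).
#' @export
step_day <- function(cohort, cfg, day) {
  ch <- cohort
  ev0 <- ch$events$n
  co0 <- ch$costs$n
  day <- as.integer(day)

  # Monthly telemonitoring fees, charged for patients alive at day start.
  if (cfg$arm == "telemedical" && is_month_start(day)) {
    fin <- cfg$financing
    n_alive <- sum(ch$status != STATUS_DEAD)
    if (fin$variant == "A") {
      if (n_alive > 0) {
        acc_add(ch$costs, day, NA_integer_, "telemed_system",
                as_cents(n_alive * fin$monthly_rate_per_patient_eur))
      }
    } else {
      if (day == 0L) {
        acc_add(ch$costs, day, NA_integer_, "telemed_system",
                as_cents(ch$n * fin$acquisition_per_system_eur))
      }
      acc_add(ch$costs, day, NA_integer_, "telemed_system",
              as_cents(fin$monthly_overhead_eur))
      if (n_alive > 0) {
        acc_add(ch$costs, day, NA_integer_, "telemed_system",
                as_cents(n_alive * fin$physician_fee_per_patient_month_eur))
      }
    }
  }

  telemedical <- cfg$arm == "telemedical"
  cycle_day <- is_control_cycle_day(day)
  for (i in seq_len(ch$n)) {
    s <- ch$status[i]
    if (s == STATUS_DEAD) next

    if (s == STATUS_HOSPITALIZED) {
      ch$days_remaining[i] <- ch$days_remaining[i] - 1L
      if (ch$days_remaining[i] == 0L) {
        if (ch$pending_death[i]) {
          ch$status[i] <- STATUS_DEAD
          acc_add(ch$events, day, i, "death_in_hospital", ch$nyha[i])
        } else {
          ch$status[i] <- STATUS_OUTPATIENT
          ch$nyha[i] <- ch$pending_nyha[i]
          acc_add(ch$events, day, i, "discharge", ch$nyha[i])
        }
      }
      next  # no outpatient activity on in-hospital or discharge days
    }

    # Routine visits scheduled for today (those that fell within a hospital
    # stay were skipped by the cursor).
    vd <- ch$visit_day[[i]]
    p <- ch$visit_ptr[i]
    while (p <= length(vd) && vd[p] < day) p <- p + 1L
    while (p <= length(vd) && vd[p] == day) {
      kind <- ch$visit_kind[[i]][p]
      acc_add(ch$events, day, i, kind, ch$nyha[i])
      .outpatient_cost_line(ch, cfg, i, day, kind)
      p <- p + 1L
    }
    ch$visit_ptr[i] <- p

    params <- cfg$nyha_params[[ch$nyha[i]]]
    stub <- list(id = i, nyha = ch$nyha[i], arm = cfg$arm,
                 status = "outpatient")
    if (!telemedical) {
      out <- conventional_daily_cycle(stub, params, cfg$toggles,
                                      ch$stream_out[[i]], day = day)
      if (out$kind == "none") next
      acc_add(ch$events, day, i, out$kind, ch$nyha[i])
      if (out$kind %in% c("emergency_admission", "referral_admission")) {
        .outpatient_cost_line(ch, cfg, i, day, out$kind)
        .admit(ch, cfg, i, day)
      } else if (out$kind == "extramural_death") {
        ch$status[i] <- STATUS_DEAD
      } else {
        .outpatient_cost_line(ch, cfg, i, day, out$kind)
      }
    } else if (cycle_day) {
      out <- telemedical_control_cycle(stub, params, cfg$toggles,
                                       ch$stream_out[[i]], day = day)
      if (out$kind == "none") next
      acc_add(ch$events, day, i, out$kind, ch$nyha[i])
      if (out$kind %in% c("emergency_admission", "referral_admission")) {
        .outpatient_cost_line(ch, cfg, i, day, out$kind)
        .admit(ch, cfg, i, day)
      } else if (out$kind == "extramural_death") {
        ch$status[i] <- STATUS_DEAD
      } else {
        ch$nyha[i] <- out$nyha_after
        .outpatient_cost_line(ch, cfg, i, day, out$kind)
      }
    }
  }

  slice <- function(a, from) lapply(a$cols, function(col) {
    col[seq(from + 1L, length.out = a$n - from)]
  })
  invisible(list(events = slice(ch$events, ev0),
                 cost_lines = slice(ch$costs, co0)))
}

#' Execute one complete simulation run
#'
#' Initialises the cohort, iterates [step_day()] over the horizon and
#' assembles the run's logs and daily series.
#'
#' @param cfg An `hf_scenario`.
#' @param run_index 1-based run number (default 1); `cfg$seed` and
#'   `run_index` together determine every draw.
#' @return An object of class `hf_run`: a list with `daily` (one row per
#'   day: alive/dead counts, per-class NYHA counts, cumulative cost in euros
#'   by category and in total), `events`, `admissions`, `cost_lines`
#'   tibbles, plus `seed`, `run_index` and the scenario `label`.
#' @export
run_single <- function(cfg, run_index = 1L) {
  v <- validate_scenario(cfg)
  if (nrow(v) > 0) {
    stop("invalid scenario configuration; see validate_scenario()",
         call. = FALSE)
  }
  ch <- init_cohort(cfg, run_index)
  h <- cfg$horizon_days
  daily <- matrix(0, nrow = h, ncol = 11)
  colnames(daily) <- c("alive", "dead", "nyha_1", "nyha_2", "nyha_3", "nyha_4",
                       "cum_ward", "cum_icu", "cum_imp",
                       "cum_outpatient_standard", "cum_telemed_system")
  cum <- c(ward = 0, icu = 0, imp = 0, outpatient_standard = 0,
           telemed_system = 0)
  for (day in seq_len(h) - 1L) {
    added <- step_day(ch, cfg, day)
    cl <- added$cost_lines
    if (length(cl$amount_cents) > 0) {
      for (j in seq_along(cl$amount_cents)) {
        cum[[cl$category[j]]] <- cum[[cl$category[j]]] + cl$amount_cents[j]
      }
    }
    alive <- ch$status != STATUS_DEAD
    daily[day + 1L, ] <- c(sum(alive), ch$n - sum(alive),
                           tabulate(ch$nyha[alive], 4L), cum)
  }
  daily_tbl <- tibble::as_tibble(daily)
  daily_tbl$day <- seq_len(h) - 1L
  for (col in grep("^cum_", names(daily_tbl), value = TRUE)) {
    daily_tbl[[col]] <- daily_tbl[[col]] / 100  # cents -> euros
  }
  daily_tbl$cum_total <- daily_tbl$cum_ward + daily_tbl$cum_icu +
    daily_tbl$cum_imp + daily_tbl$cum_outpatient_standard +
    daily_tbl$cum_telemed_system
  daily_tbl <- dplyr::relocate(daily_tbl, "day")

  costs <- acc_tibble(ch$costs)
  costs$amount_eur <- costs$amount_cents / 100
  out <- list(
    label = cfg$label,
    arm = cfg$arm,
    run_index = as.integer(run_index),
    seed = cfg$seed,
    daily = daily_tbl,
    events = acc_tibble(ch$events),
    admissions = acc_tibble(ch$admissions),
    cost_lines = costs
  )
  class(out) <- "hf_run"
  out
}

#' @export
print.hf_run <- function(x, ...) {
  last <- x$daily[nrow(x$daily), ]
  cat(sprintf("<hf_run '%s' run %d> %d days, %d dead, total cost %.2f EUR\n",
              x$label, x$run_index, nrow(x$daily), last$dead, last$cum_total))
  invisible(x)
}

#' Execute a scenario (mean of independent runs)
#'
#' Runs `cfg$n_runs` independent replicates and averages every daily series
#' across them; the run-to-run standard deviation is kept alongside so
#' reported outcomes carry their Monte-Carlo spread.
#'
#' @param cfg An `hf_scenario`.
#' @return An object of class `hf_scenario_result`: `runs` (list of
#'   [run_single()] results), `daily_mean` and `daily_sd` tibbles, and the
#'   originating `config`.
#' @export
run_scenario <- function(cfg) {
  runs <- purrr::map(seq_len(cfg$n_runs), function(r) run_single(cfg, r))
  series <- purrr::map(runs, "daily")
  num_cols <- setdiff(names(series[[1]]), "day")
  stack <- array(unlist(purrr::map(series, function(s) as.matrix(s[num_cols]))),
                 dim = c(nrow(series[[1]]), length(num_cols), length(series)))
  mean_mat <- apply(stack, c(1, 2), mean)
  sd_mat <- if (length(series) > 1) apply(stack, c(1, 2), stats::sd) else
    matrix(0, nrow(series[[1]]), length(num_cols))
  colnames(mean_mat) <- colnames(sd_mat) <- num_cols
  daily_mean <- tibble::as_tibble(mean_mat)
  daily_mean$day <- series[[1]]$day
  daily_sd <- tibble::as_tibble(sd_mat)
  daily_sd$day <- series[[1]]$day
  out <- list(
    label = cfg$label,
    arm = cfg$arm,
    runs = runs,
    daily_mean = dplyr::relocate(daily_mean, "day"),
    daily_sd = dplyr::relocate(daily_sd, "day"),
    config = cfg
  )
  class(out) <- "hf_scenario_result"
  out
}

#' @export
print.hf_scenario_result <- function(x, ...) {
  last <- x$daily_mean[nrow(x$daily_mean), ]
  cat(sprintf(
    "<hf_scenario_result '%s'> %d runs x %d days, mean deaths %.1f, mean total cost %.2f EUR\n",
    x$label, length(x$runs), nrow(x$daily_mean), last$dead, last$cum_total))
  invisible(x)
}

#' Serialise a scenario result to a directory
#'
#' Writes per-run event logs and cost lines, per-run and mean/sd daily
#' series as CSV, and a JSON summary (totals by category, deaths,
#' scenario metadata). Every report in the package can be recomputed from
#' these files alone.
#'
#' @param result An `hf_scenario_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$daily_mean, file.path(dir, "daily_mean.csv"),
                   row.names = FALSE)
  utils::write.csv(result$daily_sd, file.path(dir, "daily_sd.csv"),
                   row.names = FALSE)
  for (run in result$runs) {
    tag <- sprintf("run%03d", run$run_index)
    utils::write.csv(run$daily, file.path(dir, paste0(tag, "_daily.csv")),
                     row.names = FALSE)
    utils::write.csv(run$events, file.path(dir, paste0(tag, "_events.csv")),
                     row.names = FALSE)
    utils::write.csv(run$cost_lines,
                     file.path(dir, paste0(tag, "_cost_lines.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(as.list(glance(result)), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialised scenario result
#'
#' Reconstructs a slim `hf_scenario_result` (mean/sd series and summary,
#' without the per-run logs) from a [write_scenario_result()] directory, as
#' used by the command-line `compare` subcommand.
#'
#' @param dir Directory written by [write_scenario_result()].
#' @return An `hf_scenario_result` with `runs = list()`.
#' @export
read_scenario_result <- function(dir) {
  summary <- jsonlite::read_json(file.path(dir, "summary.json"),
                                 simplifyVector = TRUE)
  out <- list(
    label = summary$label,
    arm = summary$arm,
    runs = list(),
    daily_mean = tibble::as_tibble(
      utils::read.csv(file.path(dir, "daily_mean.csv"))),
    daily_sd = tibble::as_tibble(
      utils::read.csv(file.path(dir, "daily_sd.csv"))),
    config = NULL,
    summary = summary
  )
  class(out) <- "hf_scenario_result"
  out
}
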