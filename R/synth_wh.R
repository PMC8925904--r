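#' @title Synthetic face-perception sessions
#' @description
#' Generates BIDS-style sessions emulating the classic face-perception MEEG
#' design: 6 runs of 140-150 face presentations, every face image shown
#' exactly twice per session, half of the repeats immediate (lag 1) and
#' half delayed with 5-15 intervening face presentations, a 3-way face-type
#' factor, exactly balanced face sex, a counterbalanced key assignment
#' encoded as a setup meta-event at the first sample, and per-trial
#' cross/face/circle presentations with key-press responses.  The halves
#' are exact by construction (not binomially sampled) so the design
#' statements hold for every seed.
#' @name synth_wh
NULL

#' Session specification
#'
#' @param n_runs Number of runs (default 6).
#' @param trials_per_run Inclusive range of face presentations per run
#'   (default `c(140, 150)`); the drawn count is constrained to values for
#'   which the pairing, the immediate/delayed split and the sex split are
#'   all exact.
#' @param face_type_probs Sampling probabilities for famous / unfamiliar /
#'   scrambled face identities (default uniform thirds).
#' @param immediate_fraction Fraction of repeated faces whose second
#'   showing is immediate (default 1/2, exact).
#' @param delayed_lag_range Inclusive range of the positional lag of
#'   delayed repeats, in face presentations (default `c(5, 15)`).
#' @param female_fraction Fraction of female face identities (default 1/2,
#'   exactly balanced).
#' @param key_assignment `"left_sym"` or `"right_sym"`.
#' @param timing Uniform ranges, in seconds: `cross` display before the
#'   face, `face` display, `response` latency after face onset, `circle`
#'   display filling the inter-trial period.
#' @param sampling_rate Hz, for the `sample` column (cosmetic).
#' @param seed Optional integer seed.
#' @return A `SessionSpec`.
#' @export
wh_session_spec <- function(n_runs = 6L,
                            trials_per_run = c(140L, 150L),
                            face_type_probs = c(famous = 1/3,
                                                unfamiliar = 1/3,
                                                scrambled = 1/3),
                            immediate_fraction = 0.5,
                            delayed_lag_range = c(5L, 15L),
                            female_fraction = 0.5,
                            key_assignment = c("left_sym", "right_sym"),
                            timing = list(cross = c(0.4, 0.6),
                                          face = c(0.8, 1.0),
                                          response = c(0.2, 2.5),
                                          circle = c(1.2, 1.9)),
                            sampling_rate = 1100,
                            seed = NULL) {
  key_assignment <- match.arg(key_assignment)
  stopifnot(n_runs >= 1L, length(trials_per_run) == 2L,
            trials_per_run[1] <= trials_per_run[2],
            abs(sum(face_type_probs) - 1) < 1e-8,
            immediate_fraction >= 0, immediate_fraction <= 1,
            length(delayed_lag_range) == 2L,
            delayed_lag_range[1] >= 1L,
            delayed_lag_range[1] <= delayed_lag_range[2],
            female_fraction >= 0, female_fraction <= 1)
  if (delayed_lag_range[2] >= trials_per_run[1]) {
    stop("config error: delayed lag range exceeds the run length",
         call. = FALSE)
  }
  structure(list(n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 face_type_probs = face_type_probs,
                 immediate_fraction = immediate_fraction,
                 delayed_lag_range = as.integer(delayed_lag_range),
                 female_fraction = female_fraction,
                 key_assignment = key_assignment,
                 timing = timing,
                 sampling_rate = sampling_rate,
                 seed = seed),
            class = "SessionSpec")
}

# trial counts in range for which all exact-balance constraints are integral
feasible_trial_counts <- function(spec) {
  v <- seq(spec$trials_per_run[1], spec$trials_per_run[2])
  ok <- v %% 2L == 0L
  n_faces <- v / 2
  ok <- ok & abs(n_faces * spec$immediate_fraction -
                   round(n_faces * spec$immediate_fraction)) < 1e-9
  ok <- ok & abs(n_faces * spec$female_fraction -
                   round(n_faces * spec$female_fraction)) < 1e-9
  out <- v[ok]
  if (length(out) == 0L) {
    stop("config error: no trial count in range admits exact pairing and balance",
         call. = FALSE)
  }
  out
}

# Randomized greedy pair placement: walk the earliest free slot, start a new
# identity there, and place its repeat at lag 1 (immediate) or at a feasible
# delayed lag; dead ends restart the whole run schedule.
schedule_run <- function(n_trials, n_imm, lag_range, max_attempts = 500L) {
  n_faces <- n_trials %/% 2L
  n_del <- n_faces - n_imm
  for (attempt in seq_len(max_attempts)) {
    slot_id <- integer(n_trials)
    slot_pres <- integer(n_trials)
    lag_of <- integer(n_faces)
    imm_left <- n_imm; del_left <- n_del
    id <- 0L
    ok <- TRUE
    while (any(slot_id == 0L)) {
      p <- which(slot_id == 0L)[[1L]]
      types <- c(rep("imm", imm_left), rep("del", del_left))
      if (length(types) == 0L) { ok <- FALSE; break }
      first <- if (length(types) == 1L) types else sample(types, 1L)
      order_try <- unique(c(first, c("imm", "del")))
      placed <- FALSE
      for (ty in order_try) {
        if (ty == "imm" && imm_left > 0L) {
          if (p + 1L <= n_trials && slot_id[p + 1L] == 0L) {
            id <- id + 1L
            slot_id[c(p, p + 1L)] <- id
            slot_pres[c(p, p + 1L)] <- c(1L, 2L)
            lag_of[id] <- 1L
            imm_left <- imm_left - 1L
            placed <- TRUE
            break
          }
        } else if (ty == "del" && del_left > 0L) {
          lags <- seq(lag_range[1], lag_range[2])
          lags <- lags[p + lags <= n_trials]
          lags <- lags[slot_id[p + lags] == 0L]
          if (length(lags) > 0L) {
            l <- if (length(lags) == 1L) lags else sample(lags, 1L)
            id <- id + 1L
            slot_id[c(p, p + l)] <- id
            slot_pres[c(p, p + l)] <- c(1L, 2L)
            lag_of[id] <- l
            del_left <- del_left - 1L
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      return(data.frame(pos = seq_len(n_trials), identity = slot_id,
                        presentation = slot_pres,
                        lag = ifelse(slot_pres == 2L, lag_of[slot_id], NA_integer_)))
    }
  }
  stop("config error: could not schedule run (lag constraints infeasible)",
       call. = FALSE)
}

trigger_code <- function(event_type, face_type = NA, rep_status = NA) {
  # mirrors the printed fixture codes; informational only
  base <- c(famous_face = 6L, unfamiliar_face = 13L, scrambled_face = 16L)
  offs <- c(first_show = 1L, immediate_repeat = 2L, delayed_repeat = 3L)
  switch(event_type,
         setup_left_sym = ,
         setup_right_sym = "2",
         show_cross = "1",
         show_circle = "0",
         left_press = "256",
         right_press = "4096",
         as.character(base[[face_type]] + offs[[rep_status]]))
}

#' Generate one synthetic session
#'
#' @param spec A [wh_session_spec()].
#' @param seed Seed for this session; defaults to `spec$seed`.  `NULL`
#'   continues the current RNG stream.
#' @return A `wh_session`: `$runs` (list of `EventTable`), `$sidecar` (the
#'   packaged face-perception sidecar), `$faces` (one row per face
#'   identity: run, stim_file, face_type, sex, positions and lag),
#'   `$key_assignment`.
#' @export
generate_session <- function(spec = wh_session_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "SessionSpec"))
  if (!is.null(seed)) set.seed(seed)
  counts <- feasible_trial_counts(spec)
  type_names <- c("famous", "unfamiliar", "scrambled")
  stim_prefix <- c(famous = "f", unfamiliar = "u", scrambled = "s")
  stim_counter <- c(famous = 0L, unfamiliar = 0L, scrambled = 0L)
  setup_type <- paste0("setup_", spec$key_assignment)
  runs <- vector("list", spec$n_runs)
  faces_all <- list()

  for (r in seq_len(spec$n_runs)) {
    n_trials <- if (length(counts) == 1L) counts else sample(counts, 1L)
    n_faces <- n_trials %/% 2L
    n_imm <- as.integer(round(n_faces * spec$immediate_fraction))
    sched <- schedule_run(n_trials, n_imm, spec$delayed_lag_range)

    ftype <- sample(type_names, n_faces, replace = TRUE,
                    prob = spec$face_type_probs)
    n_female <- as.integer(round(n_faces * spec$female_fraction))
    sex <- sample(c(rep("female", n_female), rep("male", n_faces - n_female)))
    stim <- character(n_faces)
    for (i in seq_len(n_faces)) {
      stim_counter[ftype[i]] <- stim_counter[ftype[i]] + 1L
      stim[i] <- sprintf("%s%03d.bmp", stim_prefix[[ftype[i]]],
                         stim_counter[ftype[i]])
    }

    tm <- spec$timing
    t0 <- 0.4
    ev <- list()
    push <- function(onset, event_type, face_type = NA_character_,
                     rep_status = NA_character_, rep_lag = NA_character_,
                     value, stim_file = NA_character_) {
      ev[[length(ev) + 1L]] <<- list(onset = onset, event_type = event_type,
                                     face_type = face_type,
                                     rep_status = rep_status,
                                     rep_lag = rep_lag, value = value,
                                     stim_file = stim_file)
    }
    push(t0, setup_type, value = "2")
    prev_circle_onset <- NA_real_
    for (i in seq_len(n_trials)) {
      if (i == 1L) {
        face_t <- t0 + stats::runif(1, 1.0, 2.0)
        face_event <- "show_face_initial"
      } else {
        cross_t <- prev_circle_onset + stats::runif(1, tm$circle[1], tm$circle[2])
        push(cross_t, "show_cross", value = "1", stim_file = "cross.bmp")
        face_t <- cross_t + stats::runif(1, tm$cross[1], tm$cross[2])
        face_event <- "show_face"
      }
      id <- sched$identity[i]
      pres <- sched$presentation[i]
      rep_status <- if (pres == 1L) "first_show" else
        if (sched$lag[i] == 1L) "immediate_repeat" else "delayed_repeat"
      rep_lag <- if (pres == 1L) NA_character_ else as.character(sched$lag[i])
      ft_col <- paste0(ftype[id], "_face")
      push(face_t, face_event, face_type = ft_col, rep_status = rep_status,
           rep_lag = rep_lag,
           value = trigger_code("face", ft_col, rep_status),
           stim_file = stim[id])
      circle_t <- face_t + stats::runif(1, tm$face[1], tm$face[2])
      push(circle_t, "show_circle", value = "0", stim_file = "circle.bmp")
      press_t <- face_t + stats::runif(1, tm$response[1], tm$response[2])
      side <- sample(c("left_press", "right_press"), 1L)
      push(press_t, side, value = if (side == "left_press") "256" else "4096")
      prev_circle_onset <- circle_t
    }

    onsets <- vapply(ev, `[[`, numeric(1), "onset")
    ord <- order(onsets)
    ev <- ev[ord]
    onsets <- round(onsets[ord], 3)
    # strict monotonicity after millisecond rounding
    for (k in seq_along(onsets)[-1]) {
      if (onsets[k] <= onsets[k - 1]) onsets[k] <- onsets[k - 1] + 0.001
    }
    data <- data.frame(
      onset = sprintf("%.3f", onsets),
      duration = "n/a",
      sample = as.character(as.integer(round(onsets * spec$sampling_rate))),
      event_type = vapply(ev, `[[`, character(1), "event_type"),
      face_type = vapply(ev, `[[`, character(1), "face_type"),
      rep_status = vapply(ev, `[[`, character(1), "rep_status"),
      rep_lag = vapply(ev, `[[`, character(1), "rep_lag"),
      value = vapply(ev, `[[`, character(1), "value"),
      stim_file = vapply(ev, `[[`, character(1), "stim_file"),
      stringsAsFactors = FALSE)
    runs[[r]] <- event_table(data)

    firsts <- sched[sched$presentation == 1L, ]
    seconds <- sched[sched$presentation == 2L, ]
    faces_all[[r]] <- data.frame(
      run = r, identity = seq_len(n_faces), stim_file = stim,
      face_type = ftype, sex = sex,
      first_pos = firsts$pos[order(firsts$identity)],
      second_pos = seconds$pos[order(seconds$identity)],
      lag = seconds$lag[order(seconds$identity)],
      stringsAsFactors = FALSE)
  }

  structure(list(runs = runs,
                 sidecar = read_sidecar(hedlite_wh_sidecar_path()),
                 faces = do.call(rbind, faces_all),
                 key_assignment = spec$key_assignment,
                 spec = spec),
            class = "wh_session")
}

#' @export
print.wh_session <- function(x, ...) {
  counts <- vapply(x$runs, function(r)
    sum(r$data$event_type %in% c("show_face", "show_face_initial")), integer(1))
  cat(sprintf("wh_session: %d runs (%s face presentations), key assignment %s\n",
              length(x$runs), paste(counts, collapse = "/"),
              x$key_assignment))
  invisible(x)
}

#' Generate a BIDS-like synthetic dataset tree
#'
#' Writes `sub-XX/..._events.tsv` run files plus the single top-level task
#' sidecar.  Key assignment alternates across participants (exact
#' counterbalance for even counts), and the setup meta-event of every run
#' matches its participant's assignment.
#'
#' @param out_dir Target directory (created if needed).
#' @param n_participants Number of participants.
#' @param spec A [wh_session_spec()]; its seed (if any) seeds the whole
#'   dataset generation once.
#' @return `out_dir`, invisibly.
#' @export
generate_dataset <- function(out_dir, n_participants, spec = wh_session_spec()) {
  stopifnot(n_participants >= 1L)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(hedlite_wh_sidecar_path(),
            file.path(out_dir, "task-FacePerception_events.json"),
            overwrite = TRUE)
  for (p in seq_len(n_participants)) {
    pspec <- spec
    pspec$key_assignment <- if (p %% 2L == 1L) "left_sym" else "right_sym"
    ses <- generate_session(pspec, seed = NULL)
    sub <- sprintf("sub-%02d", p)
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
    for (r in seq_along(ses$runs)) {
      write_events_tsv(ses$runs[[r]], file.path(
        out_dir, sub,
        sprintf("%s_task-FacePerception_run-%d_events.tsv", sub, r)))
    }
  }
  invisible(out_dir)
}

#' Paths of the packaged face-perception fixture
#' @return Directory of the fixture dataset tree.
#' @export
hedlite_wh_root <- function() {
  system.file("extdata", "wh", package = "hedlite", mustWork = TRUE)
}

#' @rdname hedlite_wh_root
#' @return Path of the packaged task sidecar.
#' @export
hedlite_wh_sidecar_path <- function() {
  file.path(hedlite_wh_root(), "task-FacePerception_events.json")
}

#' @rdname hedlite_wh_root
#' @return Path of the packaged eight-row events excerpt.
#' @export
hedlite_wh_events_path <- function() {
  file.path(hedlite_wh_root(), "sub-002",
            "sub-002_task-FacePerception_run-1_events.tsv")
}
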