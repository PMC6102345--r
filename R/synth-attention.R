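#' Simulated listener model for attention curves
#'
#' Each simulated subject is a two-state (attend / ignore) Markov chain
#' sampled at 10 Hz.  The per-step probability of switching to the attend
#' state is boosted by `event_gain` inside a short window starting
#' `motor_delay_s` after each planted event, emulating the motor-delayed,
#' event-locked switching that produces derivative peaks in the
#' percentage-attending curve.
#'
#' @param n_subjects Number of simulated subjects (>= 2, default 20).
#' @param switch_prob_base Baseline probability per second of switching
#'   ignore -> attend (default 0.05).
#' @param event_gain Dimensionless multiplicative boost of the switch
#'   probability near events (default 30; 0 disables event locking).
#' @param motor_delay_s Motor response delay in seconds between an event
#'   and the attention switch it elicits (default 1.4).
#' @param leave_prob Baseline probability per second of switching
#'   attend -> ignore (default 0.2).
#' @param seed Integer seed.
#' @return An object of class `subject_model`.
#' @seealso [gen_salience()]
#' @export
subject_model <- function(n_subjects = 20, switch_prob_base = 0.05,
                          event_gain = 30, motor_delay_s = 1.4,
                          leave_prob = 0.2, seed = 1L) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2", call. = FALSE)
  stopifnot_scalar_number(switch_prob_base, "switch_prob_base", 0, 1)
  stopifnot_scalar_number(event_gain, "event_gain", lower = 0)
  stopifnot_scalar_number(motor_delay_s, "motor_delay_s", lower = 0)
  stopifnot_scalar_number(leave_prob, "leave_prob", 0, 1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         switch_prob_base = switch_prob_base, event_gain = event_gain,
         motor_delay_s = motor_delay_s, leave_prob = leave_prob,
         seed = as.integer(seed)),
    class = "subject_model"
  )
}

#' Simulate a behavioral salience curve for a scene
#'
#' Runs the [subject_model()] Markov chains against the scene's
#' ground-truth events and summarizes them as the percentage of subjects
#' attending over time, sampled at 10 Hz.  The switch-to-attend
#' probability is multiplied by `1 + event_gain` inside the one-second
#' window starting `motor_delay_s` after each event onset.
#'
#' @param scene An `audio_scene` with ground-truth `annotations`.
#' @param subjects A [subject_model()].
#' @param rate Curve sampling rate in Hz (default 10).
#' @return A tibble with columns `time` (s) and `percent` (in \[0, 100\]),
#'   with the subject-by-time attention matrix in attribute `"attention"`.
#' @export
gen_salience <- function(scene, subjects, rate = 10) {
  if (!inherits(scene, "audio_scene")) stop("`scene` must be an audio_scene")
  if (!inherits(subjects, "subject_model")) stop("`subjects` must be a subject_model")
  if (is.null(scene$annotations)) {
    stop("scene has no ground-truth events; attach annotations first", call. = FALSE)
  }
  dt <- 1 / rate
  n_t <- floor(scene$duration_s * rate)
  times <- (seq_len(n_t) - 1L) * dt
  # per-step boost profile: 1 everywhere, 1 + gain in post-event windows
  boost <- rep(1, n_t)
  if (nrow(scene$annotations) > 0) {
    for (t_ev in scene$annotations$onset_s) {
      w0 <- t_ev + subjects$motor_delay_s
      idx <- which(times >= w0 & times < w0 + 1)
      boost[idx] <- 1 + subjects$event_gain
    }
  }
  p_attend <- pmin(1, subjects$switch_prob_base * dt * boost)
  p_leave <- min(1, subjects$leave_prob * dt)
  with_seed(subjects$seed, {
    att <- matrix(0L, nrow = subjects$n_subjects, ncol = n_t)
    state <- rbinom(subjects$n_subjects, 1L, 0.2)   # few attend at onset
    att[, 1L] <- state
    for (k in 2:n_t) {
      u <- runif(subjects$n_subjects)
      state <- ifelse(state == 1L,
                      ifelse(u < p_leave, 0L, 1L),
                      ifelse(u < p_attend[k], 1L, 0L))
      att[, k] <- state
    }
    out <- tibble::tibble(time = times, percent = 100 * colMeans(att))
    attr(out, "attention") <- att
    attr(out, "rate") <- rate
    out
  })
}
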