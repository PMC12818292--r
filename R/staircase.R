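#' Configuration of the adaptive threshold staircase
#'
#' The clinical threshold subtest presents 16 pen triplets ordered by
#' n-butanol concentration, level 1 being the strongest and level 16 the
#' weakest. Testing starts at the weakest level and descends in steps of two
#' levels until the respondent identifies a triplet correctly twice in a
#' row; from there a single-staircase 2-down/1-up rule runs until seven
#' turning points (direction reversals) have been recorded.
#'
#' @param n_levels number of concentration levels (default 16).
#' @param initial_start starting level of the descending phase (default the
#'   weakest level, 16).
#' @param initial_step level decrement of the descending phase (default 2;
#'   the descent visits 16, 14, ..., 2 and finally 1).
#' @param required_turning_points turning points needed to finish (default 7).
#' @param t_from_last how many of the last turning points enter the
#'   threshold score (default 4).
#' @param max_main_presentations cap on main-phase presentations guarding
#'   against non-termination (default 60).
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(n_levels = 16L, initial_start = 16L,
                             initial_step = 2L, required_turning_points = 7L,
                             t_from_last = 4L, max_main_presentations = 60L) {
  if (required_turning_points <= t_from_last) {
    stop_olf("required_turning_points must exceed t_from_last")
  }
  if (initial_start < 1 || initial_start > n_levels) {
    stop_olf("initial_start must lie within the level range")
  }
  structure(list(
    n_levels = as.integer(n_levels),
    initial_start = as.integer(initial_start),
    initial_step = as.integer(initial_step),
    required_turning_points = as.integer(required_turning_points),
    t_from_last = as.integer(t_from_last),
    max_main_presentations = as.integer(max_main_presentations)
  ), class = "staircase_config")
}

#' Fresh staircase state
#'
#' @param config a [staircase_config()].
#' @return an object of class `staircase_state` with fields `phase`
#'   (`initial`, `main`, `done`, `excluded`), `current_level`, `direction`
#'   (`none`, `toward_weaker`, `toward_stronger`), `consecutive_correct`,
#'   `turning_points`, `history` (data.frame of presented level and
#'   response) and `n_main` (main-phase presentation count).
#' @export
staircase_init <- function(config = staircase_config()) {
  structure(list(
    phase = "initial",
    current_level = config$initial_start,
    direction = "none",
    consecutive_correct = 0L,
    turning_points = integer(0),
    history = data.frame(level = integer(0), correct = logical(0)),
    n_main = 0L
  ), class = "staircase_state")
}

#' Advance the staircase by one response
#'
#' Initial (descending) phase: a correct response repeats the same level; a
#' second consecutive correct records the level as the first turning point
#' and enters the main phase; an incorrect response resumes the descent
#' toward stronger levels. Failing to produce two consecutive corrects by
#' level 1 ends the run as `excluded` (suspected anosmia).
#'
#' Main phase (2-down/1-up on concentration): two consecutive corrects move
#' one level weaker, any incorrect moves one level stronger. A direction
#' reversal records the level at which it occurred as a turning point. At
#' the boundary levels the staircase holds its level and records a boundary
#' turning point, so observers who are never (or always) correct still
#' terminate. The run is `done` once the required number of turning points
#' has been recorded.
#'
#' @param state a `staircase_state`.
#' @param correct logical, whether the response to the currently presented
#'   level was correct.
#' @param config the [staircase_config()] in force.
#' @return the updated `staircase_state`.
#' @export
staircase_step <- function(state, correct, config = staircase_config()) {
  if (!inherits(state, "staircase_state")) stop_olf("not a staircase_state")
  if (state$phase %in% c("done", "excluded")) {
    stop_olf("staircase already terminated (phase ", state$phase, ")",
             class = "olfdyad_state_error")
  }
  stopifnot(is.logical(correct), length(correct) == 1, !is.na(correct))
  lvl <- state$current_level
  state$history <- rbind(state$history,
                         data.frame(level = lvl, correct = correct))

  add_tp <- function(st, level) {
    st$turning_points <- c(st$turning_points, level)
    if (length(st$turning_points) >= config$required_turning_points) {
      st$phase <- "done"
    }
    st
  }

  if (state$phase == "initial") {
    if (correct) {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct >= 2L) {
        # first turning point: enter the main phase moving toward weaker
        state <- add_tp(state, lvl)
        if (state$phase != "done") {
          state$phase <- "main"
          state$direction <- "toward_weaker"
          state$consecutive_correct <- 0L
          state$current_level <- min(lvl + 1L, config$n_levels)
        }
      }
    } else {
      state$consecutive_correct <- 0L
      if (lvl <= 1L) {
        state$phase <- "excluded"
      } else {
        state$current_level <- max(1L, lvl - config$initial_step)
      }
    }
    return(state)
  }

  # main phase
  state$n_main <- state$n_main + 1L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      state$consecutive_correct <- 0L
      if (state$direction == "toward_stronger") {
        state <- add_tp(state, lvl)
      } else if (lvl >= config$n_levels) {
        state <- add_tp(state, lvl) # boundary hold at the weakest level
      }
      state$direction <- "toward_weaker"
      if (state$phase != "done") {
        state$current_level <- min(lvl + 1L, config$n_levels)
      }
    }
  } else {
    state$consecutive_correct <- 0L
    if (state$direction == "toward_weaker") {
      state <- add_tp(state, lvl)
    } else if (lvl <= 1L) {
      state <- add_tp(state, lvl) # boundary hold at the strongest level
    }
    state$direction <- "toward_stronger"
    if (state$phase != "done") {
      state$current_level <- max(lvl - 1L, 1L)
    }
  }
  state
}

#' Threshold (T) score from a complete staircase
#'
#' The T score is the arithmetic mean of the last `t_from_last` turning
#' points of a staircase that recorded exactly `required` turning points.
#'
#' @param turning_points integer vector of turning-point levels.
#' @param required turning points a complete run must have (default 7).
#' @param t_from_last how many of the last turning points to average
#'   (default 4).
#' @return the T score (numeric scalar).
#' @export
#' @examples
#' threshold_score(c(4, 6, 5, 7, 6, 8, 7)) # 7
threshold_score <- function(turning_points, required = 7L, t_from_last = 4L) {
  if (length(turning_points) != required) {
    stop_olf("incomplete staircase: need exactly ", required,
             " turning points, got ", length(turning_points),
             class = "olfdyad_incomplete_staircase")
  }
  mean(utils::tail(turning_points, t_from_last))
}

#' Run a full threshold test against a psychometric responder
#'
#' Drives [staircase_step()] to completion, exclusion, or the main-phase
#' presentation cap, drawing each response as a Bernoulli trial from
#' `responder(level)`.
#'
#' @param responder function mapping a level (1 = strongest) to the
#'   probability of a correct response; deterministic observers may return
#'   0 or 1.
#' @param seed optional integer seed making the run reproducible.
#' @param config a [staircase_config()].
#' @return an object of class `threshold_result`: a list with `t_score`
#'   (numeric, `NA` when excluded or incomplete), `excluded_anosmia`,
#'   `complete`, `turning_points`, `n_presentations`, and the presentation
#'   `history`.
#' @export
#' @examples
#' res <- run_threshold_test(function(level) as.numeric(level <= 8), seed = 1)
#' res$turning_points # 8 9 8 9 8 9 8
#' res$t_score        # 8.5
run_threshold_test <- function(responder, seed = NULL,
                               config = staircase_config()) {
  stopifnot(is.function(responder))
  with_seed(seed, {
    state <- staircase_init(config)
    while (state$phase %in% c("initial", "main") &&
           state$n_main < config$max_main_presentations) {
      p <- responder(state$current_level)
      if (!is.finite(p) || p < 0 || p > 1) {
        stop_olf("responder must return a probability in [0, 1]")
      }
      correct <- stats::runif(1) < p
      state <- staircase_step(state, correct, config)
    }
    excluded <- state$phase == "excluded"
    complete <- state$phase == "done"
    structure(list(
      t_score = if (complete) {
        threshold_score(state$turning_points,
                        required = config$required_turning_points,
                        t_from_last = config$t_from_last)
      } else NA_real_,
      excluded_anosmia = excluded,
      complete = complete,
      turning_points = state$turning_points,
      n_presentations = nrow(state$history),
      history = state$history
    ), class = "threshold_result")
  })
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$excluded_anosmia) {
    cat("Threshold test: excluded (suspected anosmia) after",
        x$n_presentations, "presentations\n")
  } else if (!x$complete) {
    cat("Threshold test: incomplete (presentation cap reached);",
        length(x$turning_points), "turning points\n")
  } else {
    cat("Threshold test: T =", format(x$t_score),
        "| turning points:", paste(x$turning_points, collapse = " "), "\n")
  }
  invisible(x)
}

#' Deterministic step responder for staircase demonstrations
#'
#' Returns a responder that is correct exactly when the presented level is
#' at or stronger than (numerically at or below) the cutoff.
#'
#' @param cutoff level at or below which responses are correct.
#' @return a function usable as `responder` in [run_threshold_test()].
#' @export
step_responder <- function(cutoff) {
  force(cutoff)
  function(level) as.numeric(level <= cutoff)
}

#' Logistic psychometric responder for the 3AFC threshold task
#'
#' Probability of a correct response at a level is the 3AFC guessing floor
#' plus a logistic function of (theta - level) / slope, so weaker levels
#' (larger numbers) than `theta` fall toward chance.
#'
#' @param theta level at which performance is halfway between floor and
#'   ceiling.
#' @param slope logistic slope in level units (default 1.5).
#' @param floor guessing rate (default 1/3 for a 3AFC oddity task).
#' @return a responder function of `level`.
#' @export
logistic_responder <- function(theta, slope = 1.5, floor = 1 / 3) {
  force(theta); force(slope); force(floor)
  function(level) floor + (1 - floor) * stats::plogis((theta - level) / slope)
}
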