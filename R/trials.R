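# Canonical stimulus positions, ordered left to right across the display.
STIMULUS_POSITIONS <- c("left-outer", "left-inner", "right-inner", "right-outer")

#' Default stimulus-response mapping rules
#'
#' Two bijective mappings from the four stimulus positions to the four
#' response buttons. Rule "1" is the identity layout (leftmost stimulus ->
#' button 1); rule "2" is the reversed layout. The true assignments used in
#' any given experiment are arbitrary and counterbalanced, so both rules are
#' fully configurable: any named list of bijections position -> button is
#' accepted wherever `rule_definitions` is an argument.
#'
#' @return Named list of named integer vectors, one per rule; names of each
#'   vector are stimulus positions, values are buttons 1-4.
#' @export
default_rule_definitions <- function() {
  list(
    "1" = stats::setNames(1:4, STIMULUS_POSITIONS),
    "2" = stats::setNames(4:1, STIMULUS_POSITIONS)
  )
}

#' Default cue-colour to rule map
#'
#' Four cue colours, two per rule, so that rule identity cannot be read off a
#' single colour.
#'
#' @return Named character vector mapping colours `c1..c4` to rule ids.
#' @export
default_colour_rule_map <- function() {
  c(c1 = "1", c2 = "1", c3 = "2", c4 = "2")
}

check_rule_definitions <- function(rule_definitions) {
  if (!is.list(rule_definitions) || is.null(names(rule_definitions)))
    stop("rule_definitions must be a named list of position->button maps")
  for (rn in names(rule_definitions)) {
    rd <- rule_definitions[[rn]]
    if (!setequal(names(rd), STIMULUS_POSITIONS) ||
        !setequal(as.integer(rd), 1:4))
      stop("rule '", rn, "' is not a bijection from the 4 positions to buttons 1..4")
  }
  invisible(TRUE)
}

#' Map a stimulus position to the response button under a rule
#'
#' @param stimulus_position Character vector of positions (see
#'   `STIMULUS_POSITIONS`).
#' @param rule Rule id(s), matching names of `rule_definitions`.
#' @param rule_definitions Named list of bijections, see
#'   [default_rule_definitions()].
#' @return Integer vector of buttons (1-4).
#' @export
map_stimulus_to_response <- function(stimulus_position, rule,
                                     rule_definitions = default_rule_definitions()) {
  check_rule_definitions(rule_definitions)
  rule <- as.character(rule)
  bad <- setdiff(unique(rule), names(rule_definitions))
  if (length(bad)) stop("unknown rule id(s): ", paste(bad, collapse = ", "))
  if (length(rule) == 1L) rule <- rep(rule, length(stimulus_position))
  vapply(seq_along(stimulus_position), function(i) {
    rd <- rule_definitions[[rule[i]]]
    b <- rd[[stimulus_position[i]]]
    if (is.null(b)) stop("unknown stimulus position: ", stimulus_position[i])
    as.integer(b)
  }, integer(1))
}

#' Response group of a button
#'
#' Buttons 2 and 3 are pressed by the inner fingers, 1 and 4 by the outer
#' fingers.
#'
#' @param button Integer vector of buttons 1-4 (NA allowed).
#' @return Character vector `"inner"`/`"outer"` (NA propagated).
#' @export
response_group_of <- function(button) {
  ifelse(is.na(button), NA_character_,
         ifelse(button %in% c(2L, 3L), "inner", "outer"))
}

#' Generate a balanced trial sequence for the stimulus-response mapping task
#'
#' Emulates the event structure of a cued stimulus-response mapping paradigm:
#' on each trial one of four stimulus positions (two per hemifield, inner and
#' outer eccentricity) is shown together with a coloured cue indicating which
#' of two position->button rules applies. Within every block each of the 16
#' cue-colour x position configurations occurs exactly
#' `n_trials_per_block / 16` times, in randomised order. Reaction times are
#' drawn from a log-normal distribution matched to the requested mean and SD;
#' incorrect trials press a uniformly random non-target button and omitted
#' trials have no response.
#'
#' @param n_blocks Number of blocks (default 12).
#' @param n_trials_per_block Trials per block; must be divisible by 16
#'   (default 80).
#' @param colour_rule_map Named character vector mapping each cue colour to a
#'   rule id; see [default_colour_rule_map()].
#' @param rule_definitions Position->button bijections per rule.
#' @param behaviour_params List with `accuracy_rate`, `rt_mean_ms`,
#'   `rt_sd_ms`, `omission_rate`. Defaults mirror typical group behaviour in
#'   this paradigm (accuracy 0.8078, RT 1692 +/- 284 ms, 2.6% omissions).
#' @param seed Integer seed; identical inputs and seed reproduce the table
#'   exactly.
#' @return A `trial_table` (data.frame) with columns `trial_id`, `block`,
#'   `stimulus_position`, `hemifield`, `eccentricity`, `cue_colour`, `rule`,
#'   `response_button`, `response_group`, `rt_ms`, `correct`, `omitted`.
#' @export
generate_trial_sequence <- function(n_blocks = 12L,
                                    n_trials_per_block = 80L,
                                    colour_rule_map = default_colour_rule_map(),
                                    rule_definitions = default_rule_definitions(),
                                    behaviour_params = list(),
                                    seed = NULL) {
  bp <- utils::modifyList(
    list(accuracy_rate = 0.8078, rt_mean_ms = 1692, rt_sd_ms = 284,
         omission_rate = 0.026),
    behaviour_params)
  if (n_trials_per_block %% 16L != 0L)
    stop("n_trials_per_block (", n_trials_per_block,
         ") must be divisible by 16 to balance the 4 colours x 4 positions design")
  if (bp$accuracy_rate < 0 || bp$accuracy_rate > 1 ||
      bp$omission_rate < 0 || bp$omission_rate > 1)
    stop("accuracy_rate and omission_rate must lie in [0, 1]")
  if (bp$rt_mean_ms <= 0 || bp$rt_sd_ms <= 0)
    stop("rt_mean_ms and rt_sd_ms must be positive")
  check_rule_definitions(rule_definitions)
  colours <- names(colour_rule_map)
  if (is.null(colours) || length(colours) != 4L)
    stop("colour_rule_map must map exactly 4 named colours to rules")
  if (!all(colour_rule_map %in% names(rule_definitions)))
    stop("colour_rule_map assigns a colour to a rule absent from rule_definitions")
  if (!is.null(seed)) set.seed(seed)

  # log-normal parameters matched to the requested arithmetic mean / sd
  cv2 <- (bp$rt_sd_ms / bp$rt_mean_ms)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(bp$rt_mean_ms) - sdlog^2 / 2

  cell <- expand.grid(cue_colour = colours,
                      stimulus_position = STIMULUS_POSITIONS,
                      stringsAsFactors = FALSE)
  reps <- n_trials_per_block %/% 16L

  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- sample(rep(seq_len(nrow(cell)), reps))
    df <- cell[idx, , drop = FALSE]
    df$block <- b
    df
  })
  tt <- do.call(rbind, blocks)
  n <- nrow(tt)
  tt$trial_id <- seq_len(n)
  tt$hemifield <- ifelse(grepl("^left", tt$stimulus_position), "left", "right")
  tt$eccentricity <- ifelse(grepl("outer$", tt$stimulus_position), "outer", "inner")
  tt$rule <- unname(colour_rule_map[tt$cue_colour])

  tt$omitted <- stats::runif(n) < bp$omission_rate
  tt$correct <- !tt$omitted & (stats::runif(n) < bp$accuracy_rate)
  tt$rt_ms <- stats::rlnorm(n, meanlog, sdlog)
  tt$rt_ms[tt$omitted] <- NA_real_

  target <- map_stimulus_to_response(tt$stimulus_position, tt$rule, rule_definitions)
  tt$response_button <- target
  err <- !tt$omitted & !tt$correct
  if (any(err)) {
    tt$response_button[err] <- vapply(target[err], function(b)
      sample(setdiff(1:4, b), 1L), integer(1))
  }
  tt$response_button[tt$omitted] <- NA_integer_
  tt$response_group <- response_group_of(tt$response_button)

  tt <- tt[, c("trial_id", "block", "stimulus_position", "hemifield",
               "eccentricity", "cue_colour", "rule", "response_button",
               "response_group", "rt_ms", "correct", "omitted")]
  rownames(tt) <- NULL
  attr(tt, "colour_rule_map") <- colour_rule_map
  attr(tt, "rule_definitions") <- rule_definitions
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Trial table:", nrow(x), "trials,", length(unique(x$block)), "blocks\n")
  cat(sprintf("  accuracy %.1f%%, omissions %.1f%%, median RT %.0f ms\n",
              100 * mean(x$correct[!x$omitted]), 100 * mean(x$omitted),
              stats::median(x$rt_ms, na.rm = TRUE)))
  NextMethod()
}
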