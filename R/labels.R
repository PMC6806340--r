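# UPDRS-III tremor items and the derived regression targets.

#' UPDRS-III tremor labels for one assessment
#'
#' Stores the seven clinician-scored tremor items: five resting-tremor items
#' (head, left/right hand, left/right leg) and two action-tremor items
#' (left/right hand), each an integer 0 (no tremor) to 4 (severe), together
#' with the subject's most-affected side. Composite subscores are derived
#' with [tremor_target()], never stored.
#'
#' @param rest_head,rest_hand_left,rest_hand_right,rest_leg_left,rest_leg_right
#'   resting-tremor items, integers in 0-4.
#' @param action_hand_left,action_hand_right action-tremor items, 0-4.
#' @param most_affected_side `"left"` or `"right"`.
#' @return an object of class `tremor_labels`.
#' @export
tremor_labels <- function(rest_head = 0, rest_hand_left = 0, rest_hand_right = 0,
                          rest_leg_left = 0, rest_leg_right = 0,
                          action_hand_left = 0, action_hand_right = 0,
                          most_affected_side = c("right", "left")) {
  most_affected_side <- match.arg(most_affected_side)
  items <- c(rest_head = rest_head,
             rest_hand_left = rest_hand_left, rest_hand_right = rest_hand_right,
             rest_leg_left = rest_leg_left, rest_leg_right = rest_leg_right,
             action_hand_left = action_hand_left,
             action_hand_right = action_hand_right)
  if (any(items != round(items)) || any(items < 0) || any(items > 4))
    stop("every tremor item must be an integer in [0, 4]")
  structure(list(items = as.integer(items),
                 most_affected_side = most_affected_side),
            class = "tremor_labels")
}

#' @export
print.tremor_labels <- function(x, ...) {
  it <- x$items
  names(it) <- names(x$items)
  cat("<tremor_labels> most-affected side:", x$most_affected_side, "\n")
  print(it)
  cat("total:", tremor_target(x, "total"), "\n")
  invisible(x)
}

#' Derive a composite tremor subscore from labels
#'
#' * `total`: sum of all seven items (0-28);
#' * `rest_hand`: resting item of the most-affected hand (0-4);
#' * `rest_foot`: resting item of the most-affected leg (0-4);
#' * `rest_hand_foot`: their sum (0-8);
#' * `action`: action item of the most-affected hand (0-4).
#'
#' @param labels a [tremor_labels()].
#' @param target one of `"total"`, `"rest_hand_foot"`, `"rest_hand"`,
#'   `"rest_foot"`, `"action"`.
#' @return integer subscore.
#' @export
tremor_target <- function(labels, target = c("total", "rest_hand_foot",
                                             "rest_hand", "rest_foot", "action")) {
  target <- match.arg(target)
  it <- labels$items
  names(it) <- c("rest_head", "rest_hand_left", "rest_hand_right",
                 "rest_leg_left", "rest_leg_right",
                 "action_hand_left", "action_hand_right")
  side <- labels$most_affected_side
  hand <- if (side == "left") it[["rest_hand_left"]] else it[["rest_hand_right"]]
  foot <- if (side == "left") it[["rest_leg_left"]] else it[["rest_leg_right"]]
  act  <- if (side == "left") it[["action_hand_left"]] else it[["action_hand_right"]]
  switch(target,
         total = sum(it),
         rest_hand_foot = hand + foot,
         rest_hand = hand,
         rest_foot = foot,
         action = act)
}

# Vectorized target over a round table (one row per round with item columns).
target_values <- function(rounds, target) {
  vapply(seq_len(nrow(rounds)), function(i) {
    lb <- tremor_labels(rounds$rest_head[i],
                        rounds$rest_hand_left[i], rounds$rest_hand_right[i],
                        rounds$rest_leg_left[i], rounds$rest_leg_right[i],
                        rounds$action_hand_left[i], rounds$action_hand_right[i],
                        rounds$most_affected_side[i])
    as.numeric(tremor_target(lb, target))
  }, numeric(1))
}
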