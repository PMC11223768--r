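#' Per-cycle feedback schedules
#'
#' A feedback schedule lists, for each movement cycle, the cursor feedback
#' mode: `"veridical"` (cursor at the hand), `"clamp"` (cursor direction
#' fixed at `clamp_deg` away from the target regardless of the hand), or
#' `"none"` (no cursor). `blur_ratio` >= 1 scales the visual cue s.d.
#' (1 = clear cursor).
#'
#' @param mode character vector of cycle modes.
#' @param clamp_deg signed clamp angle in degrees per cycle (recycled);
#'   used only on `"clamp"` cycles.
#' @param blur_ratio blur ratio per cycle (recycled), >= 1.
#' @return A data.frame of class `"feedback_schedule"` with columns
#'   `cycle`, `mode`, `clamp_deg`, `blur_ratio`.
#' @examples
#' feedback_schedule(c("veridical", "clamp", "none"), clamp_deg = 8)
#' @export
feedback_schedule <- function(mode, clamp_deg = 0, blur_ratio = 1) {
  if (length(mode) == 0L) stop("schedule must contain at least one cycle")
  mode <- match.arg(mode, c("veridical", "clamp", "none"),
                    several.ok = TRUE)
  n <- length(mode)
  clamp_deg <- rep_len(clamp_deg, n)
  blur_ratio <- rep_len(blur_ratio, n)
  if (any(!is.finite(clamp_deg))) stop("'clamp_deg' must be finite")
  if (any(blur_ratio < 1)) stop("'blur_ratio' must be >= 1")
  structure(data.frame(cycle = seq_len(n), mode = mode,
                       clamp_deg = clamp_deg, blur_ratio = blur_ratio),
            class = c("feedback_schedule", "data.frame"))
}

#' Standard error-clamp session schedule
#'
#' The canonical session design: veridical baseline cycles, no-feedback
#' baseline cycles, error-clamp training cycles at a single clamp size,
#' and no-feedback washout cycles (defaults: 15 + 15 + 80 + 10 = 120
#' cycles, the seven-group adaptation design).
#'
#' @param theta signed clamp size, degrees.
#' @param n_baseline_veridical,n_baseline_none,n_clamp,n_washout cycle
#'   counts per phase (non-negative integers).
#' @param blur_ratio blur ratio applied on clamp cycles, >= 1.
#' @return A `"feedback_schedule"` with an extra `phase` column in
#'   `{"baseline", "clamp", "washout"}`.
#' @export
clamp_schedule <- function(theta,
                           n_baseline_veridical = 15,
                           n_baseline_none = 15,
                           n_clamp = 80,
                           n_washout = 10,
                           blur_ratio = 1) {
  counts <- c(n_baseline_veridical, n_baseline_none, n_clamp, n_washout)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cycle counts must be non-negative integers")
  if (sum(counts) == 0L) stop("schedule must contain at least one cycle")
  mode <- c(rep("veridical", n_baseline_veridical),
            rep("none", n_baseline_none),
            rep("clamp", n_clamp),
            rep("none", n_washout))
  sched <- feedback_schedule(
    mode,
    clamp_deg = c(rep(0, n_baseline_veridical + n_baseline_none),
                  rep(theta, n_clamp), rep(0, n_washout)),
    blur_ratio = c(rep(1, n_baseline_veridical + n_baseline_none),
                   rep(blur_ratio, n_clamp), rep(1, n_washout)))
  sched$phase <- c(rep("baseline", n_baseline_veridical + n_baseline_none),
                   rep("clamp", n_clamp),
                   rep("washout", n_washout))
  sched
}

# Rebuild a schedule from a tidy trajectory/data table holding
# cycle, mode, clamp_deg (and optionally blur_ratio, phase) columns.
schedule_from_data <- function(df) {
  need <- c("cycle", "mode", "clamp_deg")
  if (!all(need %in% names(df)))
    stop("data must contain columns: ", paste(need, collapse = ", "))
  df <- df[order(df$cycle), , drop = FALSE]
  blur <- if ("blur_ratio" %in% names(df)) df$blur_ratio else 1
  sched <- feedback_schedule(df$mode, clamp_deg = df$clamp_deg,
                             blur_ratio = blur)
  if ("phase" %in% names(df)) sched$phase <- df$phase
  sched
}
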