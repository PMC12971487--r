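#' Generate a pseudorandom event table for one run
#'
#' Events are laid out in category sweeps: within each sweep every category
#' appears exactly once (sweep order shuffled), and each category's exemplars
#' are assigned across consecutive sweeps without replacement, so that a
#' second exemplar of any category can only appear after every category has
#' shown its first, and so on. Stimuli are shown for \code{duration} seconds
#' with a jittered stimulus onset asynchrony drawn uniformly from
#' \code{soa_range}.
#'
#' @param stimulus_set a \code{\link{make_stimulus_set}} object.
#' @param n_repetitions number of times each exemplar appears in the run.
#' @param soa_range length-2 numeric, uniform jitter bounds (s) for the
#'   onset-to-onset interval. Default \code{c(3.5, 4.5)}.
#' @param duration stimulus duration in seconds (default 3).
#' @param seed integer seed controlling the shuffles and jitter.
#' @param run integer run id stored in the table.
#' @return An \code{event_table}: data frame with columns \code{onset},
#'   \code{duration}, \code{trial_type} (condition id), \code{run}.
#' @export
make_events <- function(stimulus_set, n_repetitions = 2,
                        soa_range = c(3.5, 4.5), duration = 3, seed = 1L,
                        run = 1L) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  if (!is.numeric(n_repetitions) || n_repetitions < 1)
    stop("n_repetitions must be >= 1")
  if (length(soa_range) != 2 || soa_range[1] > soa_range[2] || soa_range[1] <= 0)
    stop("soa_range must be increasing and positive")
  n_ex <- attr(stimulus_set, "n_exemplars")
  cats <- unique(stimulus_set$category)
  n_sweeps <- n_ex * n_repetitions
  local_rng(seed)
  # per category: exemplar order over sweeps, each exemplar once per n_ex sweeps
  ex_order <- lapply(cats, function(cc) {
    unlist(lapply(seq_len(n_repetitions), function(r) sample(seq_len(n_ex))))
  })
  names(ex_order) <- cats
  rows <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    sweep_cats <- sample(cats)
    cond <- vapply(sweep_cats, function(cc) {
      ex <- ex_order[[cc]][s]
      stimulus_set$condition[stimulus_set$category == cc &
                               stimulus_set$exemplar == ex]
    }, character(1))
    rows[[s]] <- cond
  }
  trial_type <- unlist(rows, use.names = FALSE)
  n_events <- length(trial_type)
  soa <- stats::runif(n_events, soa_range[1], soa_range[2])
  onset <- cumsum(c(0, soa[-n_events]))
  out <- data.frame(onset = onset, duration = duration,
                    trial_type = trial_type, run = as.integer(run),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Check the category ordering constraint of an event table
#'
#' At every prefix of the run, cumulative exemplar counts across categories
#' may never differ by more than 1: occurrence k+1 of any category must wait
#' until every category has had k occurrences.
#'
#' @param events an \code{event_table}.
#' @param stimulus_set the stimulus set the events were drawn from.
#' @return logical, \code{TRUE} when the constraint holds for every run.
#' @export
check_event_constraint <- function(events, stimulus_set) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  cat_of <- stats::setNames(stimulus_set$category, stimulus_set$condition)
  for (r in unique(events$run)) {
    ev <- events[events$run == r, ]
    ev <- ev[order(ev$onset), ]
    cats <- unique(stimulus_set$category)
    counts <- stats::setNames(integer(length(cats)), cats)
    for (tt in ev$trial_type) {
      cc <- cat_of[[tt]]
      counts[cc] <- counts[cc] + 1L
      if (max(counts) - min(counts) > 1L) return(FALSE)
    }
  }
  TRUE
}

# Seed the RNG when a seed is supplied; seeds are reduced mod 2^31 - 1 so
# derived seeds (seed + offset) stay within R's integer range.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% (2^31 - 1)))
  invisible(NULL)
}
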