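#' Default task configuration
#'
#' Returns the design constants of the causal-learning task: five trials of
#' five stimulus presentations per round, presentation frequencies 16:8:1 for
#' the three stimuli, one novel outcome among the five trial outcomes, novel
#' items confined to the last two trials, and outcome magnitudes of +10
#' (non-novel) and -50 (novel) currency units.
#'
#' @param n_rounds Number of rounds in a task (even; half type1, half type2).
#' @param frequencies Integer vector of per-round presentation counts, one per
#'   stimulus. Must sum to `n_trials * events_per_trial`.
#' @param magnitudes Named numeric vector with elements `non_novel` and
#'   `novel`: the monetary outcome associated with each outcome type.
#' @param novel_window Trials in which the novel stimulus and the novel
#'   outcome may appear (positions `16:25` correspond to trials `4:5`).
#' @param timing Logical; generate event timing metadata (1 s stimuli, 2 s
#'   outcomes, U(1,4) s gaps). Timing is metadata only; no model consumes it.
#' @return A list of class `os_config`.
#' @export
task_config <- function(n_rounds = 40L,
                        frequencies = c(16L, 8L, 1L),
                        magnitudes = c(non_novel = 10, novel = -50),
                        novel_window = 4:5,
                        timing = FALSE) {
  stopifnot(length(frequencies) == 3L, sum(frequencies) == 25L,
            all(c("non_novel", "novel") %in% names(magnitudes)))
  structure(list(n_rounds = as.integer(n_rounds),
                 n_trials = 5L, events_per_trial = 5L,
                 frequencies = as.integer(frequencies),
                 magnitudes = magnitudes,
                 novel_window = as.integer(novel_window),
                 timing = timing),
            class = "os_config")
}

#' Generate a single task round
#'
#' Builds one round of the causal-learning task: 25 stimulus presentation
#' slots (5 trials x 5 events) holding stimuli 1..3 at frequencies 16/8/1, and
#' five trial outcomes of which exactly one is novel. The novel stimulus is
#' placed uniformly over its admissible slots in positions 16..25 (trials 4-5)
#' and the novel outcome occupies a late trial; in a type2 round the novel
#' stimulus's trial and the novel outcome's trial coincide, in a type1 round
#' they differ. The remaining 24 slots are a uniform shuffle of the non-novel
#' presentations, mirroring the random-permutation recipe of the task program.
#'
#' @param round_type `"type1"` (novel cue paired with non-novel outcome) or
#'   `"type2"` (novel cue paired with novel outcome).
#' @param config An [task_config()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `os_round` with elements `stimulus` (length-25
#'   integer vector of stimulus indices per position), `trial` (position ->
#'   trial map), `outcome` (length-5 character vector, `"non_novel"`/
#'   `"novel"`), `magnitudes`, `round_type`, and optionally `timing`.
#' @export
generate_round <- function(round_type = c("type1", "type2"),
                           config = task_config(), seed = NULL) {
  round_type <- match.arg(round_type)
  if (!is.null(seed)) set.seed(seed)
  nt <- config$n_trials
  ept <- config$events_per_trial
  trial_of_position <- rep(seq_len(nt), each = ept)

  ## novel outcome trial drawn uniformly from the late window
  novel_trial <- resample(config$novel_window, 1L)
  ## novel stimulus trial: same trial for type2, the other late trial for type1
  s3_trial <- if (round_type == "type2") novel_trial else
    resample(setdiff(config$novel_window, novel_trial), 1L)
  s3_slot <- resample(which(trial_of_position == s3_trial), 1L)

  stimulus <- integer(nt * ept)
  stimulus[s3_slot] <- 3L
  pool <- rep.int(c(1L, 2L), config$frequencies[1:2])
  stimulus[-s3_slot] <- sample(pool)

  outcome <- rep("non_novel", nt)
  outcome[novel_trial] <- "novel"

  out <- structure(list(stimulus = stimulus,
                        trial = trial_of_position,
                        outcome = outcome,
                        magnitudes = config$magnitudes,
                        round_type = round_type),
                   class = "os_round")
  if (isTRUE(config$timing)) out$timing <- round_timing(nt, ept)
  validate_round(out, config)
  out
}

## sample() without the length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]

round_timing <- function(nt, ept) {
  n_ev <- nt * ept
  gaps <- stats::runif(n_ev, 1, 4)      # gap after every stimulus
  iti <- stats::runif(nt, 1, 4)         # inter-trial interval
  onset <- numeric(n_ev)
  t0 <- 0
  k <- 0L
  for (tr in seq_len(nt)) {
    for (e in seq_len(ept)) {
      k <- k + 1L
      onset[k] <- t0
      t0 <- t0 + 1 + gaps[k]            # 1 s stimulus + gap
    }
    t0 <- t0 + 2 + iti[tr]              # 2 s outcome + ITI
  }
  data.frame(position = seq_len(n_ev), onset = onset, duration = 1)
}

validate_round <- function(round, config = task_config()) {
  counts <- tabulate(round$stimulus, nbins = 3L)
  if (!identical(counts, config$frequencies))
    stop("constraint violation: stimulus frequencies are not ",
         paste(config$frequencies, collapse = "/"))
  if (sum(round$outcome == "novel") != 1L)
    stop("constraint violation: a round must have exactly one novel outcome")
  s3_trial <- round$trial[round$stimulus == 3L]
  if (!(s3_trial %in% config$novel_window))
    stop("constraint violation: novel stimulus outside its admissible trials")
  novel_trial <- which(round$outcome == "novel")
  matched <- s3_trial == novel_trial
  if (round$round_type == "type2" && !matched)
    stop("constraint violation: type2 requires novel cue and novel outcome in the same trial")
  if (round$round_type == "type1" && matched)
    stop("constraint violation: type1 requires the novel cue in a non-novel trial")
  invisible(round)
}

#' Generate a full task
#'
#' Generates `n_rounds` rounds with equally balanced round types (type1: the
#' novel cue is paired with a non-novel outcome; type2: with the novel
#' outcome) in randomized order. With the default balanced design of 40 rounds
#' the novel-cue/novel-outcome pairing occurs in exactly 10% of trials.
#'
#' @param n_rounds Even number of rounds (default 40).
#' @param config An [task_config()] object.
#' @param seed Optional integer seed.
#' @return A list of class `os_task` with elements `rounds` (list of
#'   `os_round`) and `config`.
#' @export
generate_task <- function(n_rounds = 40L, config = task_config(n_rounds),
                          seed = NULL) {
  if (n_rounds %% 2L != 0L) stop("n_rounds must be even to balance round types")
  if (!is.null(seed)) set.seed(seed)
  types <- sample(rep(c("type1", "type2"), each = n_rounds / 2L))
  rounds <- lapply(types, generate_round, config = config)
  structure(list(rounds = rounds, config = config), class = "os_task")
}

#' @export
print.os_task <- function(x, ...) {
  types <- vapply(x$rounds, `[[`, "", "round_type")
  cat("Causal learning task: ", length(x$rounds), " rounds (",
      sum(types == "type1"), " type1, ", sum(types == "type2"), " type2), ",
      x$config$n_trials, " trials x ", x$config$events_per_trial,
      " presentations each\n", sep = "")
  invisible(x)
}

#' @export
print.os_round <- function(x, ...) {
  cat("Round (", x$round_type, "): stimuli per trial\n", sep = "")
  m <- matrix(x$stimulus, nrow = 5L)
  dimnames(m) <- list(event = 1:5, trial = 1:5)
  print(m)
  cat("outcomes:", paste(x$outcome, collapse = " "), "\n")
  invisible(x)
}

#' Simulate causal ratings from a registered model
#'
#' Produces a table of synthetic causal ratings for every stimulus-novel
#' outcome pair in every round of a task, by running a generating model and
#' mapping its causal strengths onto the 0-10 integer rating scale with
#' additive Gaussian noise: `round(clip(10 * strength + noise, 0, 10))`.
#'
#' @param task An `os_task`.
#' @param model Model name; see [model_registry()].
#' @param params Named parameter vector for parametric models (see
#'   [model_registry()] for names); ignored for non-parametric models.
#' @param noise_sd Rating-scale (0-10) Gaussian noise standard deviation.
#' @param subtype `"additive"` (within-trial salience = presentation count) or
#'   `"sole"` (presence indicator).
#' @param subject Subject identifier recorded in the table.
#' @param seed Optional integer seed.
#' @return A data.frame of class `os_ratings` with columns `subject`, `round`,
#'   `stimulus`, `outcome_type`, `rating`, carrying a `provenance` attribute
#'   (generating model, subtype, params, noise_sd).
#' @export
simulate_ratings <- function(task, model = "BayesU", params = proto_params(),
                             noise_sd = 0.5, subtype = "additive",
                             subject = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strengths <- predict_model(model, task, params, subtype)  # rounds x 3, [0,1]
  n_rounds <- nrow(strengths)
  raw <- 10 * strengths
  if (noise_sd > 0)
    raw <- raw + matrix(stats::rnorm(length(raw), sd = noise_sd), nrow = n_rounds)
  rating <- as.integer(round(pmin(pmax(raw, 0), 10)))
  out <- data.frame(subject = subject,
                    round = rep(seq_len(n_rounds), times = 3L),
                    stimulus = rep(1:3, each = n_rounds),
                    outcome_type = "novel",
                    rating = rating)
  out <- out[order(out$round, out$stimulus), ]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(model = model, subtype = subtype,
                                  params = params, noise_sd = noise_sd)
  class(out) <- c("os_ratings", "data.frame")
  out
}

#' Tabular export and import of tasks and ratings
#'
#' `write_events()`/`read_events()` round-trip a task through a plain-text
#' events table (one row per stimulus presentation, columns `subject`,
#' `round`, `round_type`, `trial`, `position`, `stimulus`, `outcome_type`,
#' `outcome_magnitude`). `write_ratings()`/`read_ratings()` do the same for
#' rating tables (columns `subject`, `round`, `stimulus`, `outcome_type`,
#' `rating`). Files are CSV, or TSV when the path ends in `.tsv`.
#'
#' @param task An `os_task`.
#' @param path File path.
#' @param subject Subject id column value for event tables.
#' @return `read_events()` returns an `os_task`; `read_ratings()` an
#'   `os_ratings` data.frame. Writers return the path invisibly.
#' @export
write_events <- function(task, path, subject = 1L) {
  rows <- lapply(seq_along(task$rounds), function(r) {
    rd <- task$rounds[[r]]
    data.frame(subject = subject, round = r, round_type = rd$round_type,
               trial = rd$trial, position = seq_along(rd$stimulus),
               stimulus = rd$stimulus,
               outcome_type = rd$outcome[rd$trial],
               outcome_magnitude = unname(rd$magnitudes[rd$outcome[rd$trial]]))
  })
  write_table(do.call(rbind, rows), path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_table(path, c("subject", "round", "round_type", "trial",
                           "position", "stimulus", "outcome_type",
                           "outcome_magnitude"))
  config <- task_config(n_rounds = length(unique(df$round)))
  rounds <- lapply(split(df, df$round), function(d) {
    d <- d[order(d$position), ]
    mag <- c(non_novel = as.numeric(unique(
               d$outcome_magnitude[d$outcome_type == "non_novel"])),
             novel = as.numeric(unique(
               d$outcome_magnitude[d$outcome_type == "novel"])))
    structure(list(stimulus = as.integer(d$stimulus),
                   trial = as.integer(d$trial),
                   outcome = as.character(d$outcome_type[match(1:5, d$trial)]),
                   magnitudes = mag,
                   round_type = as.character(d$round_type[1])),
              class = "os_round")
  })
  rounds <- rounds[order(as.integer(names(rounds)))]
  names(rounds) <- NULL
  structure(list(rounds = rounds, config = config), class = "os_task")
}

#' @rdname write_events
#' @param ratings An `os_ratings` data.frame.
#' @export
write_ratings <- function(ratings, path) {
  write_table(as.data.frame(ratings), path)
}

#' @rdname write_events
#' @export
read_ratings <- function(path) {
  df <- read_table(path, c("subject", "round", "stimulus", "outcome_type",
                           "rating"))
  bad <- which(df$rating < 0 | df$rating > 10)
  if (length(bad))
    stop("parse error: rating outside 0..10 at row ", bad[1])
  class(df) <- c("os_ratings", "data.frame")
  df
}

write_table <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table <- function(path, required) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("parse error: missing column(s) ", paste(missing, collapse = ", "))
  df
}

## per-round summaries used by every model: within-trial presentation counts,
## presence indicators, first/last stimulus of each trial, novel-outcome flag
round_summary <- function(round) {
  nt <- max(round$trial)
  counts <- matrix(0L, nt, 3L)
  for (tr in seq_len(nt)) {
    s <- round$stimulus[round$trial == tr]
    counts[tr, ] <- tabulate(s, nbins = 3L)
  }
  firsts <- vapply(seq_len(nt), function(tr)
    round$stimulus[round$trial == tr][1L], integer(1))
  ept <- length(round$stimulus) / nt
  lasts <- vapply(seq_len(nt), function(tr) {
    s <- round$stimulus[round$trial == tr]
    s[length(s)]
  }, integer(1))
  mags <- abs(round$magnitudes[round$outcome])
  list(counts = counts, presence = counts > 0L,
       first = firsts, last = lasts,
       novel = round$outcome == "novel",
       lambda = unname(mags / max(abs(round$magnitudes))),
       stimulus = round$stimulus, trial = round$trial,
       round_type = round$round_type)
}

task_summaries <- function(task) lapply(task$rounds, round_summary)
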