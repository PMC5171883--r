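event_kinds <- c("precue_start", "cue_on", "cue_off", "poke", "reward",
                 "iti_start", "session_end")

#' Construct an operant session event log
#'
#' A time-stamped record of one Go/No-go session. Events carry a time `t`
#' (seconds from session start), a `kind` (`precue_start`, `cue_on`,
#' `cue_off`, `poke`, `reward`, `iti_start`, `session_end`) and a `detail`:
#' the trial type (`go` / `nogo`) for `cue_on`, and the poke location
#' (`cue_recess` / `center_recess`) for `poke`. Construction validates that
#' times are non-decreasing, every `cue_on` is closed by a `cue_off` before
#' the next cue, and kinds/details are from the allowed vocabulary.
#'
#' @param events Data.frame with columns `t`, `kind`, `detail`.
#' @param animal_id,day Session identifiers.
#' @param phase One of `"train1"`, `"train2"`, `"gonogo"`.
#' @param version Protocol version, `"V1"` or `"V2"`.
#' @return An object of class `event_log`.
#' @export
event_log <- function(events, animal_id = "unknown", day = 1L,
                      phase = "gonogo", version = "V1") {
  stopifnot(is.data.frame(events),
            all(c("t", "kind", "detail") %in% names(events)))
  phase <- match.arg(phase, c("train1", "train2", "gonogo"))
  version <- match.arg(version, c("V1", "V2"))
  events$t <- as.numeric(events$t)
  events$kind <- as.character(events$kind)
  events$detail <- as.character(events$detail)
  if (nrow(events)) {
    if (any(!events$kind %in% event_kinds))
      ld_abort("unknown event kind", "linedrift_structure")
    if (any(diff(events$t) < 0))
      ld_abort("event times must be non-decreasing", "linedrift_structure")
    bad <- events$kind == "poke" &
      !events$detail %in% c("cue_recess", "center_recess")
    if (any(bad))
      ld_abort("poke events need detail cue_recess or center_recess",
               "linedrift_structure")
    bad <- events$kind == "cue_on" & !events$detail %in% c("go", "nogo")
    if (any(bad))
      ld_abort("cue_on events need detail go or nogo", "linedrift_structure")
    state <- cumsum((events$kind == "cue_on") - (events$kind == "cue_off"))
    if (any(state > 1) || any(state < 0) || state[length(state)] != 0)
      ld_abort("every cue_on must be closed by one cue_off before the next",
               "linedrift_structure")
  }
  structure(list(meta = list(animal_id = animal_id, day = as.integer(day),
                             phase = phase, version = version),
                 events = events[c("t", "kind", "detail")]),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> animal %s, day %d, phase %s (%s): %d events, %d trials\n",
              x$meta$animal_id, x$meta$day, x$meta$phase, x$meta$version,
              nrow(x$events), sum(x$events$kind == "cue_on")))
  invisible(x)
}

#' Read / write event-log CSV files
#'
#' CSV dialect: data columns `t_seconds, kind, detail`, preceded by
#' commented header lines (`# key: value`) carrying the session metadata.
#'
#' @param path CSV path.
#' @return [read_event_log()] returns an `event_log`;
#'   [write_event_log()] returns `path` invisibly.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  if (!all(c("t_seconds", "kind", "detail") %in% names(df)))
    ld_abort("event log needs columns t_seconds, kind, detail",
             "linedrift_format")
  event_log(data.frame(t = df$t_seconds, kind = df$kind, detail = df$detail,
                       stringsAsFactors = FALSE),
            animal_id = meta$animal_id %||% "unknown",
            day = as.integer(meta$day %||% 1L),
            phase = meta$phase %||% "gonogo",
            version = meta$version %||% "V1")
}

#' @rdname read_event_log
#' @param log An `event_log`.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("animal_id", "day", "phase", "version"),
                     c(log$meta$animal_id, log$meta$day, log$meta$phase,
                       log$meta$version)), con)
  df <- data.frame(t_seconds = log$events$t, kind = log$events$kind,
                   detail = log$events$detail)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Score a Go/No-go session from its event log
#'
#' Computes the operant endpoints of a Go/No-go session:
#' \itemize{
#'   \item `hits` — go trials whose cue window contains a cue-recess poke
#'     (the first such poke is the response);
#'   \item `false_alarms` — no-go trials with a cue-recess poke in the
#'     window (failure to withhold);
#'   \item `hit_latency_mean`, `fa_latency_mean` — mean poke-minus-cue-onset
#'     latency over responded trials only (`NA` when none);
#'   \item `precue_responses` — cue-recess pokes during the final
#'     `precue_tail` (3 s) of a precue period;
#'   \item `cue_side_pokes` — cue-recess pokes outside any cue window and
#'     not counted as precue responses (random poking during precue, reward
#'     or intertrial periods);
#'   \item `reinforcers` — hits plus correct rejections (a correct response
#'     on either trial type earns one reward);
#'   \item `total_pokes` — all pokes at either recess;
#'   \item `efficiency` — `100 * reinforcers / total_pokes`, the raw ratio
#'     without capping; `NA` when no poke occurred.
#' }
#' Each poke counts toward exactly one category by time-window priority:
#' cue-window response, then precue response, then cue-side poke. Pokes in
#' a cue window after the scored response (possible only if the cue stayed
#' on) are counted as cue-side pokes. Center-recess pokes enter
#' `total_pokes` only.
#'
#' @param log An [event_log] of a Go/No-go (or training) session.
#' @param precue_tail Length (s) of the terminal precue span in which pokes
#'   count as precue responses; default 3.
#' @return An object of class `session_score` (a list of the fields above,
#'   plus `n_go`, `n_nogo`, `misses`, `correct_rejections`).
#' @export
score_gonogo_session <- function(log, precue_tail = 3) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  on_i <- which(ev$kind == "cue_on")
  off_i <- which(ev$kind == "cue_off")
  if (length(on_i) != length(off_i))
    ld_abort("unbalanced cue_on/cue_off events", "linedrift_structure")
  pre_i <- which(ev$kind == "precue_start")

  trials <- data.frame(on = ev$t[on_i], off = ev$t[off_i],
                       type = ev$detail[on_i])
  # precue window preceding each cue onset
  if (length(pre_i)) {
    pre_t <- ev$t[pre_i]
    trials$pre_start <- vapply(trials$on, function(on) {
      cand <- pre_t[pre_t <= on]
      if (length(cand)) max(cand) else NA_real_
    }, numeric(1))
  } else trials$pre_start <- NA_real_

  pokes <- ev[ev$kind == "poke", , drop = FALSE]
  total_pokes <- nrow(pokes)
  cue_pokes <- pokes[pokes$detail == "cue_recess", , drop = FALSE]

  n_tr <- nrow(trials)
  responded <- logical(n_tr)
  latency <- rep(NA_real_, n_tr)
  response_idx <- integer(0)
  if (nrow(cue_pokes) && n_tr) {
    for (k in seq_len(n_tr)) {
      inwin <- which(cue_pokes$t >= trials$on[k] & cue_pokes$t <= trials$off[k])
      if (length(inwin)) {
        first <- inwin[1]
        responded[k] <- TRUE
        latency[k] <- cue_pokes$t[first] - trials$on[k]
        response_idx <- c(response_idx, first)
      }
    }
  }

  is_go <- trials$type == "go"
  hits <- sum(responded & is_go)
  fas <- sum(responded & !is_go)
  misses <- sum(!responded & is_go)
  crs <- sum(!responded & !is_go)

  # classify remaining cue-recess pokes: precue response vs cue-side poke
  remaining <- setdiff(seq_len(nrow(cue_pokes)), response_idx)
  precue_responses <- 0L
  cue_side <- 0L
  for (j in remaining) {
    tj <- cue_pokes$t[j]
    tail_ok <- !is.na(trials$pre_start) &
      tj >= pmax(trials$pre_start, trials$on - precue_tail) & tj < trials$on
    if (any(tail_ok)) precue_responses <- precue_responses + 1L
    else cue_side <- cue_side + 1L
  }

  reinforcers <- hits + crs
  structure(list(
    hits = hits, false_alarms = fas, misses = misses,
    correct_rejections = crs,
    hit_latency_mean = if (hits) mean(latency[responded & is_go]) else NA_real_,
    fa_latency_mean = if (fas) mean(latency[responded & !is_go]) else NA_real_,
    precue_responses = precue_responses, cue_side_pokes = cue_side,
    reinforcers = reinforcers, total_pokes = total_pokes,
    efficiency = if (total_pokes > 0) 100 * reinforcers / total_pokes
                 else NA_real_,
    n_go = sum(is_go), n_nogo = sum(!is_go)),
    class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf(paste0("<session_score> hits %d/%d, FA %d/%d, ",
                     "precue %d, cue-side %d, reinforcers %d, ",
                     "pokes %d, efficiency %s\n"),
              x$hits, x$n_go, x$false_alarms, x$n_nogo, x$precue_responses,
              x$cue_side_pokes, x$reinforcers, x$total_pokes,
              ifelse(is.na(x$efficiency), "NA",
                     sprintf("%.1f%%", x$efficiency))))
  invisible(x)
}

#' Training criterion: 30 hits in under 40 minutes on two consecutive days
#'
#' A mouse passes a training phase on the first day `d` such that days
#' `d-1` and `d` both record at least 30 hits in a session lasting under 40
#' minutes.
#'
#' @param daily Data.frame (or list coercible to one) with columns `hits`
#'   and `session_minutes`, one row per day in chronological order.
#' @param hits_required Criterion hits per day (default 30).
#' @param max_minutes Session must finish strictly under this (default 40).
#' @return List with `passed` (logical) and `day_passed` (first day the
#'   two-day criterion is met, or `NA`).
#' @export
evaluate_training <- function(daily, hits_required = 30, max_minutes = 40) {
  daily <- as.data.frame(daily)
  stopifnot(all(c("hits", "session_minutes") %in% names(daily)))
  ok <- daily$hits >= hits_required & daily$session_minutes < max_minutes
  if (length(ok) >= 2) {
    both <- which(ok[-1] & ok[-length(ok)])
    if (length(both))
      return(list(passed = TRUE, day_passed = both[1] + 1L))
  }
  list(passed = FALSE, day_passed = NA_integer_)
}

#' Reward-collection exclusion rule
#'
#' An animal is excluded when any testing session earned reinforcers that
#' were never collected (`reinforcers > 0` with `collected = 0`), the
#' criterion used to guarantee that reward remained motivating.
#'
#' @param scores List of [session_score] objects for one animal.
#' @param collected_rewards Integer vector, rewards actually collected per
#'   session, aligned with `scores`.
#' @return List with `included` (logical), `reason` (`"ok"` or
#'   `"uncollected_reward"`) and `first_violation` (session index or `NA`).
#' @export
apply_exclusions <- function(scores, collected_rewards) {
  if (length(scores) != length(collected_rewards))
    ld_abort("`scores` and `collected_rewards` must align",
             "linedrift_alignment")
  earned <- vapply(scores, function(s) s$reinforcers, numeric(1))
  bad <- which(earned > 0 & collected_rewards == 0)
  if (length(bad))
    list(included = FALSE, reason = "uncollected_reward",
         first_violation = bad[1])
  else list(included = TRUE, reason = "ok", first_violation = NA_integer_)
}

#' Score Y-maze spontaneous alternation
#'
#' An alternation is a run of three consecutive arm entries into three
#' distinct arms (entry into all arms without revisiting one). Percent
#' alternation divides by the number of entry triplets, `entries - 2`.
#'
#' @param arm_sequence Character vector of arm labels from `A`, `B`, `C`,
#'   in entry order. Consecutive duplicates are invalid (re-entering the
#'   same arm is not an entry).
#' @return An object of class `ymaze_score`: `entries`, `alternations`,
#'   `percent_alternation` (`NA` when fewer than 3 entries).
#' @examples
#' score_ymaze(c("A", "B", "C", "A", "B", "C"))
#' @export
score_ymaze <- function(arm_sequence) {
  arm_sequence <- as.character(arm_sequence)
  if (any(!arm_sequence %in% c("A", "B", "C")))
    ld_abort("arm labels must be A, B or C", "linedrift_domain")
  n <- length(arm_sequence)
  if (n >= 2 && any(arm_sequence[-1] == arm_sequence[-n]))
    ld_abort("consecutive duplicate arm entries are invalid",
             "linedrift_domain")
  alt <- 0L
  if (n >= 3)
    for (i in seq_len(n - 2))
      if (length(unique(arm_sequence[i:(i + 2)])) == 3L) alt <- alt + 1L
  structure(list(entries = n, alternations = alt,
                 percent_alternation = if (n >= 3) 100 * alt / (n - 2)
                                       else NA_real_),
            class = "ymaze_score")
}

#' Read an arm-entry sequence CSV (one `arm` label per row)
#'
#' @param path CSV path with a single column `arm`.
#' @return Character vector of arm labels.
#' @export
read_arm_sequence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"arm" %in% names(df))
    ld_abort("arm-sequence file needs a column `arm`", "linedrift_format")
  as.character(df$arm)
}

#' Score one rotarod day
#'
#' Summarizes the 4 daily accelerating-rotarod trials as mean and maximum
#' fall latency. Trials shorter than `slip_threshold` are treated as slips
#' and replaced, in order, by the supplied extra trials; slips without a
#' replacement are retained but flagged.
#'
#' @param latencies Fall latencies (s) of the 4 regular trials.
#' @param extra Fall latencies of any extra (replacement) trials.
#' @param slip_threshold Latency (s) under which a trial counts as a slip;
#'   default 5.
#' @return List with `mean`, `max`, `retained` (the 4 latencies used),
#'   `n_slips`, `n_replaced`.
#' @examples
#' score_rotarod(c(1, 20, 30, 40), extra = 25)  # mean 28.75
#' @export
score_rotarod <- function(latencies, extra = numeric(0), slip_threshold = 5) {
  if (length(latencies) < 4)
    ld_abort("a rotarod day needs 4 regular trials",
             "linedrift_insufficient_trials")
  if (length(latencies) > 4)
    ld_abort("supply replacement trials via `extra`, not extra regular trials",
             "linedrift_insufficient_trials")
  retained <- latencies
  slips <- which(retained < slip_threshold)
  n_rep <- min(length(slips), length(extra))
  if (n_rep) retained[slips[seq_len(n_rep)]] <- extra[seq_len(n_rep)]
  list(mean = mean(retained), max = max(retained), retained = retained,
       n_slips = length(slips), n_replaced = n_rep)
}

#' Score a rotarod trial table
#'
#' Long-format input with columns `animal, day, trial, latency, is_extra`
#' (`is_extra` truthy for replacement trials); returns per animal-day mean
#' and maximum latency after slip replacement.
#'
#' @param df Data.frame as above (see [read_rotarod_table()]).
#' @param slip_threshold Passed to [score_rotarod()].
#' @return Data.frame with columns `animal, day, mean_latency, max_latency`.
#' @export
score_rotarod_table <- function(df, slip_threshold = 5) {
  stopifnot(all(c("animal", "day", "trial", "latency", "is_extra") %in%
                  names(df)))
  key <- interaction(df$animal, df$day, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    g <- g[order(g$trial), ]
    s <- score_rotarod(g$latency[!as.logical(g$is_extra)],
                       g$latency[as.logical(g$is_extra)], slip_threshold)
    data.frame(animal = g$animal[1], day = g$day[1],
               mean_latency = s$mean, max_latency = s$max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal, out$day), ]
  rownames(out) <- NULL
  out
}

#' Read a rotarod trial CSV
#'
#' @param path CSV with columns `animal, day, trial, latency, is_extra`.
#' @return Data.frame suitable for [score_rotarod_table()].
#' @export
read_rotarod_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "day", "trial", "latency", "is_extra")
  if (!all(need %in% names(df)))
    ld_abort(paste("rotarod file needs columns", paste(need, collapse = ", ")),
             "linedrift_format")
  df$latency <- as.numeric(df$latency)
  df$is_extra <- as.logical(df$is_extra)
  df
}
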