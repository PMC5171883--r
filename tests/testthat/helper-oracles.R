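# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# Tabular additive-relationship-matrix method: build the full A matrix by
# recursion over a parents-first pedigree, then F_i = A[i,i] - 1.
tabular_inbreeding <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    for (j in seq_len(i - 1L)) {
      aij <- 0
      if (s > 0) aij <- aij + 0.5 * A[j, s]
      if (d > 0) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- aij
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  diag(A) - 1
}

# Random valid pedigree as parallel sire/dam index vectors (0 = unknown),
# parents drawn from earlier individuals only.
random_pedigree_idx <- function(n, n_founders = max(4L, n %/% 5L)) {
  sire <- integer(n); dam <- integer(n)
  sex <- sample(rep_len(c("M", "F"), n))
  sex[1:2] <- c("M", "F")
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (!length(males) || !length(females)) next
    if (runif(1) < 0.15) next  # some founders appear late too
    sire[i] <- males[sample.int(length(males), 1)]
    dam[i] <- females[sample.int(length(females), 1)]
  }
  list(sire = sire, dam = dam, sex = sex)
}

# Wrap index vectors into the pedigree CSV layout used by the package.
idx_to_pedigree_df <- function(px, line = "selected") {
  n <- length(px$sire)
  gen <- integer(n)
  for (i in seq_len(n)) {
    g <- 0L
    if (px$sire[i] > 0) g <- max(g, gen[px$sire[i]] + 1L)
    if (px$dam[i] > 0) g <- max(g, gen[px$dam[i]] + 1L)
    gen[i] <- g
  }
  data.frame(id = paste0("a", seq_len(n)),
             sire = ifelse(px$sire == 0, NA, paste0("a", px$sire)),
             dam = ifelse(px$dam == 0, NA, paste0("a", px$dam)),
             sex = px$sex, generation = gen, family = "f1", line = line,
             stringsAsFactors = FALSE)
}

# Naive event-by-event Go/No-go scorer: walks the log once, tracking the
# current period, and tallies each endpoint directly from the definitions.
naive_score_gonogo <- function(log, precue_tail = 3) {
  ev <- log$events
  # reconstruct period boundaries
  ons <- ev$t[ev$kind == "cue_on"]
  offs <- ev$t[ev$kind == "cue_off"]
  types <- ev$detail[ev$kind == "cue_on"]
  pres <- ev$t[ev$kind == "precue_start"]
  pk <- ev[ev$kind == "poke", ]

  hits <- 0L; fas <- 0L; crs <- 0L; miss <- 0L
  hlat <- c(); flat <- c()
  counted <- rep(FALSE, nrow(pk))
  for (k in seq_along(ons)) {
    idx <- which(pk$detail == "cue_recess" & pk$t >= ons[k] &
                   pk$t <= offs[k] & !counted)
    if (length(idx)) {
      counted[idx[1]] <- TRUE
      lat <- pk$t[idx[1]] - ons[k]
      if (types[k] == "go") { hits <- hits + 1L; hlat <- c(hlat, lat) }
      else { fas <- fas + 1L; flat <- c(flat, lat) }
    } else {
      if (types[k] == "go") miss <- miss + 1L else crs <- crs + 1L
    }
  }
  precue <- 0L; side <- 0L
  for (j in seq_len(nrow(pk))) {
    if (counted[j] || pk$detail[j] != "cue_recess") next
    in_tail <- FALSE
    for (k in seq_along(ons)) {
      ps <- pres[pres <= ons[k]]
      if (!length(ps)) next
      lo <- max(max(ps), ons[k] - precue_tail)
      if (pk$t[j] >= lo && pk$t[j] < ons[k]) { in_tail <- TRUE; break }
    }
    if (in_tail) precue <- precue + 1L else side <- side + 1L
  }
  reinf <- hits + crs
  list(hits = hits, false_alarms = fas, misses = miss,
       correct_rejections = crs,
       hit_latency_mean = if (length(hlat)) mean(hlat) else NA_real_,
       fa_latency_mean = if (length(flat)) mean(flat) else NA_real_,
       precue_responses = precue, cue_side_pokes = side,
       reinforcers = reinf, total_pokes = nrow(pk),
       efficiency = if (nrow(pk) > 0) 100 * reinf / nrow(pk) else NA_real_)
}

# Sliding-window alternation counter.
naive_alternations <- function(seq) {
  alt <- 0L
  if (length(seq) >= 3)
    for (i in 1:(length(seq) - 2))
      if (seq[i] != seq[i + 1] && seq[i] != seq[i + 2] &&
          seq[i + 1] != seq[i + 2]) alt <- alt + 1L
  alt
}

# Build a small event log by hand from trial descriptors.
# trials: data.frame(type, latency [NA = no response])
manual_log <- function(trials, precue = 4, cue_window = 5, reward = 3,
                       iti = 10, extra_pokes = NULL) {
  rows <- list(); t <- 0
  for (k in seq_len(nrow(trials))) {
    rows[[length(rows) + 1]] <- data.frame(t = t, kind = "precue_start",
                                           detail = "")
    tc <- t + precue
    rows[[length(rows) + 1]] <- data.frame(t = tc, kind = "cue_on",
                                           detail = trials$type[k])
    lat <- trials$latency[k]
    if (!is.na(lat)) {
      rows[[length(rows) + 1]] <- data.frame(t = tc + lat, kind = "poke",
                                             detail = "cue_recess")
      toff <- tc + lat
    } else toff <- tc + cue_window
    rows[[length(rows) + 1]] <- data.frame(t = toff, kind = "cue_off",
                                           detail = "")
    correct <- (trials$type[k] == "go" && !is.na(lat)) ||
      (trials$type[k] == "nogo" && is.na(lat))
    if (correct) {
      rows[[length(rows) + 1]] <- data.frame(t = toff, kind = "reward",
                                             detail = "")
      ti <- toff + reward
    } else ti <- toff
    rows[[length(rows) + 1]] <- data.frame(t = ti, kind = "iti_start",
                                           detail = "")
    t <- ti + iti
  }
  rows[[length(rows) + 1]] <- data.frame(t = t, kind = "session_end",
                                         detail = "")
  ev <- do.call(rbind, rows)
  if (!is.null(extra_pokes)) {
    ev <- rbind(ev, data.frame(t = extra_pokes$t, kind = "poke",
                               detail = extra_pokes$detail))
    ev <- ev[order(ev$t), ]
  }
  event_log(ev)
}
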