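#' Configuration for the breeding simulator
#'
#' Describes a two-line selection experiment under the infinitesimal model:
#' `n_families` breeding pairs per line, `offspring_per_family` pups per
#' pair, bred for `generations` rounds. Traits are multivariate: breeding
#' values are drawn with additive variances `h2 * phenotypic_variance` and
#' the given genetic correlations; environmental deviations carry the
#' remaining variance. The selected line is bred under `selection_mode`
#' (`within_family`: best male and best female of each family; `mass`: best
#' overall; `random`: random within each family) on the phenotype of
#' `selected_trait`; the control line is always bred at random within
#' families. Defaults mirror the scale of the motivating colony: 10
#' families per line, 16 generations, a selected trait at `h2 = 0.33` and a
#' genetically uncorrelated second trait.
#'
#' @param n_families Breeding pairs per line (>= 2); default 10.
#' @param offspring_per_family Pups per pair (even, >= 2); default 8.
#' @param generations Number of bred generations; default 16.
#' @param h2 Heritability per trait, each in \[0, 1\].
#' @param genetic_correlation Symmetric PSD matrix with unit diagonal.
#' @param phenotypic_variance Per-trait phenotypic variance (> 0).
#' @param env_correlation Environmental correlation matrix; default
#'   identity.
#' @param selection_mode `"within_family"`, `"mass"` or `"random"`.
#' @param selected_trait Index of the trait under selection.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 10, offspring_per_family = 8,
                       generations = 16, h2 = c(0.33, 0.33),
                       genetic_correlation = diag(length(h2)),
                       phenotypic_variance = rep(1, length(h2)),
                       env_correlation = diag(length(h2)),
                       selection_mode = c("within_family", "mass", "random"),
                       selected_trait = 1, seed = NULL) {
  selection_mode <- match.arg(selection_mode)
  nt <- length(h2)
  if (!is_count(n_families) || n_families < 2)
    ld_abort("`n_families` must be an integer >= 2", "linedrift_config")
  if (!is_count(offspring_per_family) || offspring_per_family < 2 ||
      offspring_per_family %% 2 != 0)
    ld_abort("`offspring_per_family` must be an even integer >= 2",
             "linedrift_config")
  if (!is_count(generations))
    ld_abort("`generations` must be a positive integer", "linedrift_config")
  if (any(h2 < 0) || any(h2 > 1))
    ld_abort("`h2` must lie in [0, 1]", "linedrift_config")
  if (any(phenotypic_variance <= 0))
    ld_abort("`phenotypic_variance` must be positive", "linedrift_config")
  for (nm in c("genetic_correlation", "env_correlation")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != nt) || any(abs(diag(m) - 1) > 1e-12) ||
        any(abs(m - t(m)) > 1e-12))
      ld_abort(paste0("`", nm, "` must be a symmetric ", nt, "x", nt,
                      " matrix with unit diagonal"), "linedrift_config")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      ld_abort(paste0("`", nm, "` must be positive semi-definite"),
               "linedrift_config")
  }
  if (!is_count(selected_trait) || selected_trait > nt)
    ld_abort("`selected_trait` must index a trait", "linedrift_config")
  structure(list(n_families = as.integer(n_families),
                 offspring_per_family = as.integer(offspring_per_family),
                 generations = as.integer(generations), h2 = h2,
                 genetic_correlation = genetic_correlation,
                 phenotypic_variance = phenotypic_variance,
                 env_correlation = env_correlation,
                 selection_mode = selection_mode,
                 selected_trait = as.integer(selected_trait), seed = seed),
            class = "sim_config")
}

# pair selected sires and dams avoiding same-family matings
pair_avoiding_sibs <- function(sires, dams, fam_s, fam_d, max_tries = 1000) {
  n <- length(sires)
  for (try in seq_len(max_tries)) {
    p <- sample.int(n)
    if (all(fam_d[p] != fam_s)) return(list(sires = sires, dams = dams[p]))
  }
  ld_abort("could not pair breeders without mating siblings",
           "linedrift_breeding_failure")
}

# simulate one closed line; integer ids local to the line
sim_line <- function(cfg, mode) {
  nf <- cfg$n_families
  k <- cfg$offspring_per_family
  G <- cfg$generations
  nt <- length(cfg$h2)
  sA <- sqrt(cfg$h2 * cfg$phenotypic_variance)
  sE <- sqrt((1 - cfg$h2) * cfg$phenotypic_variance)
  sqA <- mat_sqrt(diag(sA, nt) %*% cfg$genetic_correlation %*% diag(sA, nt))
  sqE <- mat_sqrt(diag(sE, nt) %*% cfg$env_correlation %*% diag(sE, nt))

  N <- 2L * nf + G * nf * k
  sire <- integer(N); dam <- integer(N); sex <- character(N)
  gen <- integer(N); fam <- integer(N)
  A <- matrix(0, N, nt); P <- matrix(0, N, nt)
  Fv <- numeric(N)

  n0 <- 2L * nf
  sex[1:n0] <- rep(c("M", "F"), nf)
  fam[1:n0] <- rep(seq_len(nf), each = 2)
  A[1:n0, ] <- rmvn_sqrt(n0, sqA)
  P[1:n0, ] <- A[1:n0, , drop = FALSE] + rmvn_sqrt(n0, sqE)
  cur_sires <- seq(1L, n0, by = 2L)
  cur_dams <- seq(2L, n0, by = 2L)
  top <- n0

  for (g in seq_len(G)) {
    noff <- nf * k
    off <- top + seq_len(noff)
    os <- rep(cur_sires, each = k)
    od <- rep(cur_dams, each = k)
    sire[off] <- os
    dam[off] <- od
    fam[off] <- rep(seq_len(nf), each = k)
    sex[off] <- rep(rep_len(c("M", "F"), k), nf)
    gen[off] <- g
    # Mendelian sampling variance shrinks with parental inbreeding
    msd <- sqrt(pmax(0.5 * (1 - (Fv[os] + Fv[od]) / 2), 0))
    A[off, ] <- (A[os, , drop = FALSE] + A[od, , drop = FALSE]) / 2 +
      msd * rmvn_sqrt(noff, sqA)
    P[off, ] <- A[off, , drop = FALSE] + rmvn_sqrt(noff, sqE)
    prev <- top
    top <- top + noff
    Fv[seq_len(top)] <- inbreeding_ml(sire[seq_len(top)], dam[seq_len(top)],
                                      Fv[seq_len(prev)])

    if (g < G) {
      ph <- P[off, cfg$selected_trait]
      osex <- sex[off]
      ofam <- fam[off]
      pick <- function(keep) {
        cand <- off[keep]
        if (!length(cand))
          ld_abort("a family has no eligible breeder of one sex",
                   "linedrift_breeding_failure")
        cand
      }
      if (mode == "mass") {
        males <- pick(osex == "M")
        females <- pick(osex == "F")
        o <- order(-P[males, cfg$selected_trait], runif(length(males)))
        new_s <- males[o[seq_len(nf)]]
        o <- order(-P[females, cfg$selected_trait], runif(length(females)))
        new_d <- females[o[seq_len(nf)]]
      } else {
        new_s <- integer(nf); new_d <- integer(nf)
        for (f in seq_len(nf)) {
          m <- pick(ofam == f & osex == "M")
          fe <- pick(ofam == f & osex == "F")
          if (mode == "within_family") {
            new_s[f] <- m[order(-P[m, cfg$selected_trait],
                                runif(length(m)))[1]]
            new_d[f] <- fe[order(-P[fe, cfg$selected_trait],
                                 runif(length(fe)))[1]]
          } else {  # random
            new_s[f] <- m[sample.int(length(m), 1)]
            new_d[f] <- fe[sample.int(length(fe), 1)]
          }
        }
      }
      pr <- pair_avoiding_sibs(new_s, new_d, fam[new_s], fam[new_d])
      cur_sires <- pr$sires
      cur_dams <- pr$dams
    }
  }
  list(sire = sire, dam = dam, sex = sex, gen = gen, fam = fam,
       A = A, P = P, Fv = Fv)
}

#' Simulate a two-line selection experiment
#'
#' Forward simulation under the infinitesimal model: founder breeding
#' values are multivariate normal; offspring breeding values are the
#' midparent plus a Mendelian sampling deviation with covariance
#' `0.5 * Sigma_A * (1 - (F_sire + F_dam)/2)`; phenotype = breeding value +
#' environmental deviation. The selected line is bred under the configured
#' selection mode, the control line at random within families; matings
#' avoid sibling pairs; sexes alternate within litters so every family can
#' contribute a breeder of each sex. Inbreeding is tracked exactly from the
#' accumulating pedigree. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config].
#' @return An object of class `sim_result`: `line_means` (generation x line
#'   x trait means, SDs and counts), `pedigree` (both lines, [pedigree]
#'   layout), `realized_F` (per generation and line), `phenotypes`
#'   (individual records), `config`, `seed_used`.
#' @export
simulate_breeding <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    lines <- list(selected = sim_line(cfg, cfg$selection_mode),
                  control = sim_line(cfg, "random"))
    nt <- length(cfg$h2)
    trait_names <- paste0("trait", seq_len(nt))

    ped <- do.call(rbind, lapply(names(lines), function(ln) {
      L <- lines[[ln]]
      id <- paste0(ln, "_", seq_along(L$sire))
      data.frame(id = id,
                 sire = ifelse(L$sire == 0, NA, paste0(ln, "_", L$sire)),
                 dam = ifelse(L$dam == 0, NA, paste0(ln, "_", L$dam)),
                 sex = L$sex, generation = L$gen,
                 family = paste0(ln, "_f", L$fam), line = ln,
                 stringsAsFactors = FALSE)
    }))
    rownames(ped) <- NULL
    class(ped) <- c("pedigree", "data.frame")

    phen <- do.call(rbind, lapply(names(lines), function(ln) {
      L <- lines[[ln]]
      df <- data.frame(id = paste0(ln, "_", seq_along(L$sire)), line = ln,
                       generation = L$gen, family = L$fam, sex = L$sex,
                       F = L$Fv, stringsAsFactors = FALSE)
      for (j in seq_len(nt)) df[[trait_names[j]]] <- L$P[, j]
      df
    }))
    rownames(phen) <- NULL

    lm <- do.call(rbind, lapply(names(lines), function(ln) {
      L <- lines[[ln]]
      do.call(rbind, lapply(0:cfg$generations, function(g) {
        i <- which(L$gen == g)
        data.frame(generation = g, line = ln, trait = trait_names,
                   mean = colMeans(L$P[i, , drop = FALSE]),
                   sd = apply(L$P[i, , drop = FALSE], 2, stats::sd),
                   n = length(i), stringsAsFactors = FALSE)
      }))
    }))
    rownames(lm) <- NULL

    rf <- do.call(rbind, lapply(names(lines), function(ln) {
      L <- lines[[ln]]
      data.frame(generation = 0:cfg$generations, line = ln,
                 F = vapply(0:cfg$generations,
                            function(g) mean(L$Fv[L$gen == g]), numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(rf) <- NULL

    structure(list(line_means = lm, pedigree = ped, realized_F = rf,
                   phenotypes = phen, config = cfg,
                   seed_used = cfg$seed),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  G <- x$config$generations
  fF <- x$realized_F[x$realized_F$generation == G, ]
  cat(sprintf(paste0("<sim_result> %d generations, %d families/line, ",
                     "%d traits; final F: selected %.4f, control %.4f\n"),
              G, x$config$n_families, length(x$config$h2),
              fF$F[fF$line == "selected"], fF$F[fF$line == "control"]))
  invisible(x)
}

#' Final-generation trait summaries from a simulation
#'
#' Bridges the simulator to the drift test: summarizes the final
#' generation of each line as mean, SEM and count per trait, in the
#' [read_trait_table()] layout. By default one individual per family is
#' measured (the first-born of each litter), mirroring designs in which
#' each measured animal comes from a distinct family so that the group
#' size is approximately the family count.
#'
#' @param sim A [sim_result].
#' @param individuals_per_family Measured animals per family (default 1).
#' @return Data.frame of trait summaries (one row per trait), with `h2`
#'   and `n_families` filled from the simulation config.
#' @export
generate_trait_table <- function(sim, individuals_per_family = 1) {
  stopifnot(inherits(sim, "sim_result"))
  cfg <- sim$config
  G <- cfg$generations
  trait_names <- paste0("trait", seq_along(cfg$h2))
  ph <- sim$phenotypes[sim$phenotypes$generation == G, ]
  measured <- do.call(rbind, lapply(split(ph, list(ph$line, ph$family)),
                                    function(g) {
    g[seq_len(min(individuals_per_family, nrow(g))), , drop = FALSE]
  }))
  rows <- lapply(seq_along(trait_names), function(j) {
    tn <- trait_names[j]
    s <- lapply(c(ha = "selected", c = "control"), function(ln) {
      x <- measured[measured$line == ln, tn]
      list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
           n = length(x))
    })
    data.frame(trait_name = tn, experiment = "sim",
               ha_mean = s$ha$mean, ha_sem = s$ha$sem, ha_n = s$ha$n,
               c_mean = s$c$mean, c_sem = s$c$sem, c_n = s$c$n,
               h2 = cfg$h2[j], n_families = cfg$n_families,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo calibration of the drift test
#'
#' Repeats the whole experiment in silico: for each replicate, a two-line
#' selection experiment is simulated, the final generation is summarized,
#' the standardized divergence of a non-selected trait is computed, and it
#' is compared against [drift_ci()] built from the replicate's own realized
#' pedigree inbreeding. Under zero genetic correlation with the selected
#' trait the exceedance fraction estimates the test's false-positive rate
#' (nominally `alpha`); with increasing genetic correlation it traces the
#' power curve for detecting a correlated response.
#'
#' @param cfg A [sim_config] with at least two traits.
#' @param n_replicates Replicate experiments per correlation value.
#' @param neutral_trait_index Trait whose divergence is tested (default 2).
#' @param r_g Genetic correlation(s) between the selected and tested trait;
#'   vectorized, default 0 (the null).
#' @param alpha Significance level of the drift interval.
#' @param individuals_per_family Measured animals per family per line.
#' @return Data.frame of class `drift_calibration`: one row per `r_g` with
#'   `exceedance`, its Monte-Carlo standard error `mc_se`, `mean_abs_dy`,
#'   `mean_ci` and `mean_F`.
#' @export
run_calibration <- function(cfg, n_replicates, neutral_trait_index = 2,
                            r_g = 0, alpha = 0.05,
                            individuals_per_family = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  nt <- length(cfg$h2)
  if (nt < 2 || neutral_trait_index > nt ||
      neutral_trait_index == cfg$selected_trait)
    ld_abort("need a tested trait distinct from the selected trait",
             "linedrift_config")
  seeds <- with_seed(cfg$seed,
                     matrix(sample.int(.Machine$integer.max,
                                       n_replicates * length(r_g)),
                            n_replicates, length(r_g)))
  G <- cfg$generations
  rows <- lapply(seq_along(r_g), function(ri) {
    r <- r_g[ri]
    cfg_r <- cfg
    cfg_r$genetic_correlation[cfg$selected_trait, neutral_trait_index] <- r
    cfg_r$genetic_correlation[neutral_trait_index, cfg$selected_trait] <- r
    if (min(eigen(cfg_r$genetic_correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      ld_abort("genetic correlation matrix is not PSD at this r_g",
               "linedrift_config")
    exceeded <- logical(n_replicates)
    dys <- numeric(n_replicates)
    cis <- numeric(n_replicates)
    Fs <- numeric(n_replicates)
    for (i in seq_len(n_replicates)) {
      cfg_r$seed <- seeds[i, ri]
      sim <- simulate_breeding(cfg_r)
      tab <- generate_trait_table(sim, individuals_per_family)
      rec <- as_trait_records(tab)[[neutral_trait_index]]
      d <- standardized_divergence(rec)
      Fhat <- mean(sim$realized_F$F[sim$realized_F$generation == G])
      ci <- drift_ci(cfg$h2[neutral_trait_index], Fhat, cfg$n_families,
                     alpha)
      exceeded[i] <- abs(d) > ci
      dys[i] <- d; cis[i] <- ci; Fs[i] <- Fhat
    }
    p <- mean(exceeded)
    data.frame(r_g = r, n_replicates = n_replicates, exceedance = p,
               mc_se = sqrt(p * (1 - p) / n_replicates),
               mean_abs_dy = mean(abs(dys)), mean_ci = mean(cis),
               mean_F = mean(Fs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("drift_calibration", "data.frame")
  out
}

#' @export
plot.drift_calibration <- function(x, ...) {
  plot(x$r_g, x$exceedance, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "genetic correlation with selected trait",
       ylab = "P(|D_y| exceeds drift CI)", ...)
  graphics::abline(h = 0.05, lty = 2)
  invisible(x)
}

#' Generative parameters for a Go/No-go session
#'
#' Describes an animal's session-level behavior: response probabilities on
#' go and no-go trials, latency scales (truncated-exponential within the
#' cue window), and a Poisson rate of background poking during the precue,
#' reward and intertrial periods.
#'
#' @param p_hit,p_fa Response probabilities on go / no-go trials.
#' @param hit_latency_scale,fa_latency_scale Exponential latency scales (s).
#' @param background_poke_rate Background pokes per second (>= 0).
#' @param n_go,n_nogo Trial counts (defaults 30 + 30).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_hit = 0.8, p_fa = 0.4, hit_latency_scale = 1,
                            fa_latency_scale = 1.5,
                            background_poke_rate = 0.05,
                            n_go = 30, n_nogo = 30, seed = NULL) {
  for (p in c(p_hit, p_fa))
    if (!is.numeric(p) || p < 0 || p > 1)
      ld_abort("probabilities must lie in [0, 1]", "linedrift_config")
  if (background_poke_rate < 0 || hit_latency_scale <= 0 ||
      fa_latency_scale <= 0)
    ld_abort("rates must be non-negative and scales positive",
             "linedrift_config")
  stopifnot(is_count(n_go), is_count(n_nogo))
  structure(list(p_hit = p_hit, p_fa = p_fa,
                 hit_latency_scale = hit_latency_scale,
                 fa_latency_scale = fa_latency_scale,
                 background_poke_rate = background_poke_rate,
                 n_go = as.integer(n_go), n_nogo = as.integer(n_nogo),
                 seed = seed),
            class = "behavior_params")
}

rtrunc_exp <- function(n, scale, upper) {
  u <- runif(n)
  -scale * log(1 - u * (1 - exp(-upper / scale)))
}

#' Simulate a Go/No-go session event log
#'
#' Builds a synthetic session with the canonical trial structure: a
#' variable precue period (house light on), a 5-s cue (go or no-go, in
#' random order), a reward period after correct responses (a hit, or
#' withholding on no-go), and a darkened 10-s intertrial interval.
#' Responses are Bernoulli with the configured probabilities; response
#' latencies are truncated-exponential within the cue window, and the cue
#' ends at the response. Background cue- and center-recess pokes arrive as
#' a Poisson process during the precue, reward and intertrial periods.
#' Deterministic given `params$seed`.
#'
#' @param params A [behavior_params].
#' @param precue_choices Possible precue durations (s); default
#'   `c(3, 4.5, 6)`, drawn uniformly.
#' @param cue_window Cue duration / response window (s); default 5.
#' @param reward_duration,iti_duration Period lengths (s).
#' @param animal_id,day,version Session metadata.
#' @return An [event_log].
#' @export
simulate_gonogo_session <- function(params, precue_choices = c(3, 4.5, 6),
                                    cue_window = 5, reward_duration = 3,
                                    iti_duration = 10, animal_id = "sim",
                                    day = 1, version = "V1") {
  stopifnot(inherits(params, "behavior_params"))
  with_seed(params$seed, {
    types <- sample(c(rep("go", params$n_go), rep("nogo", params$n_nogo)))
    rows <- vector("list", length(types) * 8L)
    ri <- 0L
    add <- function(t, kind, detail = "") {
      ri <<- ri + 1L
      rows[[ri]] <<- list(t = t, kind = kind, detail = detail)
    }
    bg <- function(from, to) {
      len <- to - from
      if (len <= 0 || params$background_poke_rate == 0) return()
      npk <- rpois(1, params$background_poke_rate * len)
      if (npk == 0) return()
      ts <- sort(runif(npk, from, to))
      loc <- ifelse(runif(npk) < 0.7, "cue_recess", "center_recess")
      for (q in seq_len(npk)) add(ts[q], "poke", loc[q])
    }
    t <- 0
    for (ty in types) {
      pre <- if (length(precue_choices) == 1) precue_choices
             else sample(precue_choices, 1)
      add(t, "precue_start")
      bg(t, t + pre)
      t_cue <- t + pre
      add(t_cue, "cue_on", ty)
      p <- if (ty == "go") params$p_hit else params$p_fa
      scale <- if (ty == "go") params$hit_latency_scale
               else params$fa_latency_scale
      respond <- runif(1) < p
      if (respond) {
        lat <- rtrunc_exp(1, scale, cue_window)
        add(t_cue + lat, "poke", "cue_recess")
        t_off <- t_cue + lat
      } else t_off <- t_cue + cue_window
      add(t_off, "cue_off")
      correct <- (ty == "go" && respond) || (ty == "nogo" && !respond)
      if (correct) {
        add(t_off, "reward")
        bg(t_off, t_off + reward_duration)
        t_iti <- t_off + reward_duration
      } else t_iti <- t_off
      add(t_iti, "iti_start")
      bg(t_iti, t_iti + iti_duration)
      t <- t_iti + iti_duration
    }
    add(t, "session_end")
    ev <- do.call(rbind, lapply(rows[seq_len(ri)], function(r)
      data.frame(t = r$t, kind = r$kind, detail = r$detail,
                 stringsAsFactors = FALSE)))
    ev <- ev[order(ev$t, method = "radix"), ]
    event_log(ev, animal_id = animal_id, day = day, phase = "gonogo",
              version = version)
  })
}
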