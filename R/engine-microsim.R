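## Patient-level microsimulation: one categorical draw per patient-cycle
## over {ischemic stroke, hemorrhagic stroke, other intracranial bleed,
## extracranial bleed, death, clinical-AF conversion, remain}, with
## severity resolution, post-bleed treatment pause, first-year post-event
## excess mortality, and cycle-start utility accrual.

init_patient_states <- function(n, arm_noac) {
  list(
    alive = rep(TRUE, n),
    ctx = rep(if (arm_noac) 2L else 1L, n),  # 1 untreated, 2 NOAC, 3 clinical AF
    dis = integer(n),                         # 0 none .. 3 severe
    mse = rep(6L, n),                         # months since disabling event, capped at 6
    exct = integer(n),                        # excess-mortality type: 0/1 ischemic/2 intracranial
    exck = integer(n),                        # excess-mortality clock, cycles remaining
    pausek = integer(n),                      # pause clock, cycles remaining
    acc_q = numeric(n),                       # accrued QALYs (years)
    acc_life = numeric(n),                    # accrued life-years
    acc_sub = numeric(n)                      # years spent in subclinical AF
  )
}

## Apply the consequences of a survived-or-fatal event with known disability
## code (-1 fatal, 0 none, 1 mild, 2 moderate, 3 severe) to patients `ids`.
## Called after the default end-of-cycle clock ticks, so clock assignments
## here are "state at the start of the next cycle".
apply_event_consequences <- function(st, ids, k, dcode, cmod) {
  fatal <- dcode == -1L
  if (any(fatal)) st$alive[ids[fatal]] <- FALSE
  sv <- which(!fatal)
  if (length(sv)) {
    sids <- ids[sv]
    dc <- dcode[sv]
    st$dis[sids] <- pmax(st$dis[sids], dc)
    st$mse[sids[dc > 0L]] <- 0L  # 6-month utility phase restarts at each disabling event
    if (k <= 3L) {  # stroke or intracranial bleed: 12 months excess mortality
      st$exct[sids] <- if (k == 1L) 1L else 2L
      st$exck[sids] <- 12L
    }
    if (k >= 2L) {  # major bleed on NOAC: pause anticoagulation
      on_noac <- sids[st$ctx[sids] == 2L]
      st$pausek[on_noac] <- cmod$pause_cycles
    }
    if (cmod$dynamic_policy) {
      if (k == 1L) {        # ischemic stroke: start (or resume) NOAC
        subcl <- sids[st$ctx[sids] == 1L]
        st$ctx[subcl] <- 2L
      } else if (k <= 3L) { # intracranial bleed: stop NOAC permanently
        on_noac <- sids[st$ctx[sids] == 2L]
        st$ctx[on_noac] <- 1L
        st$pausek[on_noac] <- 0L
      }
    }
  }
  st$n_fatal <- sum(fatal)
  st
}

## One simulation cycle over the full cohort. `t` is the 0-based cycle
## index; `u1`, `u2` are per-patient uniforms (length n) for the outcome
## and severity draws.
ms_step_internal <- function(st, cmod, t, u1, u2) {
  stats <- list(alive_start = 0L, events = integer(4), deaths = 0L,
                caf = 0L, qalys = 0, sev = matrix(0, 4, 4))
  idx <- which(st$alive)
  stats$alive_start <- length(idx)
  if (!length(idx)) return(list(st = st, stats = stats))

  ctx <- st$ctx[idx]
  rc <- 1L + (ctx == 2L & st$pausek[idx] == 0L) + 2L * (ctx == 3L)

  ## utility accrual for the state occupied at cycle start (no half-cycle
  ## correction; patients dying this cycle still accrue this cycle)
  phase <- 1L + (st$mse[idx] >= 6L)
  w <- cmod$base_weight[t + 1L] * cmod$ratio[st$dis[idx] + 1L + 4L * (phase - 1L)]
  st$acc_q[idx] <- st$acc_q[idx] + w / 12
  st$acc_life[idx] <- st$acc_life[idx] + 1 / 12
  sub <- idx[ctx <= 2L]
  st$acc_sub[sub] <- st$acc_sub[sub] + 1 / 12
  stats$qalys <- sum(w) / 12

  pm <- cmod$prob_mat
  q1 <- pm[, 1L][rc]; q2 <- pm[, 2L][rc]; q3 <- pm[, 3L][rc]; q4 <- pm[, 4L][rc]
  pexc <- cmod$excess_monthly[pmax(st$exct[idx], 1L)] * (st$exck[idx] > 0L)
  pd <- 1 - (1 - pm[, 5L][rc]) * (1 - pexc)
  pcaf <- pm[, 6L][rc]
  c1 <- q1; c2 <- c1 + q2; c3 <- c2 + q3; c4 <- c3 + q4
  c5 <- c4 + pd; c6 <- c5 + pcaf
  if (any(c6 > 1 + 1e-12)) {
    abort("Total per-cycle exit probability exceeds 1 in some context.")
  }
  u <- u1[idx]
  outcome <- 1L + (u > c1) + (u > c2) + (u > c3) + (u > c4) + (u > c5) + (u > c6)

  ## default end-of-cycle clock ticks (overridden below for event patients)
  st$mse[idx] <- pmin(st$mse[idx] + 1L, 6L)
  st$exck[idx] <- pmax(st$exck[idx] - 1L, 0L)
  st$exct[idx[st$exck[idx] == 0L]] <- 0L
  st$pausek[idx] <- pmax(st$pausek[idx] - 1L, 0L)

  dsel <- idx[outcome == 5L]
  if (length(dsel)) {
    st$alive[dsel] <- FALSE
    stats$deaths <- stats$deaths + length(dsel)
  }
  csel <- idx[outcome == 6L]
  if (length(csel)) {
    st$ctx[csel] <- 3L
    stats$caf <- length(csel)
  }
  for (k in 1:4) {
    esel <- which(outcome == k)
    if (!length(esel)) next
    ids <- idx[esel]
    col <- ifelse(rc[esel] >= 2L, 2L, 1L)  # treated severities on active NOAC & in clinical AF
    cc <- cmod$sev_cum[k, , ]              # 4 slots x 2 columns
    uu <- u2[ids]
    slot <- 1L + (uu > cc[1L, col]) + (uu > cc[2L, col]) + (uu > cc[3L, col])
    dcode <- cmod$sev_dis[k, ][slot]
    st <- apply_event_consequences(st, ids, k, dcode, cmod)
    stats$events[k] <- length(ids)
    stats$deaths <- stats$deaths + st$n_fatal
    stats$sev[k, ] <- stats$sev[k, ] + tabulate(slot, 4L)
  }
  list(st = st, stats = stats)
}

#' Run the patient-level microsimulation for one decision arm
#'
#' Simulates `n_patients` independent trajectories over the configured
#' horizon of monthly cycles. Results are deterministic given the seed.
#'
#' @param config A `model_config`.
#' @param arm `"without_noac"` or `"with_noac"`: the initial treatment
#'   decision.
#' @param seed Integer seed; defaults to `config$rng_seed`. Pass `NA` to
#'   draw from the session RNG stream without reseeding (used by callers
#'   that manage their own seed, e.g. [run_decision_model()] and
#'   [run_psa()]). Ignored when `uniforms` is supplied.
#' @param n_patients Override for the cohort size (default from config).
#' @param uniforms Optional list with matrices `u1` and `u2`
#'   (`n_patients` x `horizon`) of pre-generated uniforms, used for
#'   common-random-numbers pairing across arms.
#' @param keep_patients If `TRUE`, attach per-patient accrued QALY,
#'   life-year and subclinical-time vectors.
#' @return An `arm_result`.
#' @examples
#' cfg <- base_case_config()
#' cfg$n_patients <- 500L
#' simulate_microsim(cfg, "without_noac", seed = 1)
#' @export
simulate_microsim <- function(config, arm = c("without_noac", "with_noac"),
                              seed = NULL, n_patients = NULL, uniforms = NULL,
                              keep_patients = FALSE) {
  arm <- match.arg(arm)
  config <- as_model_config(config)
  if (!is.null(n_patients)) config$n_patients <- as.integer(n_patients)
  cmod <- compile_model(config)
  run <- function() microsim_loop(cmod, arm, uniforms, keep_patients)
  if (is.null(uniforms)) {
    seed <- seed %||% config$rng_seed
    if (is.null(seed) || is.na(seed)) run() else withr::with_seed(seed, run())
  } else {
    run()
  }
}

microsim_loop <- function(cmod, arm, uniforms, keep_patients) {
  n <- cmod$n_patients
  T <- cmod$horizon
  st <- init_patient_states(n, arm == "with_noac")
  led <- matrix(0, nrow = T, ncol = 9)
  colnames(led) <- c("alive_start", EVENT_TYPES, "deaths", "caf_conversions",
                     "qalys_accrued", "cum_qalys")
  sev_tot <- matrix(0, 4, 4)
  for (t in seq_len(T) - 1L) {
    if (is.null(uniforms)) {
      u1 <- runif(n); u2 <- runif(n)
    } else {
      u1 <- uniforms$u1[, t + 1L]; u2 <- uniforms$u2[, t + 1L]
    }
    res <- ms_step_internal(st, cmod, t, u1, u2)
    st <- res$st
    s <- res$stats
    led[t + 1L, ] <- c(s$alive_start, s$events, s$deaths, s$caf, s$qalys, 0)
    sev_tot <- sev_tot + s$sev
  }
  if (T > 0) led[, "cum_qalys"] <- cumsum(led[, "qalys_accrued"])

  totals <- list(
    ischemic_stroke = sum(led[, "ischemic_stroke"]),
    hemorrhagic_stroke = sum(led[, "hemorrhagic_stroke"]),
    other_intracranial_bleeding = sum(led[, "other_intracranial_bleeding"]),
    extracranial_major_bleeding = sum(led[, "extracranial_major_bleeding"]),
    deaths = sum(led[, "deaths"]),
    caf_conversions = sum(led[, "caf_conversions"]),
    life_years = sum(st$acc_life),
    qalys = sum(st$acc_q),
    mean_subclinical_years = mean(st$acc_sub)
  )
  out <- new_arm_result(
    arm = arm, mode = "microsim", n_patients = n, horizon = T,
    totals = totals,
    severity_counts = severity_counts_tibble(sev_tot),
    trajectories = tibble::as_tibble(cbind(cycle = seq_len(T), as.data.frame(led))),
    final_disability = final_disability_tibble(
      counts = tabulate(st$dis[st$alive] + 1L, 4L), dead = sum(!st$alive)
    ),
    qaly_sd = sd(st$acc_q), life_sd = sd(st$acc_life), subclin_sd = sd(st$acc_sub)
  )
  if (keep_patients) {
    out$patients <- tibble::tibble(qalys = st$acc_q, life_years = st$acc_life,
                                   subclinical_years = st$acc_sub,
                                   alive = st$alive, disability = st$dis)
  }
  out
}

severity_counts_tibble <- function(sev_tot) {
  purrr::map_dfr(seq_along(EVENT_TYPES), function(i) {
    tibble::tibble(
      event_type = EVENT_TYPES[i],
      severity = SEVERITY_CATEGORIES[[EVENT_TYPES[i]]],
      count = sev_tot[i, ]
    )
  })
}

final_disability_tibble <- function(counts, dead) {
  tibble::tibble(
    disability = c(DISABILITY_LEVELS, "dead"),
    count = c(counts, dead)
  )
}
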