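## Deterministic cohort-expectation solver: propagates the exact expected
## state-occupancy distribution over the expanded state space
## (context x disability x months-since-event bucket x excess-mortality
## clock x pause clock), cycle by cycle. Serves as the noise-free oracle for
## the microsimulation and for arm-difference analyses.

COHORT_STATE_BOUND <- 200000L

encode_state_key <- function(ctx, dis, mse, exct, exck, pausek) {
  excid <- ifelse(exct == 0L, 0L, (exct - 1L) * 12L + exck)  # 0..24
  ((((pausek * 25L + excid) * 7L + mse) * 4L + dis) * 3L + (ctx - 1L))
}

decode_state_key <- function(key) {
  ctx <- key %% 3L + 1L; key <- key %/% 3L
  dis <- key %% 4L; key <- key %/% 4L
  mse <- key %% 7L; key <- key %/% 7L
  excid <- key %% 25L; key <- key %/% 25L
  pausek <- key
  exct <- ifelse(excid == 0L, 0L, (excid - 1L) %/% 12L + 1L)
  exck <- ifelse(excid == 0L, 0L, (excid - 1L) %% 12L + 1L)
  list(ctx = ctx, dis = dis, mse = mse, exct = exct, exck = exck, pausek = pausek)
}

#' Solve the exact cohort expectation for one decision arm
#'
#' Propagates expected state-occupancy probabilities deterministically over
#' the full expanded state space, giving the exact expectation that the
#' microsimulation converges to as the number of patients grows. Expected
#' event counts, life-years and QALYs are reported scaled to
#' `config$n_patients`.
#'
#' @param config A `model_config`.
#' @param arm `"without_noac"` or `"with_noac"`.
#' @return An `arm_result` with `mode = "cohort"`.
#' @examples
#' cfg <- base_case_config()
#' solve_cohort_expectation(cfg, "with_noac")
#' @export
solve_cohort_expectation <- function(config, arm = c("without_noac", "with_noac")) {
  arm <- match.arg(arm)
  config <- as_model_config(config)
  cmod <- compile_model(config)
  P <- cmod$pause_cycles
  bound <- 3 * 4 * 7 * 25 * (P + 1)
  if (bound > COHORT_STATE_BOUND) {
    abort(sprintf("Expanded state space (%d states) exceeds the solver bound (%d).",
                  bound, COHORT_STATE_BOUND))
  }
  T <- cmod$horizon
  n <- cmod$n_patients
  pm <- cmod$prob_mat

  st <- list(ctx = if (arm == "with_noac") 2L else 1L, dis = 0L, mse = 6L,
             exct = 0L, exck = 0L, pausek = 0L, mass = 1)

  led <- matrix(0, nrow = T, ncol = 9)
  colnames(led) <- c("alive_start", EVENT_TYPES, "deaths", "caf_conversions",
                     "qalys_accrued", "cum_qalys")
  sev_tot <- matrix(0, 4, 4)
  life <- 0; qalys <- 0; subclin <- 0

  for (t in seq_len(T) - 1L) {
    ctx <- st$ctx; dis <- st$dis; mse <- st$mse
    exct <- st$exct; exck <- st$exck; pausek <- st$pausek; mass <- st$mass

    rc <- ifelse(ctx == 3L, 3L, ifelse(ctx == 2L & pausek == 0L, 2L, 1L))
    col <- ifelse(rc >= 2L, 2L, 1L)
    q1 <- pm[, 1L][rc]; q2 <- pm[, 2L][rc]; q3 <- pm[, 3L][rc]; q4 <- pm[, 4L][rc]
    pexc <- ifelse(exck > 0L, cmod$excess_monthly[pmax(exct, 1L)], 0)
    pd <- 1 - (1 - pm[, 5L][rc]) * (1 - pexc)
    pcaf <- pm[, 6L][rc]
    prem <- 1 - (q1 + q2 + q3 + q4 + pd + pcaf)
    if (any(prem < -1e-12)) {
      abort("Total per-cycle exit probability exceeds 1 in some context.")
    }
    prem <- pmax(prem, 0)

    ## cycle-start accrual
    phase <- ifelse(mse < 6L, 1L, 2L)
    w <- cmod$base_weight[t + 1L] * cmod$ratio[cbind(dis + 1L, phase)]
    qalys_t <- sum(mass * w) / 12
    life <- life + sum(mass) / 12
    qalys <- qalys + qalys_t
    subclin <- subclin + sum(mass[ctx <= 2L]) / 12

    ## default end-of-cycle clock ticks
    mse2 <- pmin(mse + 1L, 6L)
    exck2 <- pmax(exck - 1L, 0L)
    exct2 <- ifelse(exck2 > 0L, exct, 0L)
    pk2 <- pmax(pausek - 1L, 0L)

    deaths_t <- sum(mass * pd)
    caf_t <- sum(mass * pcaf)
    events_t <- numeric(4)

    ch <- list()
    add_child <- function(ctx, dis, mse, exct, exck, pausek, m) {
      keep <- m > 0
      if (!any(keep)) return(invisible(NULL))
      ch[[length(ch) + 1L]] <<- list(
        key = encode_state_key(ctx[keep], dis[keep], mse[keep], exct[keep],
                               exck[keep], pausek[keep]),
        mass = m[keep]
      )
      invisible(NULL)
    }
    rep_like <- function(x) rep_len(as.integer(x), length(mass))

    add_child(ctx, dis, mse2, exct2, exck2, pk2, mass * prem)
    add_child(rep_like(3L), dis, mse2, exct2, exck2, pk2, mass * pcaf)

    for (k in 1:4) {
      qk <- switch(k, q1, q2, q3, q4)
      if (all(qk == 0)) next
      events_t[k] <- sum(mass * qk)
      for (s in 1:4) {
        spv <- cmod$sev_prob[k, s, ][col]
        m <- mass * qk * spv
        if (all(m == 0)) next
        dcode <- cmod$sev_dis[k, s]
        sev_tot[k, s] <- sev_tot[k, s] + sum(m)
        if (dcode == -1L) {
          deaths_t <- deaths_t + sum(m)
          next
        }
        dis_n <- pmax(dis, dcode)
        mse_n <- if (dcode > 0L) rep_like(0L) else mse2
        if (k <= 3L) {
          exct_n <- rep_like(if (k == 1L) 1L else 2L)
          exck_n <- rep_like(12L)
        } else {
          exct_n <- exct2; exck_n <- exck2
        }
        pk_n <- if (k >= 2L) ifelse(ctx == 2L, P, pk2) else pk2
        ctx_n <- ctx
        if (cmod$dynamic_policy) {
          if (k == 1L) {
            ctx_n <- ifelse(ctx == 1L, 2L, ctx)
          } else if (k <= 3L) {
            stopped <- ctx == 2L
            ctx_n <- ifelse(stopped, 1L, ctx)
            pk_n <- ifelse(stopped, 0L, pk_n)
          }
        }
        add_child(ctx_n, dis_n, mse_n, exct_n, exck_n, as.integer(pk_n), m)
      }
    }

    key <- unlist(lapply(ch, `[[`, "key"))
    m <- unlist(lapply(ch, `[[`, "mass"))
    agg <- rowsum(m, key)
    keys <- as.integer(rownames(agg))
    dec <- decode_state_key(keys)
    st <- c(dec, list(mass = as.numeric(agg)))

    led[t + 1L, ] <- c(sum(mass), events_t, deaths_t, caf_t, qalys_t, 0)
  }
  if (T > 0) led[, "cum_qalys"] <- cumsum(led[, "qalys_accrued"])

  alive_end <- sum(st$mass)
  fin_dis <- vapply(0:3, function(d) sum(st$mass[st$dis == d]), numeric(1))
  totals <- list(
    ischemic_stroke = sum(led[, "ischemic_stroke"]) * n,
    hemorrhagic_stroke = sum(led[, "hemorrhagic_stroke"]) * n,
    other_intracranial_bleeding = sum(led[, "other_intracranial_bleeding"]) * n,
    extracranial_major_bleeding = sum(led[, "extracranial_major_bleeding"]) * n,
    deaths = sum(led[, "deaths"]) * n,
    caf_conversions = sum(led[, "caf_conversions"]) * n,
    life_years = life * n,
    qalys = qalys * n,
    mean_subclinical_years = subclin
  )
  led[, c("alive_start", EVENT_TYPES, "deaths", "caf_conversions",
          "qalys_accrued", "cum_qalys")] <-
    led[, c("alive_start", EVENT_TYPES, "deaths", "caf_conversions",
            "qalys_accrued", "cum_qalys")] * n
  new_arm_result(
    arm = arm, mode = "cohort", n_patients = n, horizon = T,
    totals = totals,
    severity_counts = severity_counts_tibble(sev_tot * n),
    trajectories = tibble::as_tibble(cbind(cycle = seq_len(T), as.data.frame(led))),
    final_disability = final_disability_tibble(counts = fin_dis * n,
                                               dead = (1 - alive_end) * n)
  )
}
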