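#' Replica-exchange schedule
#'
#' Mirrors the cycle structure of constant-pH MD: each cycle performs a
#' protonation update, a short relaxation advance of the conformational
#' propagator under the new protonation, and a production advance; exchange
#' attempts between adjacent pH values happen every `exchange_every` cycles,
#' i.e. after the production advance, which places them half-way between
#' successive protonation updates when `exchange_every = 1` (the analogue of
#' equal protonation and exchange periods attempted out of phase).
#'
#' @param n_cycles cycles per replicate.
#' @param n_replicates independent replicates.
#' @param tau_prot propagator steps of the production advance per cycle.
#' @param tau_rlx propagator steps of the relaxation advance after a
#'   protonation update.
#' @param exchange_every exchange period in cycles.
#' @param burn_in_fraction fraction of initial cycles discarded from the
#'   emitted records (default 0.5, the analogue of discarding the first half
#'   of each replicate).
#' @param titration_cycles MC cycles per protonation update.
#' @return `phre_schedule` object.
#' @export
phre_schedule <- function(n_cycles, n_replicates = 1L, tau_prot = 20L,
                          tau_rlx = 2L, exchange_every = 1L,
                          burn_in_fraction = 0.5, titration_cycles = 5L) {
  stopifnot(n_cycles >= 1, n_replicates >= 1, tau_prot >= 1, tau_rlx >= 0,
            exchange_every >= 1, burn_in_fraction >= 0,
            burn_in_fraction < 1, titration_cycles >= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 n_replicates = as.integer(n_replicates),
                 tau_prot = as.integer(tau_prot),
                 tau_rlx = as.integer(tau_rlx),
                 exchange_every = as.integer(exchange_every),
                 burn_in_fraction = burn_in_fraction,
                 titration_cycles = as.integer(titration_cycles)),
            class = "phre_schedule")
}

#' pH ladder for replica exchange
#'
#' In nongradient mode each replica holds one solution pH from the ladder.
#' In gradient mode the ladder values are exterior pH values (`pH_out`) and
#' the interior bath is set either to a fixed `ph_in` (only `pH_out`
#' exchanges between replicas, the fixed-interior setup) or to
#' `pH_out + delta_ph` (a constant-offset gradient that follows the
#' exchanging label).
#'
#' @param values strictly increasing pH values, >= 2 of them.
#' @param gradient logical; gradient mode.
#' @param ph_in fixed interior pH (gradient mode), default 7.2.
#' @param delta_ph alternative gradient parameterisation,
#'   `pH_in = pH_out + delta_ph`; supply at most one of `ph_in`/`delta_ph`.
#' @return `ph_ladder` object.
#' @export
ph_ladder <- function(values = c(4, 5, 6, 7), gradient = FALSE,
                      ph_in = if (is.null(delta_ph)) 7.2 else NULL,
                      delta_ph = NULL) {
  stopifnot(length(values) >= 2, all(diff(values) > 0))
  if (gradient && !is.null(ph_in) && !is.null(delta_ph))
    stop("supply only one of ph_in / delta_ph")
  structure(list(values = as.numeric(values), gradient = isTRUE(gradient),
                 ph_in = ph_in, delta_ph = delta_ph),
            class = "ph_ladder")
}

# gradient_spec for a replica holding ladder value p
replica_grad <- function(ladder, p) {
  if (!ladder$gradient) return(gradient_spec(p, p))
  if (!is.null(ladder$delta_ph)) gradient_spec(p + ladder$delta_ph, p)
  else gradient_spec(ladder$ph_in, p)
}

# which sites' bath pH follows the exchanging replica label: in the
# fixed-interior setup only out-bath sites; otherwise every site (the
# interior terms then do not cancel from the swap ratio).
exchanging_sites <- function(ladder, baths) {
  if (ladder$gradient && is.null(ladder$delta_ph))
    names(baths)[unclass(baths) == "out"]
  else names(baths)
}

#' Replica-exchange acceptance probability
#'
#' Metropolis probability of swapping the states held at two exchanging pH
#' values: `min(1, 10^((pH_m - pH_l) * (N_i - N_j)))`, where `N_i` is the
#' bound-proton count of the state currently at `pH_m` and `N_j` that of the
#' state at `pH_l`. This is the semi-grand weight ratio of the swapped versus
#' unswapped pair. Under a fixed-interior gradient the interior terms are
#' identical on both sides of the swap and cancel, so `N` must count only
#' protons of sites coupled to the exchanging (exterior) bath.
#'
#' @param pH_m,pH_l exchanging pH values.
#' @param N_i,N_j bound-proton counts (over exchanging-bath sites) of the
#'   states currently at `pH_m` and `pH_l`.
#' @return probability in \[0, 1\].
#' @examples
#' exchange_probability(6, 7, 3, 1)  # 0.01
#' @export
exchange_probability <- function(pH_m, pH_l, N_i, N_j) {
  stopifnot(N_i >= 0, N_j >= 0)
  min(1, 10^((pH_m - pH_l) * (N_i - N_j)))
}

#' Attempt adjacent-pair exchanges on one parity
#'
#' Replicas are ordered by ladder position; adjacent pairs starting at odd
#' (parity `"even"`... pair 1-2, 3-4, ...) or even positions (pair 2-3,
#' 4-5, ...) are attempted, alternating parity between successive exchange
#' events so that every adjacent pair is attempted every other event. On
#' acceptance the pH labels are swapped between the two replicas (equivalent
#' to swapping conformation and protonation between the pH values).
#'
#' @param ph numeric vector of pH values currently held, ordered by ladder
#'   position.
#' @param N integer vector of exchanging-bath proton counts, same order.
#' @param parity `"even"` (pairs 1-2, 3-4, ...) or `"odd"` (2-3, 4-5, ...).
#' @return list with `ph` (possibly swapped) and `log`, a data.frame of the
#'   attempts (`lo`, `hi`, `ph_lo`, `ph_hi`, `p`, `accepted`).
#' @export
attempt_exchanges <- function(ph, N, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  stopifnot(length(ph) == length(N), length(ph) >= 2)
  start <- if (parity == "even") 1L else 2L
  lo <- if (start <= length(ph) - 1L)
    seq(start, length(ph) - 1L, by = 2L) else integer(0)
  logd <- data.frame(lo = integer(0), hi = integer(0), ph_lo = numeric(0),
                     ph_hi = numeric(0), p = numeric(0),
                     accepted = logical(0))
  for (a in lo) {
    b <- a + 1L
    # state i currently at the higher pH (pH_m := ph[b]), j at ph[a]
    p <- exchange_probability(ph[b], ph[a], N[b], N[a])
    acc <- runif(1) < p
    if (acc) ph[c(a, b)] <- ph[c(b, a)]
    logd <- rbind(logd, data.frame(lo = a, hi = b, ph_lo = ph[a],
                                   ph_hi = ph[b], p = p, accepted = acc))
  }
  list(ph = ph, log = logd)
}

#' Conformational propagator contract
#'
#' A propagator advances the conformational degrees of freedom at fixed
#' protonation. It must be Markovian and, for a fixed protonation state,
#' preserve its declared conformational distribution. `advance(conf,
#' protonation, n_steps)` returns the new conformation and uses R's global
#' RNG; `protonation` is a named integer vector of bound protons per site.
#' `summarize(conf)` returns a numeric scalar stored in the records (for the
#' membrane surrogate, the insertion coordinate z); `init()` returns a
#' starting conformation.
#'
#' @param advance function(conf, protonation, n_steps) -> conf.
#' @param summarize function(conf) -> numeric scalar.
#' @param init function() -> conf.
#' @return `propagator` object.
#' @export
propagator <- function(advance, summarize = function(conf) as.numeric(conf)[1],
                       init = function() 0) {
  stopifnot(is.function(advance), is.function(summarize), is.function(init))
  structure(list(advance = advance, summarize = summarize, init = init),
            class = "propagator")
}

#' Propagator that never moves (fixed conformation)
#' @param conf the conformation to hold.
#' @return a [propagator()].
#' @export
frozen_propagator <- function(conf = 0) {
  propagator(advance = function(c, m, n) c,
             summarize = function(c) as.numeric(c)[1],
             init = function() conf)
}

#' Run pH replica exchange
#'
#' Couples the protonation Monte Carlo sampler with a conformational
#' propagator across a ladder of pH replicas. Per cycle and replica: (1) the
#' protonation microstate is updated by `titration_cycles` MC cycles at the
#' replica's bath pH values (with conformation-dependent intrinsic terms when
#' the system provides `g_fun`); (2) the propagator advances `tau_rlx`
#' relaxation steps and then `tau_prot` production steps under the new
#' protonation. Exchange attempts between adjacent ladder values follow
#' [attempt_exchanges()] with alternating parity. Records are emitted after
#' burn-in, one per replica and cycle. Fully reproducible given `seeds`.
#'
#' @param system a [titration_system()]; optionally carrying attribute
#'   `g_fun`, `function(conf) -> flat intrinsic terms` (see
#'   [make_surrogate_system()]).
#' @param prop a [propagator()].
#' @param ladder a [ph_ladder()].
#' @param baths a [bath_assignment()].
#' @param schedule a [phre_schedule()].
#' @param seeds integer vector, one base seed per replicate.
#' @param pair_threshold coupling threshold for pair moves.
#' @return data.frame of class `phre_records`: `replicate`, `cycle`, `ph`
#'   (the exchanging pH: solution pH, or `pH_out` in gradient mode), `z`
#'   (conformation summary), one logical `prot_<site>` column per site, `N`
#'   (total bound protons) and `state` (tautomer labels, `|`-separated).
#'   Attribute `exchange_log` collects all attempts.
#' @export
run_phre <- function(system, prop, ladder, baths, schedule, seeds,
                     pair_threshold = 2.0) {
  stopifnot(inherits(prop, "propagator"), inherits(ladder, "ph_ladder"),
            inherits(schedule, "phre_schedule"),
            length(seeds) == schedule$n_replicates)
  cs <- compile_system(system)
  cp <- coupled_pairs_idx(cs, pair_threshold)
  g_fun <- attr(system, "g_fun")
  nrep <- length(ladder$values)
  b <- unclass(baths)[cs$site_ids]
  exch_sites <- exchanging_sites(ladder, baths)
  exch_idx <- match(exch_sites, cs$site_ids)
  burn <- floor(schedule$burn_in_fraction * schedule$n_cycles)
  rec_list <- vector("list", schedule$n_replicates)
  log_list <- list()

  keep <- schedule$n_cycles - burn
  ioff <- as.integer(cs$off); int <- as.integer(cs$nt)
  inp <- as.integer(cs$np); iptr <- as.integer(cs$adj_ptr)
  iadj <- as.integer(cs$adj_j); iwoff <- as.integer(cs$adj_woff)

  for (r in seq_len(schedule$n_replicates)) {
    set.seed(seeds[r])
    conf <- replicate(nrep, prop$init(), simplify = FALSE)
    state <- replicate(nrep,
                       vapply(cs$nt, function(m) sample.int(m, 1L) - 1L,
                              integer(1)),
                       simplify = FALSE)
    ph_held <- ladder$values            # ph_held[k]: pH of replica k
    parity <- "even"
    nr <- keep * nrep
    m_rep <- rep.int(r, nr); m_cyc <- integer(nr); m_ph <- numeric(nr)
    m_z <- numeric(nr); m_N <- numeric(nr); m_state <- character(nr)
    m_prot <- matrix(0, nr, cs$n)
    row <- 0L
    for (cyc in seq_len(schedule$n_cycles)) {
      for (k in seq_len(nrep)) {
        grad <- replica_grad(ladder, ph_held[k])
        ph_site <- ifelse(b == "in", grad$pH_in, grad$pH_out)
        g <- if (is.null(g_fun)) cs$g else g_fun(conf[[k]])
        res <- .mc_run_cpp(ioff, int, g, inp, ph_site, iptr, iadj, iwoff,
                           cs$wdata, cp$i, cp$j, as.integer(state[[k]]),
                           schedule$titration_cycles, FALSE, 1L)
        state[[k]] <- res$state
        npv <- inp[ioff + state[[k]] + 1L]
        names(npv) <- cs$site_ids
        if (schedule$tau_rlx > 0)
          conf[[k]] <- prop$advance(conf[[k]], npv, schedule$tau_rlx)
        conf[[k]] <- prop$advance(conf[[k]], npv, schedule$tau_prot)
      }
      if (cyc %% schedule$exchange_every == 0L) {
        ord <- order(match(ph_held, ladder$values))
        N <- vapply(ord, function(k)
          sum(inp[ioff[exch_idx] + state[[k]][exch_idx] + 1L]),
          numeric(1))
        ex <- attempt_exchanges(ph_held[ord], N, parity)
        ph_held[ord] <- ex$ph
        if (nrow(ex$log)) {
          ex$log$replicate <- r
          ex$log$cycle <- cyc
          log_list[[length(log_list) + 1L]] <- ex$log
        }
        parity <- if (parity == "even") "odd" else "even"
      }
      if (cyc > burn) {
        for (k in seq_len(nrep)) {
          row <- row + 1L
          m_cyc[row] <- cyc; m_ph[row] <- ph_held[k]
          m_z[row] <- prop$summarize(conf[[k]])
          npv <- inp[ioff + state[[k]] + 1L]
          m_prot[row, ] <- as.numeric(npv > 0L)
          m_N[row] <- sum(npv)
          m_state[row] <- paste(vapply(seq_len(cs$n), function(i)
            cs$tlab[[i]][state[[k]][i] + 1L], character(1)),
            collapse = "|")
        }
      }
    }
    df <- data.frame(replicate = m_rep, cycle = m_cyc, ph = m_ph, z = m_z)
    pm <- as.data.frame(m_prot)
    names(pm) <- paste0("prot_", cs$site_ids)
    df <- cbind(df, pm)
    df$N <- m_N; df$state <- m_state
    rec_list[[r]] <- df
  }
  rec <- do.call(rbind, rec_list)
  rec <- rec[order(rec$replicate, rec$ph, rec$cycle), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, class = c("phre_records", "data.frame"),
            exchange_log = do.call(rbind, log_list),
            ladder = ladder, site_ids = cs$site_ids)
}

#' @export
as.data.frame.phre_records <- function(x, ...) {
  attr(x, "exchange_log") <- NULL
  attr(x, "ladder") <- NULL
  attr(x, "site_ids") <- NULL
  class(x) <- "data.frame"
  x
}

#' Exchange attempt log of a pHRE run
#' @param records a `phre_records` object from [run_phre()].
#' @return data.frame of exchange attempts.
#' @export
exchange_log <- function(records) attr(records, "exchange_log")

#' Observations table for insertion profiling
#'
#' Flattens pHRE records into the observation format consumed by the
#' profiling module, using the conformation summary `z` as the insertion
#' coordinate of the tagged group.
#'
#' @param records `phre_records` from [run_phre()].
#' @param site site to profile (default the first).
#' @return data.frame `replicate`, `ph`, `frame`, `insertion`, `protonated`.
#' @export
phre_observations <- function(records, site = attr(records, "site_ids")[1]) {
  col <- paste0("prot_", site)
  stopifnot(col %in% names(records))
  data.frame(replicate = records$replicate, ph = records$ph,
             frame = records$cycle, insertion = records$z,
             protonated = as.integer(records[[col]] > 0))
}
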