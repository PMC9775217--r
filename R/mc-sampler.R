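#' Monte Carlo sampler settings
#'
#' @param n_cycles number of MC cycles; one cycle proposes a tautomer change
#'   at every site (shuffled order) and then a joint re-draw for every
#'   strongly coupled pair. Default 1e5.
#' @param pair_threshold coupling strength (pK units) above which a site pair
#'   receives dedicated pair moves; the comparison is strict (`> threshold`).
#'   Default 2.
#' @param seed optional integer seed; when given, [mc_titrate()] seeds R's
#'   RNG (restoring the caller's RNG state afterwards).
#' @return `mc_settings` object.
#' @export
mc_settings <- function(n_cycles = 100000L, pair_threshold = 2.0,
                        seed = NULL) {
  stopifnot(n_cycles >= 1, pair_threshold > 0)
  structure(list(n_cycles = as.integer(n_cycles),
                 pair_threshold = pair_threshold, seed = seed),
            class = "mc_settings")
}

# run fn() under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Site pairs treated with dedicated pair moves
#'
#' A pair of sites is considered strongly coupled when the largest absolute
#' pairwise interaction over all tautomer combinations exceeds the threshold
#' (strictly). Strongly coupled pairs receive joint two-site Monte Carlo
#' moves in addition to the single-site sweep, which is essential for mixing
#' when single-site moves are energetically blocked.
#'
#' @param system a [titration_system()].
#' @param threshold pK units, default 2.
#' @return data.frame with columns `site_i`, `site_j`, `max_abs_W`.
#' @export
coupled_pairs <- function(system, threshold = 2.0) {
  stopifnot(threshold > 0)
  cs <- compile_system(system)
  up <- cs$upairs
  keep <- up[, 3] > threshold
  data.frame(site_i = cs$site_ids[up[keep, 1]],
             site_j = cs$site_ids[up[keep, 2]],
             max_abs_W = up[keep, 3], row.names = NULL)
}

# internal: coupled pairs as 0-based index pairs against a compiled system
coupled_pairs_idx <- function(cs, threshold) {
  up <- cs$upairs
  keep <- up[, 3] > threshold
  list(i = as.integer(up[keep, 1] - 1L), j = as.integer(up[keep, 2] - 1L))
}

kernel_args <- function(cs, ph, cp) {
  list(off = as.integer(cs$off), nt = as.integer(cs$nt), g = cs$g,
       np = as.integer(cs$np), ph = ph, adj_ptr = as.integer(cs$adj_ptr),
       adj_j = as.integer(cs$adj_j), adj_woff = as.integer(cs$adj_woff),
       wdata = cs$wdata, cp_i = cp$i, cp_j = cp$j)
}

#' Advance a protonation microstate by Monte Carlo cycles
#'
#' One cycle proposes, for each site in a freshly shuffled order, a uniformly
#' random alternative tautomer accepted with the Metropolis probability
#' `min(1, 10^(-dG))`, followed by a joint uniform re-draw of both members of
#' every strongly coupled pair under the same rule. Uses R's global RNG.
#'
#' @param x starting [microstate()].
#' @param system,baths,grad system, bath assignment and [gradient_spec()].
#' @param n_cycles number of cycles to advance (default 1).
#' @param pair_threshold coupling threshold for pair moves.
#' @return the updated [microstate()].
#' @export
mc_cycle <- function(x, system, baths, grad, n_cycles = 1L,
                     pair_threshold = 2.0) {
  if (!inherits(x, "microstate")) x <- microstate(x, system)
  cs <- compile_system(system)
  ph <- bath_ph(system, baths, grad)
  cp <- coupled_pairs_idx(cs, pair_threshold)
  a <- kernel_args(cs, ph, cp)
  res <- do.call(.mc_run_cpp, c(a, list(
    state0 = as.integer(state_to_idx(x, cs) - 1L),
    n_cycles = as.integer(n_cycles), record = FALSE, n_batches = 1L)))
  idx_to_state(res$state + 1L, cs, system)
}

#' Monte Carlo titration of a system at fixed conformation
#'
#' Runs `n_cycles` Metropolis cycles from a uniformly random initial
#' microstate and averages the per-site protonation indicator and bound
#' proton counts over every post-cycle state (no internal burn-in; discard at
#' the pipeline level if needed). Standard errors are batch-means estimates
#' over 20 contiguous batches.
#'
#' @param system a [titration_system()].
#' @param baths a [bath_assignment()].
#' @param grad a [gradient_spec()]; `gradient_spec(pH, pH)` for one bath.
#' @param settings an [mc_settings()].
#' @return `titration_result`: list with `mean_protonation` (named, fraction
#'   of cycles the site holds >= 1 proton), `mean_np` (mean bound protons),
#'   `mean_N`, `se` (batch-means standard errors of `mean_protonation`),
#'   `final_state`, `n_cycles_run`.
#' @examples
#' sys <- single_site_system(pK_int = 6)
#' b <- bath_assignment(c(A = "out"))
#' mc_titrate(sys, b, gradient_spec(7, 7), mc_settings(2000, seed = 1))
#' @export
mc_titrate <- function(system, baths, grad, settings = mc_settings()) {
  stopifnot(inherits(settings, "mc_settings"),
            length(system$site_ids) >= 1)
  cs <- compile_system(system)
  ph <- bath_ph(system, baths, grad)
  cp <- coupled_pairs_idx(cs, settings$pair_threshold)
  a <- kernel_args(cs, ph, cp)
  with_seed(settings$seed, function() {
    init <- vapply(cs$nt, function(m) sample.int(m, 1L), integer(1))
    res <- do.call(.mc_run_cpp, c(a, list(
      state0 = as.integer(init - 1L),
      n_cycles = settings$n_cycles, record = TRUE, n_batches = 20L)))
    nb <- nrow(res$batch)
    se <- apply(res$batch, 2, stats::sd) / sqrt(nb)
    structure(list(
      mean_protonation = setNames(res$mean_ind, cs$site_ids),
      mean_np = setNames(res$mean_np, cs$site_ids),
      mean_N = sum(res$mean_np),
      se = setNames(se, cs$site_ids),
      final_state = idx_to_state(res$state + 1L, cs, system),
      n_cycles_run = settings$n_cycles, method = "mc"),
      class = "titration_result")
  })
}

#' Exact titration averages by microstate enumeration
#'
#' Sums the semi-grand weights `10^(-G(x))` over every microstate of the
#' system (guarded to at most 1e6 states) with a numerically stable
#' log-sum reduction, giving exact Boltzmann averages. Serves as the
#' oracle the Monte Carlo sampler is validated against.
#'
#' @inheritParams mc_titrate
#' @return `titration_result` with `method = "exact"` (`se` is zero).
#' @export
enumerate_exact <- function(system, baths, grad) {
  cs <- compile_system(system)
  nstates <- prod(cs$nt)
  if (nstates > 1e6)
    stop("state space too large for enumeration: ", nstates, " microstates")
  ph <- bath_ph(system, baths, grad)
  grid <- as.matrix(expand.grid(lapply(cs$nt, seq_len)))
  G <- numeric(nrow(grid))
  for (k in seq_len(cs$n)) {
    flat <- cs$off[k] + grid[, k]       # 1-based into g/np
    G <- G + cs$g[flat] + cs$np[flat] * ph[k]
  }
  up <- cs$upairs
  if (nrow(up)) {
    # rebuild per-pair W matrices from the adjacency (first direction only)
    seen <- character(0)
    for (e in seq_along(cs$adj_j)) {
      i <- findInterval(e - 1L, cs$adj_ptr, left.open = FALSE)
      j <- cs$adj_j[e] + 1L
      key <- paste(min(i, j), max(i, j))
      if (key %in% seen) next
      seen <- c(seen, key)
      nti <- cs$nt[i]; ntj <- cs$nt[j]
      W <- matrix(cs$wdata[cs$adj_woff[e] + seq_len(nti * ntj)],
                  nrow = nti, byrow = TRUE)
      G <- G + W[cbind(grid[, i], grid[, j])]
    }
  }
  lw <- -G * log(10)
  lw <- lw - max(lw)
  w <- exp(lw); w <- w / sum(w)
  ind <- matrix(0, nrow(grid), cs$n)
  npm <- matrix(0, nrow(grid), cs$n)
  for (k in seq_len(cs$n)) {
    flat <- cs$off[k] + grid[, k]
    ind[, k] <- as.numeric(cs$np[flat] > 0L)
    npm[, k] <- cs$np[flat]
  }
  mean_ind <- as.numeric(crossprod(w, ind))
  mean_np <- as.numeric(crossprod(w, npm))
  structure(list(
    mean_protonation = setNames(mean_ind, cs$site_ids),
    mean_np = setNames(mean_np, cs$site_ids),
    mean_N = sum(mean_np),
    se = setNames(rep(0, cs$n), cs$site_ids),
    final_state = NULL, n_cycles_run = 0L, method = "exact"),
    class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat("titration_result (", x$method, "): mean_N = ",
      format(x$mean_N, digits = 4), "\n", sep = "")
  df <- data.frame(site = names(x$mean_protonation),
                   mean_protonation = round(x$mean_protonation, 4),
                   se = round(x$se, 4), row.names = NULL)
  print(df)
  invisible(x)
}
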