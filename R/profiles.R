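#' Bin protonation observations along the insertion coordinate
#'
#' Observations are (replicate, pH, frame, insertion, protonated) tuples.
#' Burn-in is removed per (replicate, pH) stream by frame order, then each
#' observation is assigned to a half-open insertion window `[k*w, (k+1)*w)`
#' on a grid anchored at 0 and protonated/deprotonated conformations are
#' tallied per (bin, pH, replicate) cell.
#'
#' @param obs data.frame with columns `replicate`, `ph`, `frame`,
#'   `insertion`, `protonated` (0/1); extra scalar columns are carried
#'   through for [property_profile()].
#' @param bin_width window width in Angstrom (default 1).
#' @param burn_in_fraction fraction of initial frames discarded per
#'   (replicate, pH) stream (default 0.5).
#' @return data.frame of class `profile_bins`: `bin_low`, `bin_high`, `ph`,
#'   `replicate`, `n_prot`, `n_deprot`, `n`, `mean_prot`. Attribute `obs`
#'   keeps the post-burn-in observations.
#' @export
bin_observations <- function(obs, bin_width = 1, burn_in_fraction = 0.5) {
  stopifnot(nrow(obs) > 0,
            all(c("replicate", "ph", "frame", "insertion", "protonated")
                %in% names(obs)),
            bin_width > 0, burn_in_fraction >= 0, burn_in_fraction < 1)
  if (any(!is.finite(obs$insertion))) stop("non-finite insertion values")
  keep <- unlist(lapply(split(seq_len(nrow(obs)),
                              interaction(obs$replicate, obs$ph,
                                          drop = TRUE)),
                        function(ix) {
    ix <- ix[order(obs$frame[ix])]
    drop <- floor(burn_in_fraction * length(ix))
    ix[seq_along(ix) > drop]
  }), use.names = FALSE)
  o <- obs[sort(keep), , drop = FALSE]
  o$bin <- floor(o$insertion / bin_width)
  ag <- aggregate(cbind(n_prot = o$protonated,
                        n_deprot = 1 - o$protonated),
                  by = list(bin = o$bin, ph = o$ph,
                            replicate = o$replicate),
                  FUN = sum)
  out <- data.frame(bin_low = ag$bin * bin_width,
                    bin_high = (ag$bin + 1) * bin_width,
                    ph = ag$ph, replicate = ag$replicate,
                    n_prot = ag$n_prot, n_deprot = ag$n_deprot)
  out$n <- out$n_prot + out$n_deprot
  out$mean_prot <- out$n_prot / out$n
  out <- out[order(out$bin_low, out$ph, out$replicate), ]
  rownames(out) <- NULL
  structure(out, class = c("profile_bins", "data.frame"),
            bin_width = bin_width, obs = o)
}

#' Apply the profile acceptance criteria
#'
#' Three criteria gate the insertion-binned fits: (1) each (bin, pH,
#' replicate) cell must hold at least `min_conf` conformations of each
#' protonation state (both protonated and deprotonated); (2) at least
#' `min_replicates` surviving replicates are required for a pH to count and
#' at least `min_ph` surviving pH values for a pKa fit; (3) pooled average
#' protonations over surviving pH values, taken in ascending pH, must not
#' rise by more than `mono_tol` above the previous (lower-pH) average.
#' Protonation profiles require only criteria 1-2; pKa fits require all
#' three.
#'
#' @param bins a `profile_bins` from [bin_observations()].
#' @param min_conf minimum conformations of each protonated state per cell
#'   (default 10).
#' @param min_replicates minimum contributing replicates per pH (default 3).
#' @param min_ph minimum surviving pH values for a fit (default 2).
#' @param mono_tol allowed upward fluctuation of the average protonation
#'   with increasing pH (default 0.05).
#' @return list of class `bin_criteria`: `cells` (the bins with an `ok1`
#'   flag), `per_ph` (pooled averages per bin and surviving pH, with `ok2`),
#'   `per_bin` (per-bin flags `fit_ok` = criteria 1-3, `profile_ok` =
#'   criteria 1-2, plus `n_ph`, `n_replicates`).
#' @export
apply_bin_criteria <- function(bins, min_conf = 10, min_replicates = 3,
                               min_ph = 2, mono_tol = 0.05) {
  stopifnot(inherits(bins, "profile_bins"))
  cells <- as.data.frame(bins)
  cells$ok1 <- cells$n_prot >= min_conf & cells$n_deprot >= min_conf
  ok <- cells[cells$ok1, , drop = FALSE]
  per_ph <- if (nrow(ok)) {
    ag <- aggregate(cbind(n_prot = ok$n_prot, n = ok$n,
                          n_rep = rep(1L, nrow(ok))),
                    by = list(bin_low = ok$bin_low, ph = ok$ph), FUN = sum)
    data.frame(bin_low = ag$bin_low, ph = ag$ph,
               mean_prot = ag$n_prot / ag$n, n = ag$n,
               n_replicates = ag$n_rep,
               ok2 = ag$n_rep >= min_replicates)
  } else {
    data.frame(bin_low = numeric(0), ph = numeric(0),
               mean_prot = numeric(0), n = numeric(0),
               n_replicates = integer(0), ok2 = logical(0))
  }
  all_bins <- sort(unique(cells$bin_low))
  per_bin <- do.call(rbind, lapply(all_bins, function(bl) {
    d <- per_ph[per_ph$bin_low == bl & per_ph$ok2, , drop = FALSE]
    d <- d[order(d$ph), , drop = FALSE]
    n_ph <- nrow(d)
    mono <- if (n_ph >= 2) all(diff(d$mean_prot) <= mono_tol) else TRUE
    data.frame(bin_low = bl, n_ph = n_ph,
               n_replicates = if (n_ph) max(d$n_replicates) else 0L,
               mono_ok = mono,
               profile_ok = n_ph >= 1,
               fit_ok = n_ph >= min_ph && mono)
  }))
  structure(list(cells = cells, per_ph = per_ph, per_bin = per_bin,
                 min_conf = min_conf, min_replicates = min_replicates,
                 min_ph = min_ph, mono_tol = mono_tol,
                 bin_width = attr(bins, "bin_width")),
            class = "bin_criteria")
}

#' Hill titration curve
#'
#' Predicted average protonation `1 / (1 + 10^(n * (pH - pKa)))`: strictly
#' decreasing in pH, equal to 0.5 at `pH = pKa`.
#'
#' @param ph pH value(s).
#' @param pKa midpoint.
#' @param n Hill coefficient (> 0).
#' @return predicted protonation in \[0, 1\].
#' @export
hill_curve <- function(ph, pKa, n = 1) 1 / (1 + 10^(n * (ph - pKa)))

#' Fit the Hill equation to average protonations
#'
#' Weighted least squares of [hill_curve()] against (pH, average
#' protonation) points. The Hill coefficient is constrained to (0, 10]; the
#' pKa is unconstrained. Starting values come from the logit-linear form
#' `log10((1-p)/p) = n (pH - pKa)`; the bounded quasi-Newton refinement uses
#' analytic gradients.
#'
#' @param ph,prot,weight numeric vectors: pH values, average protonations in
#'   \[0, 1\], and fit weights (default equal).
#' @return list of class `hill_fit`: `pKa`, `n`, `residual` (weighted SSE),
#'   `converged`.
#' @export
hill_fit <- function(ph, prot, weight = rep(1, length(ph))) {
  stopifnot(length(ph) == length(prot), length(weight) == length(ph),
            all(prot >= 0 & prot <= 1), all(weight >= 0))
  if (length(unique(ph)) < 2)
    stop("at least two pH values are required for the fit")
  if (all(prot > 0.999) || all(prot < 0.001))
    stop("titration data are all-protonated or all-deprotonated; ",
         "midpoint not identifiable")
  pc <- pmin(pmax(prot, 1e-4), 1 - 1e-4)
  y <- log10((1 - pc) / pc)
  # weighted least squares y ~ ph in closed form (start values only)
  sw <- sum(weight)
  mx <- sum(weight * ph) / sw; my <- sum(weight * y) / sw
  sxx <- sum(weight * (ph - mx)^2)
  slope <- if (sxx > 0) sum(weight * (ph - mx) * (y - my)) / sxx else 1
  icpt <- my - slope * mx
  n0 <- max(min(slope, 10), 0.1)
  pKa0 <- if (abs(slope) > 1e-12) -icpt / slope else mean(ph)
  if (!is.finite(pKa0)) pKa0 <- mean(ph)
  obj <- function(par) {
    h <- hill_curve(ph, par[1], par[2])
    sum(weight * (h - prot)^2)
  }
  grad <- function(par) {
    h <- hill_curve(ph, par[1], par[2])
    hh <- h * (1 - h) * log(10)
    r <- 2 * weight * (h - prot)
    c(sum(r * par[2] * hh), -sum(r * (ph - par[1]) * hh))
  }
  fit <- optim(c(pKa0, n0), obj, grad, method = "L-BFGS-B",
               lower = c(min(ph) - 30, 1e-6), upper = c(max(ph) + 30, 10),
               control = list(factr = 10))
  if (fit$convergence != 0) {
    fit2 <- optim(c(pKa0, n0), obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-12, maxit = 2000))
    if (fit2$value < fit$value) fit <- fit2
  }
  if (!is.finite(fit$value))
    stop("Hill fit did not converge")
  structure(list(pKa = fit$par[1], n = fit$par[2], residual = fit$value,
                 converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: pKa = %.4f, n = %.4f (weighted SSE %.3g)\n",
              x$pKa, x$n, x$residual))
  invisible(x)
}

#' Bayesian-bootstrap error of a binned pKa
#'
#' Resamples the per-(pH, replicate) average-protonation samples `B` times;
#' in each bootstrap every sample receives a flat-Dirichlet random weight
#' (normalized exponentials), per-pH weighted averages are recomputed, the
#' monotonicity criterion is re-checked on them, and the Hill fit is re-run.
#' The reported pKa is the mean over criteria-passing bootstraps and the
#' error their standard deviation; bootstraps failing the criteria or the
#' fit are counted and more than `max_fail_frac` of them aborts the bin as
#' unreliable.
#'
#' @param samples data.frame with columns `ph`, `replicate`, `prot`
#'   (per-sample average protonation) and `n` (conformations behind the
#'   sample, used as fit weight).
#' @param B number of bootstraps (default 1000).
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @param mono_tol monotonicity tolerance re-applied per bootstrap.
#' @param max_fail_frac failure-fraction threshold (default 0.5).
#' @return list: `pKa`, `error`, `n_fail`, `B`, `pKa_boot` (vector of
#'   passing bootstrap estimates).
#' @export
bayesian_bootstrap_pka <- function(samples, B = 1000, seed = NULL,
                                   mono_tol = 0.05, max_fail_frac = 0.5) {
  stopifnot(all(c("ph", "replicate", "prot", "n") %in% names(samples)),
            nrow(samples) >= 2, B >= 1)
  phs <- sort(unique(samples$ph))
  if (length(phs) < 2) stop("at least two pH values are required")
  idx <- lapply(phs, function(p) which(samples$ph == p))
  wfit <- vapply(idx, function(ix) sum(samples$n[ix]), numeric(1))
  with_seed(seed, function() {
    est <- numeric(B)
    ok <- logical(B)
    ns <- nrow(samples)
    for (bset in seq_len(B)) {
      w <- rexp(ns)
      avg <- vapply(idx, function(ix)
        sum(w[ix] * samples$prot[ix]) / sum(w[ix]), numeric(1))
      if (any(diff(avg) > mono_tol)) { ok[bset] <- FALSE; next }
      ft <- tryCatch(hill_fit(phs, avg, wfit), error = function(e) NULL)
      if (is.null(ft)) { ok[bset] <- FALSE; next }
      est[bset] <- ft$pKa
      ok[bset] <- TRUE
    }
    n_fail <- sum(!ok)
    if (n_fail > max_fail_frac * B)
      stop("bin unreliable: ", n_fail, "/", B,
           " bootstraps failed the criteria or the fit")
    list(pKa = mean(est[ok]), error = stats::sd(est[ok]),
         n_fail = n_fail, B = B, pKa_boot = est[ok])
  })
}

#' Insertion-binned pKa profile
#'
#' Full profiling pipeline: bin the observations, apply the acceptance
#' criteria, and for every bin passing them fit the Hill equation to the
#' pooled per-pH average protonations (weighted by conformation counts) and
#' attach Bayesian-bootstrap errors computed from the per-replicate
#' averages.
#'
#' @inheritParams bin_observations
#' @inheritParams apply_bin_criteria
#' @param B bootstraps per bin (default 1000).
#' @param seed optional RNG seed.
#' @return data.frame of class `pka_profile`: `bin_low`, `bin_high`,
#'   `bin_mid`, `pKa` (criteria-passing bootstrap mean), `pKa_fit` (point
#'   estimate), `hill_n`, `error`, `n_ph`, `n_replicates`, `boot_fail`,
#'   `valid`. Bins failing the criteria carry `NA` estimates.
#' @export
pka_profile <- function(obs, bin_width = 1, burn_in_fraction = 0.5,
                        min_conf = 10, min_replicates = 3, min_ph = 2,
                        mono_tol = 0.05, B = 1000, seed = NULL) {
  bins <- bin_observations(obs, bin_width, burn_in_fraction)
  cr <- apply_bin_criteria(bins, min_conf, min_replicates, min_ph, mono_tol)
  out <- cr$per_bin
  out$bin_high <- out$bin_low + bin_width
  out$bin_mid <- out$bin_low + bin_width / 2
  out$pKa <- NA_real_; out$pKa_fit <- NA_real_; out$hill_n <- NA_real_
  out$error <- NA_real_; out$boot_fail <- NA_integer_
  out$valid <- FALSE
  for (i in seq_len(nrow(out))) {
    if (!out$fit_ok[i]) next
    bl <- out$bin_low[i]
    d <- cr$per_ph[cr$per_ph$bin_low == bl & cr$per_ph$ok2, ]
    d <- d[order(d$ph), ]
    ft <- tryCatch(hill_fit(d$ph, d$mean_prot, d$n),
                   error = function(e) NULL)
    if (is.null(ft)) next
    cells <- cr$cells
    sam <- cells[cells$bin_low == bl & cells$ok1 & cells$ph %in% d$ph, ]
    bb <- tryCatch(
      bayesian_bootstrap_pka(
        data.frame(ph = sam$ph, replicate = sam$replicate,
                   prot = sam$mean_prot, n = sam$n),
        B = B, seed = if (is.null(seed)) NULL else seed + i,
        mono_tol = mono_tol),
      error = function(e) NULL)
    out$pKa_fit[i] <- ft$pKa
    out$hill_n[i] <- ft$n
    if (!is.null(bb)) {
      out$pKa[i] <- bb$pKa
      out$error[i] <- bb$error
      out$boot_fail[i] <- bb$n_fail
      out$valid[i] <- TRUE
    }
  }
  structure(out[, c("bin_low", "bin_high", "bin_mid", "pKa", "pKa_fit",
                    "hill_n", "error", "n_ph", "n_replicates",
                    "boot_fail", "valid")],
            class = c("pka_profile", "data.frame"), criteria = cr)
}

#' Insertion-binned protonation profile
#'
#' Pooled average protonation per insertion bin and pH, subject to criteria
#' 1-2 only (cell counts and replicate coverage).
#'
#' @inheritParams pka_profile
#' @return data.frame `bin_low`, `bin_high`, `ph`, `mean_prot`, `n`,
#'   `n_replicates`.
#' @export
protonation_profile <- function(obs, bin_width = 1, burn_in_fraction = 0.5,
                                min_conf = 10, min_replicates = 3) {
  bins <- bin_observations(obs, bin_width, burn_in_fraction)
  cr <- apply_bin_criteria(bins, min_conf, min_replicates)
  d <- cr$per_ph[cr$per_ph$ok2, , drop = FALSE]
  d$bin_high <- d$bin_low + bin_width
  rownames(d) <- NULL
  d[, c("bin_low", "bin_high", "ph", "mean_prot", "n", "n_replicates")]
}

#' Insertion-binned profile of a generic scalar property
#'
#' Applies the same binning, burn-in and coverage machinery to any scalar
#' observable (a distance, a contact count, ...): per (bin, pH, replicate)
#' cell means, kept when the cell holds at least `min_conf` conformations,
#' pooled per (bin, pH) when at least `min_replicates` replicates survive.
#'
#' @param obs observation data.frame as in [bin_observations()] with an
#'   additional scalar column.
#' @param scalar name of the scalar column.
#' @inheritParams pka_profile
#' @return data.frame `bin_low`, `bin_high`, `ph`, `mean`, `sem` (across
#'   replicate means), `n`, `n_replicates`.
#' @export
property_profile <- function(obs, scalar, bin_width = 1,
                             burn_in_fraction = 0.5, min_conf = 10,
                             min_replicates = 3) {
  stopifnot(scalar %in% names(obs), all(is.finite(obs[[scalar]])))
  bins <- bin_observations(obs, bin_width, burn_in_fraction)
  o <- attr(bins, "obs")
  ag <- aggregate(o[[scalar]],
                  by = list(bin = o$bin, ph = o$ph,
                            replicate = o$replicate),
                  FUN = function(v) c(mean(v), length(v)))
  cells <- data.frame(bin = ag$bin, ph = ag$ph, replicate = ag$replicate,
                      mean = ag$x[, 1], n = ag$x[, 2])
  cells <- cells[cells$n >= min_conf, , drop = FALSE]
  if (nrow(cells) == 0L)
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      ph = numeric(0), mean = numeric(0), sem = numeric(0),
                      n = numeric(0), n_replicates = integer(0)))
  out <- do.call(rbind, lapply(
    split(cells, interaction(cells$bin, cells$ph, drop = TRUE)),
    function(d) data.frame(
      bin_low = d$bin[1] * bin_width,
      bin_high = (d$bin[1] + 1) * bin_width, ph = d$ph[1],
      mean = sum(d$mean * d$n) / sum(d$n),
      sem = if (nrow(d) > 1) stats::sd(d$mean) / sqrt(nrow(d)) else 0,
      n = sum(d$n), n_replicates = nrow(d))))
  out <- out[out$n_replicates >= min_replicates, , drop = FALSE]
  out <- out[order(out$bin_low, out$ph), ]
  rownames(out) <- NULL
  out
}
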