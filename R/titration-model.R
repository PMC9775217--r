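#' @useDynLib memtitra, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif sd setNames aggregate lm coef optim qchisq
#' @importFrom utils read.table write.table head tail
NULL

#' Build a titratable system
#'
#' A titratable system bundles the site definitions (tautomer lists and
#' setup z positions along the membrane normal) with the conformation-specific
#' energy terms: per-tautomer intrinsic protonation free energies `g` and
#' pairwise site-site couplings `W`, both in pK (log10) units as produced by a
#' continuum-electrostatics (Poisson-Boltzmann) calculation.
#'
#' Every site must carry at least one deprotonated tautomer (`n_protons = 0`)
#' and at least one protonated tautomer (`n_protons >= 1`). For a single
#' two-form site the intrinsic pKa is `pK_int = g(deprotonated) -
#' g(protonated)`, so that the protonated fraction at bath pH follows
#' `1 / (1 + 10^(pH - pK_int))`.
#'
#' @param tautomers data.frame with columns `site_id`, `tautomer`,
#'   `n_protons` (integer >= 0) and `g` (intrinsic term, pK units).
#' @param pairs optional data.frame with columns `site_i`, `tau_i`, `site_j`,
#'   `tau_j`, `W` (pK units). Missing combinations are treated as 0; entries
#'   are stored once and read symmetrically.
#' @param start_z optional named numeric of setup z positions (Angstrom) per
#'   site, used by [assign_proton_baths()].
#' @param bath_override optional named character (`"in"`/`"out"`) forcing the
#'   bath of specific sites regardless of `start_z`.
#' @param conformation_id label of the conformation the energies belong to.
#' @return an object of class `titration_system`.
#' @seealso [read_energy_terms()], [microstate_free_energy()], [mc_titrate()]
#' @export
titration_system <- function(tautomers, pairs = NULL, start_z = NULL,
                             bath_override = NULL,
                             conformation_id = "conf") {
  stopifnot(is.data.frame(tautomers),
            all(c("site_id", "tautomer", "n_protons", "g") %in%
                  names(tautomers)))
  tautomers$site_id <- as.character(tautomers$site_id)
  tautomers$tautomer <- as.character(tautomers$tautomer)
  tautomers$n_protons <- as.integer(tautomers$n_protons)
  tautomers$g <- as.numeric(tautomers$g)
  if (any(!is.finite(tautomers$g)))
    stop("non-finite intrinsic term g")
  if (any(tautomers$n_protons < 0L))
    stop("n_protons must be >= 0")
  key <- paste(tautomers$site_id, tautomers$tautomer)
  if (anyDuplicated(key))
    stop("duplicate (site, tautomer): ", key[duplicated(key)][1L])
  site_ids <- unique(tautomers$site_id)
  for (s in site_ids) {
    np <- tautomers$n_protons[tautomers$site_id == s]
    if (!any(np == 0L) || !any(np >= 1L))
      stop("site ", s,
           " needs at least one deprotonated and one protonated tautomer")
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    stopifnot(all(c("site_i", "tau_i", "site_j", "tau_j", "W") %in%
                    names(pairs)))
    pairs$site_i <- as.character(pairs$site_i)
    pairs$site_j <- as.character(pairs$site_j)
    pairs$tau_i <- as.character(pairs$tau_i)
    pairs$tau_j <- as.character(pairs$tau_j)
    pairs$W <- as.numeric(pairs$W)
    if (any(!is.finite(pairs$W))) stop("non-finite pairwise term W")
    ok_i <- paste(pairs$site_i, pairs$tau_i) %in% key
    ok_j <- paste(pairs$site_j, pairs$tau_j) %in% key
    if (!all(ok_i & ok_j))
      stop("pairwise term references unknown (site, tautomer)")
    if (any(pairs$site_i == pairs$site_j))
      stop("pairwise term within a single site")
  } else {
    pairs <- data.frame(site_i = character(), tau_i = character(),
                        site_j = character(), tau_j = character(),
                        W = numeric())
  }
  sz <- setNames(rep(NA_real_, length(site_ids)), site_ids)
  if (!is.null(start_z)) sz[names(start_z)] <- as.numeric(start_z)
  ov <- setNames(rep(NA_character_, length(site_ids)), site_ids)
  if (!is.null(bath_override)) {
    stopifnot(all(bath_override %in% c("in", "out")))
    ov[names(bath_override)] <- bath_override
  }
  structure(list(site_ids = site_ids, tautomers = tautomers, pairs = pairs,
                 start_z = sz, bath_override = ov,
                 conformation_id = conformation_id),
            class = "titration_system")
}

#' @export
print.titration_system <- function(x, ...) {
  cat("titration_system:", length(x$site_ids), "site(s),",
      nrow(x$tautomers), "tautomer(s),", nrow(x$pairs),
      "pairwise term(s) [conformation", x$conformation_id, "]\n")
  invisible(x)
}

#' Transmembrane pH gradient specification
#'
#' Holds the two bath pH values. The convention used throughout is
#' `delta_pH = pH_in - pH_out` (positive when the interior is more basic) and
#' `pH = (pH_in + pH_out) / 2`, so that the pair is recovered from the
#' midpoint as `pH +/- delta_pH / 2`.
#'
#' @param pH_in interior bath pH.
#' @param pH_out exterior bath pH.
#' @return object of class `gradient_spec` with fields `pH_in`, `pH_out`,
#'   `pH` (midpoint) and `delta_pH`.
#' @export
gradient_spec <- function(pH_in, pH_out) {
  stopifnot(is.finite(pH_in), is.finite(pH_out))
  structure(list(pH_in = pH_in, pH_out = pH_out,
                 pH = (pH_in + pH_out) / 2, delta_pH = pH_in - pH_out),
            class = "gradient_spec")
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat(sprintf("gradient_spec: pH_in %.3f, pH_out %.3f (midpoint %.3f, delta %.3f)\n",
              x$pH_in, x$pH_out, x$pH, x$delta_pH))
  invisible(x)
}

#' Bath pH values from midpoint and gradient magnitude
#'
#' The gradient can equivalently be given as the midpoint pH and the
#' difference `delta_pH`; the endpoints are `pH +/- delta_pH/2` with the
#' `+` half going to the interior bath (`delta_pH = pH_in - pH_out`).
#'
#' @param pH midpoint pH.
#' @param delta_pH gradient magnitude, `pH_in - pH_out`.
#' @return a [gradient_spec()].
#' @examples
#' gradient_endpoints(6.6, 1.2)  # pH_in 7.2, pH_out 6.0
#' @export
gradient_endpoints <- function(pH, delta_pH) {
  gradient_spec(pH_in = pH + delta_pH / 2, pH_out = pH - delta_pH / 2)
}

#' Assign each titratable site to a proton bath
#'
#' The membrane center partitions space into the two proton baths: sites
#' whose setup z position lies above the center couple to the exterior bath
#' (`out`), sites below it to the interior bath (`in`). An explicit
#' `bath_override` on a site always wins (used for sites that sit near the
#' center and hop between monolayers). A site exactly at the center with no
#' override is assigned `out` with a warning.
#'
#' @param system a [titration_system()] whose sites carry `start_z`.
#' @param membrane_center_z membrane center along the normal (Angstrom).
#' @return named character vector (`"in"`/`"out"`) over all sites, class
#'   `bath_assignment`.
#' @export
assign_proton_baths <- function(system, membrane_center_z = 0) {
  stopifnot(inherits(system, "titration_system"),
            is.finite(membrane_center_z))
  out <- setNames(rep(NA_character_, length(system$site_ids)),
                  system$site_ids)
  for (s in system$site_ids) {
    if (!is.na(system$bath_override[[s]])) {
      out[[s]] <- system$bath_override[[s]]
      message("site ", s, ": bath override -> ", out[[s]])
      next
    }
    z <- system$start_z[[s]]
    if (is.na(z))
      stop("site ", s, " has no start_z and no bath_override")
    if (z > membrane_center_z) out[[s]] <- "out"
    else if (z < membrane_center_z) out[[s]] <- "in"
    else {
      warning("site ", s, " starts exactly at the membrane center; ",
              "assigned to the outer bath")
      out[[s]] <- "out"
    }
  }
  structure(out, class = "bath_assignment")
}

#' Construct a bath assignment directly
#' @param x named character vector mapping every site to `"in"` or `"out"`.
#' @param system optional [titration_system()] to validate completeness.
#' @return `bath_assignment`
#' @export
bath_assignment <- function(x, system = NULL) {
  stopifnot(all(x %in% c("in", "out")), !is.null(names(x)))
  if (anyDuplicated(names(x))) stop("duplicated site in bath assignment")
  if (!is.null(system)) {
    miss <- setdiff(system$site_ids, names(x))
    if (length(miss)) stop("bath assignment missing sites: ",
                           paste(miss, collapse = ", "))
    x <- x[system$site_ids]
  }
  structure(setNames(as.character(x), names(x)), class = "bath_assignment")
}

# Per-site bath pH vector for a system under a gradient.
bath_ph <- function(system, baths, grad) {
  b <- unclass(baths)[system$site_ids]
  if (any(is.na(b))) stop("bath assignment does not cover all sites")
  ifelse(b == "in", grad$pH_in, grad$pH_out)
}

#' Construct a protonation microstate
#'
#' A microstate assigns one tautomer to every site. Its total bound-proton
#' count `N` is the quantity entering the replica-exchange acceptance
#' probability.
#'
#' @param x named character vector mapping `site_id` to a tautomer label.
#' @param system the [titration_system()] the microstate belongs to.
#' @return class `microstate` (named character) with attribute `N`.
#' @export
microstate <- function(x, system) {
  stopifnot(inherits(system, "titration_system"))
  miss <- setdiff(system$site_ids, names(x))
  if (length(miss)) stop("microstate missing sites: ",
                         paste(miss, collapse = ", "))
  x <- setNames(as.character(x[system$site_ids]), system$site_ids)
  tt <- system$tautomers
  np <- integer(length(x))
  for (k in seq_along(x)) {
    row <- tt$site_id == names(x)[k] & tt$tautomer == x[[k]]
    if (!any(row)) stop("site ", names(x)[k], " has no tautomer '",
                        x[[k]], "'")
    np[k] <- tt$n_protons[row]
  }
  structure(x, N = sum(np), n_protons = setNames(np, names(x)),
            class = "microstate")
}

#' Total bound protons of a microstate
#' @param x a [microstate()].
#' @return integer proton count `N`.
#' @export
n_protons <- function(x) {
  stopifnot(inherits(x, "microstate"))
  attr(x, "N")
}

#' Semi-grand free energy of a protonation microstate
#'
#' Evaluates, in pK (log10) units,
#' `G(x) = sum_i [ g_i(tau_i) + n_protons(tau_i) * pH_b(i) ] +
#'  sum_(i<j) W_ij(tau_i, tau_j)`,
#' where `pH_b(i)` is the pH of the proton bath site `i` is coupled to. The
#' statistical weight of the microstate is `10^(-G)`. For an isolated
#' two-form site this reduces to the Henderson-Hasselbalch protonated
#' fraction `1 / (1 + 10^(pH - pK_int))` with
#' `pK_int = g(deprot) - g(prot)`.
#'
#' @param x a [microstate()] or named character vector of tautomer labels.
#' @param system a [titration_system()].
#' @param baths a [bath_assignment()].
#' @param grad a [gradient_spec()]; use `gradient_spec(pH, pH)` for a single
#'   bath.
#' @return numeric free energy in pK units.
#' @export
microstate_free_energy <- function(x, system, baths, grad) {
  if (!inherits(x, "microstate")) x <- microstate(x, system)
  ph <- unname(bath_ph(system, baths, grad))
  tt <- system$tautomers
  G <- 0
  for (k in seq_along(system$site_ids)) {
    s <- system$site_ids[k]
    row <- tt$site_id == s & tt$tautomer == x[[s]]
    G <- G + tt$g[row] + tt$n_protons[row] * ph[k]
  }
  pr <- system$pairs
  if (nrow(pr)) {
    hit <- pr$tau_i == x[pr$site_i] & pr$tau_j == x[pr$site_j]
    G <- G + sum(pr$W[hit])
  }
  G
}

# ---- compiled (flat, integer-indexed) view used by the samplers ----------
#
# off:  0-based start of each site's tautomer block in the flat arrays
# nt:   tautomer count per site
# g/np: flat intrinsic terms and proton counts, site-major
# adjacency: for each site, the pair entries it participates in, each with a
#   W block laid out (own tautomer)-major so the kernel can index it directly.
compile_system <- function(system) {
  tt <- system$tautomers
  site_ids <- system$site_ids
  n <- length(site_ids)
  nt <- integer(n); off <- integer(n)
  g <- numeric(0); np <- integer(0)
  tlab <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- tt$site_id == site_ids[k]
    off[k] <- length(g)
    nt[k] <- sum(sel)
    g <- c(g, tt$g[sel]); np <- c(np, tt$n_protons[sel])
    tlab[[k]] <- tt$tautomer[sel]
  }
  names(tlab) <- site_ids
  sidx <- setNames(seq_len(n), site_ids)
  # dense W matrix per unordered site pair
  pr <- system$pairs
  pair_key <- list(); pair_mat <- list()
  if (nrow(pr)) for (r in seq_len(nrow(pr))) {
    i <- sidx[[pr$site_i[r]]]; j <- sidx[[pr$site_j[r]]]
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, "_", b)
    if (is.null(pair_mat[[key]])) {
      pair_mat[[key]] <- matrix(0, nt[a], nt[b])
      pair_key[[key]] <- c(a, b)
    }
    ti <- match(pr$tau_i[r], tlab[[i]]); tj <- match(pr$tau_j[r], tlab[[j]])
    if (i == pair_key[[key]][1L]) pair_mat[[key]][ti, tj] <- pr$W[r]
    else pair_mat[[key]][tj, ti] <- pr$W[r]
  }
  # adjacency flattening: entry list per direction
  adj_ptr <- integer(n + 1L); adj_j <- integer(0); adj_woff <- integer(0)
  wdata <- numeric(0)
  ent_i <- integer(0); ent_j <- integer(0); ent <- list()
  for (key in names(pair_key)) {
    a <- pair_key[[key]][1L]; b <- pair_key[[key]][2L]
    M <- pair_mat[[key]]
    ent_i <- c(ent_i, a, b); ent_j <- c(ent_j, b, a)
    ent <- c(ent, list(M), list(t(M)))
  }
  ord <- order(ent_i)
  cnt <- tabulate(ent_i, nbins = n)
  adj_ptr <- c(0L, cumsum(cnt))
  for (e in ord) {
    adj_j <- c(adj_j, ent_j[e] - 1L)
    adj_woff <- c(adj_woff, length(wdata))
    wdata <- c(wdata, as.numeric(t(ent[[e]])))  # own-tautomer-major
  }
  # unique unordered pairs with max |W| for coupled-pair selection
  up <- t(vapply(pair_key, identity, numeric(2)))
  wmax <- vapply(pair_mat, function(m) max(abs(m)), numeric(1))
  list(n = n, site_ids = site_ids, off = off, nt = nt, g = g, np = np,
       tlab = tlab, adj_ptr = adj_ptr, adj_j = adj_j, adj_woff = adj_woff,
       wdata = wdata,
       upairs = if (length(pair_key)) cbind(up, wmax)
                else matrix(numeric(0), 0, 3))
}

# microstate (named character) -> 1-based local tautomer indices
state_to_idx <- function(x, cs) {
  idx <- integer(cs$n)
  for (k in seq_len(cs$n)) {
    idx[k] <- match(x[[cs$site_ids[k]]], cs$tlab[[k]])
    if (is.na(idx[k])) stop("invalid tautomer for site ", cs$site_ids[k])
  }
  idx
}

idx_to_state <- function(idx, cs, system) {
  lab <- vapply(seq_len(cs$n), function(k) cs$tlab[[k]][idx[k]],
                character(1))
  microstate(setNames(lab, cs$site_ids), system)
}
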