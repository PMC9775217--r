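#' Simple reference systems
#'
#' Builders for small titratable systems used throughout the examples and
#' validation code: an isolated two-form site of given intrinsic pKa, a pair
#' of coupled sites, and randomized interacting systems.
#'
#' @param pK_int intrinsic pKa of the site.
#' @param site_id site label.
#' @param start_z setup z position (Angstrom).
#' @return a [titration_system()].
#' @export
single_site_system <- function(pK_int = 6.0, site_id = "A", start_z = 5) {
  titration_system(data.frame(
    site_id = site_id, tautomer = c("d", "p"), n_protons = c(0L, 1L),
    g = c(0, -pK_int)), start_z = setNames(start_z, site_id))
}

#' @rdname single_site_system
#' @param pK1,pK2 intrinsic pKa values of the two sites.
#' @param W coupling between the two protonated forms (pK units).
#' @param start_z2 setup z of the second site.
#' @export
two_site_system <- function(pK1 = 6.0, pK2 = 7.0, W = 2.5,
                            start_z = 5, start_z2 = -5) {
  titration_system(
    data.frame(site_id = rep(c("A", "B"), each = 2),
               tautomer = rep(c("d", "p"), 2), n_protons = rep(c(0L, 1L), 2),
               g = c(0, -pK1, 0, -pK2)),
    pairs = data.frame(site_i = "A", tau_i = "p", site_j = "B", tau_j = "p",
                       W = W),
    start_z = c(A = start_z, B = start_z2))
}

#' @rdname single_site_system
#' @param n_sites number of sites.
#' @param max_tautomers maximum tautomers per site (>= 2); each site gets one
#'   deprotonated and 1..(max_tautomers-1) protonated forms.
#' @param g_range range of intrinsic terms for protonated tautomers (pK
#'   units, drawn uniformly).
#' @param w_range range of pairwise couplings.
#' @param pair_prob probability that a given site pair is coupled.
#' @param seed optional RNG seed.
#' @export
random_system <- function(n_sites = 6, max_tautomers = 3,
                          g_range = c(-9, -3), w_range = c(-3, 3),
                          pair_prob = 0.5, seed = NULL) {
  with_seed(seed, function() {
    ids <- sprintf("S%02d", seq_len(n_sites))
    tt <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
      k <- sample(seq_len(max_tautomers - 1L), 1L)
      data.frame(site_id = ids[i],
                 tautomer = c("d", paste0("p", seq_len(k))),
                 n_protons = c(0L, rep(1L, k)),
                 g = c(0, runif(k, g_range[1], g_range[2])))
    }))
    pr <- NULL
    if (n_sites >= 2) {
      cmb <- utils::combn(n_sites, 2)
      picked <- runif(ncol(cmb)) < pair_prob
      rows <- list()
      for (c0 in which(picked)) {
        i <- cmb[1, c0]; j <- cmb[2, c0]
        ti <- tt$tautomer[tt$site_id == ids[i] & tt$n_protons > 0]
        tj <- tt$tautomer[tt$site_id == ids[j] & tt$n_protons > 0]
        for (a in ti) for (bb in tj)
          rows[[length(rows) + 1L]] <- data.frame(
            site_i = ids[i], tau_i = a, site_j = ids[j], tau_j = bb,
            W = runif(1, w_range[1], w_range[2]))
      }
      if (length(rows)) pr <- do.call(rbind, rows)
    }
    titration_system(tt, pairs = pr,
                     start_z = setNames(runif(n_sites, -15, 15), ids))
  })
}

#' Parameters of the 1D peptide-membrane surrogate
#'
#' The surrogate stands in for an atomistic peptide-membrane system. It has
#' one key titratable site whose intrinsic pKa depends on the insertion
#' coordinate z of its side chain through a desolvation switch:
#' `pK_int(z) = pK_mod + dpK_desolv * S((z_mid - z) / z_width)`, with `S` the
#' logistic function. Fully solvated (large z) the site titrates at its
#' solution pKa `pK_mod`; buried below the phosphate region the pKa is
#' shifted up by as much as `dpK_desolv`, the desolvation penalty on the
#' charged (deprotonated) form. The conformational coordinate z moves in a
#' harmonic well and is coupled to protonation: the neutral (protonated)
#' form gains stability with burial exactly as dictated by `pK_int(z)`, so
#' burial and protonation promote each other.
#'
#' @param pK_mod solution pKa of the key site (default 5.5, chosen so the
#'   titration straddles a 4-7 pH ladder).
#' @param dpK_desolv maximal desolvation shift, >= 0 (default 2).
#' @param z_mid sigmoid midpoint (Angstrom, insertion coordinate; default
#'   -3).
#' @param z_width sigmoid width (Angstrom, > 0; default 2).
#' @param conf_step half-width of the uniform z proposal (Angstrom).
#' @param well_z0,well_k center and curvature (1/Angstrom^2, in kT units) of
#'   the harmonic conformational well.
#' @param W_partner optional coupling (pK units) to a second, fixed-pKa
#'   partner site; `NULL` for the uncoupled surrogate.
#' @return `surrogate_params` object.
#' @export
surrogate_params <- function(pK_mod = 5.5, dpK_desolv = 2.0, z_mid = -3,
                             z_width = 2, conf_step = 1.5, well_z0 = -2,
                             well_k = 0.05, W_partner = NULL) {
  stopifnot(z_width > 0, dpK_desolv >= 0, conf_step > 0, well_k > 0)
  structure(list(pK_mod = pK_mod, dpK_desolv = dpK_desolv, z_mid = z_mid,
                 z_width = z_width, conf_step = conf_step,
                 well_z0 = well_z0, well_k = well_k, W_partner = W_partner),
            class = "surrogate_params")
}

#' Depth-dependent intrinsic pKa of the surrogate key site
#'
#' Closed form `pK_int(z) = pK_mod + dpK_desolv * S((z_mid - z)/z_width)`;
#' this is the ground truth an insertion-binned pKa profile of the uncoupled
#' surrogate must recover.
#'
#' @param params a [surrogate_params()] (no partner coupling).
#' @param z insertion coordinate(s), Angstrom (negative = buried).
#' @return numeric pKa value(s).
#' @export
analytic_pka_profile <- function(params, z) {
  stopifnot(inherits(params, "surrogate_params"))
  if (!is.null(params$W_partner))
    stop("analytic profile defined only for the uncoupled surrogate")
  params$pK_mod + params$dpK_desolv * stats::plogis((params$z_mid - z) /
                                                      params$z_width)
}

# conformational potential (kT units) at fixed protonation; the protonated
# branch carries -ln(10) * pK_int(z) so that the joint density factorizes as
# exp(-U0(z)) * 10^(-G(x; z)).
surrogate_potential <- function(params, z, protonated) {
  u <- 0.5 * params$well_k * (z - params$well_z0)^2
  if (protonated) u <- u - log(10) * analytic_pka_profile_raw(params, z)
  u
}

# pK_int(z) without the partner-coupling guard (internal)
analytic_pka_profile_raw <- function(params, z) {
  params$pK_mod + params$dpK_desolv * stats::plogis((params$z_mid - z) /
                                                      params$z_width)
}

#' Boltzmann z-density of the surrogate at fixed protonation
#'
#' Numerical quadrature of `exp(-U(z | protonation))` on a grid; the oracle
#' the surrogate propagator is validated against.
#'
#' @param params a [surrogate_params()].
#' @param protonated logical.
#' @param z grid of z values.
#' @return data.frame `z`, `density` (normalized on the grid).
#' @export
surrogate_z_density <- function(params, protonated,
                                z = seq(-25, 25, by = 0.05)) {
  u <- vapply(z, function(zz) surrogate_potential(params, zz, protonated),
              numeric(1))
  w <- exp(-(u - min(u)))
  data.frame(z = z, density = w / (sum(w) * mean(diff(z))))
}

#' Build the surrogate peptide-membrane system and its propagator
#'
#' Returns a one-site (optionally two-site) [titration_system()] whose key
#' site's intrinsic term is conformation-dependent (`g(prot) = -pK_int(z)`,
#' attached as attribute `g_fun` consumed by [run_phre()]), together with a
#' Metropolis [propagator()] on the insertion coordinate z that preserves
#' the declared conformational distribution at fixed protonation.
#'
#' @param params a [surrogate_params()].
#' @return list with `system`, `propagator` and `params`.
#' @export
make_surrogate_system <- function(params = surrogate_params()) {
  stopifnot(inherits(params, "surrogate_params"))
  tt <- data.frame(site_id = "KEY", tautomer = c("d", "p"),
                   n_protons = c(0L, 1L),
                   g = c(0, -params$pK_mod))
  pr <- NULL
  if (!is.null(params$W_partner)) {
    tt <- rbind(tt, data.frame(site_id = "PARTNER",
                               tautomer = c("d", "p"),
                               n_protons = c(0L, 1L), g = c(0, -7)))
    pr <- data.frame(site_i = "KEY", tau_i = "p", site_j = "PARTNER",
                     tau_j = "p", W = params$W_partner)
  }
  sys <- titration_system(tt, pairs = pr,
                          start_z = setNames(rep(5, length(unique(tt$site_id))),
                                             unique(tt$site_id)))
  # index of the key site's protonated tautomer in the flat g layout:
  # sites are laid out in first-appearance order, KEY first, (d, p)
  attr(sys, "g_fun") <- function(conf) {
    g <- c(0, -analytic_pka_profile_raw(params, as.numeric(conf)[1]))
    if (!is.null(params$W_partner)) g <- c(g, 0, -7)
    g
  }
  prop <- propagator(
    advance = function(conf, protonation, n_steps) {
      z <- as.numeric(conf)[1]
      prot <- protonation[["KEY"]] > 0
      dz <- runif(n_steps, -params$conf_step, params$conf_step)
      u <- runif(n_steps)
      uz <- surrogate_potential(params, z, prot)
      for (s in seq_len(n_steps)) {
        z2 <- z + dz[s]
        u2 <- surrogate_potential(params, z2, prot)
        if (u2 <= uz || u[s] < exp(uz - u2)) { z <- z2; uz <- u2 }
      }
      z
    },
    summarize = function(conf) as.numeric(conf)[1],
    init = function() params$well_z0)
  list(system = sys, propagator = prop, params = params)
}

#' Specification of synthetic membrane frames
#'
#' Describes a two-leaflet phosphate-bead membrane with an optional
#' Gaussian thinning/thickening centered on the peptide: leaflet z is
#' `+/- (half_thickness_bulk + A * exp(-r^2 / (2 sigma^2)))` plus Gaussian
#' noise, with `r` the in-plane distance to the peptide at the origin.
#' Negative `A` produces the dimple toward the membrane interior typical of
#' an inserting peptide.
#'
#' @param n_side lipids per monolayer are placed on an `n_side x n_side`
#'   grid with `spacing` Angstrom (default 12 x 12 at 8 Angstrom).
#' @param spacing grid spacing (Angstrom).
#' @param half_thickness_bulk unperturbed half thickness (Angstrom, > 0;
#'   default 19.5, in the fluid-phase phosphatidylcholine range).
#' @param A deformation amplitude (Angstrom; 0 = flat).
#' @param sigma radial width of the deformation (Angstrom, > 0).
#' @param noise_sd Gaussian z noise per atom per frame (Angstrom).
#' @param deform which monolayer(s) carry the deformation.
#' @return `frame_spec` object.
#' @export
synthetic_frame_spec <- function(n_side = 12, spacing = 8,
                                 half_thickness_bulk = 19.5, A = 0,
                                 sigma = 3, noise_sd = 0.3,
                                 deform = c("both", "upper", "lower")) {
  stopifnot(half_thickness_bulk > 0, sigma > 0, noise_sd >= 0, n_side >= 4)
  structure(list(n_side = as.integer(n_side), spacing = spacing,
                 half_thickness_bulk = half_thickness_bulk, A = A,
                 sigma = sigma, noise_sd = noise_sd,
                 deform = match.arg(deform)),
            class = "frame_spec")
}

#' Generate synthetic membrane coordinate frames
#'
#' Places one phosphate group (a P atom flanked by two O atoms) per lipid on
#' two leaflets following the deformation law of the [synthetic_frame_spec()]
#' and a probe residue (resname `PRB`, atom `CA`) at the origin in xy at the
#' requested absolute z per frame. Frames are centered so the box spans
#' `[0, L)` in xy with the peptide at `L/2` and are periodic in xy.
#'
#' @param spec a [synthetic_frame_spec()].
#' @param n_frames number of frames.
#' @param probe_z absolute probe z per frame (recycled); `NULL` omits the
#'   probe.
#' @param seed optional RNG seed.
#' @return `frame_stack`: list of `membrane_frame` objects (see
#'   [read_frames()]) with attribute `truth` holding the generating
#'   parameters.
#' @export
generate_membrane_frames <- function(spec, n_frames, probe_z = NULL,
                                     seed = NULL) {
  stopifnot(inherits(spec, "frame_spec"), n_frames >= 1)
  with_seed(seed, function() {
    L <- spec$n_side * spec$spacing
    gx <- (seq_len(spec$n_side) - 0.5) * spec$spacing
    xy <- as.matrix(expand.grid(x = gx, y = gx))
    ctr <- L / 2
    r2 <- (xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2
    bump <- spec$A * exp(-r2 / (2 * spec$sigma^2))
    nlip <- nrow(xy)
    if (!is.null(probe_z)) probe_z <- rep_len(probe_z, n_frames)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      mk_leaf <- function(sgn, tag) {
        h <- spec$half_thickness_bulk +
          if (spec$deform == "both" || spec$deform == tag) bump else 0
        zp <- sgn * h + stats::rnorm(nlip, 0, spec$noise_sd)
        zo1 <- sgn * h + stats::rnorm(nlip, 0, spec$noise_sd)
        zo2 <- sgn * h + stats::rnorm(nlip, 0, spec$noise_sd)
        data.frame(
          name = rep(c("P", "O1", "O2"), each = nlip),
          resname = "POPC",
          resid = rep(seq_len(nlip) + (tag == "lower") * nlip, 3),
          x = rep(xy[, 1], 3) + rep(c(0, 0.8, -0.8), each = nlip),
          y = rep(xy[, 2], 3),
          z = c(zp, zo1, zo2),
          monolayer = tag, role = "phosphate",
          stringsAsFactors = FALSE)
      }
      atoms <- rbind(mk_leaf(+1, "upper"), mk_leaf(-1, "lower"))
      if (!is.null(probe_z))
        atoms <- rbind(atoms, data.frame(
          name = "CA", resname = "PRB", resid = 2L * nlip + 1L,
          x = ctr, y = ctr, z = probe_z[f],
          monolayer = NA_character_, role = "probe",
          stringsAsFactors = FALSE))
      frames[[f]] <- structure(
        list(atoms = atoms,
             box = c(L, L, 2 * (spec$half_thickness_bulk + 15)),
             frame = f),
        class = "membrane_frame")
    }
    structure(frames, class = "frame_stack",
              truth = list(spec = spec, probe_z = probe_z,
                           peptide_xy = c(ctr, ctr)))
  })
}
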