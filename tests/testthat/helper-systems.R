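# shared builders for the test suite

# bath assignment covering all sites with one label
all_baths <- function(system, label = "out") {
  bath_assignment(setNames(rep(label, length(system$site_ids)),
                           system$site_ids))
}

# alternating in/out assignment
mixed_baths <- function(system) {
  n <- length(system$site_ids)
  bath_assignment(setNames(rep(c("out", "in"), length.out = n),
                           system$site_ids))
}

# synthetic profiling observations: protonation drawn from a Hill curve
# whose pKa may depend on the insertion bin; insertion drawn uniformly
# over the requested window per frame
make_hill_obs <- function(pka_fun = function(z) 6, n_replicates = 5,
                          n_frames = 400, ph = c(4, 5, 6, 7),
                          z_range = c(-6, 0), hill_n = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    do.call(rbind, lapply(ph, function(p) {
      z <- runif(n_frames, z_range[1], z_range[2])
      pr <- hill_curve(p, pka_fun(z), hill_n)
      data.frame(replicate = r, ph = p, frame = seq_len(n_frames),
                 insertion = z,
                 protonated = as.integer(runif(n_frames) < pr))
    }))
  }))
}

# a deterministic cell: k protonated then (n - k) deprotonated frames at
# fixed insertion z for each (replicate, ph)
cell_obs <- function(z, ph, replicate, n_prot, n_deprot) {
  do.call(rbind, Map(function(p, r, np, nd) {
    data.frame(replicate = r, ph = p, frame = seq_len(np + nd),
               insertion = z,
               protonated = rep(c(1L, 0L), c(np, nd)))
  }, ph, replicate, n_prot, n_deprot))
}

# single flat frame built by hand: atoms at given xyz in one monolayer,
# plus the opposite monolayer mirrored, probe optional
hand_frame <- function(x, y, z, monolayer = "upper", box = c(60, 60, 60),
                       probe = NULL, name = "P") {
  atoms <- data.frame(name = rep_len(name, length(x)), resname = "POPC",
                      resid = seq_along(x), x = x, y = y, z = z,
                      monolayer = monolayer, role = "phosphate",
                      stringsAsFactors = FALSE)
  if (!is.null(probe))
    atoms <- rbind(atoms, data.frame(
      name = "CA", resname = "PRB", resid = max(atoms$resid) + 1L,
      x = probe[1], y = probe[2], z = probe[3],
      monolayer = NA_character_, role = "probe",
      stringsAsFactors = FALSE))
  structure(list(atoms = atoms, box = box, frame = 1L),
            class = "membrane_frame")
}
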