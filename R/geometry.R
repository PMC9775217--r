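# xy minimum-image displacement components
min_image <- function(d, L) d - L * round(d / L)

phosphate_atoms <- function(frame) {
  a <- frame$atoms
  a[a$role == "phosphate", , drop = FALSE]
}

#' Membrane center along the normal
#'
#' The membrane center is the mean z position of all phosphorus atoms
#' (both monolayers).
#'
#' @param frame a `membrane_frame` (see [read_frames()] or
#'   [generate_membrane_frames()]).
#' @return numeric z (Angstrom).
#' @export
membrane_center <- function(frame) {
  p <- phosphate_atoms(frame)
  p <- p[substr(p$name, 1, 1) == "P", , drop = FALSE]
  if (nrow(p) == 0L) stop("frame has no phosphorus atoms")
  mean(p$z)
}

#' Local monolayer surface at a probe position
#'
#' The local surface is the mean z of one monolayer's phosphate-group P and
#' O atoms within a 6 Angstrom radius of the probe in the xy plane
#' (periodic minimum image). When fewer than `min_atoms` atoms fall inside
#' the radius, the `min_atoms` atoms closest to the probe in xy are used
#' regardless of distance, so the estimate never rests on fewer than
#' `min_atoms` atoms.
#'
#' @param frame a `membrane_frame`.
#' @param probe_xy length-2 numeric, probe xy position.
#' @param monolayer `"upper"` or `"lower"`.
#' @param radius xy cutoff radius (Angstrom, default 6).
#' @param min_atoms minimum atoms defining the surface (default 10).
#' @return list with `z` (surface z) and `n_atoms` used.
#' @export
local_surface_z <- function(frame, probe_xy, monolayer, radius = 6,
                            min_atoms = 10) {
  p <- phosphate_atoms(frame)
  p <- p[p$monolayer == monolayer, , drop = FALSE]
  if (nrow(p) < min_atoms)
    stop("monolayer '", monolayer, "' has only ", nrow(p),
         " phosphate atoms (< ", min_atoms, ")")
  dx <- min_image(p$x - probe_xy[1], frame$box[1])
  dy <- min_image(p$y - probe_xy[2], frame$box[2])
  d2 <- dx^2 + dy^2
  inside <- d2 <= radius^2
  if (sum(inside) >= min_atoms) {
    sel <- inside
  } else {
    sel <- rank(d2, ties.method = "first") <= min_atoms
  }
  list(z = mean(p$z[sel]), n_atoms = sum(sel))
}

probe_position <- function(frame, residue = "PRB", reference_atom = NULL) {
  a <- frame$atoms
  pr <- a[a$resname == residue, , drop = FALSE]
  if (!is.null(reference_atom))
    pr <- pr[pr$name == reference_atom, , drop = FALSE]
  if (nrow(pr) == 0L) return(NULL)
  c(x = mean(pr$x), y = mean(pr$y), z = mean(pr$z))
}

#' Signed insertion of a tagged residue relative to the local surface
#'
#' Per frame, the monolayer on the residue's side of the membrane center is
#' selected and the local phosphate surface computed with
#' [local_surface_z()]; the insertion is `s * (z_res - z_surface)` with
#' `s = +1` for the upper monolayer and `s = -1` for the lower, so negative
#' values always point toward the membrane interior.
#'
#' @param frames a `frame_stack`.
#' @param residue residue name of the tagged group (default `"PRB"`).
#' @param reference_atom atom name used as the group reference; `NULL`
#'   averages over all atoms of the residue.
#' @param radius,min_atoms see [local_surface_z()].
#' @return data.frame `frame`, `residue`, `insertion`, `monolayer`,
#'   `n_atoms`. Frames missing the residue are skipped with a warning.
#' @export
insertion_series <- function(frames, residue = "PRB", reference_atom = NULL,
                             radius = 6, min_atoms = 10) {
  out <- vector("list", length(frames))
  skipped <- 0L
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    pos <- probe_position(fr, residue, reference_atom)
    if (is.null(pos)) { skipped <- skipped + 1L; next }
    ctr <- membrane_center(fr)
    mono <- if (pos[["z"]] >= ctr) "upper" else "lower"
    s <- if (mono == "upper") 1 else -1
    surf <- local_surface_z(fr, pos[c("x", "y")], mono, radius, min_atoms)
    out[[i]] <- data.frame(frame = fr$frame, residue = residue,
                           insertion = s * (pos[["z"]] - surf$z),
                           monolayer = mono, n_atoms = surf$n_atoms)
  }
  if (skipped > 0L)
    warning(skipped, " frame(s) missing residue '", residue, "'; skipped")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) stop("residue '", residue, "' found in no frame")
  rownames(res) <- NULL
  res
}

#' Annulus half-thickness profile around the peptide
#'
#' For each monolayer and 1 Angstrom-wide radial bin centered on the peptide
#' (in-plane, periodic minimum image), the half thickness is the mean of
#' `|z - membrane_center|` over the monolayer's phosphate P and O atoms in
#' the bin, averaged over frames. The standard error is taken across frames,
#' or across replicate means when `replicate` labels are supplied.
#'
#' @param frames a `frame_stack`.
#' @param peptide_residue residue defining the annulus center (per-frame
#'   mean xy of its atoms); default `"PRB"`.
#' @param bin_width radial bin width (Angstrom, default 1).
#' @param replicate optional vector of replicate labels, one per frame.
#' @return data.frame of class `thickness_profile`: `monolayer`, `bin_low`,
#'   `bin_high`, `half_thickness`, `sem`, `n_frames`, `n_atoms`. Empty bins
#'   are absent. Attribute `frame_bins` keeps the per-frame bin means used
#'   by [local_deformation()].
#' @export
annulus_half_thickness <- function(frames, peptide_residue = "PRB",
                                   bin_width = 1, replicate = NULL) {
  stopifnot(length(frames) >= 1)
  if (!is.null(replicate)) stopifnot(length(replicate) == length(frames))
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    cxy <- probe_position(fr, peptide_residue)
    if (is.null(cxy)) stop("frame ", fr$frame, " missing residue '",
                           peptide_residue, "'")
    ctr <- membrane_center(fr)
    p <- phosphate_atoms(fr)
    dx <- min_image(p$x - cxy[["x"]], fr$box[1])
    dy <- min_image(p$y - cxy[["y"]], fr$box[2])
    r <- sqrt(dx^2 + dy^2)
    bin <- floor(r / bin_width)
    ht <- abs(p$z - ctr)
    ag <- aggregate(ht, by = list(monolayer = p$monolayer, bin = bin),
                    FUN = function(v) c(mean(v), length(v)))
    rows[[i]] <- data.frame(frame_i = i, monolayer = ag$monolayer,
                            bin = ag$bin, ht = ag$x[, 1], n = ag$x[, 2])
  }
  fb <- do.call(rbind, rows)
  fb$replicate <- if (is.null(replicate)) fb$frame_i
                  else replicate[fb$frame_i]
  key <- interaction(fb$monolayer, fb$bin, drop = TRUE)
  prof <- do.call(rbind, lapply(split(fb, key), function(d) {
    # atom-weighted mean over frames; SEM over frames or replicate means
    m <- sum(d$ht * d$n) / sum(d$n)
    grp <- tapply(d$ht, d$replicate, mean)
    sem <- if (length(grp) > 1) stats::sd(grp) / sqrt(length(grp)) else 0
    data.frame(monolayer = d$monolayer[1], bin_low = d$bin[1] * bin_width,
               bin_high = (d$bin[1] + 1) * bin_width, half_thickness = m,
               sem = sem, n_frames = nrow(d), n_atoms = sum(d$n))
  }))
  prof <- prof[order(prof$monolayer, prof$bin_low), ]
  rownames(prof) <- NULL
  structure(prof, class = c("thickness_profile", "data.frame"),
            frame_bins = fb, bin_width = bin_width)
}

#' Local membrane deformation profile
#'
#' Deformation per radial bin and monolayer: local half thickness minus the
#' bulk half thickness, where the bulk is computed from all phosphate atoms
#' whose in-plane distance to the peptide exceeds the cutoff (unperturbed
#' lipids).
#'
#' @param profile a `thickness_profile` from [annulus_half_thickness()].
#' @param bulk_cutoff bulk distance cutoff (Angstrom, default 15).
#' @return the profile with added `bulk` and `deformation` columns.
#' @export
local_deformation <- function(profile, bulk_cutoff = 15) {
  stopifnot(inherits(profile, "thickness_profile"))
  fb <- attr(profile, "frame_bins")
  bw <- attr(profile, "bin_width")
  out <- profile
  out$bulk <- NA_real_
  out$deformation <- NA_real_
  for (mono in unique(profile$monolayer)) {
    d <- fb[fb$monolayer == mono & fb$bin * bw >= bulk_cutoff, ]
    if (nrow(d) == 0L)
      stop("no atoms beyond the bulk cutoff for monolayer '", mono, "'")
    bulk <- sum(d$ht * d$n) / sum(d$n)
    sel <- out$monolayer == mono
    out$bulk[sel] <- bulk
    out$deformation[sel] <- out$half_thickness[sel] - bulk
  }
  out
}
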