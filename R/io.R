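#' Atom selection configuration for coordinate frames
#'
#' Maps residue/atom names to the roles the geometry analyses need: lipid
#' phosphate-group atoms (P and O) and the tagged probe residue.
#'
#' @param phosphate_resname lipid residue name (default `"POPC"`).
#' @param phosphate_atoms atom names of the phosphate group.
#' @param probe_resname residue name of the tagged group.
#' @return `frame_selection` list.
#' @export
frame_selection <- function(phosphate_resname = "POPC",
                            phosphate_atoms = c("P", "O1", "O2", "O3",
                                                "O4"),
                            probe_resname = "PRB") {
  structure(list(phosphate_resname = phosphate_resname,
                 phosphate_atoms = phosphate_atoms,
                 probe_resname = probe_resname),
            class = "frame_selection")
}

tag_atoms <- function(atoms, sel, center_z) {
  atoms$role <- "other"
  isph <- atoms$resname == sel$phosphate_resname &
    atoms$name %in% sel$phosphate_atoms
  atoms$role[isph] <- "phosphate"
  atoms$role[atoms$resname == sel$probe_resname] <- "probe"
  atoms$monolayer <- NA_character_
  atoms$monolayer[isph] <- ifelse(atoms$z[isph] >= center_z, "upper",
                                  "lower")
  atoms
}

#' Read multi-frame coordinate files
#'
#' Reads GRO or PDB (MODEL/ENDMDL) coordinate stacks into `membrane_frame`
#' objects. GRO coordinates are stored in nm and converted to Angstrom at
#' this boundary; PDB coordinates are Angstrom already. Phosphate and probe
#' atoms are tagged via the [frame_selection()]; monolayer membership is
#' assigned once from the first frame's geometry (side of the membrane
#' center) and held fixed, so atoms near the center do not flip between
#' leaflets frame to frame.
#'
#' @param path file ending in `.gro` or `.pdb`.
#' @param selection a [frame_selection()].
#' @return `frame_stack` (list of `membrane_frame`).
#' @export
read_frames <- function(path, selection = frame_selection()) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                gro = read_gro_raw(path),
                pdb = read_pdb_raw(path),
                stop("unknown coordinate format: .", ext,
                     " (expected .gro or .pdb)"))
  if (!length(raw)) stop("no frames found in ", path)
  # monolayer tags from frame 1
  a1 <- raw[[1]]$atoms
  isph <- a1$resname == selection$phosphate_resname &
    a1$name %in% selection$phosphate_atoms
  isp <- isph & substr(a1$name, 1, 1) == "P"
  if (!any(isp)) stop("selection matched no phosphorus atoms")
  ctr <- mean(a1$z[isp])
  mono1 <- ifelse(a1$z >= ctr, "upper", "lower")
  frames <- lapply(seq_along(raw), function(i) {
    atoms <- tag_atoms(raw[[i]]$atoms, selection, ctr)
    if (nrow(atoms) == nrow(a1))
      atoms$monolayer[atoms$role == "phosphate"] <-
        mono1[atoms$role == "phosphate"]
    structure(list(atoms = atoms, box = raw[[i]]$box, frame = i),
              class = "membrane_frame")
  })
  structure(frames, class = "frame_stack")
}

# ---- GRO ------------------------------------------------------------------
# Fixed-width: resid(5) resname(5) atom(5) serial(5) x y z (%8.3f each, nm)

read_gro_raw <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nf <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nf <- nf + 1L
    if (i + 1L > length(lines))
      stop("truncated frame ", nf, " in ", path, ": missing atom count")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      stop("frame ", nf, ": malformed atom count at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      stop("truncated frame ", nf, " in ", path)
    al <- lines[(i + 2L):(i + 1L + nat)]
    atoms <- data.frame(
      name = trimws(substr(al, 11, 15)),
      resname = trimws(substr(al, 6, 10)),
      resid = as.integer(substr(al, 1, 5)),
      x = as.numeric(substr(al, 21, 28)) * 10,
      y = as.numeric(substr(al, 29, 36)) * 10,
      z = as.numeric(substr(al, 37, 44)) * 10,
      stringsAsFactors = FALSE)
    if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)))
      stop("frame ", nf, ": malformed coordinate record near line ",
           i + 1L + which(is.na(atoms$x))[1])
    box <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[i + 2L + nat]), "\\s+")[[1]])) * 10
    if (length(box) < 3 || any(is.na(box[1:3])))
      stop("frame ", nf, ": missing or malformed box line")
    frames[[nf]] <- list(atoms = atoms, box = box[1:3])
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  frames
}

#' Write frames as GRO or PDB
#'
#' @param frames a `frame_stack`.
#' @param path output path; format from the extension (`.gro` nm, `.pdb`
#'   Angstrom).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, gro = write_gro(frames, path), pdb = write_pdb_stack(frames, path),
         stop("unknown coordinate format: .", ext))
  invisible(path)
}

write_gro <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    writeLines(sprintf("synthetic membrane, frame %d", fr$frame), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000L, a$resname, a$name,
                       seq_len(nrow(a)) %% 100000L,
                       a$x / 10, a$y / 10, a$z / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10,
                       fr$box[2] / 10, fr$box[3] / 10), con)
  }
}

# ---- PDB ------------------------------------------------------------------

write_pdb_stack <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- frames[[1]]$box
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  for (fr in frames) {
    a <- fr$atoms
    writeLines(sprintf("MODEL     %4d", fr$frame), con)
    el <- substr(a$name, 1, 1)
    # name 13-16, resName 18-21, resSeq 23-26, x/y/z 31-54, element 77-78
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, a$name, a$resname, a$resid %% 10000L,
      a$x, a$y, a$z, 1, 0, el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

read_pdb_raw <- function(path) {
  lines <- readLines(path)
  box <- c(NA_real_, NA_real_, NA_real_)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl))
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {            # single unwrapped model
    starts <- 0L; ends <- length(lines) + 1L
  }
  if (length(ends) < length(starts))
    stop("truncated frame ", length(starts), " in ", path,
         ": MODEL without ENDMDL")
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    al <- blk[startsWith(blk, "ATOM") | startsWith(blk, "HETATM")]
    if (!length(al)) stop("frame ", k, " contains no ATOM records")
    atoms <- data.frame(
      name = trimws(substr(al, 13, 16)),
      resname = trimws(substr(al, 18, 21)),
      resid = as.integer(substr(al, 23, 26)),
      x = as.numeric(substr(al, 31, 38)),
      y = as.numeric(substr(al, 39, 46)),
      z = as.numeric(substr(al, 47, 54)),
      stringsAsFactors = FALSE)
    if (any(is.na(atoms$x)))
      stop("frame ", k, ": malformed ATOM record")
    frames[[k]] <- list(atoms = atoms, box = box)
  }
  frames
}

# ---- energy terms ---------------------------------------------------------

#' Read titration energy terms
#'
#' Tab/space-separated file with two record kinds (one file per
#' conformation, `#` comments, pK units):
#' \preformatted{
#' SITE site_id tautomer n_protons g
#' PAIR site_i tau_i site_j tau_j W
#' }
#'
#' @param path input file.
#' @param start_z,bath_override passed to [titration_system()].
#' @return a [titration_system()].
#' @export
read_energy_terms <- function(path, start_z = NULL, bath_override = NULL) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; ln <- ln[keep]
  tok <- strsplit(trimws(lines), "\\s+")
  kind <- vapply(tok, `[`, character(1), 1L)
  bad <- !(kind %in% c("SITE", "PAIR"))
  if (any(bad))
    stop("unknown record kind '", kind[bad][1], "' at line ", ln[bad][1])
  srows <- which(kind == "SITE"); prows <- which(kind == "PAIR")
  num <- function(s, where) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) stop("non-numeric value at line ", where)
    v
  }
  tt <- NULL
  if (length(srows)) {
    if (any(lengths(tok[srows]) != 5L))
      stop("malformed SITE record at line ",
           ln[srows][lengths(tok[srows]) != 5L][1])
    tt <- data.frame(
      site_id = vapply(tok[srows], `[`, character(1), 2L),
      tautomer = vapply(tok[srows], `[`, character(1), 3L),
      n_protons = vapply(seq_along(srows), function(i)
        as.integer(num(tok[[srows[i]]][4], ln[srows[i]])), integer(1)),
      g = vapply(seq_along(srows), function(i)
        num(tok[[srows[i]]][5], ln[srows[i]]), numeric(1)))
    key <- paste(tt$site_id, tt$tautomer)
    if (anyDuplicated(key)) {
      d <- which(key == key[duplicated(key)][1])
      stop("duplicated SITE record for (", key[d[1]], ") at lines ",
           ln[srows][d[1]], " and ", ln[srows][d[2]])
    }
  } else stop("no SITE records in ", path)
  pr <- NULL
  if (length(prows)) {
    if (any(lengths(tok[prows]) != 6L))
      stop("malformed PAIR record at line ",
           ln[prows][lengths(tok[prows]) != 6L][1])
    pr <- data.frame(
      site_i = vapply(tok[prows], `[`, character(1), 2L),
      tau_i = vapply(tok[prows], `[`, character(1), 3L),
      site_j = vapply(tok[prows], `[`, character(1), 4L),
      tau_j = vapply(tok[prows], `[`, character(1), 5L),
      W = vapply(seq_along(prows), function(i)
        num(tok[[prows[i]]][6], ln[prows[i]]), numeric(1)))
    key <- paste(pr$site_i, pr$tau_i, pr$site_j, pr$tau_j)
    if (anyDuplicated(key)) {
      d <- which(key == key[duplicated(key)][1])
      stop("duplicated PAIR record at lines ", ln[prows][d[1]], " and ",
           ln[prows][d[2]])
    }
  }
  titration_system(tt, pairs = pr, start_z = start_z,
                   bath_override = bath_override,
                   conformation_id = basename(path))
}

#' Write titration energy terms
#' @param system a [titration_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energy_terms <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# titration energy terms (pK units)", con)
  tt <- system$tautomers
  writeLines(sprintf("SITE\t%s\t%s\t%d\t%.6g", tt$site_id, tt$tautomer,
                     tt$n_protons, tt$g), con)
  pr <- system$pairs
  if (nrow(pr))
    writeLines(sprintf("PAIR\t%s\t%s\t%s\t%s\t%.6g", pr$site_i, pr$tau_i,
                       pr$site_j, pr$tau_j, pr$W), con)
  invisible(path)
}

#' Read a bath-assignment file
#'
#' Lines of `site_id in|out` (`#` comments allowed).
#'
#' @param path input file.
#' @param system optional system to validate against.
#' @return a [bath_assignment()].
#' @export
read_bath_file <- function(path, system = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(tok) != 2L | !vapply(tok, function(t)
    t[2] %in% c("in", "out"), logical(1))
  if (any(bad)) stop("malformed bath record: '", lines[bad][1], "'")
  bath_assignment(setNames(vapply(tok, `[`, character(1), 2L),
                           vapply(tok, `[`, character(1), 1L)),
                  system = system)
}
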