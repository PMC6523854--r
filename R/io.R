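#' Write a trajectory as extended XYZ
#'
#' One block per frame: site count, then a comment line carrying the
#' orthorhombic box (`Lattice="..."`), the column layout
#' (`Properties=species:S:1:pos:R:3`), the frame time and any scalar
#' observables as `key=value` tokens, then one line per site with the type
#' label and coordinates at 10 significant digits.
#'
#' @param frames list of frames (`list(pos, box, time, obs)`).
#' @param topology matching [cg_topology] (for the species column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, topology, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$pos)
    obs <- f$obs %||% numeric(0)
    obs_str <- if (length(obs))
      paste(sprintf("%s=%.10g", names(obs), obs), collapse = " ") else ""
    header <- sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3 Time=%.10g %s',
      f$box[1], f$box[2], f$box[3], f$time %||% 0, obs_str)
    writeLines(c(as.character(n), trimws(header)), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", topology$type,
                       f$pos[, 1], f$pos[, 2], f$pos[, 3]), con)
  }
  invisible(path)
}

#' Open an extended-XYZ trajectory for streaming reads
#'
#' Returns a reader that yields one frame per call without loading the whole
#' file, so arbitrarily long trajectories can be processed frame by frame.
#'
#' @param path trajectory file.
#' @return A list with `next_frame()` (returns a frame or `NULL` at EOF) and
#'   `close()`.
#' @export
open_trajectory <- function(path) {
  con <- file(path, open = "rt")
  frame_no <- 0L
  line_no <- 0L
  next_frame <- function() {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) return(NULL)
    line_no <<- line_no + 1L
    n <- suppressWarnings(as.integer(trimws(ln)))
    if (is.na(n) || n < 1)
      stop("trajectory parse error at line ", line_no,
           ": expected site count, got '", ln, "' (last good frame: ",
           frame_no, ")")
    hdr <- readLines(con, n = 1L)
    if (!length(hdr))
      stop("truncated trajectory: header missing after line ", line_no,
           " (last good frame: ", frame_no, ")")
    line_no <<- line_no + 1L
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    if (!length(lat))
      stop("trajectory parse error at line ", line_no, ": no Lattice tag")
    latv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                                "\\s+")[[1]])
    box <- latv[c(1, 5, 9)]
    kv <- regmatches(hdr, gregexpr("[A-Za-z_][A-Za-z0-9_]*=[-+0-9.eE]+", hdr))[[1]]
    obs <- NULL
    if (length(kv)) {
      keys <- sub("=.*", "", kv)
      vals <- as.numeric(sub(".*=", "", kv))
      obs <- stats::setNames(vals, keys)
    }
    body <- readLines(con, n = n)
    if (length(body) < n)
      stop("truncated trajectory at line ", line_no + length(body),
           " (last good frame: ", frame_no, ")")
    line_no <<- line_no + n
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad))
      stop("trajectory parse error at line ", line_no - n + bad[1],
           ": expected 'species x y z'")
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    frame_no <<- frame_no + 1L
    list(pos = pos, box = box,
         time = unname(obs["Time"]) %||% NA_real_,
         species = vapply(parts, `[[`, "", 1L),
         obs = obs[setdiff(names(obs), "Time")])
  }
  list(next_frame = next_frame, close = function() close(con))
}

#' Read a whole extended-XYZ trajectory
#'
#' @param path trajectory file.
#' @param max_frames optional cap on the number of frames read.
#' @return List of frames (`list(pos, box, time, species, obs)`).
#' @export
read_trajectory <- function(path, max_frames = Inf) {
  rd <- open_trajectory(path)
  on.exit(rd$close())
  frames <- list()
  while (length(frames) < max_frames) {
    f <- rd$next_frame()
    if (is.null(f)) break
    frames[[length(frames) + 1L]] <- f
  }
  frames
}

#' Serialise a topology to JSON
#'
#' Sites (type, mass, charge, molecule), bonded terms, box and molecule
#' species; positions go to a companion extended-XYZ file if requested.
#'
#' @param topology a [cg_topology].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  doc <- list(
    n_sites = nrow(topology$pos),
    box = topology$box,
    sites = data.frame(type = topology$type, mass = topology$mass,
                       charge = topology$charge, mol_id = topology$mol_id),
    mol_species = topology$mol_species,
    bonds = as.data.frame(topology$bonds),
    bends = as.data.frame(topology$bends),
    dihedrals = as.data.frame(topology$dihedrals),
    waters = if (nrow(topology$waters)) as.data.frame(topology$waters) else
      NULL,
    positions = topology$pos
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a topology from JSON
#'
#' @param path JSON file written by [write_topology_json()].
#' @return A [cg_topology].
#' @export
read_topology_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nm) {
    m <- as.matrix(as.data.frame(x))
    if (!nrow(m)) m <- matrix(0, 0, length(nm))
    colnames(m) <- nm
    m
  }
  waters <- if (!is.null(doc$waters))
    matrix(as.integer(as.matrix(as.data.frame(doc$waters))), ncol = 3) else
    matrix(0L, 0, 3)
  new_topology(
    doc$sites$type, doc$sites$mass, doc$sites$charge, doc$sites$mol_id,
    doc$mol_species, matrix(unlist(doc$positions), ncol = 3, byrow = FALSE),
    doc$box,
    as_mat(doc$bonds, c("i", "j", "k", "r0")),
    as_mat(doc$bends, c("i", "j", "k", "ktheta", "theta0")),
    as_mat(doc$dihedrals, c("i", "j", "k", "l", "amp", "mult", "delta")),
    waters
  )
}

#' Write per-step observables to CSV
#'
#' @param observables data.frame from [run_md()] / [run_protocol()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(observables, path) {
  utils::write.csv(observables, path, row.names = FALSE)
  invisible(path)
}
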