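#' Read a (multi-model) PDB structure
#'
#' Minimal fixed-column parser for ATOM/HETATM records, sufficient for
#' gate-distance featurization of reference structures and multi-model
#' trajectories. Coordinates are converted from Angstrom to nm at parse
#' time (the package works in nm throughout). Alternate locations keep the
#' highest occupancy, ties resolved in favour of altLoc 'A'. MODEL/ENDMDL
#' blocks become an ordered list of coordinate frames over a shared atom
#' table.
#'
#' @param pdb_text character: either a file path or the PDB text itself
#'   (a vector of lines or a single string with newlines)
#' @return object of class `structure_model`: `atoms` (data.frame with
#'   name, altloc, resname, chain, resid, element, occupancy) and `frames`
#'   (list of n_atoms x 3 coordinate matrices, nm)
#' @export
read_structure <- function(pdb_text) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text))
    lines <- readLines(pdb_text)
  else
    lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE))
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stopf("no ATOM/HETATM record found")

  frames <- list()
  cur <- NULL
  atoms <- NULL
  source_id <- NA_character_
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1L, 6L)
    if (tag == "HEADER") {
      source_id <- trimws(substr(line, 63L, 66L))
    } else if (trimws(tag) == "MODEL") {
      cur <- list()
    } else if (trimws(tag) == "ENDMDL") {
      frames[[length(frames) + 1L]] <- cur
      cur <- NULL
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (nchar(line) < 54L)
        stopf("malformed ATOM/HETATM record at line %d (too short)", ln)
      x <- suppressWarnings(as.numeric(substr(line, 31L, 38L)))
      y <- suppressWarnings(as.numeric(substr(line, 39L, 46L)))
      z <- suppressWarnings(as.numeric(substr(line, 47L, 54L)))
      resid <- suppressWarnings(as.integer(substr(line, 23L, 26L)))
      if (any(is.na(c(x, y, z))) || is.na(resid))
        stopf("malformed ATOM/HETATM record at line %d", ln)
      occ <- suppressWarnings(as.numeric(substr(line, 55L, 60L)))
      at <- list(name = trimws(substr(line, 13L, 16L)),
                 altloc = substr(line, 17L, 17L),
                 resname = trimws(substr(line, 18L, 20L)),
                 chain = substr(line, 22L, 22L),
                 resid = resid,
                 element = trimws(substr(line, 77L, 78L)),
                 occupancy = if (is.na(occ)) 1 else occ,
                 x = x / 10, y = y / 10, z = z / 10)
      if (at$element == "")
        at$element <- substr(gsub("[^A-Za-z]", "", at$name), 1L, 1L)
      if (is.null(cur)) {
        # no MODEL block: single implicit frame
        if (!length(frames)) frames <- list(list())
        frames[[1]] <- c(frames[[1]], list(at))
      } else {
        cur <- c(cur, list(at))
      }
    }
  }
  if (!is.null(cur)) frames[[length(frames) + 1L]] <- cur
  frames <- Filter(length, frames)

  to_df <- function(frame) do.call(rbind, lapply(frame, as.data.frame))
  first <- to_df(frames[[1]])
  keep <- resolve_altloc(first)
  atoms <- first[keep, c("name", "altloc", "resname", "chain", "resid",
                         "element", "occupancy")]
  rownames(atoms) <- NULL
  coord_list <- lapply(frames, function(fr) {
    df <- to_df(fr)
    if (nrow(df) != nrow(first))
      stopf("models differ in atom count (%d vs %d)", nrow(df), nrow(first))
    as.matrix(df[keep, c("x", "y", "z")])
  })
  structure(list(atoms = atoms, frames = coord_list, source = source_id),
            class = "structure_model")
}

# keep one altLoc per (chain, resid, name): highest occupancy, ties -> 'A'
resolve_altloc <- function(df) {
  key <- paste(df$chain, df$resid, df$name, sep = "|")
  keep <- logical(nrow(df))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
    } else {
      occ <- df$occupancy[idx]
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) {
        a <- best[df$altloc[best] == "A"]
        best <- if (length(a)) a[1] else best[1]
      }
      keep[best[1]] <- TRUE
    }
  }
  keep
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d frame(s)%s\n", nrow(x$atoms),
              length(x$frames),
              if (!is.na(x$source) && nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Atom selections
#'
#' Inclusive residue ranges in 1-based human transporter numbering, matching
#' the "residue X to Y" convention for helix segments (e.g. TM6a = G324 to
#' L337, TM9up = F475 to S477, TM1b = L99 to Q111).
#'
#' @param chain chain identifier (single character) or NULL for any
#' @param first,last inclusive residue range
#' @param atoms atom filter: "CA", "heavy", "all", or a character vector of
#'   atom names
#' @return object of class `selection_spec`
#' @export
selection_spec <- function(first, last, chain = NULL, atoms = "CA") {
  if (first > last) stopf("selection range must have first <= last")
  structure(list(chain = chain, first = first, last = last, atoms = atoms),
            class = "selection_spec")
}

select_atoms <- function(model, sel) {
  a <- model$atoms
  idx <- a$resid >= sel$first & a$resid <= sel$last
  if (!is.null(sel$chain)) idx <- idx & a$chain == sel$chain
  if (identical(sel$atoms, "CA")) {
    idx <- idx & a$name == "CA"
  } else if (identical(sel$atoms, "heavy")) {
    idx <- idx & !(a$element %in% c("H", "D"))
  } else if (!identical(sel$atoms, "all")) {
    idx <- idx & a$name %in% sel$atoms
  }
  which(idx)
}

# standard atomic masses (u) for mass-weighted centroids
.ATOMIC_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                  NA4 = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
                  ZN = 65.38, CA2 = 40.078)

atom_masses <- function(elements) {
  el <- toupper(elements)
  m <- .ATOMIC_MASS[el]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon
  unname(m)
}
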