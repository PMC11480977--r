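# Coordinate model: PDB I/O, residue typing, interfaces, glycan topology.

# Residue-name catalogues. Monosaccharide recognition is by 3-letter code;
# the shipped list covers common pyranose/furanose codes and is extensible
# via options(glycodock.monosaccharides = c(...)).
.AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HSD", "HSE", "HSP", "CYX", "HID", "HIE", "HIP"
)

.MONOSACCHARIDES <- c(
  "GLC", "BGC", "GAL", "GLA", "MAN", "BMA", "FUC", "FUL", "XYL", "XYS",
  "ARA", "ARB", "RIB", "RIP", "RHA", "RAM", "NAG", "NDG", "NGA", "A2G",
  "SIA", "NAN", "SLB", "GCU", "BDP", "IDS", "IDR", "GCS", "PA1", "KDO",
  "ABE", "FRU", "BDF", "ALL", "AFD", "TAL", "GUP", "GL0", "G6D", "64K"
)

monosaccharide_names <- function() {
  getOption("glycodock.monosaccharides", .MONOSACCHARIDES)
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

residue_kind <- function(resname) {
  kind <- rep("other", length(resname))
  kind[resname %in% .AMINO_ACIDS] <- "amino-acid"
  kind[resname %in% monosaccharide_names()] <- "monosaccharide"
  kind
}

guess_element <- function(atname) {
  # strip digits and primes, take the leading letter; two-letter elements
  # in pseudo-atom fixtures do not occur
  s <- gsub("[0-9' ]", "", atname)
  toupper(substr(s, 1, 1))
}

new_structure <- function(atoms, role = c("receptor", "ligand"), model_id = 1L) {
  role <- match.arg(role)
  atoms$kind <- residue_kind(atoms$resname)
  atoms$is_h <- atoms$elem == "H"
  atoms$is_backbone <- atoms$kind == "amino-acid" & atoms$atname %in% .BACKBONE_NAMES
  atoms$reskey <- paste(atoms$chain, atoms$resid, sep = ":")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, role = role, model_id = as.integer(model_id)),
            class = "pg_structure")
}

#' @export
print.pg_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pg_structure> role=%s model=%d: %d atoms, %d residues (%s)\n",
              x$role, x$model_id, nrow(a), length(unique(a$reskey)),
              paste(names(table(a$kind)), table(a$kind), sep = ":", collapse = ", ")))
  invisible(x)
}

# ---- accessors -------------------------------------------------------------

str_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

heavy_idx <- function(s) which(!s$atoms$is_h)

res_keys <- function(s) unique(s$atoms$reskey)

n_atoms <- function(s) nrow(s$atoms)

centroid <- function(s, heavy_only = TRUE) {
  idx <- if (heavy_only) heavy_idx(s) else seq_len(n_atoms(s))
  colMeans(str_coords(s)[idx, , drop = FALSE])
}

bounding_radius <- function(s) {
  xyz <- str_coords(s)
  ctr <- colMeans(xyz)
  max(sqrt(rowSums(sweep(xyz, 2, ctr)^2)))
}

# ---- PDB reading -----------------------------------------------------------

#' Read a PDB file into one structure or an ensemble
#'
#' Parses fixed-width ATOM/HETATM records (via bio3d). Hydrogens are kept
#' but flagged; alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by first occurrence); each MODEL block of a
#' multi-model file becomes one structure with its own \code{model_id}.
#'
#' @param path PDB file path.
#' @param role \code{"receptor"} (protein) or \code{"ligand"} (glycan).
#' @return A \code{pg_structure}, or a list of them (class
#'   \code{pg_ensemble}) for multi-MODEL files.
#' @export
read_pdb <- function(path, role = c("receptor", "ligand")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  # pre-validate coordinate fields so malformed records are reported with
  # their line number (bio3d would fail opaquely)
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("unparseable coordinate record at line %d of %s", i, path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- guess_element(at$elety[bad])
  base <- data.frame(
    serial = at$eleno,
    atname = trimws(at$elety),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    resid = paste0(at$resno, ifelse(is.na(at$insert) | !nzchar(trimws(at$insert)),
                                    "", trimws(at$insert))),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    elem = trimws(elem),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(as.matrix(base[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1) return(new_structure(base, role, 1L))
  cols <- as.vector(vapply(keep, function(i) (i - 1L) * 3L + 1:3, integer(3)))
  out <- lapply(seq_len(nmod), function(m) {
    b <- base
    xyz <- matrix(pdb$xyz[m, cols], ncol = 3, byrow = TRUE)
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    new_structure(b, role, m)
  })
  class(out) <- "pg_ensemble"
  out
}

# keep, per (chain, resno, insert, resname, atom name), the altloc with the
# highest occupancy; tie -> first encountered
resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt) | alt == "")) return(seq_len(nrow(at)))
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, seq_len(nrow(at)))
  sort(ord[!duplicated(key[ord])])
}

# ---- PDB writing -----------------------------------------------------------

#' Write a structure (or ensemble) as a fixed-width PDB file
#'
#' Ensembles are emitted as MODEL/ENDMDL blocks. Coordinates outside the
#' +-999.999 field range raise an overflow error.
#'
#' @param structure a \code{pg_structure} or \code{pg_ensemble}/list of them.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  members <- if (inherits(structure, "pg_structure")) list(structure) else structure
  if (!length(members)) stop("empty structure")
  multi <- length(members) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(members)) {
    s <- members[[m]]
    if (!nrow(s$atoms)) stop("empty structure")
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    writeLines(format_pdb_lines(s$atoms), con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_pdb_lines <- function(a) {
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000)) stop("coordinate overflow: exceeds PDB field width")
  rectype <- ifelse(residue_kind(a$resname) == "amino-acid", "ATOM  ", "HETATM")
  resno <- as.integer(sub("([0-9-]+).*", "\\1", a$resid))
  ins <- sub("^[0-9-]+", "", a$resid)
  ins[!nzchar(ins)] <- " "
  atname <- ifelse(nchar(a$atname) <= 3, sprintf(" %-3s", a$atname),
                   sprintf("%-4s", a$atname))
  sprintf("%s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, a$serial %% 100000L, atname, a$resname, a$chain, resno, ins,
          a$x, a$y, a$z, a$occ, 0, a$elem)
}

# ---- interface detection ---------------------------------------------------

#' Detect interface residues between two partners
#'
#' A residue belongs to the interface iff any of its heavy atoms lies within
#' \code{cutoff} of any heavy atom of the partner; hydrogens never count.
#' The 3.9 A default is the contact definition used to derive true-interface
#' restraints.
#'
#' @param receptor,ligand \code{pg_structure} partners.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 3.9).
#' @return list with character vectors \code{receptor} and \code{ligand} of
#'   residue keys (\code{"chain:resid"}). Empty sets trigger a warning, not
#'   an error.
#' @export
select_interface <- function(receptor, ligand, cutoff = 3.9) {
  stopifnot(cutoff > 0)
  ra <- receptor$atoms[!receptor$atoms$is_h, , drop = FALSE]
  la <- ligand$atoms[!ligand$atoms$is_h, , drop = FALSE]
  if (!nrow(ra) || !nrow(la)) stop("empty structure in interface selection")
  d2 <- cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                    as.matrix(la[, c("x", "y", "z")]))
  hit <- d2 <= cutoff^2
  rsel <- unique(ra$reskey[rowSums(hit) > 0])
  lsel <- unique(la$reskey[colSums(hit) > 0])
  if (!length(rsel) && !length(lsel))
    warning(sprintf("no contacts at %.2f A: empty interface", cutoff))
  list(receptor = rsel, ligand = lsel)
}

# ---- glycan topology -------------------------------------------------------

#' Build the glycosidic linkage graph of a glycan
#'
#' Linkages are detected geometrically: an inter-residue carbon-oxygen
#' contact at or below \code{bond_cutoff} (default 1.8 A, covering the
#' anomeric C1-O glycosidic bond) creates an edge between the two
#' monosaccharide units. CONECT records are deliberately ignored.
#'
#' @param glycan ligand \code{pg_structure} (monosaccharide residues).
#' @param bond_cutoff C-O bond distance cutoff, Angstrom.
#' @return object of class \code{glycan_topology}: \code{n_units},
#'   \code{linkage_edges} (2-column matrix of residue keys), and
#'   \code{is_linear}.
#' @export
build_glycan_topology <- function(glycan, bond_cutoff = 1.8) {
  a <- glycan$atoms
  if (!any(a$kind == "monosaccharide"))
    stop("glycan has no monosaccharide residues")
  keys <- res_keys(glycan)
  n <- length(keys)
  carb <- a[a$elem == "C", , drop = FALSE]
  oxy <- a[a$elem == "O", , drop = FALSE]
  edges <- matrix(character(0), 0, 2)
  if (nrow(carb) && nrow(oxy)) {
    d2 <- cross_dist2(as.matrix(carb[, c("x", "y", "z")]),
                      as.matrix(oxy[, c("x", "y", "z")]))
    hit <- which(d2 <= bond_cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      e <- cbind(carb$reskey[hit[, 1]], oxy$reskey[hit[, 2]])
      e <- e[e[, 1] != e[, 2], , drop = FALSE]
      if (nrow(e)) {
        e <- t(apply(e, 1, sort))
        edges <- unique(e)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- keys
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(keys, comp$membership)
    stop("disconnected glycan linkage graph; components: ",
         paste(vapply(parts, paste, "", collapse = "+"), collapse = " | "))
  }
  deg <- igraph::degree(g)
  is_linear <- n == 1 ||
    (nrow(edges) == n - 1 && max(deg) <= 2)
  structure(list(n_units = n, linkage_edges = edges, is_linear = is_linear,
                 residues = keys, graph = g),
            class = "glycan_topology")
}

#' @export
print.glycan_topology <- function(x, ...) {
  cat(sprintf("<glycan_topology> %d units, %d linkages, %s\n",
              x$n_units, nrow(x$linkage_edges),
              if (x$is_linear) "linear" else "branched"))
  invisible(x)
}

#' Classify a glycan by size and connectivity
#'
#' Short (S) glycans have three or fewer monosaccharide units, long (L) more
#' than three; the second letter distinguishes linear (L) from branched (B)
#' chains, giving the four classes SL, SB, LL, LB.
#'
#' @param topology a \code{glycan_topology}.
#' @return one of \code{"SL"}, \code{"SB"}, \code{"LL"}, \code{"LB"}.
#' @export
classify_glycan <- function(topology) {
  stopifnot(inherits(topology, "glycan_topology"))
  paste0(if (topology$n_units <= 3) "S" else "L",
         if (topology$is_linear) "L" else "B")
}
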