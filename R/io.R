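# Readers and writers: multi-model PDB, topology descriptor, observable
# tables, and report files. Coordinates are stored internally in nm; PDB
# files are Angstrom, converted at this boundary.

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-width ATOM records, coordinates
#' converted nm to Angstrom.
#'
#' @param ens an `Ensemble`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_multimodel_pdb <- function(ens, path) {
  a <- ens$topology$atoms
  name4 <- ifelse(nchar(a$atom_name) < 4,
                  sprintf(" %-3s", a$atom_name),
                  substr(a$atom_name, 1, 4))
  el <- toupper(a$element)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    xyz <- get_frame(ens, f) / .ANG2NM
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$id, name4, a$res_name, "A", a$res_number,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, el)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into an Ensemble
#'
#' Frames are taken in file order and paired with a topology descriptor
#' (the sidecar carries donor/acceptor/ring chemistry the coordinates
#' cannot supply). Atom count and atom-name order are validated against the
#' topology. Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param path multi-model PDB file.
#' @param topology_path topology descriptor written by [write_topology()],
#'   or a `Topology` object.
#' @return an `Ensemble` with uniform frame weights.
#' @export
read_multimodel_pdb <- function(path, topology_path) {
  top <- if (inherits(topology_path, "Topology")) topology_path
         else read_topology(topology_path)
  counts <- .pdb_model_atom_counts(path)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop("PDB format error: model ", bad, " has ", counts[bad],
         " atoms but model 1 has ", counts[1])
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natom <- ncol(xyz) / 3
  if (natom != nrow(top$atoms))
    stop("PDB has ", natom, " atoms; topology annotates ", nrow(top$atoms),
         " (unannotated or missing atoms)")
  pdb_names <- trimws(pdb$atom$elety)
  if (!all(pdb_names == top$atoms$atom_name))
    stop("atom-name order mismatch between PDB and topology at atom(s): ",
         paste(head(which(pdb_names != top$atoms$atom_name), 5), collapse = ", "))
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, natom, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3 * natom, by = 3), drop = FALSE] * .ANG2NM
  ensemble(top, coords, provenance = basename(path))
}

.pdb_model_atom_counts <- function(path) {
  ln <- readLines(path)
  rec <- substr(ln, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (!length(model_starts)) return(sum(rec %in% c("ATOM  ", "HETATM")))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("PDB format error: unbalanced MODEL/ENDMDL records")
  vapply(seq_along(model_starts), function(i) {
    sum(rec[model_starts[i]:model_ends[i]] %in% c("ATOM  ", "HETATM"))
  }, integer(1))
}

#' Write a topology descriptor file
#'
#' Structured text: a tab-delimited atom table (id, residue indices/names,
#' element, heavy/donor/acceptor/hydrophobic/ligand flags, attached
#' hydrogens, ring-group membership), round-trippable by [read_topology()].
#'
#' @param top a `Topology`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_topology <- function(top, path) {
  a <- top$atoms
  ah <- vapply(as.character(a$id), function(id) {
    h <- top$attached_h[[id]]
    if (is.null(h)) "" else paste(h, collapse = ";")
  }, character(1))
  ring <- rep("", nrow(a))
  for (nm in names(top$ring_groups)) ring[top$ring_groups[[nm]]] <- nm
  out <- cbind(a, attached_h = ah, ring_group = ring)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# idpensemble topology descriptor v1", con)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a topology descriptor file
#' @param path file written by [write_topology()].
#' @return a `Topology`.
#' @export
read_topology <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("heavy", "donor", "acceptor", "hydrophobic", "ligand"))
    d[[col]] <- as.logical(d[[col]])
  d$attached_h <- as.character(ifelse(is.na(d$attached_h), "", d$attached_h))
  d$ring_group <- as.character(ifelse(is.na(d$ring_group), "", d$ring_group))
  ah <- list()
  for (i in which(nzchar(d$attached_h)))
    ah[[as.character(d$id[i])]] <- as.integer(strsplit(d$attached_h[i], ";")[[1]])
  rg <- list()
  for (nm in unique(d$ring_group[nzchar(d$ring_group)]))
    rg[[nm]] <- d$id[d$ring_group == nm]
  topology(d[, c("id", "res_index", "res_number", "res_name", "atom_name",
                 "element", "heavy", "donor", "acceptor", "hydrophobic",
                 "ligand")],
           attached_h = ah, ring_groups = rg)
}

#' Write an observable table
#'
#' Tab-delimited: header row of observable labels, one `target` row, one
#' `sigma` row, then one row per frame.
#'
#' @param obs an `ObservableTable`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_observable_table <- function(obs, path) {
  m <- rbind(target = obs$targets, sigma = obs$uncertainties, obs$values)
  d <- data.frame(frame = c("target", "sigma", seq_len(nrow(obs$values))), m,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an observable table written by [write_observable_table()]
#' @param path file path.
#' @return an `ObservableTable`.
#' @export
read_observable_table <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- names(d)[-1]
  tg <- as.numeric(d[d$frame == "target", -1])
  sg <- as.numeric(d[d$frame == "sigma", -1])
  vals <- as.matrix(d[!(d$frame %in% c("target", "sigma")), -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- NULL
  observable_table(vals, tg, sg, labels)
}

#' Write an analysis report table
#'
#' Lossless tab-delimited serialization with `# key: value` run-metadata
#' header lines (seed, package version, config hash).
#'
#' @param results a data.frame.
#' @param path output path.
#' @param metadata named list of scalar metadata values.
#' @return invisibly `path`.
#' @export
write_report <- function(results, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  metadata$version <- as.character(utils::packageVersion("idpensemble"))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]])), con)
  suppressWarnings(write.table(results, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a report table written by [write_report()]
#' @param path file path.
#' @return data.frame with a `metadata` attribute (named character vector).
#' @export
read_report <- function(path) {
  ln <- readLines(path)
  meta_lines <- grep("^# ", ln, value = TRUE)
  meta <- NULL
  if (length(meta_lines)) {
    kv <- regmatches(meta_lines, regexec("^# ([^:]+): (.*)$", meta_lines))
    meta <- setNames(vapply(kv, `[`, character(1), 3),
                     vapply(kv, `[`, character(1), 2))
  }
  body <- ln[!grepl("^# ", ln)]
  d <- if (length(body) > 1)
    read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  else
    read.delim(text = body, stringsAsFactors = FALSE)[0, , drop = FALSE]
  attr(d, "metadata") <- meta
  d
}
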