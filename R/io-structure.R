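# Coordinate file I/O.
#
# PDB reading/writing and mmCIF reading go through bio3d; a minimal
# PDBx/mmCIF writer (the `_atom_site` loop, coordinates only) is provided
# here since no installed package writes mmCIF.  Coarse-grained files store
# just the five bead atoms per residue; full-atom files are accepted and the
# beads extracted by atom name.

guess_format <- function(path) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
}

#' Read a structure into coarse-grained conformation(s)
#'
#' Accepts PDB or PDBx/mmCIF, coarse-grained or full-atom; the five bead
#' atoms (P, C4', N9|N1, C2, C6|C4) are extracted per RNA residue.  Non-RNA
#' residues are skipped with a warning; for alternate locations the first is
#' taken (with a warning).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return a [cg_conformation()]; for a multi-model PDB, a list with one
#'   conformation per model.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  pdb <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE))
  }
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  confs <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms_to_conformation(atoms, xyz)
  })
  if (n_models == 1) confs[[1]] else confs
}

atoms_to_conformation <- function(atoms, xyz) {
  if (!is.null(atoms$alt)) {
    alt <- atoms$alt
    alt[is.na(alt)] <- ""
    keep <- alt %in% c("", "A", ".")
    if (any(!keep)) {
      warning("alternate locations present; keeping the first", call. = FALSE)
      atoms <- atoms[keep, , drop = FALSE]
      xyz <- xyz[keep, , drop = FALSE]
    }
  }
  chain <- atoms$chain
  chain[is.na(chain)] <- "A"
  key <- paste(chain, atoms$resno)
  keys <- unique(key)
  rows <- list()
  for (k in keys) {
    sel <- which(key == k)
    resid <- atoms$resid[sel[1]]
    type <- sub("^R", "", toupper(trimws(resid)))
    if (!type %in% RNA_TYPES) {
      warning("skipping non-RNA residue ", resid, " at ", chain[sel[1]], "/",
              atoms$resno[sel[1]], call. = FALSE)
      next
    }
    want <- bead_names(type)
    elety <- gsub("^\"(.*)\"$|^'(.*)'$", "\\1\\2", trimws(atoms$elety[sel]))
    idx <- match(want, elety)
    if (anyNA(idx))
      stop("residue ", chain[sel[1]], "/", atoms$resno[sel[1]], " (", type,
           ") lacks atom ", want[which(is.na(idx))[1]], call. = FALSE)
    sel <- sel[idx]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chain = chain[sel], res_number = atoms$resno[sel], res_type = type,
      bead = want, x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3])
  }
  if (!length(rows)) stop("no RNA residues found", call. = FALSE)
  cg_conformation(dplyr::bind_rows(rows))
}

#' Write a conformation to PDB or PDBx/mmCIF
#'
#' @param conf a [cg_conformation()].
#' @param path output file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return the path, invisibly.  `read_structure(write_structure(conf))`
#'   reproduces the conformation (coordinates within 1e-3 A).
#' @export
write_structure <- function(conf, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "pdb") {
    n <- nrow(conf)
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(coords_matrix(conf))),
                     type = rep("ATOM", n),
                     eleno = seq_len(n),
                     resno = conf$res_number,
                     chain = conf$chain,
                     resid = conf$res_type,
                     elety = conf$bead,
                     o = rep(1, n), b = rep(0, n))
  } else {
    write_mmcif(conf, path)
  }
  invisible(path)
}

write_mmcif <- function(conf, path) {
  quote_tok <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  res_seq <- cumsum(!duplicated(paste(conf$chain, conf$res_number)))
  # the standard RCSB _atom_site column order
  lines <- c(
    "data_model",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            seq_len(nrow(conf)),
            substr(conf$bead, 1, 1),
            quote_tok(conf$bead),
            conf$res_type,
            conf$chain,
            res_seq,
            conf$x, conf$y, conf$z,
            conf$res_number,
            conf$res_type,
            conf$chain,
            quote_tok(conf$bead)),
    "#")
  writeLines(lines, path)
  invisible(path)
}
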