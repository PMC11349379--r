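#' @include AllClasses.R constructors.R
NULL

#' Read an assembly model from mmCIF or PDB
#'
#' Loads all polymer chains, keeping author residue numbering (the numbering
#' residue-level cross-link identifications use) and the B-factor column as
#' per-residue confidence. Multi-model files trigger a warning and only the
#' first model is used.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @return an [AssemblyModel].
#' @export
readStructure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif")
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)),
    error = function(e) stop("could not parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (format == "pdb" && any(grepl("^MODEL", readLines(path, warn = FALSE))))
    nmodels <- max(nmodels, sum(grepl("^MODEL", readLines(path, warn = FALSE))))
  if (nmodels > 1L)
    warning("multi-model file; using the first model only")
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no polymer (ATOM) records in ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1)
  assemblyModel(
    data.frame(chain = as.character(a$chain), resno = as.integer(a$resno),
               resid = as.character(a$resid), elety = as.character(a$elety),
               element = toupper(trimws(as.character(elem))),
               x = a$x, y = a$y, z = a$z, b = as.numeric(a$b),
               stringsAsFactors = FALSE),
    source = path, model = 1L)
}

#' Write an assembly model to mmCIF or PDB
#'
#' The mmCIF writer emits a minimal `atom_site` loop (coordinates to 1e-4
#' Angstrom, so round-trips are exact to well under 1e-3). PDB output goes
#' through [bio3d::write.pdb()] and requires single-character chain ids.
#'
#' @param model an [AssemblyModel].
#' @param path output path.
#' @param format `"auto"`, `"mmcif"` or `"pdb"`.
#' @return invisibly `path`.
#' @export
writeStructure <- function(model, path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  a <- atoms(model)
  if (format == "pdb") {
    if (any(nchar(a$chain) > 1L))
      stop("PDB output requires single-character chain ids; use mmCIF")
    bio3d::write.pdb(file = path, xyz = as.numeric(t(a[, c("x", "y", "z")])),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety, eleno = seq_len(nrow(a)),
                     o = rep(1, nrow(a)), b = ifelse(is.na(a$b), 0, a$b),
                     elesy = a$element)
    return(invisible(path))
  }
  hdr <- c("data_xlinkfit", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_comp_id",
                                   "label_asym_id", "label_entity_id",
                                   "label_seq_id", "pdbx_PDB_ins_code",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy", "B_iso_or_equiv",
                                   "auth_seq_id", "auth_comp_id",
                                   "auth_asym_id", "auth_atom_id",
                                   "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d %s %s %s %s 1 %d ? %.4f %.4f %.4f 1.00 %.2f %d %s %s %s 1",
    seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, ifelse(is.na(a$b), 0, a$b), a$resno, a$resid, a$chain,
    a$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Read residue-pair cross-links from CSV
#'
#' Expects the residue-pair export dialect with required columns `Protein1`,
#' `Residue1`, `Protein2`, `Residue2` (case-insensitive header match) and
#' optional `Score` and `Decoy` columns. Decoy rows (`Decoy` true/TRUE/1) are
#' dropped; rows whose residue fields do not parse as positive integers are
#' rejected with their row indices reported in a warning.
#'
#' @param path CSV path.
#' @return an [XLinkSet].
#' @export
readCrossLinks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(tab))
  need <- c("protein1", "residue1", "protein2", "residue2")
  if (!all(need %in% nm))
    stop("cross-link CSV is missing required column(s): ",
         paste(setdiff(need, nm), collapse = ", "))
  col <- function(k) tab[[which(nm == k)[1]]]
  if ("decoy" %in% nm) {
    dec <- tolower(trimws(as.character(col("decoy"))))
    keep <- !(dec %in% c("true", "t", "1", "yes"))
    tab <- tab[keep, , drop = FALSE]
  }
  r1 <- suppressWarnings(as.integer(as.character(col("residue1"))))
  r2 <- suppressWarnings(as.integer(as.character(col("residue2"))))
  bad <- which(is.na(r1) | is.na(r2) | r1 <= 0 | r2 <= 0)
  if (length(bad)) {
    warning("rejected ", length(bad), " row(s) with unparseable residue ",
            "numbers: ", paste(bad, collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
    r1 <- r1[-bad]; r2 <- r2[-bad]
  }
  score <- if ("score" %in% nm) as.numeric(col("score")) else NA_real_
  xlinkSet(col("protein1"), r1, col("protein2"), r2, score)
}

#' Write cross-links in the residue-pair CSV dialect
#'
#' Emits the column layout [readCrossLinks()] expects (`Protein1`,
#' `Residue1`, `Protein2`, `Residue2`, `Score`).
#'
#' @param xlinks an [XLinkSet].
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
writeCrossLinks <- function(xlinks, path) {
  l <- linkTable(xlinks)
  utils::write.csv(data.frame(Protein1 = l$protein1, Residue1 = l$residue1,
                              Protein2 = l$protein2, Residue2 = l$residue2,
                              Score = l$score), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write chain maps as YAML
#'
#' The YAML layout is a `chains` list with `chain`, `protein`, `copy`,
#' `subcomplex` and optional `unit` keys per entry.
#'
#' @param path YAML path.
#' @return [readChainMap()] a [ChainMap]; [writeChainMap()] invisibly `path`.
#' @export
readChainMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  entries <- y$chains %||% y
  m <- do.call(rbind, lapply(entries, function(e) {
    data.frame(chain = as.character(e$chain), protein = as.character(e$protein),
               copy = as.integer(e$copy),
               subcomplex = as.character(e$subcomplex %||% "other"),
               unit = as.integer(e$unit %||% NA_integer_),
               stringsAsFactors = FALSE)
  }))
  chainMap(m)
}

#' @rdname readChainMap
#' @param map a [ChainMap].
#' @export
writeChainMap <- function(map, path) {
  m <- chainMapTable(map)
  entries <- lapply(seq_len(nrow(m)), function(i) {
    e <- list(chain = m$chain[i], protein = m$protein[i], copy = m$copy[i],
              subcomplex = m$subcomplex[i])
    if (!is.na(m$unit[i])) e$unit <- m$unit[i]
    e
  })
  yaml::write_yaml(list(chains = entries), path)
  invisible(path)
}

## ---- MRC/CCP4 density maps ---------------------------------------------
## Minimal mode-2 (float32) reader/writer; x is the fast axis (MAPC/R/S =
## 1,2,3). The ORIGIN header words carry the position of voxel (1,1,1).

#' Read a density map in MRC/CCP4 format
#'
#' Supports mode 2 (32-bit float) maps with column order 1,2,3. Voxel size
#' is taken from the cell dimensions over the sampling grid; origin from the
#' ORIGIN header words, falling back to NC/NR/NS-START times the voxel.
#'
#' @param path MRC file path.
#' @return a [DensityGrid].
#' @export
readDensity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]; m <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")   # angles
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")   # dmin/max/mean
  readBin(con, "integer", n = 2, size = 4, endian = "little")   # ispg, nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little")  # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(!is.finite(c(nx, ny, nz))) || nx < 1 || ny < 1 || nz < 1 ||
      nx > 4096 || ny > 4096 || nz > 4096)
    stop("corrupt MRC header: bad grid dimensions")
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2)")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order ", paste(mapcrs, collapse = ","))
  if (any(m < 1) || any(!is.finite(cella)) || any(cella <= 0))
    stop("corrupt MRC header: bad cell/sampling")
  vox <- cella / m
  if (max(vox) - min(vox) > 1e-4 * max(vox))
    stop("anisotropic voxels are not supported")
  seek(con, 1024)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  if (length(vals) < nx * ny * nz) stop("truncated MRC data block")
  origin <- if (any(orig != 0)) orig else nstart * vox[1]
  densityGrid(array(vals, dim = c(nx, ny, nz)), vox[1], origin)
}

#' Write a density map in MRC/CCP4 format (mode 2)
#'
#' @param grid a [DensityGrid].
#' @param path output path.
#' @return invisibly `path`.
#' @export
writeDensity <- function(grid, path) {
  d <- gridData(grid)
  dm <- dim(d)
  vox <- voxelSize(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dm, 2L, 0L, 0L, 0L, dm)), con, size = 4,
           endian = "little")
  writeBin(c(dm * vox, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(c(min(d), max(d), mean(d)), con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")
  writeBin(integer(25), con, size = 4, endian = "little")
  writeBin(as.numeric(gridOrigin(grid)), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(c(0x44L, 0x44L, 0x00L, 0x00L), con, size = 1)   # little-endian stamp
  writeBin(stats::sd(as.numeric(d)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(d), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a distance-validation report as TSV
#'
#' @param reports data.frame of per-link reports (see [validateCrossLinks()]).
#' @param path output path.
#' @return invisibly `path`.
#' @export
writeReport <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write classified cross-links as a ChimeraX pseudobond file
#'
#' One atom-pair specifier per mapped link, coloured green when satisfied and
#' purple when violated (rescued links are annotated in a trailing comment).
#' Unmapped links are skipped.
#'
#' @param reports data.frame of per-link reports (see [validateCrossLinks()]).
#' @param path output `.pb` path.
#' @return invisibly `path`.
#' @export
writePseudobonds <- function(reports, path) {
  r <- reports[reports$status != "unmapped", , drop = FALSE]
  lines <- c("; pseudobonds from xlinkfit",
             "; green = satisfied, purple = violated")
  if (nrow(r)) {
    col <- ifelse(r$status == "satisfied", "green", "purple")
    note <- ifelse(!is.na(r$rescued) & r$rescued, " ; rescued", "")
    lines <- c(lines, sprintf("/%s:%d@CA /%s:%d@CA %s%s",
                              r$chain1, r$residue1, r$chain2, r$residue2,
                              col, note))
  }
  writeLines(lines, path)
  invisible(path)
}
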