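#' Single-chain C-alpha structure model
#'
#' Container for one chain of a predicted (or experimental) structure reduced
#' to its C-alpha trace: residue numbers in author numbering, one-letter
#' sequence, C-alpha coordinates, and the per-residue confidence score
#' (pLDDT, 0-100) that AlphaFold-style models store in the B-factor column.
#' All downstream computations in this package are C-alpha-only, so nothing
#' else is retained.
#'
#' @param entry_id Identifier for the entry (e.g. a UniProt or PDB code).
#' @param chain_id Chain identifier.
#' @param resno Integer vector of author residue numbers, strictly increasing.
#' @param sequence One-letter amino-acid string of the same length.
#' @param ca Numeric matrix with one row per residue and columns x, y, z (A).
#' @param plddt Numeric vector of per-residue confidence scores in [0, 100].
#'
#' @return An object of class `"structure_model"`: a list with the fields
#'   above, validated for equal lengths, strictly increasing numbering and
#'   pLDDT within range.
#' @export
structure_model <- function(entry_id, chain_id, resno, sequence, ca, plddt) {
  resno <- as.integer(resno)
  plddt <- as.numeric(plddt)
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  n <- length(resno)
  if (n < 1L) stop("empty model: at least one residue required")
  if (nchar(sequence) != n || nrow(ca) != n || length(plddt) != n)
    stop("resno, sequence, ca and plddt must describe the same residues")
  if (ncol(ca) != 3L) stop("ca must be an n x 3 coordinate matrix")
  if (any(!is.finite(ca))) stop("non-finite C-alpha coordinates")
  if (any(diff(resno) <= 0L)) stop("residue numbers must be strictly increasing")
  if (any(!is.finite(plddt)) || any(plddt < 0) || any(plddt > 100))
    stop("plddt values must be finite and within [0, 100]")
  structure(list(entry_id = as.character(entry_id),
                 chain_id = as.character(chain_id),
                 resno = resno,
                 sequence = sequence,
                 ca = ca,
                 plddt = plddt),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s chain %s: %d residues (%d-%d), mean pLDDT %.1f\n",
              x$entry_id, x$chain_id, length(x$resno),
              x$resno[1], x$resno[length(x$resno)], mean(x$plddt)))
  invisible(x)
}

#' Number of residues in a structure model
#' @param model A `structure_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(model) length(model$resno)

#' Read a predicted model into a C-alpha structure model
#'
#' Parses a PDB or mmCIF file (dispatched on file extension; `.cif` /
#' `.mmcif` go through the mmCIF reader) and extracts one chain as a
#' [structure_model()]. The per-residue confidence is taken from the B-factor
#' of each residue's C-alpha atom, following the AlphaFold Protein Structure
#' Database convention of writing pLDDT into the B-factor column. Residues
#' without a C-alpha atom are skipped with a warning; B-factors outside
#' [0, 100] are clipped with a warning so that non-AFDB files (real
#' crystallographic B-factors) can still be read.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param chain Chain identifier; default `NULL` takes the first chain.
#' @param entry_id Entry identifier stored on the model; defaults to the file
#'   base name.
#' @return A `structure_model`.
#' @export
read_structure_model <- function(path, chain = NULL, entry_id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("unparseable PDB/mmCIF file '", path, "': ",
                             conditionMessage(e)))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) {
    chains <- unique(atoms$chain)
    if (length(chains) == 0L) stop("no protein chain found in ", path)
    chain <- chains[1]
  }
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty input: no residues in chain '", chain, "' of ", path)
  # drop altloc duplicates, keep first occurrence per residue/atom name
  key <- paste(atoms$resno, atoms$insert, atoms$elety)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  all_res <- unique(atoms$resno)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("empty input: chain '", chain, "' has no C-alpha atoms")
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0L)
    warning(sprintf("skipping %d residue(s) without a C-alpha atom in chain %s",
                    length(missing_ca), chain))
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  plddt <- as.numeric(ca$b)
  if (any(plddt < 0 | plddt > 100, na.rm = TRUE)) {
    warning("B-factor values outside [0, 100]; clipping to the pLDDT range")
    plddt <- pmin(pmax(plddt, 0), 100)
  }
  plddt[is.na(plddt)] <- 0
  seq1 <- paste(bio3d::aa321(ca$resid), collapse = "")
  structure_model(entry_id = entry_id %||% tools::file_path_sans_ext(basename(path)),
                  chain_id = chain,
                  resno = ca$resno,
                  sequence = seq1,
                  ca = cbind(x = ca$x, y = ca$y, z = ca$z),
                  plddt = plddt)
}

#' Write a structure model as a C-alpha-only PDB file
#'
#' Emits fixed-width `ATOM` records with one C-alpha per residue and the
#' pLDDT score in the B-factor column (formatted to two decimals, so 100
#' serialises as `100.00`), followed by `TER`/`END`. Author residue numbering
#' is preserved verbatim.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure_model <- function(model, path) {
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  if (any(!is.finite(model$ca))) stop("non-finite coordinates cannot be written")
  aa3 <- bio3d::aa123(strsplit(model$sequence, "")[[1]])
  n <- length(model$resno)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), aa3, substr(model$chain_id, 1, 1), model$resno,
    model$ca[, 1], model$ca[, 2], model$ca[, 3], 1.00, model$plddt)
  ter <- sprintf("TER   %5d      %3s %1s%4d", n + 1L, aa3[n],
                 substr(model$chain_id, 1, 1), model$resno[n])
  writeLines(c(lines, ter, "END"), path)
  invisible(path)
}

#' Read a per-residue crosspeak-intensity table
#'
#' Tab-separated table with columns `residue`, `intensity_free`,
#' `intensity_bound`; the string `NA` marks unassigned residues.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with integer `residue` and numeric intensity columns.
#' @export
read_intensity_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA")
  need <- c("residue", "intensity_free", "intensity_bound")
  if (!all(need %in% names(tab)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  tab$residue <- as.integer(tab$residue)
  tab$intensity_free <- as.numeric(tab$intensity_free)
  tab$intensity_bound <- as.numeric(tab$intensity_bound)
  if (any(tab$intensity_free < 0 | tab$intensity_bound < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tab[order(tab$residue), need]
}

#' Write a per-residue crosspeak-intensity table
#' @param tab Data frame with columns `residue`, `intensity_free`,
#'   `intensity_bound`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_intensity_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
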