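#' Assemble domain calls from rigid units
#'
#' Turns a domain-level partition of the structured segments into one
#' [domain_call()] per unit. Member segment ranges that are sequence-adjacent
#' (no residue between them) are merged into one range; non-adjacent member
#' ranges are kept separate — split-domain candidates that
#' [detect_split_domains()] later flags. Calls are numbered `D1, D2, ...` in
#' order of their first residue.
#'
#' @param membership Integer vector assigning each structured segment to a
#'   domain-level unit (from [rigid_assemblies()]).
#' @param segments Data frame of the structured segments (`start`, `end`).
#' @return List of [domain_call()] objects.
#' @export
call_domains <- function(membership, segments) {
  if (length(membership) != nrow(segments))
    stop("membership and segments disagree in length")
  units <- split(seq_len(nrow(segments)), membership)
  first <- vapply(units, function(ix) min(segments$start[ix]), numeric(1))
  units <- units[order(first)]
  calls <- lapply(seq_along(units), function(k) {
    ix <- units[[k]][order(segments$start[units[[k]]])]
    st <- segments$start[ix]; en <- segments$end[ix]
    # merge sequence-adjacent member ranges
    keep_st <- st[1]; keep_en <- en[1]
    for (i in seq_along(st)[-1]) {
      if (st[i] == keep_en[length(keep_en)] + 1L)
        keep_en[length(keep_en)] <- en[i]
      else { keep_st <- c(keep_st, st[i]); keep_en <- c(keep_en, en[i]) }
    }
    domain_call(sprintf("D%d", k), residue_ranges(keep_st, keep_en))
  })
  calls
}

#' Flag split domains and attach part fractions
#'
#' A call whose consecutive ranges are all separated by at least
#' `min_insertion` residues is flagged as a split domain: one spatial unit
#' whose sequence is interrupted by a long insertion. Part fractions (each
#' range's share of the domain length) are stored exactly; for display they
#' are rounded to the nearest quarter by [fraction_display()] (a 90 + 30
#' residue split RWD displays as 3/4 RWD + 1/4 RWD). Calls with shorter gaps keep
#' their ranges but are not flagged — the diagram draws them as one merged
#' box.
#'
#' @param calls List of [domain_call()] objects.
#' @param min_insertion Minimum insertion length in residues (default 30).
#' @return The list of calls with `split` flags set.
#' @export
detect_split_domains <- function(calls, min_insertion = 30L) {
  lapply(calls, function(d) {
    if (nrow(d$ranges) < 2L) { d$split <- FALSE; return(d) }
    gaps <- d$ranges$start[-1] - d$ranges$end[-nrow(d$ranges)] - 1L
    d$split <- all(gaps >= min_insertion)
    d
  })
}

#' Extract a sub-model covering a set of residue ranges
#'
#' @param model A [structure_model()].
#' @param ranges Data frame of residue ranges in author numbering.
#' @return A `structure_model` restricted to those residues.
#' @export
extract_region <- function(model, ranges) {
  keep <- which(model$resno %in% range_residues(residue_ranges(ranges$start,
                                                               ranges$end)))
  if (length(keep) < 1L) stop("no model residues inside the requested ranges")
  structure_model(model$entry_id, model$chain_id, model$resno[keep],
                  paste(strsplit(model$sequence, "")[[1]][keep], collapse = ""),
                  model$ca[keep, , drop = FALSE], model$plddt[keep])
}

#' Label a domain call by superposition onto a reference structure
#'
#' Extracts the call's residues from the model, pairs them with reference
#' residues (by global sequence alignment via [pair_by_sequence()] unless an
#' explicit pairing is supplied), runs [core_superpose()], and attaches the
#' homology label together with the core RMSD and core atom count. With
#' fewer than 20 residue pairs the labelling is skipped with a warning and
#' the call is returned unchanged.
#'
#' @param call A [domain_call()].
#' @param model The query [structure_model()] the call refers to.
#' @param reference The reference `structure_model` (e.g. an experimental
#'   structure of the candidate domain).
#' @param label Homology label to attach on success.
#' @param pairing Optional data frame with columns `a` (query residue
#'   numbers) and `b` (reference residue numbers); overrides sequence
#'   alignment for remote homologs.
#' @param ... Passed to [core_superpose()].
#' @return The updated `domain_call`; on success `label_rmsd` and
#'   `label_core_atoms` are filled in.
#' @export
label_by_reference <- function(call, model, reference, label,
                               pairing = NULL, ...) {
  region <- extract_region(model, call$ranges)
  if (is.null(pairing)) {
    pr <- pair_by_sequence(region$sequence, reference$sequence)
    pairing <- data.frame(a = region$resno[pr$a], b = reference$resno[pr$b])
  }
  ia <- match(pairing$a, region$resno)
  ib <- match(pairing$b, reference$resno)
  ok <- !is.na(ia) & !is.na(ib)
  if (sum(ok) < 20L) {
    warning("labelling skipped: only ", sum(ok),
            " residue pairs map onto the reference (>= 20 required)")
    return(call)
  }
  fit <- core_superpose(region$ca[ia[ok], , drop = FALSE],
                        reference$ca[ib[ok], , drop = FALSE], ...)
  call$label <- as.character(label)
  call$label_rmsd <- fit$rmsd
  call$label_core_atoms <- fit$n_core
  call
}

#' Packaged reference architecture ranges
#'
#' Loads the packaged table of reference domain ranges for the human PARP
#' family transcribed from published results (quoted residue ranges only;
#' ranges not quoted in text are marked approximate). Intended as a
#' regression reference for [compare_architecture()].
#'
#' @return Named list: one data frame per entry with columns `label`,
#'   `start`, `end`, `approximate`.
#' @export
parp_reference_ranges <- function() {
  path <- system.file("extdata", "parp_reference_ranges.json",
                      package = "afdomains", mustWork = TRUE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js$entries
}

#' Controlled vocabulary of domain labels
#'
#' The domain and motif nomenclature used for architecture labels (HD vs HE,
#' C4 vs C4*, CCHC/CCCH zinc fingers, MZAP/NZAP, MVPID, ...), with one-line
#' descriptions.
#'
#' @return Data frame with columns `label` and `description`.
#' @export
known_domain_labels <- function() {
  path <- system.file("extdata", "domain_vocabulary.tsv",
                      package = "afdomains", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
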